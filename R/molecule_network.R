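#' Create a molecule network
#'
#' An undirected simple graph over gene identifiers (e.g. a protein-protein
#' interaction network), the reference network for the linkage algorithm.
#' Self-loops are dropped (and counted) and duplicate edges collapsed; each
#' unordered pair is stored once in canonical lexicographic order.
#'
#' @param from,to Character vectors of endpoint gene ids (recycled pairwise).
#' @param nodes Optional additional isolated nodes to retain.
#' @return An object of class `molecule_network` with fields `nodes` (sorted),
#'   `edges` (data.frame `from`/`to`, `from < to`), and
#'   `n_self_loops_dropped`.
#' @export
molecule_network <- function(from = character(), to = character(),
                             nodes = character()) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) stopf("from and to must have equal length")
  self <- from == to
  n_self <- sum(self)
  from <- from[!self]
  to <- to[!self]
  cp <- canonical_pair(from, to)
  keep <- !duplicated(paste(cp$a, cp$b, sep = "\r"))
  edges <- data.frame(from = cp$a[keep], to = cp$b[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  all_nodes <- sort(unique(c(edges$from, edges$to, as.character(nodes))))
  structure(list(nodes = all_nodes, edges = edges,
                 n_self_loops_dropped = n_self),
            class = "molecule_network")
}

#' @export
print.molecule_network <- function(x, ...) {
  cat(sprintf("Molecule network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a molecular-interaction network
#'
#' Reads an undirected simple graph from either a two-column whitespace- or
#' tab-delimited edge list (`tsv`) or a SIF file (`node relation target...`,
#' one or more targets per line). Self-loops are dropped with a logged count;
#' duplicate edges (either orientation) are collapsed.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"sif"`.
#' @return A [molecule_network()].
#' @export
read_molecule_network <- function(path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  from <- character(0)
  to <- character(0)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "[\t ]+")[[1]]
    if (dialect == "tsv") {
      if (length(tok) < 2L) stopf("line %d: fewer than 2 node ids", i)
      from <- c(from, tok[[1]])
      to <- c(to, tok[[2]])
    } else {
      if (length(tok) < 3L) stopf("line %d: SIF record needs node, relation, target", i)
      targets <- tok[-(1:2)]
      from <- c(from, rep(tok[[1]], length(targets)))
      to <- c(to, targets)
    }
  }
  net <- molecule_network(from, to)
  if (net$n_self_loops_dropped > 0) {
    message(sprintf("read_molecule_network: dropped %d self-loop(s)",
                    net$n_self_loops_dropped))
  }
  net
}

#' Write a molecule network as a two-column TSV edge list
#'
#' @param network A [molecule_network()].
#' @param path Output path.
#' @export
write_molecule_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Restrict a molecule network to a node universe (linkage step 1).
restrict_network <- function(network, universe) {
  keep <- network$edges$from %in% universe & network$edges$to %in% universe
  edges <- network$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = intersect(network$nodes, universe), edges = edges,
                 n_self_loops_dropped = 0L),
            class = "molecule_network")
}
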
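#' Construct a gene set network object
#'
#' An undirected simple network over gene set ids. Edges carry their
#' contingency counts and raw/BH-adjusted p-values; isolated sets are kept as
#' nodes. Edge endpoints are stored in canonical lexicographic order.
#'
#' @param nodes Character vector of gene set ids (includes isolated sets).
#' @param edges data.frame with columns `set_a`, `set_b` and optionally `a`,
#'   `b`, `c`, `d`, `p_raw`, `q_bh`.
#' @param edge_type One of `"co_membership"`, `"linkage"`, `"co_enrichment"`,
#'   or a free-form type for archived networks.
#' @param collection_id Identifier of the underlying collection.
#' @param tests Optional data.frame of all pair tests performed (one row per
#'   unordered pair, significant or not).
#' @return An object of class `gene_set_network`.
#' @export
gene_set_network <- function(nodes, edges, edge_type,
                             collection_id = "collection", tests = NULL) {
  nodes <- sort(unique(as.character(nodes)))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(set_a = character(0), set_b = character(0),
                        a = integer(0), b = integer(0), c = integer(0),
                        d = integer(0), p_raw = numeric(0), q_bh = numeric(0),
                        stringsAsFactors = FALSE)
  } else {
    if (any(edges$set_a == edges$set_b)) stopf("self-edges are not allowed")
    cp <- canonical_pair(as.character(edges$set_a), as.character(edges$set_b))
    edges$set_a <- cp$a
    edges$set_b <- cp$b
    if (anyDuplicated(paste(edges$set_a, edges$set_b, sep = "\r"))) {
      stopf("parallel edges are not allowed")
    }
    for (col in c("a", "b", "c", "d", "p_raw", "q_bh")) {
      if (is.null(edges[[col]])) edges[[col]] <- NA_real_
    }
    edges <- edges[order(edges$set_a, edges$set_b),
                   c("set_a", "set_b", "a", "b", "c", "d", "p_raw", "q_bh"),
                   drop = FALSE]
    rownames(edges) <- NULL
    missing_nodes <- setdiff(unique(c(edges$set_a, edges$set_b)), nodes)
    if (length(missing_nodes) > 0) {
      stopf("edge endpoints not in node set: %s",
            paste(missing_nodes, collapse = ", "))
    }
  }
  structure(list(collection_id = collection_id, edge_type = edge_type,
                 nodes = nodes, edges = edges, tests = tests,
                 n_tests = if (is.null(tests)) NA_integer_ else nrow(tests)),
            class = "gene_set_network")
}

#' @export
print.gene_set_network <- function(x, ...) {
  cat(sprintf("Gene set network [%s] over '%s': %d nodes, %d edges",
              x$edge_type, x$collection_id, length(x$nodes), nrow(x$edges)))
  if (!is.na(x$n_tests)) cat(sprintf(" (%d pair tests)", x$n_tests))
  cat("\n")
  invisible(x)
}

edge_keys <- function(network) {
  paste(network$edges$set_a, network$edges$set_b, sep = "\r")
}

#' Node degrees of a gene set network
#'
#' @param network A [gene_set_network()].
#' @return Named integer vector over all nodes (isolated nodes have degree 0).
#' @export
gsn_degree <- function(network) {
  deg <- stats::setNames(integer(length(network$nodes)), network$nodes)
  tab <- table(c(network$edges$set_a, network$edges$set_b))
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Read an archived gene set network
#'
#' Reads tab-delimited network dumps: rows of `set_a`, `set_b` followed by
#' one or more numeric columns. Two layouts are sniffed automatically: a
#' 3-column layout (`set_a, set_b, p_raw`) and the full 8-column layout
#' written by [write_gene_set_network()] (`set_a, set_b, p_raw, q_bh, a,
#' margin_a, margin_b, total`). Leading `#`-comment lines may declare
#' metadata (`#collection`, `#edge_type`) and isolated nodes (`#node<TAB>id`).
#' Duplicate rows (either orientation) are collapsed; self-edge rows are
#' rejected with a warning.
#'
#' @param path Path to the file.
#' @param edge_type Edge type to record when the file does not declare one.
#' @return A [gene_set_network()].
#' @export
read_gene_set_network_archive <- function(path, edge_type = "archived") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  meta <- lines[startsWith(lines, "#")]
  data <- lines[!startsWith(lines, "#")]

  collection_id <- "archive"
  declared_nodes <- character(0)
  for (m in meta) {
    tok <- strsplit(sub("^#", "", m), "\t", fixed = TRUE)[[1]]
    if (length(tok) < 2L) next
    key <- trimws(tok[[1]])
    if (key == "node") declared_nodes <- c(declared_nodes, tok[[2]])
    if (key == "collection") collection_id <- tok[[2]]
    if (key == "edge_type") edge_type <- tok[[2]]
  }

  if (length(data) == 0L) {
    return(gene_set_network(declared_nodes, NULL, edge_type, collection_id))
  }

  first <- strsplit(data[[1]], "\t", fixed = TRUE)[[1]]
  has_header <- length(first) >= 3L &&
    is.na(suppressWarnings(as.numeric(first[[3]])))
  df <- utils::read.table(text = paste(data, collapse = "\n"), sep = "\t",
                          header = has_header, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 3L) stopf("archive rows need set_a, set_b and a p-value column")
  if (has_header && !all(c("set_a", "set_b", "p_raw") %in% names(df))) {
    stopf("non-numeric p column or unrecognized header in %s", path)
  }
  if (!has_header) {
    names(df) <- if (ncol(df) >= 8L) {
      c("set_a", "set_b", "p_raw", "q_bh", "a", "margin_a", "margin_b",
        "total", names(df)[-seq_len(8)])
    } else {
      c("set_a", "set_b", "p_raw", names(df)[-seq_len(3)])
    }
  }
  num_cols <- setdiff(names(df), c("set_a", "set_b"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v) & !is.na(df[[col]]) & !(df[[col]] %in% c("NA", "")))) {
      stopf("non-numeric value in column '%s'", col)
    }
    df[[col]] <- v
  }

  self <- df$set_a == df$set_b
  if (any(self)) {
    warnf("rejected %d self-edge row(s)", sum(self))
    df <- df[!self, , drop = FALSE]
  }
  cp <- canonical_pair(df$set_a, df$set_b)
  df$set_a <- cp$a
  df$set_b <- cp$b
  df <- df[!duplicated(paste(df$set_a, df$set_b, sep = "\r")), , drop = FALSE]

  edges <- data.frame(set_a = df$set_a, set_b = df$set_b,
                      p_raw = df$p_raw, stringsAsFactors = FALSE)
  edges$q_bh <- if (!is.null(df$q_bh)) df$q_bh else rep(NA_real_, nrow(edges))
  if (!is.null(df$a) && !is.null(df$margin_a)) {
    edges$a <- df$a
    edges$b <- df$margin_a - df$a
    edges$c <- df$margin_b - df$a
    edges$d <- df$total - df$margin_a - df$margin_b + df$a
  }
  nodes <- unique(c(declared_nodes, edges$set_a, edges$set_b))
  gene_set_network(nodes, edges, edge_type, collection_id)
}

#' Write a gene set network
#'
#' Formats: `tsv` (self-describing archive layout, lossless round trip
#' through [read_gene_set_network_archive()]), `sif`
#' (`set_a et_<edge_type> set_b`), and `graphml` (node attribute: id; edge
#' attributes: edge_type, p_raw, q_bh, counts).
#'
#' @param network A [gene_set_network()].
#' @param path Output path.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @export
write_gene_set_network <- function(network, path,
                                   format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  e <- network$edges
  if (format == "tsv") {
    meta <- c(sprintf("#collection\t%s", network$collection_id),
              sprintf("#edge_type\t%s", network$edge_type),
              sprintf("#node\t%s", network$nodes))
    header <- paste(c("set_a", "set_b", "p_raw", "q_bh", "a", "margin_a",
                      "margin_b", "total"), collapse = "\t")
    rows <- character(0)
    if (nrow(e) > 0) {
      rows <- paste(e$set_a, e$set_b, format_num(e$p_raw), format_num(e$q_bh),
                    format_num(e$a), format_num(e$a + e$b),
                    format_num(e$a + e$c),
                    format_num(e$a + e$b + e$c + e$d), sep = "\t")
    }
    writeLines(c(meta, header, rows), path)
  } else if (format == "sif") {
    rel <- paste0("et_", network$edge_type)
    writeLines(if (nrow(e) > 0) paste(e$set_a, rel, e$set_b) else character(0),
               path)
  } else {
    writeLines(graphml_document(
      nodes = data.frame(id = network$nodes, stringsAsFactors = FALSE),
      edges = data.frame(source = e$set_a, target = e$set_b,
                         edge_type = rep(network$edge_type, nrow(e)),
                         p_raw = e$p_raw, q_bh = e$q_bh,
                         a = e$a, b = e$b, c = e$c, d = e$d,
                         stringsAsFactors = FALSE)), path)
  }
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# Minimal GraphML writer for the package's fixed attribute schema.
graphml_document <- function(nodes, edges) {
  edge_attrs <- setdiff(names(edges), c("source", "target"))
  keydefs <- sprintf(
    '  <key id="%s" for="edge" attr.name="%s" attr.type="%s"/>',
    edge_attrs, edge_attrs,
    ifelse(edge_attrs == "edge_type", "string", "double"))
  node_lines <- sprintf('    <node id="%s"/>', xml_escape(nodes$id))
  edge_lines <- character(0)
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      datas <- vapply(edge_attrs, function(k) {
        v <- edges[[k]][[i]]
        if (is.na(v)) return("")
        sprintf('      <data key="%s">%s</data>', k,
                xml_escape(if (is.numeric(v)) format_num(v) else v))
      }, character(1))
      datas <- datas[nzchar(datas)]
      edge_lines <- c(edge_lines,
                      sprintf('    <edge source="%s" target="%s">',
                              xml_escape(edges$source[[i]]),
                              xml_escape(edges$target[[i]])),
                      datas, "    </edge>")
    }
  }
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    keydefs,
    '  <graph id="G" edgedefault="undirected">',
    node_lines, edge_lines,
    "  </graph>", "</graphml>")
}
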
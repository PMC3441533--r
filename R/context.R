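# Context-specific networks: enrichment of a user gene list and overlay of
# precomputed gene set networks.

#' Enrich a user gene list against a collection
#'
#' Intersects the user's genes with the collection universe, tests every set
#' with a one-sided Fisher's exact test over that universe, BH-corrects
#' across all sets in the collection, and sorts by q-value.
#'
#' @param collection A [gene_set_collection()].
#' @param user_genes Character vector of gene ids.
#' @param config A [build_config()] (uses `enrichment_alpha`).
#' @return data.frame (`set_id`, `a` .. `d`, `p_raw`, `q_bh`, `enriched`)
#'   sorted by increasing `q_bh` then `p_raw`.
#' @export
enrich_user_list <- function(collection, user_genes, config = build_config()) {
  genes <- intersect(unique(as.character(user_genes)), collection$universe)
  if (length(genes) == 0L) {
    stopf(paste("none of the input genes are in the collection universe;",
                "check that the identifiers match the collection's"))
  }
  res <- per_list_enrichment(collection$sets, genes, collection$universe,
                             config)
  res$list_id <- NULL
  res <- res[order(res$q_bh, res$p_raw, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build a context-specific multi-edge gene set network
#'
#' Takes the sets enriched in a user gene list and overlays all precomputed
#' gene set networks: context edges are exactly the precomputed edges with
#' both endpoints enriched (typed by their source network; no edges are
#' computed on the fly). A node is highlighted when its unique input genes
#' outnumber its input genes shared with any other enriched set: with
#' `I_S = user_genes` intersected with set S (within the universe),
#' `unique(S)` = members of `I_S` belonging to no other enriched set and
#' `shared_max(S)` = the maximum over other enriched sets T of
#' `|I_S intersect T|`, the node is highlighted iff
#' `|unique(S)| > shared_max(S)`. Enriched sets with no context edge are
#' reported as functionally disjoint.
#'
#' @param enriched The result of [enrich_user_list()] (its `enriched` rows
#'   are used) or a character vector of enriched set ids.
#' @param precomputed List of [gene_set_network()] objects over the same
#'   collection.
#' @param user_genes The user's gene list.
#' @param collection The underlying [gene_set_collection()].
#' @param comparator How "shared with any other gene set" is aggregated:
#'   `"max"` (default) compares against the single most-shared other set;
#'   `"sum"` compares against the total shared count.
#' @return An object of class `context_network`: `$nodes` (set_id, overlap,
#'   q_bh, highlight), `$edges` (set_a, set_b, edge_type, p_raw, q_bh),
#'   `$isolated_nodes`.
#' @export
build_context_network <- function(enriched, precomputed, user_genes,
                                  collection, comparator = c("max", "sum")) {
  comparator <- match.arg(comparator)
  if (is.data.frame(enriched)) {
    qs <- stats::setNames(enriched$q_bh, enriched$set_id)
    enriched <- enriched$set_id[enriched$enriched]
  } else {
    qs <- stats::setNames(rep(NA_real_, length(enriched)), enriched)
  }
  enriched <- unique(as.character(enriched))
  members <- set_members(collection)
  unknown <- setdiff(enriched, names(members))
  if (length(unknown)) {
    stopf("enriched set(s) not in collection: %s", paste(unknown, collapse = ", "))
  }
  genes <- intersect(unique(as.character(user_genes)), collection$universe)

  edge_rows <- list()
  for (net in precomputed) {
    e <- net$edges
    keep <- e$set_a %in% enriched & e$set_b %in% enriched
    if (any(keep)) {
      edge_rows[[length(edge_rows) + 1L]] <-
        data.frame(set_a = e$set_a[keep], set_b = e$set_b[keep],
                   edge_type = net$edge_type, p_raw = e$p_raw[keep],
                   q_bh = e$q_bh[keep], stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(set_a = character(0), set_b = character(0),
               edge_type = character(0), p_raw = numeric(0),
               q_bh = numeric(0), stringsAsFactors = FALSE)

  overlap_genes <- lapply(enriched, function(s) intersect(genes, members[[s]]))
  names(overlap_genes) <- enriched
  highlight <- vapply(enriched, function(s) {
    i_s <- overlap_genes[[s]]
    others <- setdiff(enriched, s)
    if (length(others) == 0L) {
      shared <- 0L
    } else {
      shared_counts <- vapply(others, function(t) {
        length(intersect(i_s, members[[t]]))
      }, integer(1))
      shared <- if (comparator == "max") max(shared_counts) else sum(shared_counts)
    }
    other_members <- unique(unlist(members[others], use.names = FALSE))
    n_unique <- length(setdiff(i_s, other_members))
    n_unique > shared
  }, logical(1))

  nodes <- data.frame(set_id = enriched,
                      overlap = lengths(overlap_genes),
                      q_bh = unname(qs[enriched]),
                      highlight = highlight, stringsAsFactors = FALSE)
  connected <- unique(c(edges$set_a, edges$set_b))
  structure(list(nodes = nodes, edges = edges,
                 isolated_nodes = setdiff(enriched, connected)),
            class = "context_network")
}

#' @export
print.context_network <- function(x, ...) {
  cat(sprintf("Context network: %d enriched sets (%d highlighted), %d typed edges, %d functionally disjoint\n",
              nrow(x$nodes), sum(x$nodes$highlight), nrow(x$edges),
              length(x$isolated_nodes)))
  invisible(x)
}

#' Write a context network
#'
#' `tsv` writes the typed edge table plus `#node` metadata; `sif` writes
#' `set_a et_<type> set_b` lines; `graphml` writes nodes with highlight flags
#' and typed multi-edges.
#'
#' @param x A [build_context_network()] result.
#' @param path Output path.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @export
write_context_network <- function(x, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  e <- x$edges
  if (format == "tsv") {
    meta <- sprintf("#node\t%s\t%d\t%s", x$nodes$set_id, x$nodes$overlap,
                    ifelse(x$nodes$highlight, "highlight", "plain"))
    header <- paste(c("set_a", "set_b", "edge_type", "p_raw", "q_bh"),
                    collapse = "\t")
    rows <- if (nrow(e)) paste(e$set_a, e$set_b, e$edge_type,
                               format_num(e$p_raw), format_num(e$q_bh),
                               sep = "\t") else character(0)
    writeLines(c(meta, header, rows), path)
  } else if (format == "sif") {
    writeLines(if (nrow(e)) paste(e$set_a, paste0("et_", e$edge_type), e$set_b)
               else character(0), path)
  } else {
    writeLines(graphml_document(
      nodes = data.frame(id = x$nodes$set_id, stringsAsFactors = FALSE),
      edges = data.frame(source = e$set_a, target = e$set_b,
                         edge_type = e$edge_type, p_raw = e$p_raw,
                         q_bh = e$q_bh, stringsAsFactors = FALSE)), path)
  }
  invisible(path)
}
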
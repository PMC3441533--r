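#' Compare two gene set networks over the same collection
#'
#' Counts shared and unique edges, tests the overlap for significance with a
#' one-sided Fisher's exact test over the `N(N-1)/2` possible gene set pairs,
#' and stratifies each network's edges by whether the underlying pair's
#' shared-gene percentage lies above or below the mean over all overlapping
#' set pairs in the collection (shared-gene percentage of a pair is
#' `100 |A intersect B| / |A union B|`).
#'
#' @param net_a,net_b [gene_set_network()] objects over the same node set.
#' @param collection The underlying [gene_set_collection()].
#' @return An object of class `network_comparison` with fields
#'   `shared_edges`, `unique_a`, `unique_b`, `possible_pairs`, `overlap_p`,
#'   `overlap_table`, `mean_shared_pct`, and `stratification` (data.frame:
#'   network, above_mean, below_mean).
#' @export
compare_networks <- function(net_a, net_b, collection) {
  if (!identical(sort(net_a$nodes), sort(net_b$nodes))) {
    stopf("networks have differing node sets")
  }
  n <- length(collection$sets)
  possible <- n * (n - 1) / 2
  ka <- edge_keys(net_a)
  kb <- edge_keys(net_b)
  shared <- length(intersect(ka, kb))
  ea <- length(ka)
  eb <- length(kb)
  tab <- contingency_table(shared, ea - shared, eb - shared,
                           possible - ea - eb + shared)
  overlap_p <- fisher_right_tail(tab)

  # shared-gene percentage for every overlapping pair in the collection
  members <- set_members(collection)
  ids <- names(members)
  px <- pair_indices(n)
  inter <- vapply(seq_along(px$i), function(q) {
    length(intersect(members[[px$i[q]]], members[[px$j[q]]]))
  }, integer(1))
  uni <- lengths(members)[px$i] + lengths(members)[px$j] - inter
  pct <- ifelse(uni > 0, 100 * inter / uni, 0)
  overlapping <- inter > 0
  mean_pct <- if (any(overlapping)) mean(pct[overlapping]) else NA_real_
  pct_by_key <- stats::setNames(pct, pair_key(ids[px$i], ids[px$j]))

  strat_row <- function(keys, label) {
    p <- pct_by_key[keys]
    data.frame(network = label,
               above_mean = sum(!is.na(p) & p > mean_pct),
               below_mean = sum(!is.na(p) & p <= mean_pct),
               stringsAsFactors = FALSE)
  }
  strat <- rbind(strat_row(ka, "net_a"), strat_row(kb, "net_b"))

  structure(list(shared_edges = shared, unique_a = ea - shared,
                 unique_b = eb - shared, possible_pairs = possible,
                 overlap_p = overlap_p, overlap_table = tab,
                 mean_shared_pct = mean_pct, stratification = strat),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf(paste0("Network comparison: %d shared edges, %d/%d unique, ",
                     "%d possible pairs, overlap p = %.3g\n"),
              x$shared_edges, x$unique_a, x$unique_b, x$possible_pairs,
              x$overlap_p))
  invisible(x)
}
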
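# Degree-preserving randomization and label-based edge statistics.

# Apply `n_swaps` accepted double-edge swaps to an edge data.frame
# (columns set_a/set_b over `nodes`). Swaps creating self-loops or parallel
# edges are rejected and re-drawn. Errors if the graph admits no valid swap.
rewire_edges <- function(edges, nodes, n_swaps, label = "network") {
  m <- nrow(edges)
  if (m < 2L) stopf("%s is too small to randomize (fewer than 2 edges)", label)
  idx <- match(c(edges$set_a, edges$set_b), nodes)
  ea <- idx[seq_len(m)]
  eb <- idx[m + seq_len(m)]
  nv <- length(nodes)
  adj <- matrix(FALSE, nv, nv)
  adj[cbind(ea, eb)] <- TRUE
  adj[cbind(eb, ea)] <- TRUE
  accepted <- 0L
  tries <- 0L
  max_tries <- 200L * n_swaps + 1000L
  while (accepted < n_swaps) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stopf("%s appears too rigid for edge swaps (%d accepted after %d proposals)",
            label, accepted, tries - 1L)
    }
    pick <- sample.int(m, 2L)
    i <- pick[[1]]; j <- pick[[2]]
    a <- ea[i]; b <- eb[i]; c <- ea[j]; d <- eb[j]
    if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
    # propose (a,d) and (c,b)
    if (a == d || c == b) next
    if (adj[a, d] || adj[c, b]) next
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c, d] <- adj[d, c] <- FALSE
    adj[a, d] <- adj[d, a] <- TRUE
    adj[c, b] <- adj[b, c] <- TRUE
    eb[i] <- d
    ea[j] <- c
    eb[j] <- b
    accepted <- accepted + 1L
  }
  data.frame(set_a = nodes[ea], set_b = nodes[eb], stringsAsFactors = FALSE)
}

# Build a lightweight gene_set_network from rewired edges (statistics only).
as_rewired_network <- function(template, edges) {
  cp <- canonical_pair(edges$set_a, edges$set_b)
  gene_set_network(template$nodes,
                   data.frame(set_a = cp$a, set_b = cp$b,
                              stringsAsFactors = FALSE),
                   template$edge_type, template$collection_id)
}

#' Edge-swap randomization test for a pairwise network statistic
#'
#' Generates `n_random` pairs of degree-preserving randomizations of the two
#' networks (each randomization applies `n_swaps` accepted double-edge swaps;
#' proposals creating self-loops or parallel edges are rejected and re-drawn)
#' and builds the null distribution of absolute differences
#' `|stat(randA) - stat(randB)|`. The p-value is the fraction of null values
#' at least as large as the observed absolute difference, reported as
#' `"< 1/n_random"` when that count is zero.
#'
#' @param net_a,net_b [gene_set_network()] objects.
#' @param statistic Function mapping a network to a single number.
#' @param n_random Number of random network pairs. Default 10000.
#' @param n_swaps Accepted swaps per randomized network. Default 1000.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `null_distribution` with fields `observed`,
#'   `null_values`, `n_random`, `n_swaps`, `p_value` (the plain fraction;
#'   0 when no null value reaches the observed difference) and `p_string`.
#' @export
edge_swap_null <- function(net_a, net_b, statistic, n_random = 10000,
                           n_swaps = 1000, seed = NULL) {
  observed <- abs(statistic(net_a) - statistic(net_b))
  run <- function() {
    null_values <- numeric(n_random)
    for (r in seq_len(n_random)) {
      ra <- as_rewired_network(net_a, rewire_edges(net_a$edges, net_a$nodes,
                                                   n_swaps, "net_a"))
      rb <- as_rewired_network(net_b, rewire_edges(net_b$edges, net_b$nodes,
                                                   n_swaps, "net_b"))
      null_values[r] <- abs(statistic(ra) - statistic(rb))
    }
    null_values
  }
  null_values <- if (is.null(seed)) run() else with_seed(seed, run())
  count <- sum(null_values >= observed)
  p <- count / n_random
  structure(list(observed = observed, null_values = null_values,
                 n_random = n_random, n_swaps = n_swaps, p_value = p,
                 p_string = if (count == 0L) sprintf("< %g", 1 / n_random)
                            else format(p)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Edge-swap null: observed |difference| = %.4g, p %s (%d random pairs, %d swaps each)\n",
              x$observed,
              if (startsWith(x$p_string, "<")) x$p_string else paste("=", x$p_string),
              x$n_random, x$n_swaps))
  invisible(x)
}

#' Label- and interaction-based edge statistics
#'
#' `same_label_pct`: percentage of network edges whose two endpoints carry
#' the same label (e.g. kinase/phosphatase family), among edges with both
#' endpoints labelled. `interacting_pct`: among edges whose two endpoint
#' entities each have at least one edge in the reference interaction network,
#' the percentage whose endpoint pair is itself an interaction edge.
#'
#' @param network A [gene_set_network()].
#' @param node_labels Named character vector: node id -> label.
#' @param ppi Optional [molecule_network()] of interactions between the node
#'   entities themselves.
#' @return List with `same_label_pct`, `n_scorable`, and (when `ppi` is
#'   given) `interacting_pct` and `n_eligible` (`interacting_pct` is `NA`
#'   when no edge is eligible).
#' @export
edge_label_statistics <- function(network, node_labels, ppi = NULL) {
  e <- network$edges
  scorable <- e$set_a %in% names(node_labels) & e$set_b %in% names(node_labels)
  if (!any(scorable)) stopf("network has no scorable edges (no labelled endpoint pairs)")
  la <- node_labels[e$set_a[scorable]]
  lb <- node_labels[e$set_b[scorable]]
  out <- list(same_label_pct = 100 * mean(la == lb),
              n_scorable = sum(scorable))
  if (!is.null(ppi)) {
    deg_nodes <- unique(c(ppi$edges$from, ppi$edges$to))
    eligible <- e$set_a %in% deg_nodes & e$set_b %in% deg_nodes
    if (!any(eligible)) {
      out$interacting_pct <- NA_real_
      out$n_eligible <- 0L
    } else {
      ppi_keys <- pair_key(ppi$edges$from, ppi$edges$to)
      keys <- pair_key(e$set_a[eligible], e$set_b[eligible])
      out$interacting_pct <- 100 * mean(keys %in% ppi_keys)
      out$n_eligible <- sum(eligible)
    }
  }
  out
}
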
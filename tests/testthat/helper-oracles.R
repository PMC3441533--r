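# Independent oracles and small fixture builders used across the suite.

# Brute-force right tail of the hypergeometric: direct combinatorial sum,
# independent of stats::phyper.
hyper_tail_oracle <- function(a, b, c, d) {
  K <- a + b          # white balls
  n_draw <- a + c     # draws
  N <- a + b + c + d
  lo <- max(0, n_draw - (N - K))
  hi <- min(K, n_draw)
  if (a <= lo) return(1)
  xs <- seq.int(max(a, lo), hi)
  if (length(xs) == 0) return(0)
  sum(choose(K, xs) * choose(N - K, n_draw - xs)) / choose(N, n_draw)
}

# Textbook step-up Benjamini-Hochberg, written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# k cliques of size `size`, consecutive cliques joined by one bridge edge.
bridged_cliques <- function(k, size) {
  nodes <- sprintf("c%d_%02d", rep(seq_len(k), each = size), seq_len(size))
  edges <- do.call(rbind, lapply(seq_len(k), function(ci) {
    members <- nodes[(ci - 1) * size + seq_len(size)]
    p <- t(utils::combn(members, 2))
    data.frame(set_a = p[, 1], set_b = p[, 2], stringsAsFactors = FALSE)
  }))
  if (k > 1) {
    bridges <- data.frame(set_a = nodes[(seq_len(k - 1) - 1) * size + 1],
                          set_b = nodes[seq_len(k - 1) * size + 1],
                          stringsAsFactors = FALSE)
    edges <- rbind(edges, bridges)
  }
  gene_set_network(nodes, edges, "co_membership")
}

# A small collection built from explicit member vectors.
collection_from <- function(..., id = "toy") {
  sets <- list(...)
  gene_set_collection(lapply(names(sets), function(nm) gene_set(nm, sets[[nm]])),
                      id = id)
}
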
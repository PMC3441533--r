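#' Configuration for gene set network construction
#'
#' @param alpha Significance threshold on BH-adjusted pair p-values (edges are
#'   drawn where `q <= alpha`, inclusive). Default 0.05.
#' @param enrichment_alpha Per-list enrichment threshold used by the
#'   co-enrichment builder. Default 0.05.
#' @param min_unique_size Minimum residual set size after shared-gene removal;
#'   pairs with a smaller residual are recorded with p = 1 (degenerate) so the
#'   BH family size stays constant. Default 1.
#' @param enrichment_bh_scope How per-list enrichment p-values are corrected
#'   in the co-enrichment builder: `"within_list"` (default) corrects within
#'   each gene list over the family of all N original sets plus the two
#'   residual sets; `"global"` corrects jointly across all lists and sets.
#' @return An object of class `build_config`.
#' @export
build_config <- function(alpha = 0.05, enrichment_alpha = 0.05,
                         min_unique_size = 1,
                         enrichment_bh_scope = c("within_list", "global")) {
  if (!(alpha > 0 && alpha <= 1)) stopf("alpha must be in (0, 1]")
  if (!(enrichment_alpha > 0 && enrichment_alpha <= 1)) {
    stopf("enrichment_alpha must be in (0, 1]")
  }
  structure(list(alpha = alpha, enrichment_alpha = enrichment_alpha,
                 min_unique_size = max(1, min_unique_size),
                 enrichment_bh_scope = match.arg(enrichment_bh_scope)),
            class = "build_config")
}

# Assemble the per-pair test table in canonical (lexicographic) orientation,
# run BH across the full pair family and return the network.
finish_network <- function(ids_i, ids_j, a, b, c, d, p, alpha, nodes,
                           edge_type, collection_id) {
  swap <- ids_j < ids_i
  set_a <- ifelse(swap, ids_j, ids_i)
  set_b <- ifelse(swap, ids_i, ids_j)
  b2 <- ifelse(swap, c, b)
  c2 <- ifelse(swap, b, c)
  tests <- data.frame(set_a = set_a, set_b = set_b, a = a, b = b2, c = c2,
                      d = d, p_raw = p, q_bh = bh_adjust(p),
                      stringsAsFactors = FALSE)
  tests <- tests[order(tests$set_a, tests$set_b), , drop = FALSE]
  rownames(tests) <- NULL
  edges <- tests[tests$q_bh <= alpha, , drop = FALSE]
  gene_set_network(nodes, edges, edge_type, collection_id, tests = tests)
}

empty_network <- function(nodes, edge_type, collection_id) {
  gene_set_network(nodes, NULL, edge_type, collection_id,
                   tests = data.frame(set_a = character(0),
                                      set_b = character(0),
                                      a = numeric(0), b = numeric(0),
                                      c = numeric(0), d = numeric(0),
                                      p_raw = numeric(0), q_bh = numeric(0),
                                      stringsAsFactors = FALSE))
}

pair_indices <- function(n) {
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  list(i = i, j = j)
}

#' Build a co-membership gene set network
#'
#' Connects a pair of gene sets when their member overlap is significantly
#' high: every one of the N(N-1)/2 unordered pairs is tested with a one-sided
#' Fisher's exact test against the collection's gene universe (the union of
#' all member genes), p-values are BH-corrected across exactly that family,
#' and pairs with `q <= alpha` become edges. Isolated sets remain as nodes.
#' Run [merge_identical_sets()] first so duplicate sets do not create trivial
#' edges.
#'
#' @param collection A [gene_set_collection()].
#' @param config A [build_config()].
#' @return A [gene_set_network()] with `edge_type = "co_membership"`; the full
#'   per-pair test table is in `$tests`.
#' @export
build_comembership <- function(collection, config = build_config()) {
  ids <- set_ids(collection)
  n <- length(ids)
  if (n < 2L) {
    warnf("collection has fewer than 2 sets; returning edgeless network")
    return(empty_network(ids, "co_membership", collection$id))
  }
  u <- collection$universe
  nu <- length(u)
  inc <- matrix(0L, nrow = nu, ncol = n)
  for (k in seq_len(n)) {
    inc[match(collection$sets[[k]]$members, u), k] <- 1L
  }
  inter <- crossprod(inc)
  sizes <- diag(inter)
  px <- pair_indices(n)
  a <- inter[cbind(px$i, px$j)]
  b <- sizes[px$i] - a
  c <- sizes[px$j] - a
  d <- nu - sizes[px$i] - sizes[px$j] + a
  p <- pmin(1, phyper_right(a, b, c, d))
  finish_network(ids[px$i], ids[px$j], a, b, c, d, p, config$alpha, ids,
                 "co_membership", collection$id)
}

#' Linkage contingency table for a pair of residual gene sets
#'
#' Classifies the edges of the reference network: with `K_A` the edges having
#' at least one endpoint among the unique genes of set A, `K_B` likewise for
#' set B, `k` the edges with one endpoint in each, and `T` the total edge
#' count, the table is `(a = k, b = K_A - k, c = K_B - k,
#' d = T - K_A - K_B + k)`. Intra-set edges count only toward their own
#' margin. The inputs must already be residualized (disjoint).
#'
#' @param unique_a,unique_b Disjoint character vectors of gene ids.
#' @param network A [molecule_network()] (already restricted to the universe).
#' @return A [contingency_table()].
#' @export
linkage_contingency <- function(unique_a, unique_b, network) {
  if (length(intersect(unique_a, unique_b)) > 0) {
    stopf("unique_a and unique_b must be disjoint (shared genes removed)")
  }
  e <- network$edges
  in_a <- e$from %in% unique_a | e$to %in% unique_a
  in_b <- e$from %in% unique_b | e$to %in% unique_b
  k <- sum(in_a & in_b)
  ka <- sum(in_a)
  kb <- sum(in_b)
  contingency_table(k, ka - k, kb - k, nrow(e) - ka - kb + k)
}

#' Build a linkage gene set network
#'
#' Connects a pair of gene sets when there is a significant excess of
#' reference-network edges (e.g. protein-protein interactions) between their
#' unique members. The reference network is first restricted, once and
#' globally, to genes present in some gene set; for each pair the shared
#' genes are removed from both sets, the edges are classified with
#' [linkage_contingency()] against the background of all (restricted)
#' reference edges, and a one-sided Fisher's exact test is applied. BH runs
#' across all N(N-1)/2 pairs; pairs with an empty residual are recorded with
#' p = 1.
#'
#' @param collection A [gene_set_collection()].
#' @param network A [molecule_network()].
#' @param config A [build_config()].
#' @return A [gene_set_network()] with `edge_type = "linkage"`.
#' @export
build_linkage <- function(collection, network, config = build_config()) {
  ids <- set_ids(collection)
  n <- length(ids)
  if (n < 2L) {
    warnf("collection has fewer than 2 sets; returning edgeless network")
    return(empty_network(ids, "linkage", collection$id))
  }
  net <- restrict_network(network, collection$universe)
  tt <- nrow(net$edges)
  if (tt == 0L) {
    warnf("reference network has no edges within the collection universe")
  }
  incident <- split(rep(seq_len(max(tt, 1L)), 2L)[seq_len(2L * tt)],
                    c(net$edges$from, net$edges$to))
  members <- set_members(collection)
  px <- pair_indices(n)
  np <- length(px$i)
  a <- b <- c <- d <- integer(np)
  p <- numeric(np)
  for (q in seq_len(np)) {
    ma <- members[[px$i[q]]]
    mb <- members[[px$j[q]]]
    ua <- setdiff(ma, mb)
    ub <- setdiff(mb, ma)
    if (tt == 0L || length(ua) < config$min_unique_size ||
        length(ub) < config$min_unique_size) {
      a[q] <- 0L; b[q] <- 0L; c[q] <- 0L; d[q] <- tt
      p[q] <- 1
      next
    }
    ea <- unique(unlist(incident[ua], use.names = FALSE))
    eb <- unique(unlist(incident[ub], use.names = FALSE))
    k <- length(intersect(ea, eb))
    a[q] <- k
    b[q] <- length(ea) - k
    c[q] <- length(eb) - k
    d[q] <- tt - length(ea) - length(eb) + k
    p[q] <- min(1, phyper_right(a[q], b[q], c[q], d[q]))
  }
  finish_network(ids[px$i], ids[px$j], a, b, c, d, p, config$alpha, ids,
                 "linkage", collection$id)
}

#' Per-list enrichment of gene sets
#'
#' Tests each gene set for overrepresentation in one experimentally derived
#' gene list with a one-sided Fisher's exact test over the given universe
#' (the gene list is intersected with the universe before testing), then
#' BH-corrects across the supplied family of sets.
#'
#' @param sets_under_test List of [gene_set()] objects (or named character
#'   vectors of members).
#' @param gene_list An [experiment_gene_list()] (or a character vector).
#' @param universe Background gene ids.
#' @param config A [build_config()] (uses `enrichment_alpha`).
#' @return data.frame with columns `list_id`, `set_id`, `a`, `b`, `c`, `d`,
#'   `p_raw`, `q_bh`, `enriched`.
#' @export
per_list_enrichment <- function(sets_under_test, gene_list, universe,
                                config = build_config()) {
  lid <- if (inherits(gene_list, "experiment_gene_list")) gene_list$id else "list"
  genes <- if (inherits(gene_list, "experiment_gene_list")) gene_list$genes
           else unique(as.character(gene_list))
  l <- intersect(genes, universe)
  ids <- vapply(seq_along(sets_under_test), function(k) {
    s <- sets_under_test[[k]]
    if (inherits(s, "gene_set")) s$id
    else if (!is.null(names(sets_under_test)[k]) && nzchar(names(sets_under_test)[k]))
      names(sets_under_test)[k]
    else paste0("set", k)
  }, character(1))
  mem <- lapply(sets_under_test, function(s) {
    if (inherits(s, "gene_set")) s$members else unique(as.character(s))
  })
  nl <- length(l)
  nu <- length(universe)
  a <- vapply(mem, function(m) length(intersect(m, l)), integer(1))
  sz <- lengths(mem)
  if (nl == 0L) {
    warnf("gene list '%s' has no genes in the universe; all p = 1", lid)
    p <- rep(1, length(mem))
    a <- rep(0L, length(mem))
  } else {
    p <- pmin(1, phyper_right(a, sz - a, nl - a, nu - sz - nl + a))
  }
  q <- bh_adjust(p)
  data.frame(list_id = lid, set_id = ids, a = a, b = sz - a, c = nl - a,
             d = nu - sz - nl + a, p_raw = p, q_bh = q,
             enriched = q <= config$enrichment_alpha,
             stringsAsFactors = FALSE)
}

# BH significance flags for the two residual-set p-values, per list, within
# the family {N original sets} + {A', B'}. P0 is the N x M matrix of cached
# original-set p-values; pa/pb are length-M residual p-vectors.
coenrich_flags <- function(P0, pa, pb, alpha, scope) {
  m_lists <- ncol(P0)
  fam <- rbind(P0, pa, pb)
  m <- nrow(fam)
  if (scope == "global") {
    q <- stats::p.adjust(as.vector(fam), method = "BH")
    qm <- matrix(q, nrow = m)
    return(list(a = qm[m - 1L, ] <= alpha, b = qm[m, ] <= alpha))
  }
  crit <- alpha * seq_len(m) / m
  enc_a <- logical(m_lists)
  enc_b <- logical(m_lists)
  for (j in seq_len(m_lists)) {
    s <- sort(fam[, j])
    ok <- which(s <= crit)
    thr <- if (length(ok)) s[max(ok)] else -1
    enc_a[j] <- pa[j] <= thr
    enc_b[j] <- pb[j] <= thr
  }
  list(a = enc_a, b = enc_b)
}

#' Build a co-enrichment gene set network
#'
#' Connects a pair of gene sets when a significantly high number of
#' experimentally derived gene lists show both sets simultaneously
#' overrepresented. For each pair, shared genes are first removed from both
#' sets (residualization); per list, enrichment of the two residual sets is
#' assessed within the BH family of all N original sets plus the two
#' residuals; the counts `m_A` (lists where the A residual is enriched),
#' `m_B`, and `m_AB` (both enriched) feed a pair-level one-sided Fisher's
#' exact test against the background of all M lists; BH then runs across all
#' N(N-1)/2 pairs. Per-list p-values of the unmodified sets are computed once
#' and cached; only the residual sets are recomputed per pair. Pairs with an
#' empty residual (one set contained in the other) are recorded with p = 1.
#'
#' @param collection A [gene_set_collection()].
#' @param compendium A [gene_list_compendium()].
#' @param config A [build_config()].
#' @return A [gene_set_network()] with `edge_type = "co_enrichment"`; in the
#'   `$tests` table the counts are `a = m_AB`, `b = m_A - m_AB`,
#'   `c = m_B - m_AB`, `d = M - m_A - m_B + m_AB`.
#' @export
build_coenrichment <- function(collection, compendium,
                               config = build_config()) {
  ids <- set_ids(collection)
  n <- length(ids)
  m_lists <- length(compendium$lists)
  if (m_lists < 1L) stopf("compendium must contain at least one gene list")
  if (n < 2L) {
    warnf("collection has fewer than 2 sets; returning edgeless network")
    return(empty_network(ids, "co_enrichment", collection$id))
  }
  u <- collection$universe
  nu <- length(u)
  lmat <- matrix(FALSE, nrow = nu, ncol = m_lists)
  for (j in seq_len(m_lists)) {
    lmat[stats::na.omit(match(compendium$lists[[j]]$genes, u)), j] <- TRUE
  }
  size_l <- colSums(lmat)
  mem_idx <- lapply(collection$sets, function(s) match(s$members, u))

  set_p <- function(idx) {
    sz <- length(idx)
    aa <- if (sz == 1L) as.integer(lmat[idx, ]) else colSums(lmat[idx, , drop = FALSE])
    pmin(1, phyper_right(aa, sz - aa, size_l - aa, nu - sz - size_l + aa))
  }
  p0 <- t(vapply(mem_idx, set_p, numeric(m_lists)))
  if (m_lists == 1L) p0 <- matrix(p0, ncol = 1L)

  px <- pair_indices(n)
  np <- length(px$i)
  a <- b <- c <- d <- integer(np)
  p <- numeric(np)
  for (q in seq_len(np)) {
    ia <- mem_idx[[px$i[q]]]
    ib <- mem_idx[[px$j[q]]]
    ua <- setdiff(ia, ib)
    ub <- setdiff(ib, ia)
    if (length(ua) < config$min_unique_size ||
        length(ub) < config$min_unique_size) {
      a[q] <- 0L; b[q] <- 0L; c[q] <- 0L; d[q] <- m_lists
      p[q] <- 1
      next
    }
    no_shared <- length(ua) == length(ia) && length(ub) == length(ib)
    pa <- if (no_shared) p0[px$i[q], ] else set_p(ua)
    pb <- if (no_shared) p0[px$j[q], ] else set_p(ub)
    enc <- coenrich_flags(p0, pa, pb, config$enrichment_alpha,
                          config$enrichment_bh_scope)
    m_a <- sum(enc$a)
    m_b <- sum(enc$b)
    m_ab <- sum(enc$a & enc$b)
    a[q] <- m_ab
    b[q] <- m_a - m_ab
    c[q] <- m_b - m_ab
    d[q] <- m_lists - m_a - m_b + m_ab
    p[q] <- min(1, phyper_right(a[q], b[q], c[q], d[q]))
  }
  finish_network(ids[px$i], ids[px$j], a, b, c, d, p, config$alpha, ids,
                 "co_enrichment", collection$id)
}
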
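# Seeded synthetic-data generators. Each generator plants the statistical
# structure one of the network builders is designed to detect, so the whole
# pipeline is testable without any database download.

#' Specification for the synthetic generators
#'
#' Defaults describe a small but realistic benchmark: 20 sets of 25 genes
#' drawn disjointly from a 1000-gene pool, a background interaction density
#' of 0.002, and 200 experiment gene lists of 60 genes with a 5% baseline
#' activation rate.
#'
#' @param universe_size Size of the gene id pool sets are drawn from.
#' @param n_sets Number of gene sets.
#' @param set_size Genes per set.
#' @param planted_overlap_pairs List of `c(i, j, n_shared)` triples: sets i
#'   and j share exactly `n_shared` genes (a set may appear in at most one
#'   such pair); all other pairs are disjoint by construction.
#' @param planted_linkage_pairs List of `c(i, j, n_extra_edges)` triples:
#'   extra interaction edges planted between the residual (non-shared)
#'   members of sets i and j.
#' @param planted_coactivation_pairs List of `c(i, j, rate)` triples: both
#'   sets jointly activated in a gene list with probability `rate`
#'   (otherwise each falls back to the independent baseline draw).
#' @param background_edge_prob Probability of each background gene-gene edge.
#' @param n_lists Number of experiment gene lists.
#' @param list_size Target genes per list.
#' @param baseline_activation Per-list probability that a set is activated.
#' @param contribution_fraction Fraction of an activated set's residual
#'   members contributed to the list. Default 0.6.
#' @param seed Integer seed; every generator is deterministic under it.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(universe_size = 1000, n_sets = 20, set_size = 25,
                       planted_overlap_pairs = list(),
                       planted_linkage_pairs = list(),
                       planted_coactivation_pairs = list(),
                       background_edge_prob = 0.002,
                       n_lists = 200, list_size = 60,
                       baseline_activation = 0.05,
                       contribution_fraction = 0.6, seed = 17) {
  norm_pairs <- function(pairs, what, prob = FALSE) {
    lapply(pairs, function(p) {
      if (length(p) != 3L) stopf("each %s entry needs (i, j, value)", what)
      i <- min(p[[1]], p[[2]])
      j <- max(p[[1]], p[[2]])
      if (i < 1 || j > n_sets || i == j) stopf("invalid set indices in %s", what)
      v <- p[[3]]
      if (prob && (v < 0 || v > 1)) stopf("%s rate must be in [0, 1]", what)
      if (!prob && (v < 0 || v != round(v))) stopf("%s count must be a non-negative integer", what)
      c(i, j, v)
    })
  }
  for (p in c(background_edge_prob, baseline_activation, contribution_fraction)) {
    if (p < 0 || p > 1) stopf("probabilities must lie in [0, 1]")
  }
  spec <- structure(list(
    universe_size = universe_size, n_sets = n_sets, set_size = set_size,
    planted_overlap_pairs = norm_pairs(planted_overlap_pairs, "planted_overlap_pairs"),
    planted_linkage_pairs = norm_pairs(planted_linkage_pairs, "planted_linkage_pairs"),
    planted_coactivation_pairs = norm_pairs(planted_coactivation_pairs,
                                            "planted_coactivation_pairs", prob = TRUE),
    background_edge_prob = background_edge_prob, n_lists = n_lists,
    list_size = list_size, baseline_activation = baseline_activation,
    contribution_fraction = contribution_fraction, seed = as.integer(seed)),
    class = "synth_spec")
  ov <- unlist(lapply(spec$planted_overlap_pairs, function(p) p[1:2]))
  if (anyDuplicated(ov)) {
    stopf("a set may appear in at most one planted overlap pair")
  }
  if (any(vapply(spec$planted_overlap_pairs, function(p) p[[3]] > set_size,
                 logical(1)))) {
    stopf("n_shared cannot exceed set_size")
  }
  spec
}

# Zero-padded gene ids so lexicographic and numeric order agree.
synth_gene_ids <- function(n) sprintf("g%06d", seq_len(n))

#' Generate a gene set collection with planted overlaps
#'
#' Draws `n_sets` sets of `set_size` genes without replacement across sets,
#' so all pairs are disjoint except the planted ones, which share exactly
#' their requested number of genes. Fully reproducible under `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return A [gene_set_collection()].
#' @export
gen_collection <- function(spec) {
  shared_total <- sum(vapply(spec$planted_overlap_pairs, `[[`, numeric(1), 3L))
  needed <- spec$n_sets * spec$set_size - shared_total
  if (needed > spec$universe_size) {
    stopf("universe_size %d too small: need %d distinct genes",
          spec$universe_size, needed)
  }
  partner <- integer(spec$n_sets)   # partner[j] = i for the second set of a pair
  n_shared <- integer(spec$n_sets)
  for (p in spec$planted_overlap_pairs) {
    partner[p[[2]]] <- p[[1]]
    n_shared[p[[2]]] <- p[[3]]
  }
  with_seed(spec$seed, {
    pool <- sample(synth_gene_ids(spec$universe_size), needed)
    ptr <- 0L
    take <- function(k) {
      out <- pool[ptr + seq_len(k)]
      ptr <<- ptr + k
      out
    }
    members <- vector("list", spec$n_sets)
    for (s in seq_len(spec$n_sets)) {
      if (partner[s] > 0L) {
        shared <- members[[partner[s]]][seq_len(n_shared[s])]
        members[[s]] <- c(shared, take(spec$set_size - n_shared[s]))
      } else {
        members[[s]] <- take(spec$set_size)
      }
    }
    width <- max(2L, nchar(as.character(spec$n_sets)))
    sets <- lapply(seq_len(spec$n_sets), function(s) {
      gene_set(sprintf("S%0*d", width, s), members[[s]])
    })
    gene_set_collection(sets, id = "synthetic")
  })
}

#' Generate a molecule network with planted inter-set edge bundles
#'
#' Background: every unordered gene pair within the collection universe is an
#' edge independently with `background_edge_prob`. Planted: `n_extra_edges`
#' distinct edges added uniformly between the residual (non-shared) members
#' of each planted pair. Seeded from `spec$seed`.
#'
#' @param collection The [gen_collection()] output.
#' @param spec A [synth_spec()].
#' @return A [molecule_network()] over the collection universe.
#' @export
gen_molecule_network <- function(collection, spec) {
  u <- collection$universe
  nu <- length(u)
  members <- set_members(collection)
  with_seed(spec$seed + 1L, {
    npairs <- nu * (nu - 1) / 2
    ndraw <- stats::rbinom(1, npairs, spec$background_edge_prob)
    from <- character(0)
    to <- character(0)
    if (ndraw > 0) {
      idx <- sort(sample.int(npairs, ndraw))
      # decode linear index of the upper triangle (column-major, i < j)
      j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
      i <- idx - (j - 1) * (j - 2) / 2
      # guard against sqrt rounding at triangular-number boundaries
      over <- i < 1
      j[over] <- j[over] - 1
      i[over] <- idx[over] - (j[over] - 1) * (j[over] - 2) / 2
      under <- i > j - 1
      j[under] <- j[under] + 1
      i[under] <- idx[under] - (j[under] - 1) * (j[under] - 2) / 2
      from <- u[i]
      to <- u[j]
    }
    for (p in spec$planted_linkage_pairs) {
      ma <- members[[p[[1]]]]
      mb <- members[[p[[2]]]]
      ua <- setdiff(ma, mb)
      ub <- setdiff(mb, ma)
      avail <- length(ua) * length(ub)
      if (p[[3]] > avail) {
        stopf("planted pair (%d, %d): %d edges requested but only %d cross pairs exist",
              p[[1]], p[[2]], p[[3]], avail)
      }
      pick <- sample.int(avail, p[[3]])
      from <- c(from, ua[(pick - 1) %% length(ua) + 1])
      to <- c(to, ub[(pick - 1) %/% length(ua) + 1])
    }
    molecule_network(from, to, nodes = u)
  })
}

#' Generate a gene list compendium with planted coactivation
#'
#' Per list, each set is activated independently with `baseline_activation`;
#' for each planted pair, with probability `rate` both sets are jointly
#' activated (overriding their independent draws). An activated set
#' contributes `contribution_fraction` of its residual members (residual with
#' respect to its planted partner, if any) to the list; remaining slots up to
#' `list_size` are filled uniformly from the universe. Seeded from
#' `spec$seed`.
#'
#' @param collection The [gen_collection()] output.
#' @param spec A [synth_spec()].
#' @return A [gene_list_compendium()]; the activation matrix (sets x lists)
#'   is attached as attribute `"activation"`.
#' @export
gen_compendium <- function(collection, spec) {
  if (spec$list_size > length(collection$universe)) {
    stopf("list_size exceeds the universe size")
  }
  members <- set_members(collection)
  n <- spec$n_sets
  residual <- members
  for (p in c(spec$planted_coactivation_pairs, spec$planted_overlap_pairs)) {
    i <- p[[1]]; j <- p[[2]]
    residual[[i]] <- setdiff(members[[i]], members[[j]])
    residual[[j]] <- setdiff(members[[j]], members[[i]])
  }
  u <- collection$universe
  with_seed(spec$seed + 2L, {
    activation <- matrix(FALSE, nrow = n, ncol = spec$n_lists)
    lists <- vector("list", spec$n_lists)
    for (l in seq_len(spec$n_lists)) {
      act <- stats::runif(n) < spec$baseline_activation
      for (p in spec$planted_coactivation_pairs) {
        if (stats::runif(1) < p[[3]]) act[c(p[[1]], p[[2]])] <- TRUE
      }
      genes <- character(0)
      for (s in which(act)) {
        res <- residual[[s]]
        k <- round(spec$contribution_fraction * length(res))
        if (k > 0) genes <- c(genes, sample(res, k))
      }
      genes <- unique(genes)
      if (length(genes) < spec$list_size) {
        fill <- sample(setdiff(u, genes), spec$list_size - length(genes))
        genes <- c(genes, fill)
      }
      activation[, l] <- act
      lists[[l]] <- experiment_gene_list(sprintf("L%04d", l), genes,
                                         source = "synthetic")
    }
    out <- gene_list_compendium(lists, id = "synthetic_compendium")
    attr(out, "activation") <- activation
    out
  })
}
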
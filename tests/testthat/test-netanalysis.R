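test_that("network density follows 2E/(V(V-1))", {
  expect_equal(network_density(5, 10), 1)
  expect_equal(network_density(5, 0), 0)
  expect_equal(network_density(201, 2097), 2 * 2097 / (201 * 200))
  expect_error(network_density(1, 0), "at least 2")
})

test_that("a clique is never split (child density cannot beat the parent)", {
  net <- bridged_cliques(1, 10)
  res <- cluster_network(net)
  expect_length(res$clusters, 1L)
  expect_length(res$clusters[[1]], 10L)
})

test_that("two bridged 6-cliques split into the cliques", {
  net <- bridged_cliques(2, 6)
  # parent: 12 nodes, 31 edges, density 2*31/132; children are 6-cliques
  expect_equal(network_density(12, 31), 62 / 132)
  res <- cluster_network(net)
  expect_length(res$clusters, 2L)
  expect_setequal(vapply(res$clusters, length, integer(1)), c(6L, 6L))
  expect_true(all(startsWith(sort(res$clusters[[1]]), "c1_")))
  acc <- res$split_log[res$split_log$accepted, ]
  expect_equal(nrow(acc), 1L)
  expect_equal(c(acc$child1_density, acc$child2_density), c(1, 1))
})

test_that("small graphs are never split and clusters always partition the nodes", {
  net4 <- gene_set_network(c("a", "b", "c", "d"),
                           data.frame(set_a = c("a", "b", "c"),
                                      set_b = c("b", "c", "d")), "x")
  res4 <- cluster_network(net4)
  expect_length(res4$clusters, 1L)

  for (k in c(2, 3, 4)) {
    net <- bridged_cliques(k, 6)
    res <- cluster_network(net)
    expect_setequal(unlist(res$clusters), net$nodes)
    expect_equal(sum(lengths(res$clusters)), length(net$nodes))
    expect_length(res$clusters, k)
    # accepted splits satisfy the size and density-improvement rules
    acc <- res$split_log[res$split_log$accepted, ]
    expect_true(all(acc$child1_size >= 5 & acc$child2_size >= 5))
    expect_true(all(acc$child1_density > acc$parent_density &
                    acc$child2_density > acc$parent_density))
  }
})

test_that("clustering is deterministic and treats components as the frontier", {
  net <- bridged_cliques(3, 7)
  r1 <- cluster_network(net)
  r2 <- cluster_network(net)
  expect_identical(r1, r2)

  # disjoint union: components become clusters; a small component never splits
  nodes <- c(sprintf("x%02d", 1:6), "y1", "y2")
  edges <- rbind(data.frame(set_a = "y1", set_b = "y2"),
                 data.frame(set_a = sprintf("x%02d", 1:5),
                            set_b = sprintf("x%02d", 2:6)))
  res <- cluster_network(gene_set_network(nodes, edges, "x"))
  expect_length(res$clusters, 2L)
})

test_that("label_modules labels clusters by Fisher-significant groups", {
  # 100 nodes, one 10-node cluster identical to a 10-node group
  nodes <- sprintf("n%03d", 1:100)
  clustering <- structure(list(clusters = list(nodes[1:10], nodes[11:100]),
                               split_log = NULL), class = "gsn_clustering")
  groups <- stats::setNames(rep("G", 10), nodes[1:10])
  res <- label_modules(clustering, groups)
  expect_equal(res$labels[["1"]], "G")
  expect_length(res$labels[["2"]], 0L)
  row <- res$tests[res$tests$cluster == 1, ]
  expect_equal(row$p_raw, hyper_tail_oracle(10, 0, 0, 90), tolerance = 1e-12)

  # group absent from a cluster (a = 0) is never a label
  groups2 <- stats::setNames(rep("H", 5), nodes[96:100])
  res2 <- label_modules(clustering, groups2)
  expect_length(res2$labels[["1"]], 0L)

  res3 <- label_modules(clustering, stats::setNames(character(0), character(0)))
  expect_length(res3$labels, 0L)
})

test_that("compare_networks counts overlap and tests it against the pair universe", {
  sp <- synth_spec(n_sets = 10, set_size = 8, universe_size = 200, seed = 2)
  col <- gen_collection(sp)
  ids <- sprintf("S%02d", 1:10)
  mk <- function(pairs) {
    gene_set_network(ids, data.frame(set_a = pairs[[1]], set_b = pairs[[2]]),
                     "co_membership", col$id)
  }
  a <- mk(list(c("S01", "S01", "S02", "S03", "S04"),
               c("S02", "S03", "S03", "S04", "S05")))
  b <- mk(list(c("S01", "S01", "S06", "S07"), c("S02", "S03", "S07", "S08")))
  cmp <- compare_networks(a, b, col)
  expect_equal(cmp$shared_edges, 2L)
  expect_equal(cmp$unique_a, 3L)
  expect_equal(cmp$unique_b, 2L)
  expect_equal(cmp$possible_pairs, 45)
  expect_equal(cmp$overlap_p, hyper_tail_oracle(2, 3, 2, 38), tolerance = 1e-12)

  expect_equal(compare_networks(a, a, col)$shared_edges, 5L)
  c_net <- mk(list("S09", "S10"))
  expect_equal(compare_networks(a, c_net, col)$shared_edges, 0L)

  bad <- gene_set_network(c(ids, "S99"), NULL, "co_membership")
  expect_error(compare_networks(a, bad, col), "differing node sets")
})

test_that("overlap significance equals brute-force enumeration for small collections", {
  sp <- synth_spec(n_sets = 12, set_size = 6, universe_size = 150, seed = 3)
  col <- gen_collection(sp)
  ids <- sprintf("S%02d", 1:12)
  set.seed(99)
  for (rep in 1:10) {
    pick <- function(k) {
      p <- t(utils::combn(ids, 2))[sample.int(66, k), , drop = FALSE]
      gene_set_network(ids, data.frame(set_a = p[, 1], set_b = p[, 2]), "x", col$id)
    }
    a <- pick(sample(3:20, 1))
    b <- pick(sample(3:20, 1))
    cmp <- compare_networks(a, b, col)
    s <- cmp$shared_edges
    ea <- s + cmp$unique_a
    eb <- s + cmp$unique_b
    expect_equal(cmp$overlap_p, hyper_tail_oracle(s, ea - s, eb - s, 66 - ea - eb + s),
                 tolerance = 1e-12)
  }
})

test_that("edge stratification splits by the mean shared-gene percentage", {
  col <- collection_from(A = sprintf("g%02d", 1:10), B = sprintf("g%02d", 6:15),
                         C = sprintf("g%02d", 15:24), D = sprintf("g%02d", 30:39))
  ids <- c("A", "B", "C", "D")
  # overlapping pairs: A-B (5/15), B-C (1/19); mean pct = (100*5/15 + 100*1/19)/2
  net <- gene_set_network(ids, data.frame(set_a = c("A", "B"), set_b = c("B", "C")),
                          "x", col$id)
  cmp <- compare_networks(net, net, col)
  expect_equal(cmp$mean_shared_pct, mean(c(100 * 5 / 15, 100 * 1 / 19)))
  strat <- cmp$stratification
  expect_equal(strat$above_mean[strat$network == "net_a"], 1L)   # A-B above
  expect_equal(strat$below_mean[strat$network == "net_a"], 1L)   # B-C below
})

test_that("edge swaps preserve degree sequences and edge counts", {
  net <- bridged_cliques(2, 6)
  stat <- function(n) nrow(n$edges)
  res <- edge_swap_null(net, net, stat, n_random = 100, n_swaps = 30, seed = 5)
  expect_length(res$null_values, 100)
  expect_equal(res$p_value, 1)          # observed difference is 0

  # degree preservation, asserted sample by sample
  set.seed(11)
  deg0 <- sort(gsn_degree(net))
  for (r in 1:100) {
    rw <- gsnet:::as_rewired_network(net, gsnet:::rewire_edges(net$edges, net$nodes, 25))
    expect_identical(sort(gsn_degree(rw)), deg0)
    expect_identical(nrow(rw$edges), nrow(net$edges))
  }
})

test_that("hand-rolled swaps agree with igraph's degree-preserving rewiring contract", {
  net <- bridged_cliques(2, 6)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
  set.seed(3)
  gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 100))
  expect_equal(sort(igraph::degree(gr)), sort(igraph::degree(g)))
  rw <- gsnet:::with_seed(3, gsnet:::rewire_edges(net$edges, net$nodes, 50))
  expect_identical(sort(as.integer(table(c(rw$set_a, rw$set_b)))),
                   sort(as.integer(table(c(net$edges$set_a, net$edges$set_b)))))
})

test_that("a strongly planted statistic difference yields p below the resolution", {
  # statistic: fraction of edges internal to the "c1" clique
  same_clique <- function(n) {
    mean(substr(n$edges$set_a, 1, 2) == substr(n$edges$set_b, 1, 2))
  }
  a <- bridged_cliques(2, 6)                 # nearly all edges within cliques
  # a degree-matched but label-scrambled variant: rewire heavily
  set.seed(21)
  scr <- gsnet:::as_rewired_network(a, gsnet:::rewire_edges(a$edges, a$nodes, 200))
  res <- edge_swap_null(a, scr, same_clique, n_random = 200, n_swaps = 100,
                        seed = 8)
  expect_equal(res$p_string, "< 0.005")
  expect_equal(res$p_value, 0)
})

test_that("rigid or tiny networks cannot be randomized", {
  k4 <- bridged_cliques(1, 4)               # complete graph: no valid swap
  expect_error(gsnet:::rewire_edges(k4$edges, k4$nodes, 10, "net_a"), "rigid")
  one <- gene_set_network(c("a", "b"), data.frame(set_a = "a", set_b = "b"), "x")
  expect_error(edge_swap_null(one, one, function(n) 0, n_random = 1, n_swaps = 1),
               "fewer than 2")
})

test_that("edge label statistics score same-label and interacting pairs", {
  net <- gene_set_network(c("k1", "k2", "p1"),
                          data.frame(set_a = c("k1", "k1"), set_b = c("k2", "p1")),
                          "co_membership")
  labs <- c(k1 = "K", k2 = "K", p1 = "P")
  expect_equal(edge_label_statistics(net, labs)$same_label_pct, 50)
  expect_equal(edge_label_statistics(net, c(k1 = "X", k2 = "X", p1 = "X"))$same_label_pct,
               100)

  ppi <- molecule_network(c("k1", "k2"), c("k2", "p1"))
  st <- edge_label_statistics(net, labs, ppi)
  # both edges eligible (all endpoints interact), only k1-k2 is itself a PPI
  expect_equal(st$interacting_pct, 50)
  expect_equal(st$n_eligible, 2L)
  st2 <- edge_label_statistics(net, labs, molecule_network("z1", "z2"))
  expect_true(is.na(st2$interacting_pct))
  expect_equal(st2$n_eligible, 0L)

  expect_error(edge_label_statistics(net, c(zz = "K")), "no scorable")
})
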
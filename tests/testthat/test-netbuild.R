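test_that("co-membership: disjoint collections yield the null network", {
  col <- gen_collection(synth_spec(n_sets = 8, set_size = 10,
                                   universe_size = 200, seed = 1))
  net <- build_comembership(col)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(net$n_tests, choose(8, 2))
  expect_length(net$nodes, 8L)          # isolated sets retained
})

test_that("co-membership recovers exactly a planted overlap", {
  sp <- synth_spec(n_sets = 20, planted_overlap_pairs = list(c(1, 2, 15)),
                   seed = 17)
  net <- build_comembership(gen_collection(sp))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(c(net$edges$set_a, net$edges$set_b), c("S01", "S02"))
  expect_equal(net$edges$a, 15)
  # planted pair p-value equals the enumeration oracle
  expect_equal(net$edges$p_raw,
               hyper_tail_oracle(net$edges$a, net$edges$b, net$edges$c,
                                 net$edges$d),
               tolerance = 1e-12)
})

test_that("co-membership is invariant to the order of sets in the collection", {
  sp <- synth_spec(n_sets = 6, set_size = 10, universe_size = 200,
                   planted_overlap_pairs = list(c(1, 4, 8)), seed = 5)
  col <- gen_collection(sp)
  rev_col <- gene_set_collection(rev(col$sets), id = col$id)
  n1 <- build_comembership(col)
  n2 <- build_comembership(rev_col)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$tests, n2$tests)
})

test_that("builders warn and return an edgeless network for <2 sets", {
  col <- collection_from(A = c("g1", "g2"))
  expect_warning(net <- build_comembership(col), "fewer than 2")
  expect_equal(nrow(net$edges), 0L)
})

test_that("linkage_contingency classifies reference edges", {
  tab_vec <- function(tb) as.numeric(unlist(tb[c("a", "b", "c", "d")]))
  net <- molecule_network(c("1", "2", "4", "5"), c("3", "5", "6", "6"))
  expect_equal(tab_vec(linkage_contingency(c("1", "2"), c("3", "4"), net)),
               c(1, 1, 1, 1))

  # no edge touches either residual set
  net2 <- molecule_network(c("x1", "x2", "x3", "x4"), c("y1", "y2", "y3", "y4"))
  expect_equal(tab_vec(linkage_contingency(c("a"), c("b"), net2)),
               c(0, 0, 0, 4))

  # an intra-set edge counts only toward its own margin
  net3 <- molecule_network("1", "2")
  expect_equal(tab_vec(linkage_contingency(c("1", "2"), "3", net3)),
               c(0, 1, 0, 0))

  expect_error(linkage_contingency(c("1", "2"), c("2", "3"), net),
               "disjoint")
})

test_that("linkage: identical sets are untested (p = 1) and empty networks warn", {
  col <- collection_from(A = c("g1", "g2", "g3"), B = c("g1", "g2", "g3"))
  ppi <- molecule_network("g1", "g2")
  net <- build_linkage(col, ppi)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(net$tests$p_raw, 1)

  col2 <- collection_from(A = c("g1", "g2"), B = c("g3", "g4"))
  empty_ppi <- molecule_network()
  expect_warning(net2 <- build_linkage(col2, empty_ppi), "no edges")
  expect_equal(nrow(net2$edges), 0L)
})

test_that("linkage restricts the reference network to the universe before counting", {
  col <- collection_from(A = c("g1", "g2"), B = c("g3", "g4"))
  # edges to genes outside any set must not enter the background
  ppi <- molecule_network(c("g1", "g1", "zz1", "zz3"),
                          c("g3", "zz1", "zz2", "zz4"))
  net <- build_linkage(col, ppi)
  expect_equal(net$tests$d + net$tests$a + net$tests$b + net$tests$c, 1)
})

test_that("linkage recovers exactly a planted inter-set edge bundle", {
  sp <- synth_spec(n_sets = 10, planted_linkage_pairs = list(c(1, 2, 20)),
                   seed = 17)
  col <- gen_collection(sp)
  mn <- gen_molecule_network(col, sp)
  net <- build_linkage(col, mn)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(c(net$edges$set_a, net$edges$set_b), c("S01", "S02"))
  expect_gte(net$edges$a, 20)
  expect_equal(net$n_tests, choose(10, 2))
})

test_that("linkage is invariant to genes shared by a pair", {
  sp <- synth_spec(n_sets = 4, set_size = 10, universe_size = 300,
                   planted_linkage_pairs = list(c(1, 2, 10)), seed = 9)
  col <- gen_collection(sp)
  mn <- gen_molecule_network(col, sp)
  base <- build_linkage(col, mn)
  # add one common gene (already in the universe) to both members of the pair
  shared_gene <- col$sets[[3]]$members[[1]]
  sets2 <- col$sets
  sets2[[1]] <- gene_set("S01", c(sets2[[1]]$members, shared_gene))
  sets2[[2]] <- gene_set("S02", c(sets2[[2]]$members, shared_gene))
  col2 <- gene_set_collection(sets2, id = col$id)
  mod <- build_linkage(col2, mn)
  row_base <- base$tests[base$tests$set_a == "S01" & base$tests$set_b == "S02", ]
  row_mod <- mod$tests[mod$tests$set_a == "S01" & mod$tests$set_b == "S02", ]
  expect_equal(row_mod[, c("a", "b", "c", "d", "p_raw")],
               row_base[, c("a", "b", "c", "d", "p_raw")],
               ignore_attr = TRUE)
})

test_that("per-list enrichment handles degenerate lists per contract", {
  col <- collection_from(A = sprintf("g%02d", 1:10), B = sprintf("g%02d", 11:20),
                         C = sprintf("g%02d", 21:99))
  u <- col$universe
  # list equal to the universe: right tail is the whole mass, p = 1
  res <- per_list_enrichment(col$sets, u, u)
  expect_true(all(res$p_raw == 1))
  # list disjoint from a set: p = 1 for that set
  res2 <- per_list_enrichment(col$sets, sprintf("g%02d", 11:20), u)
  expect_equal(res2$p_raw[res2$set_id == "A"], 1)
  # list entirely outside the universe
  expect_warning(res3 <- per_list_enrichment(col$sets, c("zz1", "zz2"), u),
                 "no genes in the universe")
  expect_true(all(res3$p_raw == 1) && !any(res3$enriched))
})

test_that("per-list enrichment table matches the hypergeometric oracle", {
  u <- sprintf("g%03d", 1:100)
  s <- gene_set("S", u[1:10])
  l <- experiment_gene_list("L", c(u[6:10], u[90:94]))
  res <- per_list_enrichment(list(s), l, u)
  expect_equal(as.numeric(res[1, c("a", "b", "c", "d")]), c(5, 5, 5, 85))
  expect_equal(res$p_raw, hyper_tail_oracle(5, 5, 5, 85), tolerance = 1e-12)
})

test_that("co-enrichment: identical or nested pairs and dead compendia give no edge", {
  col <- collection_from(A = sprintf("g%02d", 1:10), B = sprintf("g%02d", 1:10),
                         C = sprintf("g%02d", 11:30))
  cmp <- gene_list_compendium(list(experiment_gene_list("L1", "g05"),
                                   experiment_gene_list("L2", "g25")))
  net <- build_coenrichment(col, cmp)
  ab <- net$tests[net$tests$set_a == "A" & net$tests$set_b == "B", ]
  expect_equal(ab$p_raw, 1)            # empty residuals
  expect_equal(nrow(net$edges), 0L)
})

test_that("co-enrichment recovers exactly a planted coactivated pair", {
  sp <- synth_spec(n_sets = 12, planted_coactivation_pairs = list(c(1, 2, 0.3)),
                   seed = 17)
  col <- gen_collection(sp)
  cmp <- gen_compendium(col, sp)
  net <- build_coenrichment(col, cmp)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(c(net$edges$set_a, net$edges$set_b), c("S01", "S02"))
  expect_equal(net$n_tests, choose(12, 2))

  # recount m_A, m_B, m_AB through the public per-list API and check the
  # pair-level p-value against the enumeration oracle
  cfg <- build_config()
  sets_plus <- c(col$sets, list(gene_set("A'", setdiff(col$sets[[1]]$members,
                                                       col$sets[[2]]$members)),
                                gene_set("B'", setdiff(col$sets[[2]]$members,
                                                       col$sets[[1]]$members))))
  enc <- vapply(cmp$lists, function(l) {
    r <- per_list_enrichment(sets_plus, l, col$universe, cfg)
    c(r$enriched[r$set_id == "A'"], r$enriched[r$set_id == "B'"])
  }, logical(2))
  m_a <- sum(enc[1, ]); m_b <- sum(enc[2, ]); m_ab <- sum(enc[1, ] & enc[2, ])
  expect_equal(as.numeric(net$edges[1, c("a", "b", "c", "d")]),
               c(m_ab, m_a - m_ab, m_b - m_ab, 200 - m_a - m_b + m_ab))
  expect_equal(net$edges$p_raw,
               hyper_tail_oracle(m_ab, m_a - m_ab, m_b - m_ab,
                                 200 - m_a - m_b + m_ab),
               tolerance = 1e-12)
})

test_that("co-enrichment residual test inputs are invariant to genes shared by a pair", {
  sp <- synth_spec(n_sets = 4, n_lists = 40,
                   planted_coactivation_pairs = list(c(1, 2, 0.4)), seed = 11)
  col <- gen_collection(sp)
  cmp <- gen_compendium(col, sp)
  shared_gene <- col$sets[[3]]$members[[1]]
  grown <- lapply(col$sets[1:2], function(s) gene_set(s$id, c(s$members, shared_gene)))
  # residualization removes the added common gene from both sides
  res_base <- lapply(1:2, function(k) {
    setdiff(col$sets[[k]]$members, col$sets[[3 - k]]$members)
  })
  res_grown <- lapply(1:2, function(k) {
    setdiff(grown[[k]]$members, grown[[3 - k]]$members)
  })
  expect_setequal(res_base[[1]], res_grown[[1]])
  expect_setequal(res_base[[2]], res_grown[[2]])
  # and the residual per-list enrichment p-values are therefore unchanged
  rsets <- function(res) list(gene_set("A'", res[[1]]), gene_set("B'", res[[2]]))
  for (l in cmp$lists[1:5]) {
    expect_equal(per_list_enrichment(rsets(res_base), l, col$universe)$p_raw,
                 per_list_enrichment(rsets(res_grown), l, col$universe)$p_raw,
                 tolerance = 1e-12)
  }
})
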
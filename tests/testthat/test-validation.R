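test_that("BH step-up matches hand-computed and reference results", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(1.0), 1.0)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  # sorted input gives non-decreasing adjusted values
  p <- sort(runif(50))
  expect_true(all(diff(bh_adjust(p)) >= 0))
  # agreement with the reference implementation on random vectors
  set.seed(14)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("enrichment p equals the hypergeometric tail enumeration", {
  # worked example: universe 10, term of 4, set of 5, overlap 4
  ann <- data.frame(gene = paste0("g", 1:4), term = "T1",
                    evidence = "EXP")
  tab <- fisher_enrichment(paste0("g", 1:5), ann, paste0("g", 1:10))
  expect_equal(tab$p[tab$term == "T1"], 6 / 252, tolerance = 1e-12)

  # brute-force oracle over random small configurations (universe <= 30)
  set.seed(15)
  for (i in 1:50) {
    N <- sample(5:30, 1)
    universe <- sprintf("u%02d", 1:N)
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    term_genes <- sample(universe, K)
    gene_set <- sample(universe, n)
    ann <- data.frame(gene = c(term_genes, universe),
                      term = c(rep("T", K), rep("BG", N)),
                      evidence = "EXP")
    tab <- fisher_enrichment(gene_set, ann, universe)
    k <- length(intersect(gene_set, term_genes))
    expect_equal(tab$p[tab$term == "T"], hyper_tail(k, K, N, n),
                 tolerance = 1e-12)
    # cross-check against the one-sided Fisher exact test
    ft <- stats::fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2),
                             alternative = "greater")
    expect_equal(tab$p[tab$term == "T"], ft$p.value, tolerance = 1e-9)
  }
})

test_that("degenerate enrichment inputs behave as defined", {
  ann <- data.frame(gene = c("g1", "g2"), term = c("T1", "T2"),
                    evidence = "EXP")
  universe <- paste0("g", 1:4)
  # set = universe: every overlap equals the term size, p = 1
  tab <- fisher_enrichment(universe, ann, universe)
  expect_true(all(tab$p == 1))
  expect_error(fisher_enrichment("g1", ann, character(0)), "universe")
  expect_error(fisher_enrichment("zz", ann, universe), "subset")
})

test_that("significant term counting applies the adjusted threshold", {
  tab <- structure(data.frame(term = c("a", "b"), p_adj = c(0.01, 0.2)),
                   class = c("enrichment_table", "data.frame"))
  expect_identical(significant_term_count(tab, 0.05), 1L)
  empty <- structure(data.frame(term = character(0), p_adj = numeric(0)),
                     class = c("enrichment_table", "data.frame"))
  expect_identical(significant_term_count(empty), 0L)
})

test_that("random-set baselines are reproducible and well calibrated", {
  u <- sprintf("g%03d", 1:100)
  const <- random_set_baseline(u, 10, 20, length, seed = 1)
  expect_true(all(const$values == 10))

  a <- random_set_baseline(u, 10, 20, function(g) sum(match(g, u)), seed = 2)
  b <- random_set_baseline(u, 10, 20, function(g) sum(match(g, u)), seed = 2)
  expect_identical(a$values, b$values)

  # overlap with a fixed half-universe set has hypergeometric mean size/2
  half <- u[1:50]
  ov <- random_set_baseline(u, 20, 400,
                            function(g) length(intersect(g, half)), seed = 3)
  expect_equal(ov$mean, 10, tolerance = 0.5)
  expect_error(random_set_baseline(u, 200, 5, length), "universe")
})

test_that("disease density comparison recovers trivial KS cases", {
  dis <- data.frame(gene = c("A", "A", "B"), disease = c("D1", "D2", "D1"))
  # panel identical to the sampling universe of size 2 -> D = 0, p = 1
  cmp <- disease_density_comparison(c("A", "B"), dis, n_random = 50,
                                    seed = 4, universe = c("A", "B"))
  expect_equal(cmp$ks_stat, 0)
  expect_equal(cmp$ks_p, 1)

  # disjoint supports -> D = 1
  dis2 <- data.frame(gene = rep(c("X", "Y", "U", "V"), times = c(3, 3, 1, 1)),
                     disease = paste0("D", 1:8))
  cmp2 <- disease_density_comparison(c("X", "Y"), dis2, n_random = 50,
                                     seed = 5, universe = c("U", "V"))
  expect_equal(cmp2$ks_stat, 1)
  expect_gt(cmp2$mean_ratio, 1)
})

test_that("centrality crosscheck compares panel and background medians", {
  nodes <- sprintf("n%d", 1:8)
  ring <- regulatory_network(data.frame(source = nodes,
                                        target = c(nodes[-1], nodes[1])))
  cc <- centrality_crosscheck(nodes[1:4], ring)
  expect_equal(cc$ratio, 1, tolerance = 1e-9)   # uniform-score graph
  expect_error(centrality_crosscheck(nodes, ring), "background")
  expect_error(centrality_crosscheck("zz", ring), "no panel gene")
})

test_that("interaction coverage fractions and baseline CI behave", {
  net <- regulatory_network(data.frame(source = c("A", "B", "C"),
                                       target = c("B", "C", "D")))
  cov <- interaction_coverage(c("A", "D"), net, n_boot = 100, seed = 6)
  expect_equal(cov$upstream, 1 / 3)
  expect_equal(cov$downstream, 1 / 3)
  expect_equal(cov$involved, 2 / 3)
  expect_lte(cov$involved, cov$upstream + cov$downstream)

  none <- interaction_coverage(c("Z1", "Z2"), net, n_boot = 10, seed = 6)
  expect_equal(none$involved, 0)

  # a panel covering every endpoint is involved in every edge,
  # and the random baseline CI excludes 1 for small random sets
  full <- interaction_coverage(c("A", "B", "C", "D"), net,
                               n_boot = 100, seed = 7)
  expect_equal(full$involved, 1)
  sub <- interaction_coverage(c("A", "B"), net, n_boot = 200, seed = 8)
  expect_true(all(sub$baseline$values <= 1))
})
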
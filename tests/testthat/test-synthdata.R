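small_kb <- function(seed = 7) {
  simulate_knowledge_base(
    n_genes = 150, n_pathways = 12, hub_fraction = 0.06,
    redundancy = list(n_pairs = 3, membership_size = 6),
    annotation = list(n_terms = 40, n_enriched = 8,
                      background_rate = 2, enriched_coverage = 0.5),
    disease = list(n_diseases = 80, mean_count = 2, density_factor = 3),
    coexpression = list(n_clusters = 3, cluster_size = 3, n_background = 40),
    seed = seed)
}

test_that("the generator echoes its parameters and is deterministic", {
  kb1 <- small_kb(); kb2 <- small_kb()
  expect_identical(kb1$assoc, kb2$assoc)
  expect_identical(kb1$network, kb2$network)
  expect_identical(kb1$annotations, kb2$annotations)
  expect_identical(kb1$diseases, kb2$diseases)
  expect_identical(kb1$truth, kb2$truth)
  expect_length(kb1$truth$hubs, round(0.06 * 150))
  expect_false(identical(small_kb(8)$network, kb1$network))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_knowledge_base(kb1, d1); write_knowledge_base(kb2, d2)
  for (f in c("associations.gmt", "network.tsv", "annotations.tsv",
              "diseases.tsv", "correlations.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("every planted entity exists in the emitted knowledge base", {
  kb <- small_kb()
  expect_true(all(kb$truth$hubs %in% kb$assoc$genes))
  expect_true(all(kb$truth$hubs %in% network_nodes(kb$network)))
  # clone pairs share identical membership
  sets <- gene_set_list(kb$assoc)
  memb_of <- function(g) sort(kb$assoc$edges$pathway[kb$assoc$edges$gene == g])
  for (i in seq_len(nrow(kb$truth$redundant_pairs)))
    expect_identical(memb_of(kb$truth$redundant_pairs$gene_a[i]),
                     memb_of(kb$truth$redundant_pairs$gene_b[i]))
  # cluster members correlate above 0.9 pairwise
  for (cl in kb$truth$clusters) {
    sub <- kb$correlations[kb$correlations$gene_a %in% cl &
                             kb$correlations$gene_b %in% cl, ]
    expect_equal(nrow(sub), choose(length(cl), 2))
    expect_true(all(sub$r > 0.9))
  }
  expect_true(all(kb$truth$enriched_terms %in% kb$annotations$term))
})

test_that("planted hubs dominate the network and the disease table", {
  kb <- small_kb()
  pr <- pagerank(kb$network, mode = "undirected")
  hub_scores <- score_of(pr, kb$truth$hubs)
  bg_scores <- pr$score[!pr$gene %in% kb$truth$hubs]
  expect_gt(median(hub_scores), median(bg_scores))

  out_deg <- table(factor(kb$network$edges$source,
                          levels = network_nodes(kb$network)))
  expect_gte(min(out_deg[kb$truth$hubs]), 5 * median(out_deg))

  counts <- table(factor(kb$diseases$gene, levels = kb$assoc$genes))
  expect_gt(mean(counts[kb$truth$hubs]),
            1.5 * mean(counts[setdiff(kb$assoc$genes, kb$truth$hubs)]))
})

test_that("infeasible specifications are rejected", {
  expect_error(simulate_knowledge_base(n_genes = 5), "n_genes")
  expect_error(simulate_knowledge_base(n_pathways = 1), "n_pathways")
  expect_error(simulate_knowledge_base(
    n_genes = 20, n_pathways = 5,
    redundancy = list(n_pairs = 40, membership_size = 3)), "infeasible")
  expect_error(simulate_knowledge_base(
    n_genes = 100, n_pathways = 5,
    redundancy = list(n_pairs = 2, membership_size = 9)), "infeasible")
})

test_that("simulated counts honor the design, library sizes and dispersion", {
  sets <- list(PW1 = sprintf("g%02d", 1:10), PW2 = sprintf("g%02d", 11:30))
  design <- data.frame(condition = rep(c("c0", "c1"), each = 3))
  sim <- simulate_expression(sets, design,
                             libsize_range = c(1e5, 2e5),
                             dispersion = 0.1, seed = 4)
  expect_identical(dim(sim$counts), c(30L, 6L))
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  expect_identical(sim$meta$condition, design$condition)

  expect_identical(sim$counts,
                   simulate_expression(sets, design,
                                       libsize_range = c(1e5, 2e5),
                                       dispersion = 0.1, seed = 4)$counts)
  expect_error(simulate_expression(sets, design, dispersion = 0), "dispersion")
  expect_error(simulate_expression(sets, design[0, , drop = FALSE]),
               "nonempty")

  # dispersion recovery: 100 replicate columns, method-of-moments estimate
  big <- simulate_expression(sets,
                             data.frame(condition = rep("c", 100)),
                             libsize_range = c(2e5, 2e5),
                             dispersion = 0.2, seed = 5)
  mu <- rowMeans(big$counts)
  v <- apply(big$counts, 1, var)
  disp_hat <- (v - mu) / mu^2
  med <- median(disp_hat[mu > 50])
  expect_gt(med, 0.2 / 2)
  expect_lt(med, 0.2 * 2)
})

test_that("planted activation shifts the activated genes' counts", {
  sets <- list(PW1 = sprintf("g%02d", 1:10), PW2 = sprintf("g%02d", 11:40))
  design <- data.frame(condition = rep(c("c0", "c1"), each = 4))
  act <- data.frame(pathway = "PW1", condition = "c1", log2fc = 2)
  sim <- simulate_expression(sets, design, activation = act,
                             dispersion = 0.05, seed = 6)
  lcpm <- log2_cpm(sim$counts)
  delta <- rowMeans(lcpm[, 5:8]) - rowMeans(lcpm[, 1:4])
  bg <- setdiff(rownames(lcpm), sets$PW1)
  # activated genes rise ~2 log2 units relative to the background, which
  # itself shifts down by the cpm compositional renormalization
  expect_equal(mean(delta[sets$PW1]) - mean(delta[bg]), 2, tolerance = 0.3)
  expect_lt(mean(delta[bg]), 0)
})

test_that("tri-phasic activation profiles peak where planted", {
  tp <- triphasic_activation(c("a", "b", "c"), c("t0", "t1", "t2", "t3"),
                             effect = 1.5)
  expect_setequal(unique(tp$groups), c("early", "transient", "late"))
  for (p in c("a", "b", "c")) {
    prof <- tp$activation[tp$activation$pathway == p, ]
    peak_cond <- prof$condition[which.max(prof$log2fc)]
    expected <- switch(tp$groups[[p]], early = "t0", transient = "t2",
                       late = "t3")
    expect_identical(peak_cond, expected)
    expect_equal(max(prof$log2fc), 1.5)
  }
  expect_error(triphasic_activation("a", c("t0", "t1")), "3 conditions")
})
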
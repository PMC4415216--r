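test_that("log2-cpm follows the offset formula and is monotone", {
  counts <- matrix(c(1, 3), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  # pre-offset cpm proportions sum to 1e6
  expect_equal(sum(counts / sum(counts) * 1e6), 1e6)
  val <- log2_cpm(counts)
  expect_equal(val[, 1],
               c(g1 = log2(1.5 / 5 * 1e6), g2 = log2(3.5 / 5 * 1e6)))
  # strictly monotone in counts within a sample
  expect_true(val["g2", 1] > val["g1", 1])

  # the offsets vanish with coverage: doubling counts and library size
  # perturbs a gene with c >= 50 by < 0.01, and less as c grows
  big <- matrix(c(50, 1000, 5000), 3, 1,
                dimnames = list(paste0("g", 1:3), "s"))
  d <- abs(log2_cpm(2 * big) - log2_cpm(big))
  expect_true(all(d < 0.01))
  expect_true(all(diff(d[, 1]) < 0))

  expect_error(log2_cpm(matrix(0, 2, 1)), "library")
  expect_error(log2_cpm(matrix(-1, 1, 1)), "non-negative")
})

test_that("mean-rank z scores match the closed form and its symmetry", {
  expr <- matrix(c(1:5, 5:1), 5, 2,
                 dimnames = list(paste0("g", 1:5), c("s1", "s2")))
  top <- activity_scores(expr, list(P = c("g4", "g5")))
  # set occupying ranks {4,5} of 5: z = 1.5 / sqrt(0.75)
  expect_equal(top["P", "s1"], 1.5 / sqrt(0.75), tolerance = 1e-12)
  # mirrored expression puts the set at ranks {1,2}: -sqrt(3)
  expect_equal(top["P", "s2"], -sqrt(3), tolerance = 1e-12)

  expect_error(activity_scores(expr, list(P = paste0("g", 1:5))),
               "every profiled gene")
  expect_warning(activity_scores(expr, list(P = c("g4", "g5"), Q = "nope")),
                 "skipped")
})

test_that("activity scores are rank-based, null-standardized", {
  set.seed(16)
  expr <- matrix(rnorm(200 * 10), 200, 10,
                 dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:10)))
  sets <- list(A = sample(rownames(expr), 20))
  s1 <- activity_scores(expr, sets)
  # invariant under strictly monotone per-sample transforms
  s2 <- activity_scores(exp(expr) + 5, sets)
  expect_equal(unclass(s1), unclass(s2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # under exchangeable expression, random sets score mean ~0, var ~1
  draws <- replicate(2000, {
    g <- sample(rownames(expr), 10)
    activity_scores(expr[, 1, drop = FALSE], list(X = g))[1, 1]
  })
  expect_lt(abs(mean(draws)), 0.1)
  expect_lt(abs(var(draws) - 1), 0.15)
})

test_that("row z-scoring centers, scales, and flags constant rows", {
  m <- matrix(c(1, 2, 3, 7, 7, 7), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "const"), NULL))
  expect_warning(z <- row_zscore(m), "constant")
  expect_equal(z["a", ], c(-1, 0, 1))
  expect_equal(z["const", ], c(0, 0, 0))
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_error(row_zscore(m[, 1, drop = FALSE]), "2 columns")
})

test_that("peak-time ordering is stable and classifies the three phases", {
  sc <- matrix(c(3, 1, 0,   # early
                 0, 2, 1,   # transient
                 0, 1, 5,   # late
                 2, 1, 0),  # early (second)
               4, 3, byrow = TRUE,
               dimnames = list(c("pw_a", "pw_b", "pw_c", "pw_d"),
                               c("t0", "t1", "t2")))
  ord <- peak_time_ordering(sc)
  expect_identical(ord$pathway, c("pw_a", "pw_d", "pw_b", "pw_c"))
  expect_identical(ord$group, c("early", "early", "transient", "late"))

  # all rows peaking at t0 preserve input order
  flat <- matrix(c(2, 1, 0, 5, 1, 0), 2, 3, byrow = TRUE,
                 dimnames = list(c("z", "a"), c("t0", "t1", "t2")))
  expect_identical(peak_time_ordering(flat)$pathway, c("z", "a"))
})

test_that("replicate averaging reduces columns to conditions", {
  sc <- matrix(1:8, 2, 4, dimnames = list(c("p1", "p2"), NULL))
  avg <- average_by_condition(sc, c("d0", "d0", "d1", "d1"))
  expect_identical(colnames(avg), c("d0", "d1"))
  expect_equal(avg["p1", "d0"], 2)
})

test_that("variance-explained fractions hit the analytic endpoints", {
  set.seed(17)
  expr <- matrix(rnorm(50 * 8), 50, 8,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:8)))
  expect_equal(
    variance_explained_fraction(expr, rownames(expr), "varsum")$fraction, 1)
  expr2 <- rbind(expr, flat1 = 1, flat2 = 2)
  expect_equal(
    variance_explained_fraction(expr2, c("flat1", "flat2"),
                                "varsum")$fraction, 0)
  # projection on all genes spans the sample space
  expect_equal(
    variance_explained_fraction(expr, rownames(expr),
                                "projection")$fraction, 1, tolerance = 1e-9)
  pr <- variance_explained_fraction(expr, rownames(expr)[1:5], "projection",
                                    n_random = 20, seed = 1)
  expect_true(pr$fraction >= 0 && pr$fraction <= 1)
  expect_length(pr$baseline$values, 20)
})

test_that("pathway regulation test matches the hypergeometric worked case", {
  panel <- sprintf("g%02d", 1:10)
  sets <- list(PW = panel[1:4], OTHER = panel[5:6])
  res <- pathway_regulation_test(panel[1:4], panel, sets)
  expect_equal(res$p[res$pathway == "PW"], 1 / choose(10, 4),
               tolerance = 1e-12)
  # empty DE set: all p = 1
  res0 <- pathway_regulation_test(character(0), panel, sets)
  expect_true(all(res0$p == 1))
  expect_error(pathway_regulation_test("g01", character(0), sets), "empty")
  expect_error(pathway_regulation_test("zz", panel, sets), "not in the panel")
})

test_that("trend test signs, conventions and null behavior hold", {
  dose <- rep(c(0, 1, 3, 10), each = 2)
  set.seed(18)
  down <- 5 - 0.4 * dose + rnorm(8, sd = 0.01)
  const <- rep(2, 8)
  expr <- rbind(down = down, const = const)
  tr <- trend_test(expr, dose, degree = 1)
  expect_lt(tr$linear[tr$gene == "down"], 0)
  expect_identical(tr$direction[tr$gene == "down"], -1)
  expect_equal(tr$linear[tr$gene == "const"], 0)
  expect_equal(tr$p[tr$gene == "const"], 1)

  tr2 <- trend_test(expr, dose, degree = 2)
  expect_lt(tr2$p[tr2$gene == "down"], 0.01)
  expect_equal(tr2$p[tr2$gene == "const"], 1)

  expect_error(trend_test(expr, rep(1, 8)), "constant")
  expect_error(trend_test(expr, dose[1:3]), "length")

  # under the global null p-values are approximately uniform
  set.seed(19)
  null_expr <- matrix(rnorm(1000 * 8), 1000, 8,
                      dimnames = list(sprintf("g%04d", 1:1000), NULL))
  trn <- trend_test(null_expr, dose, degree = 2)
  expect_gt(stats::ks.test(trn$p, "punif")$p.value, 0.01)
})

test_that("DE calling applies the fold-change and FDR thresholds", {
  dose <- rep(c(0, 1, 3, 10), each = 3)
  set.seed(20)
  expr <- rbind(
    up = 2 + 0.15 * dose + rnorm(12, sd = 0.1),     # lfc 1.5 over the range
    small = 2 + 0.02 * dose + rnorm(12, sd = 0.1),  # significant, lfc 0.2
    noise = rnorm(12))
  tr <- trend_test(expr, dose, degree = 2)
  de <- call_de(tr, lfc_threshold = 1, alpha = 0.05)
  expect_true("up" %in% de)
  expect_false("small" %in% de)
})
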
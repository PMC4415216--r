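#' Log2 counts-per-million transformation
#'
#' Library-size normalization for targeted RNA count matrices:
#' `log2((count + pseudocount) / (libsize + 1) * 1e6)`. The pseudocount
#' keeps zeros finite and the `+ 1` on the library size keeps the transform
#' defined for single-gene libraries; both offsets become negligible for
#' well-covered genes.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param pseudocount added to every count before scaling.
#' @return Real matrix of the same shape (log2-cpm layer).
#' @export
log2_cpm <- function(counts, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size in column(s): ",
                          paste(utils::head(which(lib == 0), 5), collapse = ", "))
  log2(sweep(counts + pseudocount, 2, lib + 1, "/") * 1e6)
}

#' Single-sample pathway activity scores (mean-rank z)
#'
#' Converts a log2-cpm expression matrix into a pathway x sample activity
#' matrix. Per sample, all G profiled genes are ranked (ties = average
#' rank); a set of m member genes with mean rank Rbar scores
#' `z = (Rbar - (G+1)/2) / sqrt((G+1)(G-m) / (12 m))`,
#' i.e. the mean rank standardized by its exact null mean and variance under
#' random membership (sampling m ranks without replacement from 1..G). The
#' score is rank-based, hence invariant under any strictly monotone
#' per-sample transform of expression, has closed-form null mean 0 and
#' variance 1, and a sign that directly reads as up- or down-regulation of
#' the set.
#'
#' @param expr numeric matrix (genes x samples), e.g. from [log2_cpm()].
#' @param gene_sets a [pathway_gene_associations] object or a named list of
#'   gene id vectors.
#' @param method score variant; only `"meanrank-z"` is defined.
#' @return An `activity_scores` matrix (pathways x samples) with attributes
#'   `method` and `set_sizes`. Sets with no profiled member are skipped with
#'   a warning; a set covering every profiled gene is an error (the score
#'   variance is zero).
#' @export
activity_scores <- function(expr, gene_sets, method = "meanrank-z") {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expr needs gene ids as rownames")
  if (nrow(expr) < 2) stop("need at least 2 profiled genes")
  sets <- if (inherits(gene_sets, "pathway_gene_associations"))
    gene_set_list(gene_sets) else gene_sets
  stopifnot(is.list(sets), !is.null(names(sets)))
  G <- nrow(expr)
  ranks <- apply(expr, 2, rank, ties.method = "average")
  scores <- matrix(NA_real_, nrow = 0, ncol = ncol(expr))
  kept <- character(0); sizes <- integer(0)
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], rownames(expr))
    m <- length(members)
    if (m == 0) {
      warning("pathway ", nm, ": no member gene profiled, skipped")
      next
    }
    if (m == G)
      stop("pathway ", nm, " covers every profiled gene (score variance 0)")
    rbar <- colMeans(ranks[members, , drop = FALSE])
    z <- (rbar - (G + 1) / 2) / sqrt((G + 1) * (G - m) / (12 * m))
    scores <- rbind(scores, z)
    kept <- c(kept, nm); sizes <- c(sizes, m)
  }
  if (!nrow(scores)) stop("no pathway had any profiled member gene")
  dimnames(scores) <- list(kept, colnames(expr))
  structure(scores, method = method,
            set_sizes = stats::setNames(sizes, kept),
            class = c("activity_scores", class(scores)))
}

#' Average activity scores within conditions
#'
#' Scores are computed per sample; for display and peak-time analysis the
#' replicate samples of each condition are averaged.
#'
#' @param scores pathways x samples matrix.
#' @param condition vector (length = columns) assigning each sample to a
#'   condition; column order of the result follows the order of first
#'   appearance.
#' @return Pathways x conditions matrix.
#' @export
average_by_condition <- function(scores, condition) {
  stopifnot(length(condition) == ncol(scores))
  levels <- unique(as.character(condition))
  out <- vapply(levels, function(l)
    rowMeans(scores[, condition == l, drop = FALSE]),
    numeric(nrow(scores)))
  out <- matrix(out, nrow = nrow(scores),
                dimnames = list(rownames(scores), levels))
  out
}

#' Row-wise z-score normalization
#'
#' Centers every row to mean zero and scales to unit sample standard
#' deviation, enabling between-pathway comparison of activity profiles.
#' Constant rows become all zeros with a warning.
#'
#' @param scores numeric matrix with >= 2 columns.
#' @return Matrix of the same shape.
#' @export
row_zscore <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) stop("need >= 2 columns to z-score rows")
  mu <- rowMeans(scores)
  sdv <- apply(scores, 1, stats::sd)
  flat <- sdv == 0
  if (any(flat)) {
    warning(sum(flat), " constant row(s) set to zero")
    sdv[flat] <- 1
  }
  out <- (scores - mu) / sdv
  out[flat, ] <- 0
  out
}

#' Order pathways by the time their activity peaks
#'
#' Sorts pathway activity profiles by the index of the column (time point)
#' where each row attains its maximum (first maximum on ties; the sort is
#' stable, so rows peaking at the same time keep their input order).
#' Pathways are classified into an earliest-peak group (active at the start,
#' then fading — the stem-cell-like profile), a latest-peak group
#' (cell-type-specific profile) and a transient interior-peak group
#' ("switch" pathways).
#'
#' @param scores pathways x time-points matrix, columns in temporal order
#'   (or reordered via `time_order`).
#' @param time_order optional character vector giving the temporal order of
#'   the column names.
#' @return data.frame (pathway, peak_index, peak_time, group in
#'   early/transient/late), rows in peak order.
#' @export
peak_time_ordering <- function(scores, time_order = NULL) {
  scores <- as.matrix(scores)
  if (!is.null(time_order)) {
    stopifnot(setequal(time_order, colnames(scores)))
    scores <- scores[, time_order, drop = FALSE]
  }
  k <- ncol(scores)
  peak <- apply(scores, 1, which.max)
  group <- ifelse(peak == 1, "early", ifelse(peak == k, "late", "transient"))
  out <- data.frame(pathway = rownames(scores), peak_index = peak,
                    peak_time = colnames(scores)[peak], group = group,
                    stringsAsFactors = FALSE)
  out <- out[order(out$peak_index), ]   # stable: ties keep input order
  rownames(out) <- NULL
  out
}

#' Fraction of expression variance attributable to a gene subset
#'
#' Two notions are offered. `varsum`: the summed per-gene variance of the
#' subset divided by the summed per-gene variance of all genes. `projection`:
#' the fraction of total (centered) expression variance explained by
#' regressing every gene on the top principal components of the subset's
#' expression (number of components = min(subset size, samples - 1)). An
#' optional random-gene-set baseline puts the fraction in context.
#'
#' @param expr numeric matrix, genes x samples.
#' @param subset gene ids; must intersect the rownames of `expr`.
#' @param method `"varsum"` or `"projection"`.
#' @param n_random if > 0, evaluate the same statistic on this many random
#'   subsets of equal size (see [random_set_baseline()]).
#' @param seed RNG seed for the baseline.
#' @return List with `fraction`, `method` and (when requested) `baseline`.
#' @export
variance_explained_fraction <- function(expr, subset,
                                        method = c("varsum", "projection"),
                                        n_random = 0L, seed = NULL) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  subset <- intersect(unique(subset), rownames(expr))
  if (!length(subset)) stop("subset does not intersect the expression matrix")
  stat <- function(genes) {
    if (method == "varsum") {
      sum(apply(expr[genes, , drop = FALSE], 1, stats::var)) /
        sum(apply(expr, 1, stats::var))
    } else {
      Y <- t(expr)                              # samples x genes
      Y <- Y - colMeans(Y)[col(Y)]
      X <- t(expr[genes, , drop = FALSE])
      X <- X - colMeans(X)[col(X)]
      k <- min(length(genes), nrow(X) - 1)
      pcs <- stats::prcomp(X, center = FALSE)$x[, seq_len(k), drop = FALSE]
      Q <- qr.Q(qr(pcs))
      sum(crossprod(Q, Y)^2) / sum(Y^2)
    }
  }
  out <- list(fraction = stat(subset), method = method)
  if (n_random > 0)
    out$baseline <- random_set_baseline(rownames(expr), length(subset),
                                        n_random, stat, seed = seed)
  out
}

#' Per-pathway regulation test on differentially expressed reporter genes
#'
#' Given the set of differentially expressed genes among the profiled panel,
#' asks for every pathway whether its reporter genes are over-represented in
#' the DE set: a one-sided (greater) Fisher exact test on the 2x2 table of
#' pathway-reporter membership versus DE status within the panel.
#'
#' @param de_genes differentially expressed genes; must be a subset of the
#'   panel.
#' @param panel a `reporter_panel` or character vector of panel genes.
#' @param gene_sets a [pathway_gene_associations] object or named list of
#'   pathway gene vectors.
#' @return data.frame (pathway, n_reporters, n_de_reporters, p, p_adj),
#'   ascending p.
#' @export
pathway_regulation_test <- function(de_genes, panel, gene_sets) {
  genes <- unique(if (inherits(panel, "reporter_panel")) panel$genes
                  else panel)
  if (!length(genes)) stop("panel is empty")
  de <- unique(de_genes)
  outside <- setdiff(de, genes)
  if (length(outside))
    stop("DE gene(s) not in the panel: ",
         paste(utils::head(outside, 5), collapse = ", "))
  sets <- if (inherits(gene_sets, "pathway_gene_associations"))
    gene_set_list(gene_sets) else gene_sets
  N <- length(genes); n <- length(de)
  rows <- lapply(names(sets), function(nm) {
    reporters <- intersect(sets[[nm]], genes)
    K <- length(reporters)
    k <- length(intersect(reporters, de))
    data.frame(pathway = nm, n_reporters = K, n_de_reporters = k,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, out$pathway), ]
  rownames(out) <- NULL
  out
}

#' Polynomial trend test for time- or dose-dependent expression
#'
#' Fits, per gene, an ordinary-least-squares polynomial of the covariate
#' (degree 1 or 2) and tests the polynomial terms jointly: an F-test on the
#' linear + quadratic terms for degree 2, a two-sided t-test on the slope
#' for degree 1. The reported direction is the sign of the linear
#' coefficient, and `lfc` is the fitted log2 change between the smallest and
#' the largest covariate value. Genes with zero variance get coefficient 0
#' and p = 1 by convention. BH adjustment is applied across genes.
#'
#' @param expr numeric matrix (genes x samples), typically log2-cpm.
#' @param covariate numeric vector (length = samples), e.g. time or dose;
#'   must not be constant.
#' @param degree polynomial degree, 1 or 2; needs at least degree + 2
#'   samples.
#' @return A `trend_result` data.frame: gene, linear, quadratic (degree 2),
#'   lfc, statistic, p, p_adj, direction.
#' @export
trend_test <- function(expr, covariate, degree = 2L) {
  expr <- as.matrix(expr)
  n <- ncol(expr)
  if (length(covariate) != n)
    stop("covariate length must equal the number of samples")
  if (length(unique(covariate)) < 2) stop("covariate is constant")
  if (!degree %in% c(1L, 2L)) stop("degree must be 1 or 2")
  if (n < degree + 2) stop("need at least degree + 2 samples")
  X <- cbind(1, stats::poly(covariate, degree, raw = TRUE))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("polynomial design is rank-deficient for this covariate")
  Y <- t(expr)                          # samples x genes
  beta <- qr.coef(qrX, Y)               # (degree+1) x genes
  res <- Y - X %*% beta
  rss <- colSums(res^2)
  tss <- colSums((Y - colMeans(Y)[col(Y)])^2)
  df_res <- n - (degree + 1)
  flat <- tss <= .Machine$double.eps * n
  if (degree == 2L) {
    fstat <- ((tss - rss) / 2) / (rss / df_res)
    p <- stats::pf(fstat, 2, df_res, lower.tail = FALSE)
    stat <- fstat
  } else {
    xtx_inv <- chol2inv(qr.R(qrX))
    se <- sqrt(xtx_inv[2, 2] * rss / df_res)
    stat <- beta[2, ] / se
    p <- 2 * stats::pt(-abs(stat), df_res)
  }
  lin <- beta[2, ]
  quad <- if (degree == 2L) beta[3, ] else NULL
  xr <- range(covariate)
  lfc <- lin * (xr[2] - xr[1]) +
    if (degree == 2L) quad * (xr[2]^2 - xr[1]^2) else 0
  if (any(flat)) {
    lin[flat] <- 0; if (!is.null(quad)) quad[flat] <- 0
    lfc[flat] <- 0; stat[flat] <- 0; p[flat] <- 1
  }
  p[is.na(p)] <- 1
  out <- data.frame(gene = rownames(expr), linear = lin, lfc = lfc,
                    statistic = stat, p = p, stringsAsFactors = FALSE)
  if (degree == 2L) out$quadratic <- quad
  out$p_adj <- bh_adjust(out$p)
  out$direction <- sign(out$linear)
  rownames(out) <- NULL
  structure(out, class = c("trend_result", "data.frame"), degree = degree)
}

#' Call differentially expressed genes from a trend test
#'
#' Applies the standard thresholds: absolute fitted log2 fold-change >= 1
#' and BH-adjusted p < 0.05 (both configurable).
#'
#' @param trend a `trend_result` from [trend_test()].
#' @param lfc_threshold minimum absolute fitted log2 fold-change.
#' @param alpha maximum BH-adjusted p.
#' @return Character vector of DE gene ids.
#' @export
call_de <- function(trend, lfc_threshold = 1, alpha = 0.05) {
  stopifnot(inherits(trend, "trend_result"))
  trend$gene[abs(trend$lfc) >= lfc_threshold & trend$p_adj < alpha]
}
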
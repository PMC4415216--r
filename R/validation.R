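#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment of a p-value vector: sort ascending,
#' multiply the i-th smallest by n/i, enforce monotonicity from the largest
#' down (step-up), cap at 1, and restore the original order. Implemented in
#' the package so the core has no dependency on a particular stats stack;
#' it agrees with the reference step-up procedure.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1] and non-missing")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(n / seq(n, 1) * p[o]))
  adj[order(o)]
}

#' One-sided Fisher enrichment of a gene set against annotation terms
#'
#' For every annotation term, builds the 2x2 table of term membership versus
#' gene-set membership over the universe and computes the one-sided
#' (enrichment) hypergeometric tail probability — the one-sided Fisher exact
#' test. Terms with zero overlap are included. BH adjustment is applied
#' across all tested terms.
#'
#' @param gene_set character vector of genes, a subset of the universe.
#' @param annotations data.frame (gene, term, ...), e.g. from
#'   [read_annotation_table()], already filtered to the desired evidence
#'   codes (see [filter_experimental()]).
#' @param universe gene universe; defaults to all genes with at least one
#'   annotation.
#' @return An `enrichment_table` data.frame: term, overlap, term_size,
#'   set_size, universe_size, odds_ratio, p, p_adj.
#' @export
fisher_enrichment <- function(gene_set, annotations, universe = NULL) {
  stopifnot(is.data.frame(annotations),
            all(c("gene", "term") %in% names(annotations)))
  if (is.null(universe)) universe <- unique(annotations$gene)
  if (!length(universe)) stop("empty gene universe")
  gene_set <- unique(gene_set)
  outside <- setdiff(gene_set, universe)
  if (length(outside))
    stop("gene set is not a subset of the universe (e.g. ",
         paste(utils::head(outside, 3), collapse = ", "), ")")
  ann <- unique(annotations[annotations$gene %in% universe,
                            c("gene", "term")])
  terms <- sort(unique(ann$term))
  N <- length(universe)
  n <- length(gene_set)
  term_size <- as.integer(table(factor(ann$term, levels = terms)))
  in_set <- ann[ann$gene %in% gene_set, , drop = FALSE]
  overlap <- as.integer(table(factor(in_set$term, levels = terms)))
  p <- stats::phyper(overlap - 1, term_size, N - term_size, n,
                     lower.tail = FALSE)
  # sample odds ratio of the 2x2 table (Inf/NaN possible for empty margins)
  or <- (overlap * (N - term_size - n + overlap)) /
    ((term_size - overlap) * (n - overlap))
  out <- data.frame(term = terms, overlap = overlap, term_size = term_size,
                    set_size = n, universe_size = N, odds_ratio = or,
                    p = p, p_adj = bh_adjust(p), stringsAsFactors = FALSE)
  structure(out[order(out$p, out$term), ],
            class = c("enrichment_table", "data.frame"))
}

#' Count significantly enriched terms
#' @param table an `enrichment_table`.
#' @param alpha BH-adjusted significance level.
#' @return Integer count of terms with adjusted p < alpha.
#' @export
significant_term_count <- function(table, alpha = 0.05) {
  stopifnot("p_adj" %in% names(table))
  sum(table$p_adj < alpha)
}

#' Random gene-set baseline for an arbitrary statistic
#'
#' Draws `n_sets` uniform without-replacement gene sets of the given size
#' from the universe, evaluates `statistic` on each, and summarizes the
#' resulting null distribution with its mean and a percentile interval.
#'
#' @param universe genes to draw from.
#' @param size set size (<= length of universe).
#' @param n_sets number of random sets.
#' @param statistic function mapping a character vector to one number.
#' @param seed optional RNG seed.
#' @param probs percentile interval bounds.
#' @return List with `values`, `mean`, `ci` (named quantiles) and the
#'   parameters.
#' @export
random_set_baseline <- function(universe, size, n_sets, statistic,
                                seed = NULL, probs = c(0.025, 0.975)) {
  if (size > length(universe)) stop("size exceeds the universe")
  if (!is.null(seed)) set.seed(seed)
  values <- vapply(seq_len(n_sets), function(i)
    statistic(sample(universe, size)), numeric(1))
  list(values = values, mean = mean(values),
       ci = stats::quantile(values, probs = probs, names = TRUE),
       size = size, n_sets = n_sets, seed = seed)
}

#' Disease-association density of a panel versus random gene sets
#'
#' Compares the per-gene disease-association counts of the panel with the
#' pooled per-gene counts of random same-size gene sets, using the
#' two-sample Kolmogorov-Smirnov test (asymptotic p). Genes without any
#' recorded association count as zero. The mean-count ratio
#' (panel / baseline) is reported alongside.
#'
#' @param panel a `reporter_panel` or character vector of genes.
#' @param diseases data.frame (gene, disease), deduplicated pairs.
#' @param n_random number of random sets (>= 1).
#' @param seed optional RNG seed.
#' @param universe genes the random sets are drawn from; defaults to all
#'   genes in the disease table.
#' @return List with `ks_stat`, `ks_p`, `mean_ratio`, `panel_counts`,
#'   `baseline_counts`.
#' @export
disease_density_comparison <- function(panel, diseases, n_random = 1000L,
                                       seed = NULL, universe = NULL) {
  genes <- unique(if (inherits(panel, "reporter_panel")) panel$genes
                  else panel)
  stopifnot(is.data.frame(diseases),
            all(c("gene", "disease") %in% names(diseases)))
  if (n_random < 1) stop("n_random must be >= 1")
  if (is.null(universe)) universe <- unique(diseases$gene)
  if (!is.null(seed)) set.seed(seed)
  counts_of <- function(g) {
    tab <- table(factor(diseases$gene[diseases$gene %in% g], levels = g))
    as.integer(tab)
  }
  panel_counts <- counts_of(genes)
  size <- min(length(genes), length(universe))
  baseline_counts <- unlist(lapply(seq_len(n_random), function(i)
    counts_of(sample(universe, size))))
  ks <- suppressWarnings(stats::ks.test(panel_counts, baseline_counts,
                                        exact = FALSE))
  list(ks_stat = unname(ks$statistic), ks_p = ks$p.value,
       mean_ratio = mean(panel_counts) / mean(baseline_counts),
       panel_counts = panel_counts, baseline_counts = baseline_counts)
}

#' Cross-check panel centrality on an independent regulatory network
#'
#' Computes PageRank on a network that was not used for panel design and
#' compares the median centrality of panel genes with that of all other
#' genes in that network.
#'
#' @param panel a `reporter_panel` or character vector of genes.
#' @param network independent [regulatory_network].
#' @param mode,damping PageRank parameters.
#' @return List with `median_panel`, `median_background`, `ratio`,
#'   `n_panel_in_network`.
#' @export
centrality_crosscheck <- function(panel, network, mode = "undirected",
                                  damping = 0.85) {
  genes <- unique(if (inherits(panel, "reporter_panel")) panel$genes
                  else panel)
  scores <- pagerank(network, mode = mode, damping = damping)
  in_panel <- scores$gene %in% genes
  if (!any(in_panel)) stop("no panel gene occurs in the network")
  if (all(in_panel)) stop("background is empty: panel covers every network gene")
  med_p <- stats::median(scores$score[in_panel])
  med_b <- stats::median(scores$score[!in_panel])
  list(median_panel = med_p, median_background = med_b,
       ratio = med_p / med_b, n_panel_in_network = sum(in_panel))
}

#' Interaction-role coverage of a panel with a bootstrap baseline
#'
#' Fraction of regulatory interactions (edges) in which a panel gene acts as
#' the upstream regulator (edge source), as the downstream target (edge
#' target), or as either ("involved"). The baseline resamples random gene
#' sets of the same size from the network's nodes and reports the mean and
#' percentile confidence interval of their involvement.
#'
#' @param panel a `reporter_panel` or character vector of genes.
#' @param network a [regulatory_network].
#' @param n_boot number of random baseline sets (>= 1).
#' @param seed optional RNG seed.
#' @return A `coverage_report` list: `upstream`, `downstream`, `involved`
#'   fractions; `n_upstream_genes`, `n_downstream_genes` panel-gene counts
#'   per role; `baseline` (mean and 2.5/97.5 percentile CI of the involved
#'   fraction over random sets, plus the resampled values).
#' @export
interaction_coverage <- function(panel, network, n_boot = 500L,
                                 seed = NULL) {
  genes <- unique(if (inherits(panel, "reporter_panel")) panel$genes
                  else panel)
  stopifnot(inherits(network, "regulatory_network"))
  if (n_boot < 1) stop("n_boot must be >= 1")
  src <- network$edges$source
  tgt <- network$edges$target
  nodes <- network_nodes(network)
  frac <- function(g) {
    s <- src %in% g; t <- tgt %in% g
    c(upstream = mean(s), downstream = mean(t), involved = mean(s | t))
  }
  obs <- frac(genes)
  size <- min(length(genes), length(nodes))
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i)
    frac(sample(nodes, size))[["involved"]], numeric(1))
  structure(list(
    upstream = obs[["upstream"]], downstream = obs[["downstream"]],
    involved = obs[["involved"]],
    n_upstream_genes = length(intersect(genes, unique(src))),
    n_downstream_genes = length(intersect(genes, unique(tgt))),
    baseline = list(mean = mean(boot),
                    ci = stats::quantile(boot, c(0.025, 0.975)),
                    values = boot, n_boot = n_boot, size = size)),
    class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "coverage_report: upstream %.1f%%, downstream %.1f%%, involved %.1f%%\n",
    100 * x$upstream, 100 * x$downstream, 100 * x$involved))
  cat(sprintf("  random baseline involved: %.1f%% (95%% CI %.1f%%-%.1f%%)\n",
              100 * x$baseline$mean, 100 * x$baseline$ci[[1]],
              100 * x$baseline$ci[[2]]))
  invisible(x)
}
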
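#' Shared pathway counts for all gene pairs
#'
#' For every unordered pair of genes that shares at least one pathway in the
#' bipartite association graph, counts the number of common pathway
#' neighbors. Pairs with disjoint membership are absent from the table.
#'
#' @param assoc a [pathway_gene_associations] object.
#' @return data.frame with columns `gene_a`, `gene_b` (with
#'   `gene_a < gene_b`) and `shared`.
#' @export
shared_pathway_counts <- function(assoc) {
  stopifnot(inherits(assoc, "pathway_gene_associations"))
  if (!nrow(assoc$edges)) stop("association graph is empty")
  B <- incidence_matrix(assoc)
  S <- Matrix::crossprod(B)   # gene x gene shared-pathway counts
  tab <- Matrix::summary(Matrix::triu(S, k = 1))
  genes <- colnames(B)
  out <- data.frame(gene_a = genes[tab$i], gene_b = genes[tab$j],
                    shared = as.integer(tab$x), stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  out
}

# 0/1 pathway x gene incidence matrix (membership, roles collapsed)
incidence_matrix <- function(assoc) {
  e <- unique(assoc$edges[, c("pathway", "gene")])
  p <- factor(e$pathway, levels = assoc$pathways)
  g <- factor(e$gene, levels = assoc$genes)
  Matrix::sparseMatrix(i = as.integer(p), j = as.integer(g), x = 1,
                       dims = c(length(assoc$pathways), length(assoc$genes)),
                       dimnames = list(assoc$pathways, assoc$genes))
}

#' Gene pairs sharing more pathways than a degree-preserving null
#'
#' Tests, for every gene pair with at least one shared pathway, whether the
#' observed number of shared pathways exceeds what is expected under a
#' degree-preserving randomization of the bipartite pathway-gene graph. Each
#' null replicate rewires the graph by checked edge swaps (preserving every
#' pathway's and every gene's degree) and recomputes the shared counts; the
#' empirical p-value uses the add-one estimator
#' p = (1 + #\{null >= observed\}) / (1 + n_permutations). Pairs below
#' `alpha` (raw, unadjusted) are flagged as informationally redundant.
#'
#' @param assoc a [pathway_gene_associations] object.
#' @param n_permutations number of null replicates (>= 100).
#' @param alpha raw significance level in (0, 1).
#' @param seed integer seed for the rewiring RNG (optional).
#' @param swap_factor number of attempted swaps per replicate, as a multiple
#'   of the edge count; each replicate restarts from the observed graph.
#' @return An object of class `redundant_pairs`: list with `pairs` (the
#'   significant pairs, ascending p then pair key), `tested` (all pairs with
#'   >= 1 shared pathway and their empirical p), and the parameters.
#' @export
sicore_pairs <- function(assoc, n_permutations = 1000L, alpha = 0.05,
                         seed = NULL, swap_factor = 10) {
  stopifnot(inherits(assoc, "pathway_gene_associations"))
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  obs <- shared_pathway_counts(assoc)
  genes <- assoc$genes
  e <- unique(assoc$edges[, c("pathway", "gene")])
  pi <- as.integer(factor(e$pathway, levels = assoc$pathways))
  gi <- as.integer(factor(e$gene, levels = genes))
  m <- length(pi)
  n_swaps <- as.integer(ceiling(swap_factor * m))
  npair_key <- length(genes) + 1
  ia <- match(obs$gene_a, genes)
  ib <- match(obs$gene_b, genes)
  obs_key <- ia * npair_key + ib
  exceed <- integer(nrow(obs))
  dims <- c(length(assoc$pathways), length(genes))
  for (r in seq_len(n_permutations)) {
    perm <- swap_bipartite_edges(pi, gi, n_swaps)
    Bp <- Matrix::sparseMatrix(i = perm[, 1], j = perm[, 2], x = 1,
                               dims = dims)
    Sp <- Matrix::summary(Matrix::triu(Matrix::crossprod(Bp), k = 1))
    null_counts <- Sp$x[match(obs_key, Sp$i * npair_key + Sp$j)]
    null_counts[is.na(null_counts)] <- 0
    exceed <- exceed + (null_counts >= obs$shared)
  }
  obs$empirical_p <- (1 + exceed) / (1 + n_permutations)
  sig <- obs[obs$empirical_p < alpha, , drop = FALSE]
  sig <- sig[order(sig$empirical_p, sig$gene_a, sig$gene_b), , drop = FALSE]
  rownames(sig) <- NULL
  structure(list(pairs = sig, tested = obs,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, seed = seed),
            class = "redundant_pairs")
}

#' @export
print.redundant_pairs <- function(x, ...) {
  cat("redundant_pairs:", nrow(x$pairs), "significant of", nrow(x$tested),
      "tested pairs (alpha =", x$alpha, ", N =", x$n_permutations, ")\n")
  invisible(x)
}

#' Remove the lower-centrality member of each redundant gene pair
#'
#' Pairs are processed in ascending empirical p (ties by the lexicographic
#' pair key) so the strongest redundancies are honored first. A pair is
#' skipped when either member was already removed by an earlier pair; from
#' each remaining pair the gene with the lower PageRank centrality is removed
#' (on a score tie, the lexicographically later gene id).
#'
#' @param ranking a `centrality_scores` object covering all pair members.
#' @param pairs a `redundant_pairs` object, or a data.frame with columns
#'   `gene_a`, `gene_b` and optionally `empirical_p`.
#' @return Character vector of retained genes in ranking order, with
#'   attribute `removed`: data.frame (gene, paired_with, empirical_p).
#' @export
prune_by_pairs <- function(ranking, pairs) {
  if (inherits(pairs, "redundant_pairs")) pairs <- pairs$pairs
  stopifnot(is.data.frame(pairs))
  if (is.null(pairs$empirical_p))
    pairs$empirical_p <- rep(NA_real_, nrow(pairs))
  if (nrow(pairs)) {
    score_of(ranking, unique(c(pairs$gene_a, pairs$gene_b)))  # fail fast
    pairs <- pairs[order(pairs$empirical_p, pairs$gene_a, pairs$gene_b), ]
    removed <- character(0)
    paired_with <- character(0)
    p_at_removal <- numeric(0)
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
      if (a %in% removed || b %in% removed) next
      sa <- unname(score_of(ranking, a))
      sb <- unname(score_of(ranking, b))
      drop <- if (sa > sb) b else if (sb > sa) a else max(a, b)
      keep <- setdiff(c(a, b), drop)
      removed <- c(removed, drop)
      paired_with <- c(paired_with, keep)
      p_at_removal <- c(p_at_removal, pairs$empirical_p[i])
    }
  } else {
    removed <- character(0); paired_with <- character(0)
    p_at_removal <- numeric(0)
  }
  retained <- setdiff(ranking$gene, removed)
  structure(retained,
            removed = data.frame(gene = removed, paired_with = paired_with,
                                 empirical_p = p_at_removal,
                                 stringsAsFactors = FALSE))
}

#' Co-expression clusters from pairwise correlations
#'
#' Clusters are the connected components of the graph whose edges join gene
#' pairs with correlation strictly greater than `r_min`. Only positive
#' correlations form edges; strongly anti-correlated genes stay in separate
#' clusters. Genes present in the correlation table but without any strong
#' partner become singletons.
#'
#' @param correlations data.frame with columns `gene_a`, `gene_b`, `r`.
#' @param r_min correlation threshold (strict inequality); default 0.90.
#' @return An object of class `coexpression_clusters`: data.frame mapping
#'   `gene` to `cluster`, with attribute `r_min`.
#' @export
coexpression_clusters <- function(correlations, r_min = 0.90) {
  stopifnot(is.data.frame(correlations),
            all(c("gene_a", "gene_b", "r") %in% names(correlations)))
  if (any(abs(correlations$r) > 1))
    stop("correlation values must lie in [-1, 1]")
  covered <- sort(unique(c(correlations$gene_a, correlations$gene_b)))
  strong <- correlations[correlations$r > r_min, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    strong[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = covered))
  comp <- igraph::components(g)
  out <- data.frame(gene = covered,
                    cluster = sprintf("C%03d", comp$membership[covered]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("coexpression_clusters", "data.frame"),
            r_min = r_min)
}

#' Keep one representative per co-expression cluster
#'
#' Within each co-expression cluster, only the gene with the highest PageRank
#' centrality among the input genes is retained (score tie: lexicographically
#' earlier id); the others are removed. Genes outside any cluster pass
#' through unchanged.
#'
#' @param genes candidate gene ids (order preserved in the output).
#' @param clusters a [coexpression_clusters] object.
#' @param ranking a `centrality_scores` object covering all clustered input
#'   genes.
#' @return Character vector of retained genes, with attribute `removed`:
#'   data.frame (gene, cluster, representative).
#' @export
coexpression_dedup <- function(genes, clusters, ranking) {
  stopifnot(inherits(clusters, "coexpression_clusters"))
  cl <- clusters$cluster[match(genes, clusters$gene)]
  removed <- character(0); removed_cl <- character(0); rep_of <- character(0)
  for (cid in unique(cl[!is.na(cl)])) {
    members <- genes[!is.na(cl) & cl == cid]
    if (length(members) < 2) next
    sc <- score_of(ranking, members)
    keep <- members[order(-sc, members)][1]
    drop <- setdiff(members, keep)
    removed <- c(removed, drop)
    removed_cl <- c(removed_cl, rep(cid, length(drop)))
    rep_of <- c(rep_of, rep(keep, length(drop)))
  }
  structure(setdiff(genes, removed),
            removed = data.frame(gene = removed, cluster = removed_cl,
                                 representative = rep_of,
                                 stringsAsFactors = FALSE))
}
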
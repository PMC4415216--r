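#' Simulate a knowledge base with planted ground truth
#'
#' Generates every knowledge input the panel-design pipeline consumes —
#' a directed regulatory network, bipartite pathway-gene associations, a
#' pairwise co-expression table, a gene-annotation table and a gene-disease
#' table — with planted structure whose recovery the test suite checks:
#' \itemize{
#'   \item hub genes with out-degree far above the median, built by
#'     preferential attachment, which also join more pathways, carry the
#'     designated enriched annotation terms (experimental evidence) and a
#'     multiple of the background disease-association rate;
#'   \item redundant gene pairs cloned with identical pathway membership;
#'   \item co-expression clusters whose members correlate above 0.9.
#' }
#' Each artifact draws from its own RNG stream derived from the master seed,
#' so components can be regenerated independently and a fixed seed
#' reproduces the knowledge base exactly.
#'
#' @param n_genes number of genes (>= 10).
#' @param n_pathways number of pathways (>= 2).
#' @param hub_fraction fraction of genes designated as hubs.
#' @param redundancy list: `n_pairs` cloned pairs, `membership_size` shared
#'   pathways per clone pair.
#' @param annotation list: `n_terms` total terms, `n_enriched` hub-enriched
#'   terms, `background_rate` mean terms per gene, `enriched_coverage`
#'   fraction of hubs carrying each enriched term.
#' @param disease list: `n_diseases` disease pool size, `mean_count`
#'   background mean associations per gene, `density_factor` hub multiplier.
#' @param coexpression list: `n_clusters`, `cluster_size`, `n_background`
#'   weakly correlated pairs.
#' @param seed master seed.
#' @param hubs optional explicit hub gene ids (from the generated `G...`
#'   namespace), e.g. to build an independent network that plants the same
#'   hub identities; overrides `hub_fraction`.
#' @return A `synthetic_knowledge_base` list: `assoc`
#'   ([pathway_gene_associations]), `network` ([regulatory_network]),
#'   `correlations`, `annotations`, `diseases` (data.frames) and `truth`
#'   (planted hubs, redundant pairs, clusters, enriched terms, parameters).
#' @export
simulate_knowledge_base <- function(
    n_genes = 1000L, n_pathways = 30L, hub_fraction = 0.05,
    redundancy = list(n_pairs = 10L, membership_size = 6L),
    annotation = list(n_terms = 200L, n_enriched = 20L,
                      background_rate = 2, enriched_coverage = 0.4),
    disease = list(n_diseases = 300L, mean_count = 2, density_factor = 3),
    coexpression = list(n_clusters = 10L, cluster_size = 3L,
                        n_background = 200L),
    seed = 1L, hubs = NULL) {
  if (n_genes < 10) stop("n_genes must be >= 10")
  if (n_pathways < 2) stop("n_pathways must be >= 2")
  genes <- sprintf("G%05d", seq_len(n_genes))
  pathways <- sprintf("PW%03d", seq_len(n_pathways))
  if (is.null(hubs)) {
    n_hubs <- round(hub_fraction * n_genes)
  } else {
    if (!all(hubs %in% genes))
      stop("designated hubs must be drawn from the generated gene ids")
    n_hubs <- length(hubs)
  }
  if (2 * redundancy$n_pairs + coexpression$n_clusters *
        coexpression$cluster_size + n_hubs > n_genes)
    stop("infeasible specification: planted hubs, clone pairs and clusters ",
         "exceed the gene count")
  if (redundancy$membership_size > n_pathways)
    stop("infeasible specification: clone membership exceeds pathway count")

  set.seed(seed %% .Machine$integer.max)
  if (is.null(hubs)) hubs <- sort(sample(genes, n_hubs))
  non_hub <- setdiff(genes, hubs)
  clone_genes <- sample(non_hub, 2 * redundancy$n_pairs)
  clone_pairs <- data.frame(
    gene_a = pmin(clone_genes[seq_len(redundancy$n_pairs)],
                  clone_genes[-seq_len(redundancy$n_pairs)]),
    gene_b = pmax(clone_genes[seq_len(redundancy$n_pairs)],
                  clone_genes[-seq_len(redundancy$n_pairs)]),
    stringsAsFactors = FALSE)
  cluster_pool <- setdiff(non_hub, clone_genes)
  cluster_members <- sample(cluster_pool,
                            coexpression$n_clusters * coexpression$cluster_size)
  clusters <- split(cluster_members,
                    rep(seq_len(coexpression$n_clusters),
                        each = coexpression$cluster_size))
  names(clusters) <- sprintf("K%02d", seq_along(clusters))

  # --- regulatory network: preferential attachment, hubs fan out widely ---
  set.seed((seed + 1001L) %% .Machine$integer.max)
  is_hub <- genes %in% hubs
  out_deg <- 1L + stats::rpois(n_genes, 1)
  out_deg[is_hub] <- 15L + stats::rpois(n_hubs, 5)
  deg_weight <- rep(1, n_genes)
  src_idx <- integer(0); tgt_idx <- integer(0)
  for (i in sample.int(n_genes)) {
    k <- min(out_deg[i], n_genes - 1L)
    w <- deg_weight; w[i] <- 0
    tgts <- sample.int(n_genes, k, prob = w)
    src_idx <- c(src_idx, rep(i, k)); tgt_idx <- c(tgt_idx, tgts)
    deg_weight[tgts] <- deg_weight[tgts] + 1
    deg_weight[i] <- deg_weight[i] + k
  }
  network <- regulatory_network(data.frame(
    source = genes[src_idx], target = genes[tgt_idx],
    relation = "regulates", stringsAsFactors = FALSE))

  # --- bipartite associations ---
  # Background genes carry exactly two pathway memberships (a "slot", i.e.
  # an unordered pathway pair): any incidental slot collision is a pair
  # with fully identical membership, a genuine redundancy the pipeline is
  # expected to prune. Hubs are pleiotropic and join about a third of all
  # pathways, drawn so that no two hubs share more than half of them:
  # overlap of that order is unremarkable under the degree-preserving
  # null, so hubs are not flagged against each other or against background
  # genes. Planted clone pairs get identical memberships of size
  # `membership_size`, the redundancy signal proper.
  set.seed((seed + 2002L) %% .Machine$integer.max)
  memb <- vector("list", n_genes)
  names(memb) <- genes
  bg <- setdiff(genes, c(hubs, clone_genes))
  slot_pairs <- utils::combn(pathways, 2L)
  slot_idx <- sample.int(ncol(slot_pairs), length(bg), replace = TRUE)
  memb[bg] <- lapply(slot_idx, function(j) slot_pairs[, j])
  hub_deg <- max(2L, min(floor(n_pathways / 3), n_pathways - 1L))
  hub_max_overlap <- max(1L, floor(hub_deg * 0.5))
  usage <- stats::setNames(rep(0, n_pathways), pathways)
  hub_sets <- list()
  for (h in hubs) {
    pick <- NULL
    for (try in 1:100) {
      cand <- sample(pathways, hub_deg, prob = 1 / (1 + usage))
      if (!length(hub_sets) ||
          max(vapply(hub_sets, function(s) length(intersect(s, cand)), 0L))
          <= hub_max_overlap) { pick <- cand; break }
    }
    if (is.null(pick)) pick <- cand
    hub_sets[[h]] <- pick
    usage[pick] <- usage[pick] + 1
    memb[[h]] <- pick
  }
  for (j in seq_len(nrow(clone_pairs))) {
    shared <- sample(pathways, redundancy$membership_size)
    memb[[clone_pairs$gene_a[j]]] <- shared
    memb[[clone_pairs$gene_b[j]]] <- shared
  }
  edge_gene <- rep(genes, lengths(memb))
  assoc <- pathway_gene_associations(data.frame(
    pathway = unlist(memb, use.names = FALSE), gene = edge_gene,
    role = ifelse(edge_gene %in% hubs, "regulator", "target"),
    provenance = I(as.list(rep("synthetic", length(edge_gene)))),
    stringsAsFactors = FALSE))

  # --- co-expression table ---
  set.seed((seed + 3003L) %% .Machine$integer.max)
  corr <- do.call(rbind, lapply(clusters, function(cl) {
    idx <- utils::combn(sort(cl), 2)
    data.frame(gene_a = idx[1, ], gene_b = idx[2, ],
               r = stats::runif(ncol(idx), 0.92, 0.99),
               stringsAsFactors = FALSE)
  }))
  bg_a <- sample(genes, coexpression$n_background, replace = TRUE)
  bg_b <- sample(genes, coexpression$n_background, replace = TRUE)
  keep <- bg_a != bg_b
  corr <- rbind(corr, data.frame(
    gene_a = pmin(bg_a[keep], bg_b[keep]),
    gene_b = pmax(bg_a[keep], bg_b[keep]),
    r = stats::runif(sum(keep), -0.5, 0.5), stringsAsFactors = FALSE))
  corr <- corr[!duplicated(corr[, c("gene_a", "gene_b")]), ]
  rownames(corr) <- NULL

  # --- annotations: hubs enriched for designated terms ---
  set.seed((seed + 4004L) %% .Machine$integer.max)
  terms <- sprintf("T%04d", seq_len(annotation$n_terms))
  enriched_terms <- terms[seq_len(annotation$n_enriched)]
  exp_codes <- c("EXP", "IDA", "IMP")
  other_codes <- c("IEA", "ISS")
  n_bg <- stats::rpois(n_genes, annotation$background_rate)
  ann_bg <- data.frame(
    gene = rep(genes, n_bg),
    term = sample(terms, sum(n_bg), replace = TRUE),
    evidence = sample(c(exp_codes, other_codes), sum(n_bg), replace = TRUE),
    stringsAsFactors = FALSE)
  ann_en <- do.call(rbind, lapply(enriched_terms, function(t) {
    carriers <- sample(hubs, max(2, round(annotation$enriched_coverage *
                                            length(hubs))))
    data.frame(gene = carriers, term = t,
               evidence = sample(exp_codes, length(carriers), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  annotations <- unique(rbind(ann_bg, ann_en))
  rownames(annotations) <- NULL

  # --- diseases: hubs carry density_factor x the background rate ---
  set.seed((seed + 5005L) %% .Machine$integer.max)
  lambda <- rep(disease$mean_count, n_genes)
  lambda[is_hub] <- disease$mean_count * disease$density_factor
  n_dis <- stats::rpois(n_genes, lambda)
  diseases <- unique(data.frame(
    gene = rep(genes, n_dis),
    disease = sprintf("D%04d", sample.int(disease$n_diseases, sum(n_dis),
                                          replace = TRUE)),
    stringsAsFactors = FALSE))
  rownames(diseases) <- NULL

  structure(list(
    assoc = assoc, network = network, correlations = corr,
    annotations = annotations, diseases = diseases,
    truth = list(hubs = hubs, redundant_pairs = clone_pairs,
                 clusters = clusters, enriched_terms = enriched_terms,
                 high_density_genes = hubs,
                 params = list(n_genes = n_genes, n_pathways = n_pathways,
                               hub_fraction = hub_fraction,
                               redundancy = redundancy,
                               annotation = annotation, disease = disease,
                               coexpression = coexpression),
                 seed = seed)),
    class = "synthetic_knowledge_base")
}

#' @export
print.synthetic_knowledge_base <- function(x, ...) {
  cat("synthetic_knowledge_base:", length(x$assoc$genes), "genes,",
      length(x$assoc$pathways), "pathways,",
      length(x$truth$hubs), "planted hubs\n")
  invisible(x)
}

#' Write a synthetic knowledge base to disk
#'
#' Emits the same plain-text formats the reading functions consume:
#' `associations.gmt`, `network.tsv`, `correlations.tsv`,
#' `annotations.tsv`, `diseases.tsv` and `truth.json`.
#'
#' @param kb a `synthetic_knowledge_base`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_knowledge_base <- function(kb, dir) {
  stopifnot(inherits(kb, "synthetic_knowledge_base"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("associations.gmt", "network.tsv",
                            "correlations.tsv", "annotations.tsv",
                            "diseases.tsv", "truth.json"))
  write_gene_sets(kb$assoc, paths[1])
  utils::write.table(kb$network$edges, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(kb$correlations, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(kb$annotations, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(kb$diseases, paths[5], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(kb$truth, paths[6], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Simulate a targeted RNA count matrix with planted pathway activation
#'
#' Draws negative-binomial counts for the union of the gene-set genes over a
#' condition x replicate design. Per-gene baseline means are log-normal;
#' activated pathways shift their member genes' means by the planted
#' per-condition log2 fold-change (genes in several activated pathways
#' accumulate the shifts); per-sample library sizes are uniform in
#' `libsize_range` and gene means are rescaled so expected column sums match
#' them.
#'
#' @param gene_sets a [pathway_gene_associations] object or named list of
#'   gene vectors; the profiled genes are their union.
#' @param design data.frame with a `condition` column and optionally
#'   `replicate` (defaults to one row per replicate as given); one row per
#'   sample.
#' @param activation data.frame (pathway, condition, log2fc) of planted
#'   effects, or NULL for the global null.
#' @param libsize_range range of per-sample library sizes.
#' @param dispersion negative-binomial dispersion (> 0); variance is
#'   mu + dispersion * mu^2.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline means.
#' @param seed RNG seed.
#' @return List with `counts` (integer matrix, genes x samples), `meta`
#'   (sample metadata data.frame) and `truth` (baseline means, activation
#'   table, parameters).
#' @export
simulate_expression <- function(gene_sets, design, activation = NULL,
                                libsize_range = c(5e5, 1e6),
                                dispersion = 0.1,
                                baseline_meanlog = log(100),
                                baseline_sdlog = 1, seed = 1L) {
  sets <- if (inherits(gene_sets, "pathway_gene_associations"))
    gene_set_list(gene_sets) else gene_sets
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (!is.data.frame(design) || !nrow(design))
    stop("design must be a nonempty data.frame")
  if (!"condition" %in% names(design))
    stop("design needs a 'condition' column")
  if (dispersion <= 0) stop("dispersion must be > 0")
  genes <- sort(unique(unlist(sets)))
  n_samples <- nrow(design)
  if (is.null(design$replicate))
    design$replicate <- stats::ave(seq_len(n_samples),
                                   design$condition, FUN = seq_along)
  sample_ids <- paste0(design$condition, "_r", design$replicate)

  set.seed(seed %% .Machine$integer.max)
  mu0 <- stats::rlnorm(length(genes), baseline_meanlog, baseline_sdlog)
  names(mu0) <- genes
  lfc <- matrix(0, length(genes), n_samples,
                dimnames = list(genes, sample_ids))
  if (!is.null(activation) && nrow(activation)) {
    stopifnot(all(c("pathway", "condition", "log2fc") %in% names(activation)))
    for (j in seq_len(nrow(activation))) {
      members <- intersect(sets[[activation$pathway[j]]], genes)
      cols <- which(design$condition == activation$condition[j])
      lfc[members, cols] <- lfc[members, cols] + activation$log2fc[j]
    }
  }
  lib <- round(stats::runif(n_samples, libsize_range[1], libsize_range[2]))
  counts <- matrix(0L, length(genes), n_samples,
                   dimnames = list(genes, sample_ids))
  for (s in seq_len(n_samples)) {
    mu <- mu0 * 2^lfc[, s]
    mu <- mu / sum(mu) * lib[s]
    counts[, s] <- stats::rnbinom(length(genes), mu = mu,
                                  size = 1 / dispersion)
  }
  meta <- cbind(data.frame(sample = sample_ids, stringsAsFactors = FALSE),
                design)
  list(counts = counts, meta = meta,
       truth = list(baseline_mu = mu0, activation = activation,
                    libsizes = lib,
                    params = list(dispersion = dispersion,
                                  libsize_range = libsize_range,
                                  seed = seed)))
}

#' Planted tri-phasic activation profile for a set of pathways
#'
#' Convenience builder for the early / transient / late design used by the
#' temporal simulations: early pathways are active in the first condition
#' and decay, transient ones peak in an interior condition, late ones rise
#' towards the last condition.
#'
#' @param pathways pathway ids.
#' @param conditions ordered condition labels (>= 3).
#' @param effect peak log2 fold-change.
#' @param groups optional group assignment (`early`/`transient`/`late`),
#'   recycled over pathways; defaults to a balanced round-robin.
#' @return List with `activation` (data.frame pathway, condition, log2fc)
#'   and `groups` (named character vector of planted labels).
#' @export
triphasic_activation <- function(pathways, conditions, effect = 1.5,
                                 groups = NULL) {
  k <- length(conditions)
  if (k < 3) stop("need >= 3 conditions for a tri-phasic design")
  if (is.null(groups))
    groups <- rep(c("early", "transient", "late"),
                  length.out = length(pathways))
  names(groups) <- pathways
  profile_of <- function(g) {
    peak <- switch(g, early = 1, transient = ceiling((k + 1) / 2), late = k)
    # triangular profile, maximum `effect` at the peak condition
    effect * (1 - abs(seq_len(k) - peak) / k)
  }
  activation <- do.call(rbind, lapply(pathways, function(p)
    data.frame(pathway = p, condition = conditions,
               log2fc = profile_of(groups[[p]]), stringsAsFactors = FALSE)))
  list(activation = activation, groups = groups)
}
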
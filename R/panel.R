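#' Select the reporter panel from a ranked non-redundant gene list
#'
#' Takes the top `ceiling(fraction * n)` genes by descending centrality,
#' truncates to `max_size`, then removes any exclusion-list members without
#' backfilling (mirroring a vendor-driven removal after the panel has been
#' designed). An audit record is written for every candidate gene.
#'
#' @param ranked a `centrality_scores` object (or data.frame with columns
#'   `gene`, `score`) restricted to the non-redundant candidate genes.
#' @param fraction fraction of the ranked list to keep, in (0, 1].
#' @param max_size hard cap on the panel size (>= 1).
#' @param exclusions genes removed after selection (no backfill).
#' @return An object of class `reporter_panel`: list with `genes` (selected,
#'   descending centrality, ties by id), `audit` (data.frame gene, score,
#'   rank, status in selected/below-cutoff/excluded) and `params`.
#' @export
select_panel <- function(ranked, fraction = 0.2, max_size = Inf,
                         exclusions = character(0)) {
  stopifnot(is.data.frame(ranked), all(c("gene", "score") %in% names(ranked)))
  if (!nrow(ranked)) stop("ranked gene list is empty")
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  if (max_size < 1) stop("max_size must be >= 1")
  ord <- order(-ranked$score, ranked$gene)
  genes <- ranked$gene[ord]
  scores <- ranked$score[ord]
  n_cut <- min(ceiling(fraction * length(genes)), max_size)
  in_cut <- seq_along(genes) <= n_cut
  status <- ifelse(in_cut, "selected", "below-cutoff")
  status[in_cut & genes %in% exclusions] <- "excluded"
  audit <- data.frame(gene = genes, score = scores,
                      rank = seq_along(genes), status = status,
                      stringsAsFactors = FALSE)
  structure(list(genes = genes[status == "selected"],
                 audit = audit,
                 params = list(fraction = fraction, max_size = max_size,
                               exclusions = exclusions)),
            class = "reporter_panel")
}

#' @export
print.reporter_panel <- function(x, ...) {
  cat("reporter_panel:", length(x$genes), "genes selected of",
      nrow(x$audit), "candidates (fraction =", x$params$fraction, ")\n")
  invisible(x)
}

#' Design a reporter panel from knowledge inputs, end to end
#'
#' Runs the full prioritization workflow: PageRank centrality on the
#' regulatory network, removal of gene pairs sharing significantly more
#' pathways than the degree-preserving null (keeping the higher-centrality
#' member), co-expression-cluster deduplication, and the top-fraction panel
#' cut. Genes of the knowledge base absent from the regulatory network are
#' assigned score 0 and rank at the bottom of the list.
#'
#' @param assoc harmonized [pathway_gene_associations].
#' @param network a [regulatory_network] used for centrality.
#' @param correlations optional pairwise co-expression table
#'   (`gene_a`, `gene_b`, `r`); when NULL the co-expression filter is skipped.
#' @param mode,damping PageRank parameters, see [pagerank()].
#' @param n_permutations,alpha redundancy-test parameters, see
#'   [sicore_pairs()].
#' @param r_min co-expression clustering threshold.
#' @param fraction,max_size,exclusions panel-cut parameters, see
#'   [select_panel()].
#' @param seed seed for the permutation null.
#' @return A `reporter_panel` whose audit covers every gene of the knowledge
#'   base with a terminal status (selected / pruned-redundant /
#'   pruned-coexpression / below-cutoff / excluded); additional components
#'   `scores` (full centrality ranking) and `redundant_pairs`.
#' @export
design_panel <- function(assoc, network, correlations = NULL,
                         mode = "undirected", damping = 0.85,
                         n_permutations = 1000L, alpha = 0.05, r_min = 0.90,
                         fraction = 0.2, max_size = Inf,
                         exclusions = character(0), seed = NULL) {
  stopifnot(inherits(assoc, "pathway_gene_associations"),
            inherits(network, "regulatory_network"))
  scores <- pagerank(network, mode = mode, damping = damping)
  candidates <- assoc$genes
  sc <- data.frame(gene = candidates,
                   score = ifelse(candidates %in% scores$gene,
                                  scores$score[match(candidates, scores$gene)],
                                  0),
                   stringsAsFactors = FALSE)
  sc$rank <- rank_by_score(sc$score, sc$gene)
  sc <- sc[order(sc$rank), ]
  rownames(sc) <- NULL
  class(sc) <- c("centrality_scores", "data.frame")

  pairs <- sicore_pairs(assoc, n_permutations = n_permutations,
                        alpha = alpha, seed = seed)
  after_pairs <- prune_by_pairs(sc, pairs)
  pruned_red <- attr(after_pairs, "removed")

  if (!is.null(correlations)) {
    clusters <- coexpression_clusters(correlations, r_min = r_min)
    after_coexp <- coexpression_dedup(after_pairs, clusters, sc)
    pruned_co <- attr(after_coexp, "removed")
  } else {
    after_coexp <- after_pairs
    pruned_co <- data.frame(gene = character(0), cluster = character(0),
                            representative = character(0))
  }

  panel <- select_panel(sc[sc$gene %in% after_coexp, , drop = FALSE],
                        fraction = fraction, max_size = max_size,
                        exclusions = exclusions)

  audit <- panel$audit
  pruned <- rbind(
    data.frame(gene = pruned_red$gene,
               status = rep("pruned-redundant", nrow(pruned_red)),
               stringsAsFactors = FALSE),
    data.frame(gene = pruned_co$gene,
               status = rep("pruned-coexpression", nrow(pruned_co)),
               stringsAsFactors = FALSE))
  if (nrow(pruned)) {
    pruned$score <- sc$score[match(pruned$gene, sc$gene)]
    pruned$rank <- sc$rank[match(pruned$gene, sc$gene)]
    audit <- rbind(audit, pruned[, c("gene", "score", "rank", "status")])
  }
  audit <- audit[order(audit$rank), ]
  rownames(audit) <- NULL
  panel$audit <- audit
  panel$scores <- sc
  panel$redundant_pairs <- pairs
  panel$params <- c(panel$params,
                    list(mode = mode, damping = damping,
                         n_permutations = n_permutations, alpha = alpha,
                         r_min = r_min, seed = seed))
  panel
}

#' Pathway coverage of a reporter panel
#'
#' Reports how many panel genes report on each pathway and how many pathways
#' each panel gene belongs to; pathways left without any reporter are
#' flagged.
#'
#' @param panel a `reporter_panel` object or a character vector of genes.
#' @param assoc a [pathway_gene_associations] object containing all panel
#'   genes.
#' @return List with `per_pathway` (pathway, n_reporters), `per_gene`
#'   (gene, n_pathways) and `uncovered` (pathways with zero reporters).
#' @export
pathway_coverage <- function(panel, assoc) {
  genes <- if (inherits(panel, "reporter_panel")) panel$genes else panel
  stopifnot(inherits(assoc, "pathway_gene_associations"))
  missing <- setdiff(genes, assoc$genes)
  if (length(missing))
    stop("panel gene(s) absent from associations: ",
         paste(utils::head(missing, 5), collapse = ", "))
  e <- unique(assoc$edges[, c("pathway", "gene")])
  e_panel <- e[e$gene %in% genes, , drop = FALSE]
  per_pathway <- data.frame(
    pathway = assoc$pathways,
    n_reporters = as.integer(table(factor(e_panel$pathway,
                                          levels = assoc$pathways))),
    stringsAsFactors = FALSE)
  per_gene <- data.frame(
    gene = genes,
    n_pathways = as.integer(table(factor(e_panel$gene, levels = genes))),
    stringsAsFactors = FALSE)
  list(per_pathway = per_pathway, per_gene = per_gene,
       uncovered = per_pathway$pathway[per_pathway$n_reporters == 0])
}

#' Write a panel and its audit trail as TSV
#' @param panel a `reporter_panel` object.
#' @param path output path for the panel table; the audit goes to
#'   `<path base>_audit.tsv`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "reporter_panel"))
  sel <- panel$audit[panel$audit$status == "selected", ]
  utils::write.table(sel[, c("gene", "rank", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  audit_path <- sub("(\\.[^.]*)?$", "_audit.tsv", path)
  utils::write.table(panel$audit, audit_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, audit_path))
}
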
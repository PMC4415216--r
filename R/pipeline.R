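#' Default pipeline configuration
#'
#' Returns the full configuration skeleton understood by [run_pipeline()]:
#' input paths under `$inputs`, stage parameters under `$params`, and the
#' output directory under `$output$dir`. Unknown keys in a user
#' configuration are rejected, so the run manifest always documents every
#' parameter of every executed stage.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    inputs = list(
      gene_sets = NULL,            # one GMT path or a vector of them
      network = NULL,              # regulatory network edge-list TSV
      correlations = NULL,         # co-expression pairs TSV (optional)
      annotations = NULL,          # annotation TSV (optional, validation)
      diseases = NULL,             # disease TSV (optional, validation)
      independent_network = NULL   # cross-check network TSV (optional)
    ),
    params = list(
      mode = "undirected", damping = 0.85,
      n_permutations = 1000L, alpha = 0.05, r_min = 0.90,
      fraction = 0.2, max_size = Inf, exclusions = character(0),
      n_random = 1000L, n_boot = 500L,
      experimental_evidence_only = TRUE,
      seed = 1L
    ),
    output = list(dir = ".")
  )
}

validate_config <- function(config, template = default_config()) {
  unknown <- setdiff(names(config), names(template))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      bad <- setdiff(names(config[[nm]]), names(template[[nm]]))
      if (length(bad))
        stop("unknown configuration key(s) under '", nm, "': ",
             paste(bad, collapse = ", "))
    }
  }
  merged <- template
  for (nm in names(config))
    merged[[nm]] <- utils::modifyList(template[[nm]], as.list(config[[nm]]))
  merged
}

#' Run the full panel-design workflow from a configuration
#'
#' Executes harmonization, centrality, redundancy filtering, panel selection
#' and (when annotation / disease / independent-network inputs are present)
#' the in-silico validation suite, writing all outputs and a run manifest to
#' the configured directory. Rerunning with an identical configuration and
#' inputs reproduces identical output tables.
#'
#' @param config nested list as in [default_config()], or the path of a
#'   YAML file holding one. Unknown keys are rejected before any stage runs.
#' @return Invisibly, a list with the `panel`, the optional `validation`
#'   report, and the `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  config <- validate_config(config)
  inp <- config$inputs
  par <- config$params
  if (is.null(inp$gene_sets))
    stop("configuration error: inputs$gene_sets is required")
  if (is.null(inp$network))
    stop("configuration error: inputs$network is required")
  for (p in c(unlist(inp))) if (!is.null(p) && !file.exists(p))
    stop("configuration error: input file not found: ", p)

  dir.create(config$output$dir, showWarnings = FALSE, recursive = TRUE)
  out_file <- function(name) file.path(config$output$dir, name)

  assoc <- harmonize(lapply(inp$gene_sets, read_gene_sets))
  network <- read_edge_list(inp$network)
  correlations <- if (!is.null(inp$correlations))
    utils::read.delim(inp$correlations, stringsAsFactors = FALSE) else NULL

  panel <- design_panel(
    assoc, network, correlations = correlations,
    mode = par$mode, damping = par$damping,
    n_permutations = par$n_permutations, alpha = par$alpha,
    r_min = par$r_min, fraction = par$fraction, max_size = par$max_size,
    exclusions = par$exclusions, seed = par$seed)
  write_panel(panel, out_file("panel.tsv"))
  write_centrality(panel$scores, out_file("scores.tsv"))
  utils::write.table(panel$redundant_pairs$pairs,
                     out_file("redundant_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  validation <- NULL
  report <- list()
  if (!is.null(inp$annotations)) {
    ann <- read_annotation_table(inp$annotations)
    if (isTRUE(par$experimental_evidence_only)) ann <- filter_experimental(ann)
    universe <- unique(ann$gene)
    enr <- fisher_enrichment(intersect(panel$genes, universe), ann, universe)
    report$enrichment <- list(
      significant_terms = significant_term_count(enr, par$alpha),
      n_terms_tested = nrow(enr))
  }
  if (!is.null(inp$diseases)) {
    dis <- read_disease_table(inp$diseases)
    dd <- disease_density_comparison(panel$genes, dis,
                                     n_random = par$n_random,
                                     seed = par$seed)
    report$disease_density <- dd[c("ks_stat", "ks_p", "mean_ratio")]
  }
  if (!is.null(inp$independent_network)) {
    indep <- read_edge_list(inp$independent_network)
    cc <- centrality_crosscheck(panel$genes, indep, mode = par$mode,
                                damping = par$damping)
    cov <- interaction_coverage(panel$genes, indep, n_boot = par$n_boot,
                                seed = par$seed)
    report$centrality_crosscheck <- cc
    report$interaction_coverage <- list(
      upstream = cov$upstream, downstream = cov$downstream,
      involved = cov$involved,
      baseline_mean = cov$baseline$mean,
      baseline_ci = as.numeric(cov$baseline$ci))
  }
  if (length(report)) {
    validation <- report
    jsonlite::write_json(report, out_file("validation_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  manifest <- list(
    package = "pathpanel",
    version = as.character(utils::packageVersion("pathpanel")),
    inputs = inp[!vapply(inp, is.null, TRUE)],
    input_md5 = as.list(tools::md5sum(unlist(
      inp[!vapply(inp, is.null, TRUE)]))),
    params = par,
    n_panel_genes = length(panel$genes))
  jsonlite::write_json(manifest, out_file("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(panel = panel, validation = validation,
                 manifest = manifest))
}
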
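#' Pathway-gene association container
#'
#' A `pathway_gene_associations` object stores a bipartite graph linking
#' pathway nodes to gene nodes. Every edge carries a role (is the gene a
#' regulator of the pathway, one of its expression targets, or is the role
#' unspecified) and a provenance set naming the knowledge sources that
#' contributed it. Pathway and gene identifier namespaces must be disjoint so
#' that the graph stays bipartite.
#'
#' @param edges data.frame with columns `pathway`, `gene`, `role` and,
#'   optionally, `provenance` (a list column of character vectors; a plain
#'   character column is promoted to singleton sets). Duplicate
#'   (pathway, gene, role) triples are merged and their provenance unioned.
#'
#' @return An object of class `pathway_gene_associations`: a list with
#'   components `edges` (data.frame with a `provenance` list column),
#'   `pathways` and `genes` (character vectors of the declared node sets).
#' @export
pathway_gene_associations <- function(edges) {
  stopifnot(is.data.frame(edges))
  required <- c("pathway", "gene")
  if (!all(required %in% names(edges)))
    stop("edges must have columns 'pathway' and 'gene'")
  edges$pathway <- as.character(edges$pathway)
  edges$gene <- as.character(edges$gene)
  if (is.null(edges$role)) edges$role <- "unspecified"
  edges$role <- as.character(edges$role)
  bad <- setdiff(unique(edges$role), c("regulator", "target", "unspecified"))
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (is.null(edges$provenance)) {
    edges$provenance <- replicate(nrow(edges), character(0), simplify = FALSE)
  } else if (!is.list(edges$provenance)) {
    edges$provenance <- as.list(as.character(edges$provenance))
  }
  overlap <- intersect(unique(edges$pathway), unique(edges$gene))
  if (length(overlap))
    stop("pathway and gene namespaces overlap (not bipartite): ",
         paste(utils::head(overlap, 5), collapse = ", "))
  # merge duplicate (pathway, gene, role) triples, unioning provenance
  key <- paste(edges$pathway, edges$gene, edges$role, sep = "\r")
  if (anyDuplicated(key)) {
    prov <- lapply(split(edges$provenance, key), function(p)
      sort(unique(unlist(p))))
    first <- !duplicated(key)
    merged <- edges[first, c("pathway", "gene", "role")]
    merged$provenance <- unname(prov[key[first]])
    edges <- merged
  } else {
    edges$provenance <- lapply(edges$provenance, function(p) sort(unique(p)))
    edges <- edges[, c("pathway", "gene", "role", "provenance")]
  }
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 pathways = sort(unique(edges$pathway)),
                 genes = sort(unique(edges$gene))),
            class = "pathway_gene_associations")
}

#' @export
print.pathway_gene_associations <- function(x, ...) {
  cat("pathway_gene_associations:", length(x$pathways), "pathways,",
      length(x$genes), "genes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Parses the tab-separated GMT format (set name, description, then member
#' genes) into a bipartite pathway-gene association object. Member genes are
#' deduplicated within each set; the edge role is `"unspecified"` because GMT
#' does not distinguish regulators from targets.
#'
#' @param path path to a GMT file.
#' @param label provenance label recorded on every edge; defaults to the file
#'   name without extension.
#' @param id_map optional two-column data.frame (`from`, `to`) applied to gene
#'   identifiers at read time; unmapped identifiers pass through unchanged.
#' @return A [pathway_gene_associations] object.
#' @export
read_gene_sets <- function(path, label = sub("\\.[^.]*$", "", basename(path)),
                           id_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  pws <- character(0); gns <- character(0)
  for (i in seq_along(lines)) {
    # sentinel keeps trailing empty fields that strsplit would drop
    fields <- strsplit(paste0(lines[[i]], "\x1e"), "\t", fixed = TRUE)[[1]]
    fields[length(fields)] <- sub("\x1e$", "", fields[length(fields)])
    if (length(fields) < 3)
      stop("malformed GMT line ", i, ": expected >= 3 tab-separated fields")
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      warning("GMT line ", i, " (", fields[[1]], "): empty gene list, skipped")
      next
    }
    pws <- c(pws, rep(fields[[1]], length(genes)))
    gns <- c(gns, genes)
  }
  if (!is.null(id_map)) gns <- apply_id_map(gns, id_map)
  pathway_gene_associations(data.frame(
    pathway = pws, gene = gns,
    role = rep("unspecified", length(gns)),
    provenance = I(as.list(rep(label, length(gns)))),
    stringsAsFactors = FALSE))
}

#' Write gene sets to a GMT file
#'
#' Emits one line per pathway: pathway id, description placeholder, then the
#' sorted member genes (roles and provenance are not representable in GMT).
#'
#' @param assoc a [pathway_gene_associations] object.
#' @param path output path.
#' @export
write_gene_sets <- function(assoc, path) {
  stopifnot(inherits(assoc, "pathway_gene_associations"))
  members <- split(assoc$edges$gene, assoc$edges$pathway)
  lines <- vapply(names(members), function(p)
    paste(c(p, "na", sort(unique(members[[p]]))), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

apply_id_map <- function(ids, id_map) {
  stopifnot(is.data.frame(id_map), ncol(id_map) >= 2)
  m <- match(ids, as.character(id_map[[1]]))
  ids[!is.na(m)] <- as.character(id_map[[2]])[m[!is.na(m)]]
  ids
}

#' Harmonize pathway-gene associations from multiple sources
#'
#' Unions the edge sets of several association objects. Identical
#' (pathway, gene, role) edges merge their provenance sets; when two sources
#' disagree on the role of the same pathway-gene link, both role-specific
#' edges are retained.
#'
#' @param sources list of [pathway_gene_associations] objects.
#' @return A single harmonized [pathway_gene_associations] object.
#' @export
harmonize <- function(sources) {
  if (inherits(sources, "pathway_gene_associations")) sources <- list(sources)
  stopifnot(all(vapply(sources, inherits, TRUE, "pathway_gene_associations")))
  if (!length(sources))
    return(pathway_gene_associations(
      data.frame(pathway = character(0), gene = character(0),
                 role = character(0), stringsAsFactors = FALSE)))
  edges <- do.call(rbind, lapply(sources, `[[`, "edges"))
  pathway_gene_associations(edges)
}

#' Per-pathway gene membership as a named list
#'
#' @param assoc a [pathway_gene_associations] object.
#' @return Named list mapping pathway id to its unique member genes.
#' @export
gene_set_list <- function(assoc) {
  stopifnot(inherits(assoc, "pathway_gene_associations"))
  lapply(split(assoc$edges$gene, assoc$edges$pathway), unique)
}

#' Directed transcriptional regulatory network
#'
#' Stores a directed gene-gene edge list under the convention that the source
#' gene regulates the target gene. Duplicate (source, target, relation) rows
#' collapse to one edge.
#'
#' @param edges data.frame with columns `source`, `target` and optionally
#'   `relation`.
#' @param allow_self_loops keep `source == target` rows instead of failing.
#' @return An object of class `regulatory_network` holding the deduplicated
#'   edge data.frame; node set is derivable from the edges.
#' @export
regulatory_network <- function(edges, allow_self_loops = FALSE) {
  stopifnot(is.data.frame(edges))
  if (!all(c("source", "target") %in% names(edges)))
    stop("edges must have columns 'source' and 'target'")
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (is.null(edges$relation)) edges$relation <- NA_character_
  loops <- edges$source == edges$target
  if (any(loops) && !allow_self_loops)
    stop("self-loop edge(s) present (e.g. ",
         edges$source[which(loops)[1]],
         "); pass allow_self_loops = TRUE to keep them")
  edges <- edges[!duplicated(edges[, c("source", "target", "relation")]),
                 c("source", "target", "relation")]
  rownames(edges) <- NULL
  structure(list(edges = edges), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory_network:", length(network_nodes(x)), "genes,",
      nrow(x$edges), "directed edges\n")
  invisible(x)
}

#' Nodes of a regulatory network
#' @param network a [regulatory_network] object.
#' @return Sorted character vector of gene ids occurring in any edge.
#' @export
network_nodes <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  sort(unique(c(network$edges$source, network$edges$target)))
}

#' Read a directed edge list from a TSV file
#'
#' First column is the regulating gene, second its target; an optional third
#' column is kept as the relation label. Self-loops are rejected unless
#' `allow_self_loops = TRUE`.
#'
#' @param path TSV path.
#' @param header whether the file carries a header line.
#' @param allow_self_loops keep self-loop rows.
#' @param id_map optional identifier mapping, as in [read_gene_sets()].
#' @return A [regulatory_network] object.
#' @export
read_edge_list <- function(path, header = FALSE, allow_self_loops = FALSE,
                           id_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("edge list needs >= 2 columns: ", path)
  edges <- data.frame(source = tab[[1]], target = tab[[2]],
                      relation = if (ncol(tab) >= 3) tab[[3]] else NA_character_,
                      stringsAsFactors = FALSE)
  if (!is.null(id_map)) {
    edges$source <- apply_id_map(edges$source, id_map)
    edges$target <- apply_id_map(edges$target, id_map)
  }
  regulatory_network(edges, allow_self_loops = allow_self_loops)
}

#' Read a gene annotation table
#'
#' Expects named columns `gene`, `term`, `evidence` (extra columns are
#' ignored). Rows are deduplicated.
#'
#' @param path TSV path with a header line.
#' @return data.frame with columns gene, term, evidence.
#' @export
read_annotation_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(tab)))
    stop("annotation table needs columns 'gene' and 'term': ", path)
  if (is.null(tab$evidence)) tab$evidence <- NA_character_
  tab <- tab[, c("gene", "term", "evidence")]
  unique(tab)
}

#' Restrict annotations to experimental evidence codes
#'
#' Keeps only rows whose evidence code is in the standard experimental set
#' (EXP, IDA, IPI, IMP, IGI, IEP by default). The filter only ever removes
#' rows.
#'
#' @param annotations data.frame as from [read_annotation_table()].
#' @param codes evidence codes treated as experimental.
#' @return Filtered annotation data.frame.
#' @export
filter_experimental <- function(annotations,
                                codes = c("EXP", "IDA", "IPI", "IMP",
                                          "IGI", "IEP")) {
  stopifnot(is.data.frame(annotations), "evidence" %in% names(annotations))
  annotations[annotations$evidence %in% codes, , drop = FALSE]
}

#' Read a gene-disease association table
#'
#' Expects named columns `gene` and `disease`; pairs are deduplicated.
#'
#' @param path TSV path with a header line.
#' @return data.frame with columns gene, disease.
#' @export
read_disease_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene", "disease") %in% names(tab)))
    stop("disease table needs columns 'gene' and 'disease': ", path)
  unique(tab[, c("gene", "disease")])
}
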
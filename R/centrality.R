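#' PageRank centrality of genes in a regulatory network
#'
#' Ranks genes by the stationary distribution of a damped random walk on the
#' transcriptional regulatory network: a gene is important when it is attached
#' to other important genes. The walk follows edges with probability
#' `damping` and teleports to a uniformly chosen gene otherwise; dangling
#' genes (no outgoing edge in the chosen orientation) redistribute their mass
#' uniformly. Multi-edges are collapsed before iteration (unweighted walk).
#'
#' The orientation of the walk is controlled by `mode`:
#' \describe{
#'   \item{undirected}{each directed edge is collapsed to one undirected
#'     edge — the undirected backbone of the network (default);}
#'   \item{directed}{walk follows regulation source to target;}
#'   \item{reversed}{walk follows target to source, so centrality accrues to
#'     upstream regulators.}
#' }
#'
#' @param network a [regulatory_network] object.
#' @param mode walk orientation, see Details.
#' @param damping damping factor in (0, 1).
#' @param tol L1 residual threshold for convergence of the power iteration.
#' @param max_iter maximum number of power iterations.
#' @return An object of class `centrality_scores`: a data.frame with columns
#'   `gene`, `score` (sums to one over genes) and `rank` (1 = highest score;
#'   ties broken by gene id), with attributes `damping`, `mode`,
#'   `iterations` and `residual`.
#' @examples
#' net <- regulatory_network(data.frame(source = c("A", "B", "C"),
#'                                      target = c("B", "C", "A")))
#' pagerank(net, mode = "directed")
#' @export
pagerank <- function(network, mode = c("undirected", "directed", "reversed"),
                     damping = 0.85, tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(network, "regulatory_network"))
  mode <- match.arg(mode)
  if (!(damping > 0 && damping < 1)) stop("damping must be in (0, 1)")
  nodes <- network_nodes(network)
  n <- length(nodes)
  if (n == 0) stop("network is empty")
  src <- match(network$edges$source, nodes)
  tgt <- match(network$edges$target, nodes)
  ij <- switch(mode,
    directed = cbind(src, tgt),
    reversed = cbind(tgt, src),
    undirected = {
      # collapse each directed edge to one undirected edge, then expand
      a <- pmin(src, tgt); b <- pmax(src, tgt)
      und <- unique(cbind(a, b))
      loops <- und[, 1] == und[, 2]
      rbind(und, und[!loops, c(2, 1), drop = FALSE])
    })
  ij <- unique(ij)
  A <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1, dims = c(n, n))
  outdeg <- Matrix::rowSums(A)
  dangling <- outdeg == 0
  inv <- ifelse(dangling, 0, 1 / outdeg)
  # column-stochastic transition operator: M x, with M = t(Dinv A)
  M <- Matrix::t(A * inv)
  x <- rep(1 / n, n)
  teleport <- (1 - damping) / n
  it <- 0L
  residual <- Inf
  while (it < max_iter) {
    it <- it + 1L
    x_new <- as.numeric(M %*% x) * damping +
      damping * sum(x[dangling]) / n + teleport
    residual <- sum(abs(x_new - x))
    x <- x_new
    if (residual < tol) break
  }
  if (residual >= tol)
    stop(sprintf(
      "PageRank did not converge in %d iterations (L1 residual %.3e)",
      max_iter, residual))
  out <- data.frame(gene = nodes, score = x, stringsAsFactors = FALSE)
  out$rank <- rank_by_score(out$score, out$gene)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  structure(out, class = c("centrality_scores", "data.frame"),
            damping = damping, mode = mode, iterations = it,
            residual = residual)
}

# competition-free ranking: descending score, ties broken by gene id
rank_by_score <- function(score, gene) {
  order(order(-score, gene))
}

#' Look up centrality scores for a set of genes
#' @param scores a `centrality_scores` object (or data.frame with columns
#'   `gene` and `score`).
#' @param genes gene ids to look up; all must be present.
#' @return Named numeric vector of scores.
#' @export
score_of <- function(scores, genes) {
  m <- match(genes, scores$gene)
  if (anyNA(m))
    stop("gene(s) missing from centrality ranking: ",
         paste(utils::head(genes[is.na(m)], 5), collapse = ", "))
  stats::setNames(scores$score[m], genes)
}

#' Write centrality scores as TSV
#' @param scores a `centrality_scores` object.
#' @param path output path.
#' @export
write_centrality <- function(scores, path) {
  utils::write.table(as.data.frame(scores)[, c("gene", "score", "rank")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
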
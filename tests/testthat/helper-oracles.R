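# Independent oracles and small fixture builders used across the suite.

# Dense-matrix PageRank oracle: explicit Google matrix, iterated to 1e-14.
# Deliberately a separate code path from pagerank(): dense algebra on the
# fully materialized transition matrix.
dense_pagerank <- function(edges, nodes, damping = 0.85,
                           mode = c("directed", "reversed", "undirected")) {
  mode <- match.arg(mode)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    s <- edges$source[i]; t <- edges$target[i]
    if (mode == "directed") A[s, t] <- 1
    else if (mode == "reversed") A[t, s] <- 1
    else { A[s, t] <- 1; A[t, s] <- 1 }
  }
  if (mode == "undirected") diag(A)[diag(A) > 0] <- 1
  out <- rowSums(A)
  P <- matrix(1 / n, n, n)
  nz <- out > 0
  P[nz, ] <- A[nz, , drop = FALSE] / out[nz]
  G <- damping * P + (1 - damping) / n
  x <- rep(1 / n, n)
  for (it in 1:10000) {
    x_new <- as.numeric(x %*% G)
    if (sum(abs(x_new - x)) < 1e-14) { x <- x_new; break }
    x <- x_new
  }
  stats::setNames(x, nodes)
}

# Uniform random directed graph (no self-loops, no multi-edges).
random_network <- function(n_nodes, n_edges) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  regulatory_network(pairs[sample.int(nrow(pairs), min(n_edges, nrow(pairs))), ])
}

# Brute-force one-sided hypergeometric tail: sum of point masses
# P(X >= k) for X ~ Hypergeom(term K of universe N, draw n).
hyper_tail <- function(k, K, N, n) {
  if (k > min(K, n)) return(0)
  if (k <= max(0, n - (N - K))) return(1)
  kk <- seq(k, min(K, n))
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Random null bipartite association graph: each gene joins 1 + Pois(1)
# pathways chosen uniformly.
random_bipartite <- function(n_genes, n_pathways, mean_extra_degree = 1) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  pws <- sprintf("p%03d", seq_len(n_pathways))
  deg <- pmin(1 + stats::rpois(n_genes, mean_extra_degree), n_pathways)
  pathway_gene_associations(data.frame(
    pathway = unlist(lapply(deg, function(k) sample(pws, k))),
    gene = rep(genes, deg), stringsAsFactors = FALSE))
}

# Tiny three-pathway association fixture used by several modules.
toy_assoc <- function() {
  pathway_gene_associations(data.frame(
    pathway = c("P1", "P1", "P2", "P2", "P3", "P3"),
    gene = c("G1", "G2", "G1", "G3", "G2", "G3"),
    stringsAsFactors = FALSE))
}

scores_from <- function(genes, scores) {
  out <- data.frame(gene = genes, score = scores, stringsAsFactors = FALSE)
  out$rank <- order(order(-out$score, out$gene))
  class(out) <- c("centrality_scores", "data.frame")
  out
}
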
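#' Weighted-graph descriptors of an attention matrix
#'
#' An input-attention matrix is analysed as a weighted graph on the genes
#' (diagonal zeroed: self-attention is not an edge between distinct genes).
#' Three per-node descriptors summarize its structure:
#'
#' * `weighted_clustering()` -- the Barrat weighted clustering coefficient,
#'   computed on the symmetrized matrix `(W + t(W)) / 2` (the coefficient is
#'   defined for undirected weighted graphs):
#'   `C_i = 1/(s_i (k_i - 1)) * sum_{j,h} (w_ij + w_ih)/2 * a_ij a_ih a_jh`,
#'   with `s_i` the node strength, `k_i` the degree and `a` the binary
#'   adjacency.  Nodes with degree below 2 get 0.
#' * `betweenness_centrality()` -- directed weighted betweenness; edge
#'   weights are used directly as path costs by default (the convention of
#'   the igraph call it reproduces), with `invert_weights = TRUE` available
#'   to treat attention as an affinity (cost = 1/w).
#' * `hub_score()` -- Kleinberg's hub score, the principal eigenvector of
#'   `W %*% t(W)`, normalized so the maximum is 1.
#'
#' @param W square nonnegative weight matrix (e.g. an attention matrix).
#' @return A numeric vector with one entry per node.
#' @name attention_graph_descriptors
NULL

as_weight_graph <- function(W, mode) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == ncol(W), all(W >= 0))
  diag(W) <- 0
  igraph::graph_from_adjacency_matrix(W, mode = mode, weighted = TRUE,
                                      diag = FALSE)
}

#' @rdname attention_graph_descriptors
#' @export
weighted_clustering <- function(W) {
  W <- as.matrix(W)
  S <- (W + t(W)) / 2
  g <- as_weight_graph(S, mode = "undirected")
  ci <- igraph::transitivity(g, type = "barrat", isolates = "zero")
  ci[!is.finite(ci)] <- 0
  unname(ci)
}

#' @rdname attention_graph_descriptors
#' @param invert_weights treat weights as affinities (path cost `1/w`)
#'   instead of costs.
#' @export
betweenness_centrality <- function(W, invert_weights = FALSE) {
  g <- as_weight_graph(W, mode = "directed")
  wts <- igraph::E(g)$weight
  if (invert_weights) wts <- 1 / wts
  unname(igraph::betweenness(g, directed = TRUE, weights = wts))
}

#' @rdname attention_graph_descriptors
#' @export
hub_score <- function(W) {
  W <- as.matrix(W)
  diag(W) <- 0
  if (all(W == 0)) stop("hub score of an all-zero matrix is undefined")
  g <- as_weight_graph(W, mode = "directed")
  hs <- if ("hits_scores" %in% getNamespaceExports("igraph")) {
    igraph::hits_scores(g, scale = TRUE)$hub
  } else {
    igraph::hub_score(g, scale = TRUE)$vector
  }
  unname(hs)
}

#' Sorted descriptor vectors and the architecture-level feature matrix
#'
#' Because genes of different networks have no a-priori correspondence,
#' each network is summarized by its per-node descriptor values sorted in
#' decreasing order (ties keep the original node order).
#' `assemble_descriptor_matrix()` stacks one such vector per architecture
#' into the (architectures x genes) matrix used for clustering and PCA.
#'
#' @param values numeric per-node descriptor values.
#' @return `descriptor_vector()`: the values sorted non-increasingly.
#' @export
descriptor_vector <- function(values) {
  values[order(values, decreasing = TRUE)]
}

#' @rdname descriptor_vector
#' @param attention_matrices named list of square weight matrices (one per
#'   architecture, equal size).
#' @param descriptor which descriptor to compute.
#' @param ... passed to the descriptor function.
#' @return `assemble_descriptor_matrix()`: matrix with architecture rows
#'   (named) and non-increasing values left to right.
#' @export
assemble_descriptor_matrix <- function(attention_matrices,
                                       descriptor = c("clustering",
                                                      "betweenness", "hub"),
                                       ...) {
  descriptor <- match.arg(descriptor)
  ns <- vapply(attention_matrices, nrow, 0L)
  if (length(unique(ns)) != 1) stop("all matrices must have the same size")
  fn <- switch(descriptor, clustering = weighted_clustering,
               betweenness = betweenness_centrality, hub = hub_score)
  rows <- lapply(attention_matrices, function(W) descriptor_vector(fn(W, ...)))
  out <- do.call(rbind, rows)
  rownames(out) <- names(attention_matrices)
  attr(out, "descriptor") <- descriptor
  out
}

#' Correlation between attention and the true interaction matrix
#'
#' Pearson correlation over all N^2 flattened entries, the ground-truth
#' matrix cast to real \{-1, 0, 1\}.  A constant input (zero variance) yields
#' 0 with a warning -- the convention used when reporting that attention does
#' not recover causal edges.
#'
#' @param A attention matrix.
#' @param J signed interaction matrix of the same shape.
#' @return Pearson correlation coefficient.
#' @export
attention_truth_correlation <- function(A, J) {
  A <- as.matrix(A); J <- as.matrix(J)
  if (!all(dim(A) == dim(J))) stop("A and J must have the same shape")
  a <- as.vector(A); j <- as.double(as.vector(J))
  if (sd(a) == 0 || sd(j) == 0) {
    warning("zero variance input; correlation reported as 0")
    return(0)
  }
  cor(a, j)
}
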
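standardize_columns <- function(mat) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop("non-finite values in feature matrix")
  mu <- colMeans(mat)
  sdv <- apply(mat, 2, sd)
  sdv[sdv == 0] <- 1          # constant columns carry no signal; leave at 0
  sweep(sweep(mat, 2, mu), 2, sdv, `/`)
}

#' Hierarchical clustering of an architecture feature matrix
#'
#' Columns are standardized to zero mean and unit variance, distances are
#' Euclidean and the linkage is complete -- the configuration used
#' throughout the study.  The result is deterministic for a given matrix.
#'
#' @param mat feature matrix with one (labelled) row per architecture.
#' @param standardize standardize columns first (default `TRUE`).
#' @return An [stats::hclust] tree over the row labels.
#' @export
descriptor_hclust <- function(mat, standardize = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least two rows to cluster")
  if (standardize) mat <- standardize_columns(mat)
  hclust(dist(mat, method = "euclidean"), method = "complete")
}

#' Silhouette-optimal partition from a dendrogram
#'
#' Cuts the tree at every `k` in `k_range`, scores each cut by the mean
#' silhouette width `s = (DN - DI) / max(DI, DN)` (Euclidean distances on
#' the standardized matrix; singleton clusters contribute 0) and returns
#' the best cut; ties go to the smallest `k`.
#'
#' @param mat the feature matrix the tree was built from.
#' @param hc the [descriptor_hclust()] tree.
#' @param k_range candidate numbers of clusters (default `2:(n - 1)`).
#' @param standardize must match the choice used for `hc`.
#' @return A list with `k`, `partition` (named cluster ids), `silhouette`
#'   (the attained mean width) and `scores` (per-k table).
#' @export
silhouette_best_k <- function(mat, hc, k_range = NULL, standardize = TRUE) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 3) stop("need at least three samples for a silhouette sweep")
  if (is.null(k_range)) k_range <- 2:(n - 1)
  stopifnot(all(k_range >= 2), all(k_range <= n))
  if (standardize) mat <- standardize_columns(mat)
  d <- dist(mat, method = "euclidean")
  scores <- vapply(k_range, function(k) {
    cl <- cutree(hc, k = k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, 0)
  best <- k_range[which.max(scores)]   # which.max takes the first maximum
  part <- cutree(hc, k = best)
  list(k = best, partition = part, silhouette = max(scores),
       scores = data.frame(k = k_range, mean_silhouette = scores))
}

#' Principal component analysis of a feature matrix
#'
#' Standardized PCA with a deterministic sign convention: each component is
#' flipped so that its largest-magnitude loading is positive.
#'
#' @inheritParams descriptor_hclust
#' @return A list with `scores`, `loadings` and `ratios` (explained-variance
#'   ratios; they sum to 1).
#' @export
descriptor_pca <- function(mat, standardize = TRUE) {
  mat <- as.matrix(mat)
  if (standardize) mat <- standardize_columns(mat)
  pc <- prcomp(mat, center = FALSE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation,
       ratios = pc$sdev^2 / sum(pc$sdev^2))
}

#' Convert a dendrogram to Newick
#'
#' Branch lengths follow the ultrametric reading of the merge heights: a
#' child hanging from a node merged at height `h` gets length `h` minus the
#' child's own merge height (0 for leaves), so two leaves merged at height
#' `h` yield `(A:h,B:h);`.  The string round-trips through standard Newick
#' parsers.
#'
#' @param hc an [stats::hclust] tree with labels.
#' @return A single Newick string.
#' @export
dendrogram_to_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  labs <- hc$labels
  if (is.null(labs)) labs <- as.character(seq_along(hc$order))
  if (anyNA(hc$height) || is.unsorted(hc$height)) {
    stop("malformed tree: merge heights must be finite and non-decreasing")
  }
  node <- function(i) {
    # i < 0: leaf -i ; i > 0: internal merge i
    if (i < 0) list(str = labs[-i], height = 0)
    else {
      a <- node(hc$merge[i, 1])
      b <- node(hc$merge[i, 2])
      h <- hc$height[i]
      list(str = sprintf("(%s:%.12g,%s:%.12g)", a$str, h - a$height,
                         b$str, h - b$height),
           height = h)
    }
  }
  paste0(node(nrow(hc$merge))$str, ";")
}

# Non-trivial splits of a (rooted or unrooted) tree as leaf membership
# vectors, canonicalized so the side containing the first leaf (sorted
# order) is TRUE; complements deduplicated.
tree_splits <- function(tree, leaf_order) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  n <- length(leaf_order)
  seen <- character(0)
  out <- list()
  for (cl in pp) {
    memb <- leaf_order %in% labs[cl]
    if (!memb[1]) memb <- !memb
    sz <- sum(!memb)
    if (sum(memb) < 2 || sz < 2) next       # trivial split
    key <- paste(as.integer(memb), collapse = "")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1]] <- memb
  }
  out
}

split_entropy <- function(memb) {
  n <- length(memb)
  p <- c(sum(memb), n - sum(memb)) / n
  -sum(p * log2(p))
}

split_mutual_information <- function(m1, m2) {
  n <- length(m1)
  tab <- table(factor(m1, c(FALSE, TRUE)), factor(m2, c(FALSE, TRUE))) / n
  pr <- rowSums(tab); pc <- colSums(tab)
  mi <- 0
  for (a in 1:2) for (b in 1:2) {
    if (tab[a, b] > 0) mi <- mi + tab[a, b] * log2(tab[a, b] / (pr[a] * pc[b]))
  }
  as.numeric(mi)
}

# Exact maximum-weight assignment by bitmask dynamic programming over the
# smaller side (split counts here are tiny: at most n - 3).
assignment_max <- function(score) {
  n1 <- nrow(score); n2 <- ncol(score)
  if (n1 == 0 || n2 == 0) return(0)
  if (n1 > n2) return(assignment_max(t(score)))
  if (n2 > 14) stop("too many splits for exact matching")
  full <- bitwShiftL(1L, n2) - 1L
  dp <- rep(-Inf, full + 1L)
  dp[1] <- 0
  for (i in seq_len(n1)) {
    nd <- rep(-Inf, full + 1L)
    for (mask in 0:full) {
      if (!is.finite(dp[mask + 1L])) next
      nd[mask + 1L] <- max(nd[mask + 1L], dp[mask + 1L])  # leave row i unmatched
      for (j in seq_len(n2)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) == 0L) {
          nm <- bitwOr(mask, bit)
          cand <- dp[mask + 1L] + score[i, j]
          if (cand > nd[nm + 1L]) nd[nm + 1L] <- cand
        }
      }
    }
    dp <- nd
  }
  max(dp)
}

#' Information-based generalized Robinson-Foulds distance
#'
#' The clustering-information tree distance: every non-trivial split of a
#' tree is scored by its clustering entropy (in bits, per leaf), pairs of
#' splits across the two trees share their mutual clustering information,
#' and an exact assignment finds the matching that maximizes the total
#' shared information.  The distance is the total split information of both
#' trees minus twice the optimally matched shared information; identical
#' trees are at distance 0 and the measure is symmetric.
#'
#' @param tree1,tree2 `phylo` objects or Newick strings on the same leaf
#'   set.
#' @return Nonnegative distance in bits.
#' @export
tree_distance <- function(tree1, tree2) {
  as_tree <- function(x) {
    if (inherits(x, "phylo")) x else ape::read.tree(text = x)
  }
  t1 <- as_tree(tree1); t2 <- as_tree(tree2)
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) stop("trees have different leaf sets")
  s1 <- tree_splits(t1, l1)
  s2 <- tree_splits(t2, l1)
  h1 <- vapply(s1, split_entropy, 0)
  h2 <- vapply(s2, split_entropy, 0)
  if (length(s1) == 0 || length(s2) == 0) return(sum(h1) + sum(h2))
  score <- matrix(0, length(s1), length(s2))
  for (i in seq_along(s1)) for (j in seq_along(s2)) {
    score[i, j] <- split_mutual_information(s1[[i]], s2[[j]])
  }
  shared <- assignment_max(score)
  max(sum(h1) + sum(h2) - 2 * shared, 0)
}

#' Variation of information between two partitions
#'
#' `VI(C, C') = H(C) + H(C') - 2 I(C, C')` in nats; zero exactly when the
#' partitions coincide (up to label permutation) and a metric on partitions
#' of the same set.
#'
#' @param part1,part2 named cluster-id vectors over the same items.
#' @return Nonnegative value in nats.
#' @export
variation_of_information <- function(part1, part2) {
  if (is.null(names(part1)) || is.null(names(part2))) {
    if (length(part1) != length(part2)) stop("partitions differ in length")
    names(part1) <- names(part2) <- paste0("item", seq_along(part1))
  }
  if (!setequal(names(part1), names(part2))) {
    stop("partitions are over different item sets")
  }
  part2 <- part2[names(part1)]
  n <- length(part1)
  tab <- table(part1, part2) / n
  pr <- rowSums(tab); pc <- colSums(tab)
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  mi <- 0
  for (a in seq_along(pr)) for (b in seq_along(pc)) {
    if (tab[a, b] > 0) mi <- mi + tab[a, b] * log(tab[a, b] / (pr[a] * pc[b]))
  }
  max(ent(pr) + ent(pc) - 2 * mi, 0)
}

#' Correlation between two feature matrices on a signed-log scale
#'
#' Both matrices are flattened, transformed elementwise by
#' `sign(x) * ln(1 + |x|)` (an odd map that compresses large values while
#' keeping zero fixed) and Pearson-correlated.
#'
#' @param m1,m2 equal-shape numeric matrices.
#' @return Pearson correlation of the transformed entries.
#' @export
matrix_correlation <- function(m1, m2) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2))) stop("matrices must have the same shape")
  tf <- function(x) sign(x) * log1p(abs(x))
  a <- tf(as.vector(m1)); b <- tf(as.vector(m2))
  if (sd(a) == 0 || sd(b) == 0) stop("zero variance after transform")
  cor(a, b)
}
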
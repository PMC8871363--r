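test_that("complete-linkage clustering matches a naive oracle", {
  set.seed(4)
  mat <- matrix(rnorm(40), 8, 5)
  rownames(mat) <- letters[1:8]
  hc <- descriptor_hclust(mat, standardize = FALSE)
  coph <- as.matrix(stats::cophenetic(hc))
  oracle <- oracle_complete_linkage_cophenetic(mat)
  dimnames(oracle) <- dimnames(coph)[c(1, 1)]
  expect_equal(coph[rownames(oracle), rownames(oracle)], oracle,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("identical rows merge at height zero; distant pairs merge first", {
  mat <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10), d = c(10.5, 10))
  hc <- descriptor_hclust(mat, standardize = FALSE)
  expect_equal(hc$height[1], 0)
  # the first two merges are the two tight pairs
  cl <- cutree(hc, 2)
  expect_equal(unname(cl[c("a", "b")]), c(1, 1))
  expect_equal(unname(cl[c("c", "d")]), c(2, 2))
  expect_error(descriptor_hclust(mat[1, , drop = FALSE]), "two rows")
  expect_error(descriptor_hclust(rbind(a = c(1, NA), b = c(0, 1))),
               "non-finite")
})

test_that("the silhouette sweep finds well-separated blobs and obeys bounds", {
  set.seed(11)
  blob1 <- matrix(rnorm(10, mean = 0, sd = 0.05), 5, 2)
  blob2 <- matrix(rnorm(10, mean = 8, sd = 0.05), 5, 2)
  mat <- rbind(blob1, blob2)
  rownames(mat) <- paste0("s", 1:10)
  hc <- descriptor_hclust(mat, standardize = FALSE)
  best <- silhouette_best_k(mat, hc, standardize = FALSE)
  expect_equal(best$k, 2)
  expect_gt(best$silhouette, 0.9)
  expect_true(all(best$scores$mean_silhouette >= -1 &
                  best$scores$mean_silhouette <= 1))
  # the two blobs are the two clusters
  expect_length(unique(best$partition[1:5]), 1)
  expect_length(unique(best$partition[6:10]), 1)
  expect_error(silhouette_best_k(mat[1:2, ], hc), "three")
})

test_that("mean silhouettes agree with the direct formula", {
  set.seed(21)
  mat <- matrix(rnorm(24), 8, 3)
  rownames(mat) <- paste0("r", 1:8)
  hc <- descriptor_hclust(mat, standardize = FALSE)
  best <- silhouette_best_k(mat, hc, standardize = FALSE)
  for (row in seq_len(nrow(best$scores))) {
    k <- best$scores$k[row]
    expect_equal(best$scores$mean_silhouette[row],
                 oracle_mean_silhouette(mat, cutree(hc, k)),
                 tolerance = 1e-12)
  }
})

test_that("PCA ratios sum to one and scores match an SVD oracle", {
  set.seed(31)
  mat <- matrix(rnorm(120), 12, 10)
  pc <- descriptor_pca(mat)
  expect_equal(sum(pc$ratios), 1, tolerance = 1e-9)

  Z <- scale(mat)
  attr(Z, "scaled:center") <- NULL; attr(Z, "scaled:scale") <- NULL
  sv <- svd(Z)
  scores_oracle <- sv$u %*% diag(sv$d)
  for (j in 1:3) {
    a <- pc$scores[, j]; b <- scores_oracle[, j]
    expect_equal(abs(cor(a, b)), 1, tolerance = 1e-9)
    expect_equal(sd(a), sd(b), tolerance = 1e-9)
  }

  # rank-1 input concentrates all variance on PC1
  r1 <- outer(rnorm(6), rnorm(4))
  pc1 <- descriptor_pca(r1, standardize = FALSE)
  expect_equal(pc1$ratios[1], 1, tolerance = 1e-9)

  # deterministic sign: the largest loading of each component is positive
  for (j in seq_len(ncol(pc$loadings))) {
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
})

test_that("dendrograms serialize to parseable ultrametric Newick", {
  # two leaves at height h: "(A:h,B:h);"
  mat <- rbind(A = 0, B = 3)
  hc <- descriptor_hclust(cbind(mat), standardize = FALSE)
  hc$labels <- rownames(mat)
  expect_equal(dendrogram_to_newick(hc), "(A:3,B:3);")

  set.seed(41)
  mat <- matrix(rnorm(60), 12, 5)
  rownames(mat) <- paste0("arch", 1:12)
  hc <- descriptor_hclust(mat)
  nwk <- dendrogram_to_newick(hc)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, rownames(mat))
  # ultrametric: all leaves equally deep, at the root height
  depths <- ape::node.depth.edgelength(tree)[seq_len(12)]
  expect_equal(max(abs(depths - max(hc$height))), 0, tolerance = 1e-6)
  # topology matches the hclust merge structure
  expect_equal(sort(as.vector(as.matrix(stats::cophenetic(hc)))),
               sort(as.vector(ape::cophenetic.phylo(tree) / 2)),
               tolerance = 1e-6)
})

test_that("tree distance is an information-based generalized RF distance", {
  cat6 <- "(((((a:1,b:1):1,c:2):1,d:3):1,e:4):1,f:5);"   # caterpillar
  bal6 <- "(((a:1,b:1):2,(c:1,d:1):2):1,(e:2,f:2):2);"   # balanced
  expect_equal(tree_distance(cat6, cat6), 0, tolerance = 1e-12)
  expect_equal(tree_distance(bal6, bal6), 0, tolerance = 1e-12)
  d12 <- tree_distance(cat6, bal6)
  expect_equal(d12, tree_distance(bal6, cat6), tolerance = 1e-12)
  expect_gt(d12, 0)
  expect_equal(d12, oracle_tree_distance(cat6, bal6), tolerance = 1e-10)

  # a different topology pair, again against exhaustive matching
  t3 <- "((a:1,e:1):1,((b:1,f:1):1,(c:1,d:1):2):1);"
  expect_equal(tree_distance(cat6, t3), oracle_tree_distance(cat6, t3),
               tolerance = 1e-10)
  expect_error(tree_distance(cat6, "((a:1,b:1):1,(c:1,x:1):1);"),
               "leaf sets")
})

test_that("variation of information has its closed forms and oracle", {
  p1 <- setNames(c(1, 1, 2, 2), letters[1:4])
  expect_equal(variation_of_information(p1, p1), 0)

  # one cluster vs all singletons on n = 4: VI = ln 4
  whole <- setNames(rep(1, 4), letters[1:4])
  singl <- setNames(1:4, letters[1:4])
  expect_equal(variation_of_information(whole, singl), log(4),
               tolerance = 1e-12)

  set.seed(51)
  for (r in 1:5) {
    q1 <- setNames(sample(1:4, 20, replace = TRUE), paste0("x", 1:20))
    q2 <- setNames(sample(1:3, 20, replace = TRUE), paste0("x", 1:20))
    expect_equal(variation_of_information(q1, q2), oracle_vi(q1, q2),
                 tolerance = 1e-12)
    # symmetry and label-order invariance
    expect_equal(variation_of_information(q2, q1),
                 variation_of_information(q1, sample(q2)), tolerance = 1e-12)
  }
  expect_error(variation_of_information(p1, setNames(1:3, c("a", "b", "z"))),
               "different")
})

test_that("matrix correlation uses the signed-log transform", {
  set.seed(61)
  M1 <- matrix(rnorm(30, sd = 4), 5, 6)
  expect_equal(matrix_correlation(M1, M1), 1)

  tf <- function(x) sign(x) * log1p(abs(x))
  expect_equal(tf(0), 0)
  expect_equal(tf(-2.5), -tf(2.5))

  M2 <- matrix(rnorm(30, sd = 2), 5, 6)
  expect_equal(matrix_correlation(M1, M2),
               cor(as.vector(tf(M1)), as.vector(tf(M2))), tolerance = 1e-12)
  expect_error(matrix_correlation(M1, M2[, 1:3]), "shape")
  expect_error(matrix_correlation(matrix(0, 2, 2), matrix(1, 2, 2)),
               "variance")
})
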
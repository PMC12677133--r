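test_that("PCA matches a dense covariance eigendecomposition", {
  set.seed(21)
  x <- matrix(rnorm(30 * 8), 30, 8)
  rownames(x) <- sprintf("c%02d", 1:30)
  emb <- pca_embed(x, n_pcs = 5, scale. = FALSE)

  # oracle: eigendecomposition of the sample covariance matrix
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)
  expect_equal(emb$sdev^2, ev$values[1:5], tolerance = 1e-10)
  scores_oracle <- xc %*% ev$vectors[, 1:5]
  for (j in 1:5)  # eigenvectors defined up to sign
    expect_equal(abs(emb$scores[, j]), abs(scores_oracle[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA components are orthogonal with decreasing variance", {
  set.seed(22)
  x <- matrix(rnorm(40 * 12), 40, 12)
  emb <- pca_embed(x, n_pcs = 6)
  g <- crossprod(emb$scores)
  expect_equal(g[upper.tri(g)], rep(0, sum(upper.tri(g))),
               tolerance = 1e-8)
  expect_true(all(diff(emb$var_explained) <= 1e-12))

  # a rank-2 matrix is fully explained by 2 components
  u <- matrix(rnorm(40 * 2), 40, 2)
  v <- matrix(rnorm(2 * 12), 2, 12)
  emb2 <- pca_embed(u %*% v, n_pcs = 2, scale. = FALSE)
  expect_equal(sum(emb2$var_explained), 1, tolerance = 1e-10)
  expect_error(pca_embed(x, n_pcs = 50), "n_pcs")
})

test_that("kNN neighbor lists match an exhaustive distance sort", {
  set.seed(23)
  pts <- matrix(rnorm(20 * 3), 20, 3)
  rownames(pts) <- sprintf("c%02d", 1:20)
  k <- 4
  g <- knn_graph(pts, k = k)
  d <- as.matrix(dist(pts)); diag(d) <- Inf
  for (i in 1:20) {
    nn <- order(d[i, ])[1:k]
    expect_true(all(g$w[i, nn] > 0))   # own kNN present after union
  }
  # every edge is either an i->j or j->i nearest-neighbor relation
  idx <- which(as.matrix(g$w) > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    expect_true(j %in% order(d[i, ])[1:k] || i %in% order(d[j, ])[1:k])
  }
  w <- as.matrix(g$w)
  expect_true(all(diag(w) == 0))
  expect_true(all(w[w > 0] <= 1) && all(w[w > 0] > 0))
  expect_equal(w, t(w))
})

test_that("collinear 3-point graph with k=1 joins the middle to both ends", {
  pts <- cbind(c(0, 1, 2.5), 0)
  g <- knn_graph(pts, k = 1)
  w <- as.matrix(g$w)
  expect_true(w[2, 1] > 0 && w[2, 3] > 0)  # union symmetrization
  expect_error(knn_graph(pts, k = 3), "smaller")
})

test_that("diffusion eigenpairs agree with a dense eigensolver to 1e-8", {
  set.seed(24)
  n <- 80
  pts <- cbind(seq_len(n) + rnorm(n, 0, 0.1), rnorm(n, 0, 0.1))
  g <- knn_graph(pts, k = 5)
  d <- diffusion_map(g, n_comps = 10)

  # oracle: dense eigendecomposition of the same symmetric conjugate
  w <- as.matrix(g$w)
  q <- rowSums(w)
  k1 <- w / outer(q, q)
  dd <- rowSums(k1)
  ms <- diag(1 / sqrt(dd)) %*% k1 %*% diag(1 / sqrt(dd))
  ev <- eigen((ms + t(ms)) / 2, symmetric = TRUE)
  expect_equal(d$evals, ev$values[2:11], tolerance = 1e-8)
  expect_equal(ev$values[1], 1, tolerance = 1e-10)  # stationary eigenvalue
  expect_true(all(diff(d$evals) <= 1e-12))
  expect_true(all(d$evals <= 1 + 1e-10))
  # first diffusion component is monotone along the line
  expect_true(all(diff(d$psi[, 1]) > 0) || all(diff(d$psi[, 1]) < 0))
})

test_that("disconnected graphs are rejected with component sizes", {
  pts <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
               matrix(rnorm(10, 100, 0.1), 5, 2))
  g <- knn_graph(pts, k = 2)
  expect_error(diffusion_map(g, 3), "2 components")
})

test_that("root selection maximizes marker expression with barcode ties", {
  x <- Matrix::Matrix(rbind(c(1, 0), c(5, 0), c(2, 0), c(9, 9)),
                      sparse = TRUE)
  dimnames(x) <- list(c("b", "a", "c", "d"), c("Mark1", "Other"))
  meta <- data.frame(barcode = rownames(x),
                     cluster = c("GBC", "GBC", "GBC", "mOSN"))
  expect_equal(select_root(x, meta, "GBC", "Mark1"), 2)
  # tie: two cells at the max -> lexicographically smallest barcode
  x2 <- x; x2[1, 1] <- 5
  expect_equal(select_root(x2, meta, "GBC", "Mark1"), 2)  # "a" < "b"
  expect_error(select_root(x, meta, "INP", "Mark1"), "available")
})

test_that("pseudotime on a path graph recovers the 1-D ordering", {
  set.seed(25)
  n <- 50
  pts <- cbind(seq_len(n) + rnorm(n, 0, 0.05), 0)
  g <- knn_graph(pts, k = 3)
  d <- diffusion_map(g, n_comps = 10)
  pt <- compute_dpt(d, root = 1)
  expect_equal(unname(pt[1]), 0)
  expect_equal(max(pt), 1)
  expect_gte(cor(pt, seq_len(n), method = "spearman"), 0.95)

  # symmetry of the underlying DPT distance: d(root -> x) == d(x -> root)
  pt_a <- compute_dpt(d, root = 1)
  pt_b <- compute_dpt(d, root = n)
  d_ab <- unname(pt_a[n]) * attr(pt_a, "scale")
  d_ba <- unname(pt_b[1]) * attr(pt_b, "scale")
  expect_equal(d_ab, d_ba, tolerance = 1e-10)
})

test_that("bin assignment covers [0,1] with conservation and sparse flags", {
  b <- assign_bins(c(0, 1, 0.5), B = 3, min_cells = 1)
  expect_equal(b$bin, c(0L, 2L, 1L))

  set.seed(26)
  pt <- runif(100)
  b2 <- assign_bins(pt, B = 10, min_cells = 1)
  expect_equal(sum(b2$occupancy), 100)
  expect_true(all(b2$bin >= 0 & b2$bin <= 9))

  b3 <- assign_bins(rep(0.05, 20), B = 5, min_cells = 1)
  expect_equal(sum(b3$sparse), 4)
  expect_error(assign_bins(runif(3), B = 10), "more bins")
})

test_that("bin means match brute-force group-by and interpolate gaps", {
  # forced example: members {2, 4} -> mean 3
  x <- Matrix::Matrix(matrix(c(2, 4), 2, 1), sparse = TRUE)
  bins <- list(bin = c(0L, 0L), edges = c(0, 0.5, 1),
               occupancy = c(2L, 1L), sparse = c(FALSE, FALSE))
  # need >= 2 populated bins; use 3 cells across 2 bins instead
  x <- Matrix::Matrix(matrix(c(2, 4, 7), 3, 1), sparse = TRUE)
  bins <- list(bin = c(0L, 0L, 1L), edges = c(0, 0.5, 1),
               occupancy = c(2L, 1L), sparse = c(FALSE, FALSE))
  colnames(x) <- "g1"
  tr <- bin_trajectories(x, log1p(x), bins)
  expect_equal(unname(tr$forms$NORM["g1", ]), c(3, 7))

  # brute-force group-by oracle on a 200-cell random fixture
  set.seed(27)
  n <- 200
  xx <- Matrix::Matrix(matrix(rpois(n * 5, 4), n, 5), sparse = TRUE)
  colnames(xx) <- sprintf("g%d", 1:5)
  pt <- runif(n)
  bb <- assign_bins(pt, B = 8, min_cells = 1)
  tr2 <- bin_trajectories(xx, log1p(xx), bb)
  dense <- as.matrix(xx)
  for (b in which(!bb$sparse)) {
    members <- bb$bin == (b - 1)
    expect_equal(unname(tr2$forms$NORM[, b]),
                 unname(colMeans(dense[members, , drop = FALSE])))
  }
  # permuting cell order leaves trajectories unchanged
  perm <- sample(n)
  bb_p <- list(bin = bb$bin[perm], edges = bb$edges,
               occupancy = bb$occupancy, sparse = bb$sparse)
  tr3 <- bin_trajectories(xx[perm, ], log1p(xx[perm, ]), bb_p)
  expect_equal(tr3$forms$NORM, tr2$forms$NORM)

  # empty middle bin between means 1 and 3 -> interpolated 2, flagged
  x4 <- Matrix::Matrix(matrix(c(1, 3), 2, 1), sparse = TRUE)
  colnames(x4) <- "g1"
  b4 <- list(bin = c(0L, 2L), edges = seq(0, 1, length.out = 4),
             occupancy = c(1L, 0L, 1L), sparse = c(FALSE, TRUE, FALSE))
  tr4 <- bin_trajectories(x4, log1p(x4), b4)
  expect_equal(unname(tr4$forms$NORM["g1", ]), c(1, 2, 3))
  expect_equal(tr4$interpolated, c(FALSE, TRUE, FALSE))
  b5 <- list(bin = c(0L, 0L), edges = c(0, 0.5, 1),
             occupancy = c(2L, 0L), sparse = c(FALSE, TRUE))
  expect_error(bin_trajectories(x4, log1p(x4), b5), "populated")
})
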
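test_that("tfidf reproduces the hand-computed example", {
  # 2 features x 2 cells: X = [[1,0],[1,1]]
  m <- feature_cell_matrix(matrix(c(1, 1, 0, 1), 2), c("f1", "f2"),
                           c("c1", "c2"), binarized = TRUE)
  w <- as.matrix(tfidf(m))
  expected <- matrix(c(0.5 * log(1 + 2 / 1), 0.5 * log(1 + 2 / 2),
                       0, 1 * log(1 + 2 / 2)), 2,
                     dimnames = list(c("f1", "f2"), c("c1", "c2")))
  expect_equal(w, expected, tolerance = 1e-12)

  single <- feature_cell_matrix(matrix(1, 1, 1), "f", "c", binarized = TRUE)
  expect_equal(as.numeric(tfidf(single)), log(2), tolerance = 1e-12)
})

test_that("tfidf errors on zero-feature cells and permutes with columns", {
  m <- feature_cell_matrix(matrix(c(1, 0, 0, 0), 2), c("f1", "f2"),
                           c("good", "empty"), binarized = TRUE)
  expect_error(tfidf(m), "empty")

  set.seed(3)
  x <- matrix(rbinom(50 * 8, 1, 0.5), 50, 8)
  x[1, colSums(x) == 0] <- 1
  m2 <- feature_cell_matrix(x, sprintf("f%02d", 1:50), sprintf("c%d", 1:8),
                            binarized = TRUE)
  w <- as.matrix(tfidf(m2))
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  m3 <- feature_cell_matrix(x[, perm], m2$feature_ids, m2$barcodes[perm],
                            binarized = TRUE)
  expect_equal(as.matrix(tfidf(m3)), w[, perm], tolerance = 1e-14)
})

test_that("tfidf matches an independent dense implementation", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rbinom(50 * 40, 1, 0.3), 50, 40)
    x[1, colSums(x) == 0] <- 1
    m <- feature_cell_matrix(x, sprintf("f%02d", 1:50),
                             sprintf("c%02d", 1:40), binarized = TRUE)
    expect_equal(unname(as.matrix(tfidf(m))), bf_tfidf(x),
                 tolerance = 1e-10)
  }
})

test_that("lsi matches dense SVD and fixes signs deterministically", {
  set.seed(11)
  x <- matrix(rbinom(50 * 40, 1, 0.3), 50, 40)
  x[1, colSums(x) == 0] <- 1
  w <- bf_tfidf(x)
  colnames(w) <- sprintf("c%02d", 1:40)
  K <- 10
  r <- lsi(w, K = K)
  s <- svd(w)
  expect_equal(r$singular_values, s$d[1:K], tolerance = 1e-8)
  expect_false(is.unsorted(rev(r$singular_values)))
  # K-truncated reconstruction error matches the dense oracle
  recon_oracle <- sum((w - s$u[, 1:K] %*% diag(s$d[1:K]) %*%
                         t(s$v[, 1:K]))^2)
  recon_lsi <- sum((w - r$feature_loadings %*% t(r$embedding))^2)
  expect_equal(recon_lsi, recon_oracle, tolerance = 1e-8)
  # embedding Gram matrix is sign-invariant and matches the oracle
  gram_oracle <- s$v[, 1:K] %*% diag(s$d[1:K]^2) %*% t(s$v[, 1:K])
  expect_equal(r$embedding %*% t(r$embedding), gram_oracle,
               tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: largest-magnitude loading positive
  for (k in seq_len(K)) {
    l <- r$feature_loadings[, k]
    expect_gt(l[which.max(abs(l))], 0)
  }
  expect_error(lsi(w, K = 100), "min")
})

test_that("rank-deficient input yields a vanishing second singular value", {
  u <- runif(30)
  v <- runif(12)
  w <- outer(u, v)
  colnames(w) <- sprintf("c%02d", 1:12)
  r <- lsi(w, K = 2)
  expect_lt(r$singular_values[2], 1e-8 * r$singular_values[1])
})

test_that("duplicated cells receive identical embeddings", {
  set.seed(21)
  x <- matrix(rbinom(40 * 10, 1, 0.4), 40, 10)
  x[1, colSums(x) == 0] <- 1
  x <- cbind(x, x[, 5])
  w <- bf_tfidf(x)
  colnames(w) <- sprintf("c%02d", 1:11)
  r <- lsi(w, K = 5)
  expect_equal(r$embedding[5, ], r$embedding[11, ], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("depth-correlated components are dropped, others kept", {
  set.seed(8)
  n <- 50
  depth <- log10(sample(500:5000, n))
  emb <- cbind(depth * 2 + 1,            # |r| = 1 with depth
               rnorm(n),                  # ~independent
               -depth + rnorm(n, sd = 1e-3))
  rownames(emb) <- sprintf("c%02d", 1:n)
  r <- structure(list(embedding = emb, singular_values = c(3, 2, 1),
                      component_depth_corr = rep(NA_real_, 3),
                      dropped_components = integer(0),
                      feature_loadings = matrix(0, 2, 3)),
                 class = "LSIResult")
  out <- drop_depth_components(r, depth, r_max = 0.9)
  expect_equal(out$dropped_components, c(1L, 3L))
  expect_equal(ncol(out$embedding), 1L)
  expect_equal(out$singular_values, 2)
  # r_max = 1 drops nothing
  out2 <- drop_depth_components(r, depth, r_max = 1.0)
  expect_equal(out2$dropped_components, integer(0))
  expect_equal(ncol(out2$embedding), 3L)
})

test_that("k-means recovers well-separated clouds deterministically", {
  set.seed(4)
  n <- 40
  emb <- rbind(matrix(rnorm(n * 3, mean = 0, sd = 0.05), n, 3),
               matrix(rnorm(n * 3, mean = 5, sd = 0.05), n, 3))
  rownames(emb) <- sprintf("c%03d", seq_len(2 * n))
  r <- structure(list(embedding = emb, singular_values = c(3, 2, 1),
                      component_depth_corr = rep(NA_real_, 3),
                      dropped_components = integer(0)),
                 class = "LSIResult")
  a <- cluster_cells(r, k = 2, seed = 42)
  truth <- setNames(rep(c(1, 2), each = n), rownames(emb))
  expect_equal(adjusted_rand_index(a, truth), 1.0)
  # determinism: same seed, same input -> identical assignment
  b <- cluster_cells(r, k = 2, seed = 42)
  expect_identical(a$assignment, b$assignment)
  # k = n cells: every cell its own cluster
  small <- structure(list(embedding = emb[1:5, ]), class = "LSIResult")
  solo <- cluster_cells(small, k = 5, seed = 1)
  expect_equal(sort(unname(solo$assignment)), 0:4)
  expect_error(cluster_cells(small, k = 6, seed = 1), "exceed")
})

test_that("adjusted Rand index matches closed forms and is invariant", {
  a <- setNames(c(0, 0, 1, 1), letters[1:4])
  expect_equal(adjusted_rand_index(a, a), 1.0)
  # all-in-one vs balanced two-way truth: ARI = 0 by the closed form
  one <- setNames(rep(0, 4), letters[1:4])
  expect_equal(adjusted_rand_index(one, a), 0.0)
  # permuting labels changes nothing
  flip <- setNames(c(1, 1, 0, 0), letters[1:4])
  expect_equal(adjusted_rand_index(flip, a), 1.0)
  expect_error(adjusted_rand_index(a, setNames(1:4, letters[2:5])),
               "different barcode")
})

test_that("adjusted Rand index agrees with an independent implementation", {
  set.seed(13)
  for (i in 1:5) {
    x <- setNames(sample(0:3, 60, replace = TRUE), sprintf("c%02d", 1:60))
    y <- setNames(sample(0:2, 60, replace = TRUE), names(x))
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y[names(x)]),
                 tolerance = 1e-12)
  }
})
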
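test_that("PCA reproduces a dense eigensolve and conserves variance", {
  x <- rbind(c(2, 4, 1), c(3, 9, 2), c(5, 1, 7), c(8, 6, 4))
  p <- fit_pca(x)
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(p$explained_variance, ev / sum(ev), tolerance = 1e-10)
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-10)
  # orthonormal loadings and exact reconstruction from all components
  expect_equal(crossprod(p$loadings), diag(p$n_components),
               tolerance = 1e-10, ignore_attr = TRUE)
  recon <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(recon - sweep(x, 2, p$center))), 1e-8)
  # rank-1 data: first component carries all the variance
  r1 <- outer(c(1, 2, 3, 5), c(2, -1, 4))
  expect_equal(fit_pca(r1)$explained_variance[1], 1, tolerance = 1e-12)
  expect_error(fit_pca(x, n_components = 4), "between 1 and")
})

test_that("PCA reconstruction error decreases monotonically with components", {
  set.seed(66)
  x <- matrix(rnorm(20 * 8), 20) %*% diag(c(4, 3, 2, 1.5, 1, 0.5, 0.2, 0.1))
  xc <- scale(x, scale = FALSE)
  errs <- vapply(1:8, function(k) {
    p <- fit_pca(x, n_components = k)
    sum((xc - p$scores %*% t(p$loadings))^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("PC-LDA separates noiseless displaced classes completely", {
  set.seed(9)
  base <- matrix(rnorm(12 * 5, sd = 0.2), 12, 5)
  base[, 3] <- rep(c(0, 10), each = 6)       # classes split on one coordinate
  labels <- rep(c("a", "b"), each = 6)
  fit <- fit_pc_lda(base, labels, n_pcs = 4)
  expect_equal(ncol(fit$scores), 1L)
  expect_equal(predict_pc_lda(fit, base), labels)
  # the two groups do not overlap on LD1
  expect_gt(min(fit$scores[labels == "b"]), max(fit$scores[labels == "a"]))
})

test_that("PC-LDA discriminant eigenvalues equal the brute-force generalized solve", {
  x <- rbind(c(1, 2, 0, 3), c(2, 1, 1, 4), c(0, 3, 2, 2),
             c(7, 5, 9, 1), c(8, 7, 8, 0), c(6, 6, 7, 2))
  labels <- rep(c("a", "b"), each = 3)
  fit <- fit_pc_lda(x, labels, n_pcs = 4)
  # oracle: scatter matrices in the original variable space
  Sw <- matrix(0, 4, 4); Sb <- matrix(0, 4, 4)
  grand <- colMeans(x)
  for (g in c("a", "b")) {
    xg <- x[labels == g, ]
    cg <- sweep(xg, 2, colMeans(xg))
    Sw <- Sw + crossprod(cg)
    d <- colMeans(xg) - grand
    Sb <- Sb + nrow(xg) * tcrossprod(d)
  }
  oracle <- sort(Re(eigen(solve(Sw) %*% Sb)$values), decreasing = TRUE)
  expect_equal(fit$eigenvalues[1], oracle[1], tolerance = 1e-9)
  # one discriminant axis for two classes; it holds all discriminant variance
  expect_equal(fit$axis_variance, 1)
})

test_that("PC-LDA agrees with an independent LDA on group separability", {
  skip_if_not_installed("MASS")
  set.seed(123)
  sc <- h_two_treatment_spec(seed = 321, n_per_class = 15)
  sm <- synth_map(sc$spec, h_fingerprint())
  X <- vector_normalize(sm$map)$absorbance
  labels <- sm$map$meta$treatment
  fit <- fit_pc_lda(X, labels, n_pcs = 10)
  pcs <- fit_pca(X, n_components = 10)$scores
  m <- MASS::lda(pcs, grouping = labels)
  ours <- predict_pc_lda(fit, X)
  theirs <- as.character(predict(m, pcs)$class)
  expect_gt(mean(ours == theirs), 0.95)
})

test_that("discriminant eigenvalues are invariant to an orthogonal rotation of the data", {
  set.seed(31)
  x <- matrix(rnorm(18 * 6), 18, 6)
  x[1:6, 1] <- x[1:6, 1] + 4
  x[7:12, 2] <- x[7:12, 2] + 4
  labels <- rep(c("a", "b", "c"), each = 6)
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  f1 <- fit_pc_lda(x, labels, n_pcs = 6)
  f2 <- fit_pc_lda(x %*% Q, labels, n_pcs = 6)
  expect_equal(f1$eigenvalues, f2$eigenvalues, tolerance = 1e-8)
})

test_that("a three-class scenario with two planted directions ordinates cleanly", {
  skip_if_not_installed("cluster")
  set.seed(55)
  n <- 10
  p <- 40
  dir1 <- rnorm(p); dir1 <- dir1 / sqrt(sum(dir1^2))
  dir2 <- rnorm(p); dir2 <- dir2 - sum(dir2 * dir1) * dir1
  dir2 <- dir2 / sqrt(sum(dir2^2))
  means <- rbind(0 * dir1, 6 * dir1, 3 * dir1 + 6 * dir2)
  x <- do.call(rbind, lapply(1:3, function(g)
    matrix(rnorm(n * p, sd = 0.5), n, p) +
      matrix(means[g, ], n, p, byrow = TRUE)))
  labels <- rep(c("g1", "g2", "g3"), each = n)
  fit <- fit_pc_lda(x, labels, n_pcs = 10)
  expect_gte(sum(fit$axis_variance[1:2]), 0.80)
  sil <- cluster::silhouette(as.integer(factor(labels)), dist(fit$scores))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  # leave-one-out nearest-centroid assignment recovers the labels
  hits <- vapply(seq_len(nrow(x)), function(i) {
    f <- fit_pc_lda(x[-i, ], labels[-i], n_pcs = 10)
    predict_pc_lda(f, x[i, , drop = FALSE]) == labels[i]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cluster vectors are centroid displacements back-projected to wavenumber space", {
  set.seed(88)
  x <- matrix(rnorm(12 * 20, sd = 0.1), 12, 20)
  x[7:12, 5] <- x[7:12, 5] + 3
  labels <- rep(c("a", "b"), each = 6)
  fit <- fit_pc_lda(x, labels, n_pcs = 5)
  cv <- cluster_vector_spectra(fit, x)
  # two equal-size classes: vectors are negatives of each other
  expect_equal(cv["a", ], -cv["b", ], tolerance = 1e-10)
  expect_equal(unname(which.max(abs(cv["b", ]))), 5L)
  expect_error(cluster_vector_spectra(fit, x, labels = rev(labels)),
               "labels")
})

test_that("a class sitting at the grand mean has a null cluster vector", {
  set.seed(99)
  base <- matrix(rnorm(18 * 10, sd = 0.01), 18, 10)
  shift <- c(rep(-2, 6), rep(0, 6), rep(2, 6))
  x <- base + outer(shift, c(1, rep(0, 9)))
  labels <- rep(c("lo", "mid", "hi"), each = 6)
  fit <- fit_pc_lda(x, labels, n_pcs = 9)
  cv <- cluster_vector_spectra(fit, x)
  expect_lt(sqrt(sum(cv["mid", ]^2)), 0.05)
  expect_gt(sqrt(sum(cv["hi", ]^2)), 1)
})

test_that("a class elevated in the carbohydrate region points its cluster vector there", {
  w <- h_fingerprint()
  glyco <- compound_reference("glyco", "storage", c(1152, 1080, 1022))
  # trace storage signal over the fixed biomass background: normalization
  # closure then barely perturbs the background bands
  conc <- rbind(control = 0.02, high = 0.06)
  spec <- scenario_spec(list(glyco), conc, n_per_class = 12,
                        background = h_background(), noise_sd = 0.001,
                        scale_range = c(1, 1),
                        baseline_ranges = list(c(0, 0)), seed = 808)
  sm <- synth_map(spec, w)
  X <- vector_normalize(sm$map)$absorbance
  fit <- fit_pc_lda(X, sm$map$meta$treatment, wavenumber = w)
  cv <- cluster_vector_spectra(fit, X)
  top <- w[order(abs(cv["high", ]), decreasing = TRUE)[1:5]]
  expect_true(all(top >= 1000 & top <= 1300))
})

test_that("PC-LDA input validation catches degenerate designs", {
  x <- matrix(rnorm(12), 4, 3)
  expect_error(fit_pc_lda(x, rep("a", 4)), "2 classes")
  expect_error(fit_pc_lda(x, c("a", "a", "a", "b")), ">= 2 spectra")
  expect_error(fit_pc_lda(x, c("a", "a", "b", "b"), n_pcs = 9), "exceeds")
})
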
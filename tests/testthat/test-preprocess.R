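test_that("qc_filter handles the empty map and keeps consistent counts", {
  w <- h_extended()
  empty <- spectral_map(w, matrix(numeric(0), 0, length(w)))
  r <- qc_filter(empty)
  expect_equal(r$report$n_in, 0L)
  expect_equal(n_spectra(r$map), 0L)
  # identical spectra above threshold: nothing removed
  m <- spectral_map(w, matrix(rep(h_gauss(w, 1650, 1, 15), 3), 3,
                              byrow = TRUE))
  m$absorbance <- m$absorbance + 1e-6   # nonzero noise floor in 1800-1900
  r2 <- qc_filter(m, snr_threshold = 10)
  expect_equal(r2$report$n_kept, 3L)
  expect_true(all(r2$report$snr >= r2$report$threshold))
  expect_lte(r2$report$n_kept, r2$report$n_in)
})

test_that("qc_filter separates structured from pure-noise spectra by design", {
  w <- h_extended()
  set.seed(101)
  noise_rms <- 0.001
  structured <- t(replicate(10, h_gauss(w, 1650, 50 * noise_rms, 15) +
                              rnorm(length(w), sd = noise_rms)))
  pure <- t(replicate(5, rnorm(length(w), sd = noise_rms)))
  m <- spectral_map(w, rbind(structured, pure))
  r <- qc_filter(m, snr_threshold = 10)
  expect_equal(r$report$n_kept, 10L)
  expect_setequal(r$map$meta$spectrum_id, paste0("s", 1:10))
})

test_that("qc_filter requires both the signal and the noise window", {
  m <- spectral_map(h_fingerprint(), matrix(1, 1, length(h_fingerprint())))
  expect_error(qc_filter(m), "1800-1900")
})

test_that("EMSC is the identity on the reference and recovers constructed inputs", {
  w <- h_fingerprint()
  ref <- synth_spectrum(list(band_shape(1650, 1, 12), band_shape(1540, 0.6, 10),
                             band_shape(1080, 0.4, 14)), w)
  fit <- emsc_correct(ref, ref, poly_order = 2)
  expect_lt(max(abs(fit$corrected$absorbance - ref$absorbance)), 1e-9)
  expect_equal(fit$scale, 1, tolerance = 1e-9)
  expect_lt(max(abs(fit$baseline_coeffs)), 1e-9)

  # input built from the model: baseline + 2 * reference
  inp <- ref
  u <- 2 * (w - min(w)) / diff(range(w)) - 1
  inp$absorbance <- 0.5 + 0.3 * u + 2 * ref$absorbance
  fit2 <- emsc_correct(inp, ref, poly_order = 1)
  expect_equal(fit2$scale, 2, tolerance = 1e-9)
  expect_lt(max(abs(fit2$corrected$absorbance - ref$absorbance)), 1e-8)

  # independent oracle: normal-equations solve of the same design
  X <- cbind(1, u, ref$absorbance)
  beta <- solve(t(X) %*% X, t(X) %*% inp$absorbance)
  expect_equal(fit2$scale, beta[3], tolerance = 1e-9)
  expect_equal(fit2$baseline_coeffs, beta[1:2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("EMSC exactly recovers the reference for any in-model distortion", {
  w <- h_fingerprint()
  set.seed(202)
  ref <- synth_spectrum(list(band_shape(1650, 1, 12), band_shape(1240, 0.5, 9)), w)
  u <- 2 * (w - min(w)) / diff(range(w)) - 1
  for (k in 1:25) {
    b <- runif(1, 0.2, 3)
    coefs <- runif(3, -0.5, 0.5)
    distorted <- ref
    distorted$absorbance <- coefs[1] + coefs[2] * u + coefs[3] * u^2 +
      b * ref$absorbance
    fit <- emsc_correct(distorted, ref, poly_order = 2)
    expect_lt(max(abs(fit$corrected$absorbance - ref$absorbance)), 1e-8)
    expect_equal(fit$scale, b, tolerance = 1e-8)
  }
})

test_that("EMSC raises errors for degenerate scale and mismatched grids", {
  w <- h_fingerprint()
  ref <- synth_spectrum(list(band_shape(1650, 1, 12)), w)
  flat <- ir_spectrum(w, rep(1, length(w)))   # pure baseline, b ~ 0
  expect_error(emsc_correct(flat, ref, poly_order = 0), "degenerate|rank")
  other <- synth_spectrum(list(band_shape(1650, 1, 12)), seq(900, 1796, 4))
  expect_error(emsc_correct(other, ref), "different grids")
})

test_that("EMSC improves agreement with the reference on noisy distorted copies", {
  w <- h_fingerprint()
  ref <- synth_spectrum(list(band_shape(1650, 1, 12), band_shape(1400, 0.5, 10),
                             band_shape(1080, 0.7, 14)), w)
  u <- 2 * (w - min(w)) / diff(range(w)) - 1
  set.seed(303)
  raw_cor <- corr_cor <- numeric(200)
  for (k in 1:200) {
    b <- runif(1, 0.5, 2)
    raw <- ref
    raw$absorbance <- runif(1, -0.3, 0.3) + runif(1, -0.3, 0.3) * u +
      runif(1, -0.2, 0.2) * u^2 + b * ref$absorbance +
      rnorm(length(w), sd = 0.01)
    fit <- emsc_correct(raw, ref, poly_order = 2)
    raw_cor[k] <- cor(raw$absorbance, ref$absorbance)
    corr_cor[k] <- cor(fit$corrected$absorbance, ref$absorbance)
  }
  expect_gt(mean(corr_cor), mean(raw_cor))
  expect_gt(mean(corr_cor), 0.99)
})

test_that("vector normalization yields unit region norm, scale invariance and idempotence", {
  w <- h_fingerprint()
  s <- synth_spectrum(list(band_shape(1650, 2, 12), band_shape(1100, 1, 10)), w)
  n1 <- vector_normalize(s)
  expect_equal(sqrt(sum(n1$absorbance^2)), 1, tolerance = 1e-12)
  s5 <- s
  s5$absorbance <- 5 * s$absorbance
  expect_equal(vector_normalize(s5)$absorbance, n1$absorbance,
               tolerance = 1e-12)
  expect_equal(vector_normalize(n1)$absorbance, n1$absorbance,
               tolerance = 1e-12)
  # 226 fingerprint points of ones -> every value 1/sqrt(226)
  ones <- ir_spectrum(w, rep(1, length(w)))
  expect_equal(vector_normalize(ones)$absorbance,
               rep(1 / sqrt(226), 226), tolerance = 1e-12)
  zero <- ir_spectrum(w, rep(0, length(w)))
  expect_error(vector_normalize(zero), "all-zero")
})

test_that("mean centering removes column means and is invertible", {
  expect_equal(mean_center(rbind(c(1, 2), c(1, 2)))$centered,
               matrix(0, 2, 2))
  mc <- mean_center(rbind(c(0, 0), c(2, 2)))
  expect_equal(unname(mc$centered), rbind(c(-1, -1), c(1, 1)))
  expect_equal(unname(mc$means), c(1, 1))
  set.seed(11)
  x <- matrix(rnorm(10 * 226), 10)
  mc2 <- mean_center(x)
  expect_lt(max(abs(colMeans(mc2$centered))), 1e-12)
  expect_equal(sweep(mc2$centered, 2, mc2$means, "+"), x)
  expect_error(mean_center(matrix(1, 1, 5)), "at least 2")
})
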
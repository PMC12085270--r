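test_that("Savitzky-Golay second derivative is exact on low-degree polynomials", {
  w <- seq(900, 1400, 4)
  # constant -> zero everywhere
  d0 <- savgol_second_derivative(ir_spectrum(w, rep(3, length(w))))
  expect_equal(d0$d2, rep(0, length(w)), tolerance = 1e-14)
  # quadratic A = (w/100)^2 -> d2 = 2e-4 at interior points
  dq <- savgol_second_derivative(ir_spectrum(w, (w / 100)^2))
  expect_equal(dq$d2[!dq$edge], rep(2e-4, sum(!dq$edge)), tolerance = 1e-9)
  # cubic A = (w/100)^3 -> d2 = 6 w / 1e6 (order-3 filter is exact on cubics)
  dc <- savgol_second_derivative(ir_spectrum(w, (w / 100)^3))
  expect_equal(dc$d2[!dc$edge], 6 * w[!dc$edge] / 1e6, tolerance = 1e-10)
  # edge points replicate the nearest interior value and are flagged
  expect_equal(sum(dq$edge), 6L)
  expect_equal(dq$d2[1:3], rep(dq$d2[4], 3))
})

test_that("Savitzky-Golay output equals the windowed polynomial-fit oracle on Gaussians", {
  # independent oracle: refit the degree-3 least-squares polynomial in every
  # 7-point window and take its second derivative at the window center
  w <- h_fingerprint()
  s <- synth_spectrum(list(band_shape(1650, 1, 12)), w)
  d2 <- savgol_second_derivative(s)
  interior <- which(!d2$edge)
  oracle <- vapply(interior, function(i) {
    idx <- (i - 3):(i + 3)
    u <- w[idx] - w[i]               # centered predictor keeps the fit stable
    fit <- lm(s$absorbance[idx] ~ u + I(u^2) + I(u^3))
    2 * unname(coef(fit)[3])
  }, numeric(1))
  expect_equal(d2$d2[interior], oracle, tolerance = 1e-8)
})

test_that("Gaussian curvature attenuation shrinks as bands broaden relative to the window", {
  # the 7-point order-3 filter smooths: its curvature estimate is attenuated
  # for narrow bands and converges to the analytic value for broad ones
  w <- h_fingerprint()
  rel_err <- vapply(c(8, 12, 20, 40), function(sigma) {
    s <- synth_spectrum(list(band_shape(1650, 1, sigma)), w)
    d2 <- savgol_second_derivative(s)
    analytic <- h_gauss_d2(w, 1650, 1, sigma)
    max(abs(d2$d2[!d2$edge] - analytic[!d2$edge])) * sigma^2
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))   # monotone improvement with sigma
  expect_lt(rel_err[4], 0.025)          # broad-band limit approaches exactness
  # the band is still read at the right place and with the right sign
  s8 <- synth_spectrum(list(band_shape(1650, 1, 8)), w)
  pk <- detect_d2_peaks(savgol_second_derivative(s8), prominence = 1e-6)
  expect_length(pk, 1L)
  expect_lte(abs(pk - 1650), 4)
})

test_that("savgol parameters are validated", {
  w <- seq(900, 1800, 4)
  s <- ir_spectrum(w, rep(1, length(w)))
  expect_error(savgol_second_derivative(s, window = 6), "odd")
  expect_error(savgol_second_derivative(s, window = 7, polyorder = 7),
               "smaller")
  short <- ir_spectrum(seq(900, 916, 4), rep(1, 5))
  expect_error(savgol_second_derivative(short, window = 9), "exceeds")
})

test_that("d2 amplitude quantifies the negative lobe and scales linearly", {
  w <- h_fingerprint()
  zero <- savgol_second_derivative(ir_spectrum(w, rep(0, length(w))))
  expect_equal(d2_amplitude(zero, 1650, 8), 0)
  # concentration doubling doubles the amplitude (Beer-Lambert)
  a1 <- d2_amplitude(savgol_second_derivative(
    synth_spectrum(list(band_shape(1650, 0.3, 10)), w)), 1650, 8)
  a2 <- d2_amplitude(savgol_second_derivative(
    synth_spectrum(list(band_shape(1650, 0.6, 10)), w)), 1650, 8)
  expect_gt(a1, 0)
  expect_equal(a2 / a1, 2, tolerance = 0.01)
  # homogeneity of degree 1 in absorbance scale
  s <- synth_spectrum(list(band_shape(1402, 0.3, 10)), w)
  s7 <- s
  s7$absorbance <- 7 * s$absorbance
  expect_equal(d2_amplitude(savgol_second_derivative(s7), 1402, 8),
               7 * d2_amplitude(savgol_second_derivative(s), 1402, 8),
               tolerance = 1e-10)
  expect_error(d2_amplitude(zero, 2500, 8), "outside")
})

test_that("amplitude regressed on concentration is linear (R2 > 0.999)", {
  w <- h_fingerprint()
  conc <- 1:5
  set.seed(404)
  amp <- vapply(conc, function(cc) {
    s <- synth_spectrum(list(band_shape(1650, 0.1 * cc, 10)), w)
    s$absorbance <- s$absorbance + rnorm(length(w), sd = 0.001)
    d2_amplitude(savgol_second_derivative(s), 1650, 8)
  }, numeric(1))
  fit <- lm(amp ~ conc)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("peak detection finds planted bands and nothing on flat input", {
  w <- h_fingerprint()
  flat <- savgol_second_derivative(ir_spectrum(w, rep(2, length(w))))
  expect_length(detect_d2_peaks(flat), 0L)
  one <- savgol_second_derivative(synth_spectrum(
    list(band_shape(1650, 1, 12)), w))
  pk <- detect_d2_peaks(one, prominence = 1e-6)
  expect_length(pk, 1L)
  expect_lte(abs(pk - 1650), 4)
  two <- savgol_second_derivative(synth_spectrum(
    list(band_shape(1500, 1, 10), band_shape(1620, 1, 10)), w))
  expect_length(detect_d2_peaks(two, prominence = 1e-6), 2L)
})

test_that("peak detection is invariant to constant offsets", {
  w <- h_fingerprint()
  s <- synth_spectrum(list(band_shape(1500, 1, 10), band_shape(1100, 0.4, 9)), w)
  p0 <- detect_d2_peaks(savgol_second_derivative(s), prominence = 1e-6)
  s$absorbance <- s$absorbance + 10
  p1 <- detect_d2_peaks(savgol_second_derivative(s), prominence = 1e-6)
  expect_equal(p0, p1)
})

test_that("band-region integrals follow hand-computed trapezoids and linearity", {
  w <- h_fingerprint()
  zero <- ir_spectrum(w, rep(0, length(w)))
  amide2 <- band_regions()[band_regions()$name == "amide_II", ]
  expect_equal(region_integral(zero, amide2), 0)
  # grid points inside 1519-1544 are 1520..1544: 7 points, 6 steps of 4
  ones <- ir_spectrum(w, rep(1, length(w)))
  expect_equal(region_integral(ones, amide2), 24)
  s <- synth_spectrum(list(band_shape(1530, 1, 6)), w)
  s2 <- s
  s2$absorbance <- 2 * s$absorbance
  expect_equal(region_integral(s2, amide2), 2 * region_integral(s, amide2))
  # additivity over adjacent regions sharing an on-grid boundary
  left <- region_integral(s, c(1000, 1200))
  right <- region_integral(s, c(1200, 1300))
  expect_equal(left + right, region_integral(s, c(1000, 1300)),
               tolerance = 1e-12)
  expect_error(region_integral(s, c(2000, 2100)), "overlap")
  expect_error(region_integral(s, c(1300, 1000)), "lo < hi")
})

test_that("the shipped band-region table carries the analysis regions", {
  br <- band_regions()
  get <- function(n) unlist(br[br$name == n, c("lo", "hi")], use.names = FALSE)
  expect_equal(get("fatty_acid_carbonyl"), c(1680, 1770))
  expect_equal(get("amide_I"), c(1600, 1700))
  expect_equal(get("amide_II"), c(1519, 1544))
  expect_equal(get("phosphate_PO2"), c(1200, 1230))
  expect_equal(get("carbohydrate"), c(1000, 1300))
  expect_true(all(br$lo < br$hi))
})
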
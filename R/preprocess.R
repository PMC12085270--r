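# Preprocessing: SNR quality filter, Kohler EMSC, vector normalization,
# mean-centering.  Pipeline order for ordination: QC -> EMSC -> vector
# normalize -> mean-center.

.window_idx <- function(wavenumber, lo, hi) {
  idx <- which(wavenumber >= lo - 1e-9 & wavenumber <= hi + 1e-9)
  if (length(idx) < 3L)
    stop(sprintf("grid does not cover the %g-%g cm^-1 window", lo, hi))
  idx
}

#' Signal-to-noise estimate of one spectrum
#'
#' SNR is the amide I peak height (maximum absorbance in the signal window
#' above the straight line joining the window's endpoints) divided by the
#' RMS of the linearly detrended absorbance in a signal-free noise window.
#'
#' @param spectrum an `ir_spectrum`.
#' @param signal_window amide I band window, cm^-1.
#' @param noise_window signal-free window, cm^-1.
#' @return dimensionless SNR.
#' @export
spectrum_snr <- function(spectrum, signal_window = c(1600, 1700),
                         noise_window = c(1800, 1900)) {
  w <- spectrum$wavenumber
  a <- spectrum$absorbance
  si <- .window_idx(w, signal_window[1L], signal_window[2L])
  ni <- .window_idx(w, noise_window[1L], noise_window[2L])
  ws <- w[si]; as <- a[si]
  base <- as[1L] + (as[length(as)] - as[1L]) * (ws - ws[1L]) / (ws[length(ws)] - ws[1L])
  height <- max(as - base)
  res <- stats::lm.fit(cbind(1, w[ni]), a[ni])$residuals
  noise <- sqrt(mean(res^2))
  if (noise <= .Machine$double.eps) return(Inf)
  height / noise
}

#' Quality-filter a spectral map by signal-to-noise
#'
#' Removes spectra whose SNR (see [spectrum_snr()]) falls below the
#' threshold, emulating the removal of spectra from non-monolayer regions or
#' with poor signal-to-noise.  The default threshold of 10 is a package
#' convention (configurable); the windows must both be covered by the grid.
#'
#' @param map a `spectral_map`.
#' @param snr_threshold minimal acceptable SNR.
#' @param signal_window,noise_window windows passed to [spectrum_snr()].
#' @return list with elements `map` (kept spectra) and `report`, a
#'   `qc_report` holding `n_in`, `n_kept`, per-spectrum `snr` and the
#'   threshold.
#' @export
qc_filter <- function(map, snr_threshold = 10,
                      signal_window = c(1600, 1700),
                      noise_window = c(1800, 1900)) {
  n_in <- n_spectra(map)
  if (n_in == 0L) {
    rep <- structure(list(n_in = 0L, n_kept = 0L,
                          snr = numeric(0), threshold = snr_threshold),
                     class = "qc_report")
    return(list(map = map, report = rep))
  }
  .window_idx(map$wavenumber, signal_window[1L], signal_window[2L])
  .window_idx(map$wavenumber, noise_window[1L], noise_window[2L])
  snr <- vapply(seq_len(n_in), function(i)
    spectrum_snr(map_spectrum(map, i), signal_window, noise_window), numeric(1))
  keep <- snr >= snr_threshold
  rep <- structure(list(n_in = n_in, n_kept = sum(keep),
                        snr = setNames(snr, map$meta$spectrum_id),
                        threshold = snr_threshold),
                   class = "qc_report")
  list(map = subset_map(map, keep), report = rep)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> kept %d / %d spectra (SNR threshold %g)\n",
              x$n_kept, x$n_in, x$threshold))
  invisible(x)
}

# orthonormal-ish polynomial baseline basis on wavenumber mapped to [-1, 1];
# scaling keeps the EMSC design well conditioned for orders up to ~4
.poly_basis <- function(wavenumber, order) {
  u <- 2 * (wavenumber - min(wavenumber)) / diff(range(wavenumber)) - 1
  vapply(0:order, function(j) u^j, numeric(length(wavenumber)))
}

#' Kohler EMSC scatter correction of a spectrum
#'
#' Fits the basic Kohler extended multiplicative signal correction model
#' \deqn{A(w) = \sum_j d_j P_j(w) + b\,R(w) + e(w)}
#' by least squares, where \eqn{P_j} is a polynomial baseline basis of the
#' given order (on wavenumber rescaled to \[-1, 1\]), \eqn{R} the reference
#' spectrum and \eqn{b} the multiplicative scatter scale.  The corrected
#' spectrum is \eqn{R + e/b}: baseline removed, scatter scale divided out,
#' chemical deviations from the reference preserved.
#'
#' @param spectrum an `ir_spectrum`.
#' @param reference an `ir_spectrum` on the identical grid (typically the
#'   mean of the control-treatment spectra after QC).
#' @param poly_order baseline polynomial order (default 2).
#' @return an `emsc_fit` with elements `corrected` (`ir_spectrum`),
#'   `baseline_coeffs`, `scale`, `residual_rms`.
#' @export
emsc_correct <- function(spectrum, reference, poly_order = 2) {
  if (poly_order < 0 || poly_order != round(poly_order))
    stop("poly_order must be a nonnegative integer")
  w <- spectrum$wavenumber
  if (!isTRUE(all.equal(w, reference$wavenumber, tolerance = 1e-9)))
    stop("spectrum and reference are on different grids (use resample_to_grid explicitly)")
  X <- cbind(.poly_basis(w, poly_order), reference$absorbance)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("EMSC design matrix is rank deficient")
  beta <- qr.coef(qrX, spectrum$absorbance)
  b <- beta[length(beta)]
  resid <- spectrum$absorbance - X %*% beta
  if (!is.finite(b) || abs(b) <= 1e-12)
    stop("degenerate EMSC scale (b ~ 0); reference does not explain the spectrum")
  corrected <- spectrum
  corrected$absorbance <- as.numeric(reference$absorbance + resid / b)
  structure(list(corrected = corrected,
                 baseline_coeffs = unname(beta[-length(beta)]),
                 scale = unname(b),
                 residual_rms = sqrt(mean(resid^2))),
            class = "emsc_fit")
}

#' @export
print.emsc_fit <- function(x, ...) {
  cat(sprintf("<emsc_fit> scale b = %.4g, baseline order %d, residual RMS %.3g\n",
              x$scale, length(x$baseline_coeffs) - 1L, x$residual_rms))
  invisible(x)
}

#' EMSC-correct every spectrum of a map against one reference
#'
#' @param map a `spectral_map`.
#' @param reference reference `ir_spectrum`; default the mean spectrum of
#'   the map itself.  The recommended reference is the mean control spectrum
#'   (see [mean_spectrum()] and the pipeline in [run_experiment()]).
#' @param poly_order baseline polynomial order.
#' @return list with `map` (corrected) and `fits`, a `data.frame` of scale
#'   and residual RMS per spectrum.
#' @export
emsc_correct_map <- function(map, reference = NULL, poly_order = 2) {
  if (is.null(reference)) reference <- mean_spectrum(map)
  out <- map$absorbance
  scales <- numeric(n_spectra(map))
  rms <- numeric(n_spectra(map))
  for (i in seq_len(n_spectra(map))) {
    f <- emsc_correct(map_spectrum(map, i), reference, poly_order)
    out[i, ] <- f$corrected$absorbance
    scales[i] <- f$scale
    rms[i] <- f$residual_rms
  }
  list(map = spectral_map(map$wavenumber, out, map$meta, map$raster_step),
       fits = data.frame(spectrum_id = map$meta$spectrum_id,
                         scale = scales, residual_rms = rms,
                         stringsAsFactors = FALSE))
}

#' Mean spectrum of a map
#' @param map a `spectral_map` with at least one spectrum.
#' @param id identifier for the resulting spectrum.
#' @return an `ir_spectrum`.
#' @export
mean_spectrum <- function(map, id = "mean") {
  if (n_spectra(map) == 0L) stop("cannot average an empty map")
  ir_spectrum(map$wavenumber, colMeans(map$absorbance), id = id)
}

#' Vector-normalize spectra over a wavenumber region
#'
#' Divides the whole spectrum by the Euclidean norm of its absorbance over
#' the given region (default: the 900--1800 cm^-1 fingerprint region), so
#' the region norm of the output is exactly 1.  Idempotent, and invariant to
#' positive scaling of the input.
#'
#' @param x an `ir_spectrum` or `spectral_map`.
#' @param region normalization window `c(lo, hi)` in cm^-1.
#' @return object of the same class as `x`.
#' @export
vector_normalize <- function(x, region = c(900, 1800)) UseMethod("vector_normalize")

#' @export
vector_normalize.ir_spectrum <- function(x, region = c(900, 1800)) {
  idx <- .window_idx(x$wavenumber, region[1L], region[2L])
  nrm <- sqrt(sum(x$absorbance[idx]^2))
  if (nrm <= .Machine$double.eps)
    stop("all-zero absorbance in the normalization region")
  x$absorbance <- x$absorbance / nrm
  x
}

#' @export
vector_normalize.spectral_map <- function(x, region = c(900, 1800)) {
  idx <- .window_idx(x$wavenumber, region[1L], region[2L])
  nrm <- sqrt(rowSums(x$absorbance[, idx, drop = FALSE]^2))
  if (any(nrm <= .Machine$double.eps))
    stop("all-zero absorbance in the normalization region for spectrum ",
         paste(x$meta$spectrum_id[nrm <= .Machine$double.eps], collapse = ", "))
  x$absorbance <- x$absorbance / nrm
  x
}

#' Column-wise mean-centering of a spectra matrix
#'
#' @param x numeric matrix, spectra in rows (at least 2).
#' @return list with `centered` (same shape, column means 0) and `means`.
#' @export
mean_center <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("mean-centering needs at least 2 spectra")
  means <- colMeans(x)
  list(centered = sweep(x, 2L, means), means = means)
}
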
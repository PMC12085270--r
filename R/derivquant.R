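# Savitzky-Golay second-derivative spectroscopy and Beer-Lambert
# quantitation.  Under A(w) = alpha(w) * I * c, the second derivative
# d2A/dw2 = (d2alpha/dw2) * I * c remains linear in concentration, so the
# magnitude of the negative d2 lobe at a band center is a relative
# concentration proxy.

#' Savitzky-Golay second derivative of a spectrum or map
#'
#' Convolves each spectrum with the central-point Savitzky-Golay
#' second-derivative filter (default: 7-point window, polynomial order 3),
#' scaled by the physical grid step so the output is d2A/dw2 in
#' absorbance per (cm^-1)^2.  The (window-1)/2 points at each end have no
#' full window; they are filled by replicating the nearest interior value
#' and flagged in the `edge` element, and are excluded from quantitation by
#' [d2_amplitude()] and [detect_d2_peaks()].
#'
#' @param x an `ir_spectrum` or `spectral_map`.
#' @param window odd filter length (points).
#' @param polyorder fitting polynomial degree, `< window`.
#' @return for a spectrum, a `d2_spectrum` (elements `wavenumber`, `d2`,
#'   `edge`, `source_id`); for a map, a `d2_map` (matrix `d2`, shared
#'   `edge`, `meta`).
#' @export
savgol_second_derivative <- function(x, window = 7, polyorder = 3)
  UseMethod("savgol_second_derivative")

.sg_d2_coef <- function(window, polyorder, step) {
  if (window %% 2 != 1 || window < 5) stop("window must be an odd integer >= 5")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  if (polyorder < 2) stop("polyorder must be >= 2 for a second derivative")
  F <- signal::sgolay(p = polyorder, n = window, m = 2, ts = step)
  as.numeric(F[(window + 1L) %/% 2L, ])
}

.sg_d2_vec <- function(y, coefs) {
  n <- length(y)
  window <- length(coefs)
  if (window > n) stop("window (", window, ") exceeds spectrum length (", n, ")")
  h <- (window - 1L) %/% 2L
  interior <- (h + 1L):(n - h)
  d2 <- numeric(n)
  for (i in interior) d2[i] <- sum(coefs * y[(i - h):(i + h)])
  d2[seq_len(h)] <- d2[h + 1L]
  d2[(n - h + 1L):n] <- d2[n - h]
  edge <- rep(FALSE, n)
  edge[c(seq_len(h), (n - h + 1L):n)] <- TRUE
  list(d2 = d2, edge = edge)
}

#' @export
savgol_second_derivative.ir_spectrum <- function(x, window = 7, polyorder = 3) {
  step <- attr(validate_wavenumbers(x$wavenumber), "step")
  cf <- .sg_d2_coef(window, polyorder, step)
  r <- .sg_d2_vec(x$absorbance, cf)
  structure(list(wavenumber = x$wavenumber, d2 = r$d2, edge = r$edge,
                 source_id = x$id, isolate = x$isolate,
                 treatment = x$treatment),
            class = "d2_spectrum")
}

#' @export
savgol_second_derivative.spectral_map <- function(x, window = 7, polyorder = 3) {
  step <- attr(validate_wavenumbers(x$wavenumber), "step")
  cf <- .sg_d2_coef(window, polyorder, step)
  d2 <- x$absorbance
  edge <- NULL
  for (i in seq_len(n_spectra(x))) {
    r <- .sg_d2_vec(x$absorbance[i, ], cf)
    d2[i, ] <- r$d2
    edge <- r$edge
  }
  if (is.null(edge)) edge <- rep(FALSE, length(x$wavenumber))
  structure(list(wavenumber = x$wavenumber, d2 = d2, edge = edge,
                 meta = x$meta),
            class = "d2_map")
}

#' @export
print.d2_spectrum <- function(x, ...) {
  cat(sprintf("<d2_spectrum of '%s'> %d points, %g-%g cm^-1\n", x$source_id,
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' @export
print.d2_map <- function(x, ...) {
  cat(sprintf("<d2_map> %d spectra x %d wavenumbers\n", nrow(x$d2),
              length(x$wavenumber)))
  invisible(x)
}

#' Extract one second-derivative spectrum from a d2 map
#' @param d2map a `d2_map`.
#' @param i row index or spectrum id.
#' @return a `d2_spectrum`.
#' @export
d2_map_spectrum <- function(d2map, i) {
  if (is.character(i)) i <- match(i, d2map$meta$spectrum_id)
  m <- d2map$meta[i, ]
  structure(list(wavenumber = d2map$wavenumber, d2 = d2map$d2[i, ],
                 edge = d2map$edge, source_id = m$spectrum_id,
                 isolate = m$isolate, treatment = m$treatment),
            class = "d2_spectrum")
}

#' Mean second-derivative spectrum of a d2 map
#' @param d2map a `d2_map`.
#' @return a `d2_spectrum`.
#' @export
mean_d2_spectrum <- function(d2map) {
  structure(list(wavenumber = d2map$wavenumber, d2 = colMeans(d2map$d2),
                 edge = d2map$edge, source_id = "mean",
                 isolate = NA_character_, treatment = NA_character_),
            class = "d2_spectrum")
}

# local minima of d2 at interior (non-edge) points; strict on the left,
# non-strict on the right so plateaus count once
.d2_minima <- function(d2s) {
  d2 <- d2s$d2
  n <- length(d2)
  ok <- logical(n)
  for (i in 2L:(n - 1L))
    ok[i] <- !d2s$edge[i] && d2[i] < d2[i - 1L] && d2[i] <= d2[i + 1L]
  which(ok)
}

#' Band amplitude from the second derivative
#'
#' Returns the magnitude of the deepest negative second-derivative local
#' minimum within `peak +- search_tol` (absorbance bands appear as negative
#' d2 lobes), or 0 when no negative local minimum lies in the window.  By
#' the Beer-Lambert law this amplitude is proportional to concentration for
#' a fixed band shape, so it serves as a relative concentration measure.
#'
#' @param d2s a `d2_spectrum`.
#' @param peak band center, cm^-1.
#' @param search_tol half-width of the search window, cm^-1.
#' @return nonnegative amplitude (absorbance per (cm^-1)^2).
#' @export
d2_amplitude <- function(d2s, peak, search_tol = 8) {
  w <- d2s$wavenumber
  lo <- peak - search_tol
  hi <- peak + search_tol
  if (hi < min(w) - 1e-9 || lo > max(w) + 1e-9)
    stop(sprintf("search window %g +- %g cm^-1 lies outside the grid", peak, search_tol))
  mins <- .d2_minima(d2s)
  mins <- mins[w[mins] >= lo - 1e-9 & w[mins] <= hi + 1e-9 & d2s$d2[mins] < 0]
  if (!length(mins)) return(0)
  max(-d2s$d2[mins])
}

#' Detect band positions as negative second-derivative minima
#'
#' @param d2s a `d2_spectrum`.
#' @param prominence minimal depth (`-d2` at the minimum) for a band to be
#'   reported.
#' @return ascending numeric vector of band positions, cm^-1 (possibly
#'   empty).
#' @export
detect_d2_peaks <- function(d2s, prominence = 0) {
  mins <- .d2_minima(d2s)
  mins <- mins[-d2s$d2[mins] >= prominence & d2s$d2[mins] < 0]
  sort(d2s$wavenumber[mins])
}

#' Convert a d2 map to a spectral map for export
#'
#' Repackages second-derivative values as a `spectral_map` so they can be
#' written with [write_spectra()] in the same CSV-wide dialect as
#' absorbance maps.
#'
#' @param d2map a `d2_map`.
#' @return a `spectral_map` whose "absorbance" matrix holds d2 values.
#' @export
d2_as_map <- function(d2map) {
  spectral_map(d2map$wavenumber, d2map$d2, d2map$meta)
}

#' Default spectral band regions
#'
#' The analysis regions of the fingerprint window: fatty-acid carbonyl
#' (1680--1770), a broad lipid alternative (1600--1760), amide I
#' (1600--1700), amide II (1519--1544), phosphate PO2- (1200--1230), and
#' carbohydrate (1000--1300, with 1000--1250 and 1000--1200 as selectable
#' alternatives).  Edit or extend via an ordinary `data.frame` or the CSV at
#' `system.file("extdata", "band_regions.csv", package = "srftir")`.
#'
#' @return a `data.frame` with columns `name`, `lo`, `hi` (cm^-1).
#' @export
band_regions <- function() {
  read.csv(system.file("extdata", "band_regions.csv", package = "srftir"),
           stringsAsFactors = FALSE)
}

#' Trapezoidal band-region integral of an absorbance spectrum
#'
#' @param spectrum an `ir_spectrum`.
#' @param region either a row of [band_regions()] (anything with `lo` and
#'   `hi`) or a numeric `c(lo, hi)` in cm^-1.
#' @return area in absorbance * cm^-1.
#' @export
region_integral <- function(spectrum, region) {
  if (is.numeric(region)) region <- list(lo = region[1L], hi = region[2L])
  lo <- as.numeric(region$lo)
  hi <- as.numeric(region$hi)
  if (lo >= hi) stop("region must satisfy lo < hi")
  idx <- which(spectrum$wavenumber >= lo - 1e-9 & spectrum$wavenumber <= hi + 1e-9)
  if (length(idx) < 2L)
    stop(sprintf("region [%g, %g] does not overlap the grid", lo, hi))
  w <- spectrum$wavenumber[idx]
  a <- spectrum$absorbance[idx]
  sum(diff(w) * (head(a, -1L) + tail(a, -1L)) / 2)
}
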
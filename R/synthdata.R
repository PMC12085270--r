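# Seeded generators of synthetic mixture spectra, spectral maps with
# treatment group structure, and growth curves.  Spectra are Beer-Lambert
# mixtures: sums of compound band signatures scaled by concentration,
# corrupted by a multiplicative scatter scale, an additive polynomial
# baseline, and white noise -- the same model family the EMSC correction
# assumes, plus an optional out-of-model sinusoidal distortion.

#' Construct a band shape
#'
#' @param center band center, cm^-1.
#' @param height peak absorbance (proportional to absorptivity x pathlength
#'   x concentration).
#' @param sigma Gaussian width, cm^-1.
#' @param shape `"gaussian"` or `"pseudo_voigt"`.
#' @param eta Lorentzian mixing fraction for pseudo-Voigt (0 = Gaussian).
#' @return a `band_shape`.
#' @export
band_shape <- function(center, height, sigma, shape = c("gaussian",
                                                        "pseudo_voigt"),
                       eta = 0) {
  shape <- match.arg(shape)
  if (height < 0) stop("height must be >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (eta < 0 || eta > 1) stop("eta must be in [0, 1]")
  structure(list(center = center, height = height, sigma = sigma,
                 shape = shape, eta = eta),
            class = "band_shape")
}

.eval_band <- function(band, w) {
  g <- exp(-(w - band$center)^2 / (2 * band$sigma^2))
  if (band$shape == "gaussian" || band$eta == 0)
    return(band$height * g)
  l <- band$sigma^2 / ((w - band$center)^2 + band$sigma^2)
  band$height * (band$eta * l + (1 - band$eta) * g)
}

#' Evaluate a sum of bands on a wavenumber grid
#'
#' Exactly linear in every band's height, so doubling a concentration
#' doubles the corresponding contribution pointwise.
#'
#' @param bands list of `band_shape`s (empty list gives the zero spectrum).
#' @param wavenumber grid, cm^-1.
#' @param id,isolate,treatment metadata for the resulting spectrum.
#' @return an `ir_spectrum`.
#' @export
synth_spectrum <- function(bands, wavenumber, id = "synth",
                           isolate = NA_character_,
                           treatment = NA_character_) {
  w <- as.numeric(validate_wavenumbers(wavenumber))
  a <- numeric(length(w))
  for (b in bands) a <- a + .eval_band(b, w)
  ir_spectrum(w, a, id = id, isolate = isolate, treatment = treatment)
}

#' Bands of a compound at a given concentration
#'
#' Each characteristic peak of the reference becomes a band of height
#' `weight * concentration` and the given width, realizing the Beer-Lambert
#' proportionality between concentration and band amplitude.
#'
#' @param ref a `compound_reference`.
#' @param concentration nonnegative concentration (arbitrary units).
#' @param sigma band width, cm^-1.
#' @param shape,eta passed to [band_shape()].
#' @return list of `band_shape`s.
#' @export
compound_bands <- function(ref, concentration, sigma = 10,
                           shape = "gaussian", eta = 0) {
  if (concentration < 0) stop("concentration must be >= 0")
  mapply(function(p, wt) band_shape(p, wt * concentration, sigma,
                                    shape = shape, eta = eta),
         ref$peaks, ref$weights, SIMPLIFY = FALSE)
}

#' Scenario specification for synthetic spectral maps
#'
#' Describes the ground truth of a simulated experiment: a compound panel
#' with per-class concentrations, optional fixed background bands (the
#' biomass bands every cell shows: amide I/II, bulk carbohydrate), the
#' scatter model (uniform ranges for a multiplicative scale and polynomial
#' baseline coefficients on wavenumber rescaled to \[-1, 1\]), white-noise
#' standard deviation, spectra per class, and the seed.
#'
#' @param compounds list of `compound_reference`s.
#' @param concentrations numeric matrix, classes (rows, named) by compounds
#'   (columns); all entries >= 0.
#' @param n_per_class spectra per class (>= 2).
#' @param background list of `band_shape`s added to every spectrum.
#' @param scale_range multiplicative scatter scale range (uniform draw).
#' @param baseline_ranges list of `c(lo, hi)` ranges, one per polynomial
#'   order starting at 0, for baseline coefficients.
#' @param noise_sd additive white-noise standard deviation, absorbance.
#' @param band_sigma compound band width, cm^-1.
#' @param sine_amplitude,sine_period optional out-of-model sinusoidal
#'   distortion (amplitude in absorbance, period in cm^-1); 0 disables it.
#' @param seed integer seed making the scenario bit-reproducible.
#' @return a `scenario_spec`.
#' @export
scenario_spec <- function(compounds, concentrations, n_per_class = 10,
                          background = list(),
                          scale_range = c(0.7, 1.3),
                          baseline_ranges = list(c(-0.05, 0.05),
                                                 c(-0.02, 0.02),
                                                 c(-0.01, 0.01)),
                          noise_sd = 0.005, band_sigma = 10,
                          sine_amplitude = 0, sine_period = 120,
                          seed = 1) {
  concentrations <- as.matrix(concentrations)
  if (is.null(rownames(concentrations)))
    rownames(concentrations) <- paste0("class", seq_len(nrow(concentrations)))
  if (ncol(concentrations) != length(compounds))
    stop("one concentration column per compound required")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (n_per_class < 2L) stop("n_per_class must be >= 2")
  colnames(concentrations) <- vapply(compounds, `[[`, "", "name")
  structure(list(compounds = compounds, concentrations = concentrations,
                 n_per_class = n_per_class, background = background,
                 scale_range = scale_range,
                 baseline_ranges = baseline_ranges,
                 noise_sd = noise_sd, band_sigma = band_sigma,
                 sine_amplitude = sine_amplitude, sine_period = sine_period,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Generate a synthetic spectral map with group structure
#'
#' For each class, `n_per_class` spectra are built as
#' `scale * (background + compound mixture) + baseline + sine + noise`.
#' Draw order per spectrum is fixed (scale, then baseline coefficients by
#' ascending order, then sine phase if enabled, then the noise vector), and
#' a single seeded stream drives the whole scenario, so identical
#' specifications regenerate byte-identical maps.
#'
#' @param spec a `scenario_spec`.
#' @param wavenumber grid (default `seq(900, 1800, 4)`, the fingerprint
#'   analysis crop).
#' @return list with `map` (a `spectral_map` whose `treatment` column holds
#'   the class name) and `truth` (a `data.frame` of the true scale,
#'   baseline coefficients and per-compound concentrations per spectrum).
#' @export
synth_map <- function(spec, wavenumber = seq(900, 1800, by = 4)) {
  w <- as.numeric(validate_wavenumbers(wavenumber))
  u <- 2 * (w - min(w)) / diff(range(w)) - 1
  set.seed(spec$seed)
  classes <- rownames(spec$concentrations)
  bg <- numeric(length(w))
  for (b in spec$background) bg <- bg + .eval_band(b, w)
  rows <- list()
  truth <- list()
  k <- 0L
  for (cl in classes) {
    clean <- bg
    for (j in seq_along(spec$compounds)) {
      bands <- compound_bands(spec$compounds[[j]],
                              spec$concentrations[cl, j],
                              sigma = spec$band_sigma)
      for (b in bands) clean <- clean + .eval_band(b, w)
    }
    for (r in seq_len(spec$n_per_class)) {
      k <- k + 1L
      scale <- runif(1, spec$scale_range[1L], spec$scale_range[2L])
      coefs <- vapply(spec$baseline_ranges, function(rg)
        runif(1, rg[1L], rg[2L]), numeric(1))
      baseline <- numeric(length(w))
      for (j in seq_along(coefs)) baseline <- baseline + coefs[j] * u^(j - 1L)
      distort <- 0
      if (spec$sine_amplitude > 0) {
        phase <- runif(1, 0, 2 * pi)
        distort <- spec$sine_amplitude * sin(2 * pi * w / spec$sine_period + phase)
      }
      noise <- rnorm(length(w), sd = spec$noise_sd)
      rows[[k]] <- scale * clean + baseline + distort + noise
      truth[[k]] <- data.frame(spectrum_id = sprintf("%s_%02d", cl, r),
                               class = cl, scale = scale,
                               t(setNames(coefs, paste0("baseline_c",
                                                        seq_along(coefs) - 1L))),
                               t(setNames(spec$concentrations[cl, ],
                                          paste0("conc_",
                                                 gsub("[^A-Za-z0-9]", "_",
                                                      colnames(spec$concentrations))))),
                               stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  n <- nrow(truth)
  meta <- data.frame(spectrum_id = truth$spectrum_id,
                     isolate = "synthetic",
                     treatment = truth$class,
                     x_um = 5 * ((seq_len(n) - 1L) %% 25L),
                     y_um = 5 * ((seq_len(n) - 1L) %/% 25L),
                     stringsAsFactors = FALSE)
  map <- spectral_map(w, do.call(rbind, rows), meta)
  list(map = map, truth = truth)
}

#' Generate a synthetic OD660 growth curve
#'
#' Logistic trajectory `K od0 e^(mu t) / (K + od0 (e^(mu t) - 1))` sampled
#' hourly for 72 hours (the measurement design this package targets), with
#' multiplicative lognormal noise.  `K = Inf` gives exact exponential
#' growth.
#'
#' @param mu_true specific growth rate, per hour (>= 0).
#' @param od0 initial OD660.
#' @param K carrying capacity (OD units; `Inf` for pure exponential).
#' @param noise_frac multiplicative noise fraction (lognormal sd of
#'   log-OD).
#' @param seed integer seed.
#' @param hours duration, hours.
#' @param dt sampling interval, hours.
#' @return `data.frame` with columns `time_h` and `od660`.
#' @export
synth_growth <- function(mu_true, od0 = 0.005, K = 1, noise_frac = 0.01,
                         seed = 1, hours = 72, dt = 1) {
  if (mu_true < 0) stop("mu_true must be >= 0")
  if (od0 <= 0) stop("od0 must be positive")
  t <- seq(0, hours, by = dt)
  od <- if (is.infinite(K)) od0 * exp(mu_true * t)
        else K * od0 * exp(mu_true * t) / (K + od0 * (exp(mu_true * t) - 1))
  if (noise_frac > 0) {
    set.seed(seed)
    od <- od * exp(rnorm(length(t), sd = noise_frac))
  }
  data.frame(time_h = t, od660 = od)
}
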
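# Characteristic-peak compound identification and z-test significance
# versus control spectra.  A compound is "identified" when at least 75% of
# the (weighted) characteristic peaks have a matching negative
# second-derivative minimum; relative concentration is the weighted mean d2
# amplitude at the reference peaks.

#' Construct a compound reference
#'
#' A compound is described by two or more characteristic mid-IR peak
#' positions (with optional weights) inside the 900--1800 cm^-1 fingerprint
#' region, a compound class, and a matching tolerance.
#'
#' @param name compound name.
#' @param class one of `"storage"`, `"osmolyte"`, `"general_stress"`.
#' @param peaks numeric vector of characteristic peak positions, cm^-1
#'   (at least 2).
#' @param weights positive weights, one per peak (default equal).
#' @param match_tol matching tolerance in cm^-1 (default 8, two grid steps
#'   of a 4 cm^-1 grid).
#' @return a `compound_reference`.
#' @export
compound_reference <- function(name, class = c("storage", "osmolyte",
                                               "general_stress"),
                               peaks, weights = NULL, match_tol = 8) {
  class <- match.arg(class)
  peaks <- as.numeric(peaks)
  if (length(peaks) < 2L)
    stop("a compound reference needs multiple characteristic peaks (>= 2)")
  if (any(peaks < 900 - 1e-9 | peaks > 1800 + 1e-9))
    stop("characteristic peaks must lie in the 900-1800 cm^-1 fingerprint region")
  if (is.null(weights)) weights <- rep(1, length(peaks))
  if (length(weights) != length(peaks) || any(weights <= 0))
    stop("weights must be positive, one per peak")
  structure(list(name = name, class = class, peaks = peaks,
                 weights = as.numeric(weights), match_tol = match_tol),
            class = "compound_reference")
}

#' @export
print.compound_reference <- function(x, ...) {
  cat(sprintf("<compound_reference '%s'> class %s; peaks %s cm^-1 (tol %g)\n",
              x$name, x$class, paste(x$peaks, collapse = ", "), x$match_tol))
  invisible(x)
}

#' Load a compound library from CSV
#'
#' The CSV has columns `compound`, `class`, `peak_cm1`, `weight`, `tol_cm1`
#' with one row per characteristic peak.
#'
#' @param path library CSV path.
#' @return named list of `compound_reference` objects.
#' @export
read_compound_library <- function(path) {
  if (!file.exists(path)) stop("compound library not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "class", "peak_cm1", "weight", "tol_cm1")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("compound library lacks columns: ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(df, df$compound), function(g)
    compound_reference(g$compound[1L], g$class[1L], g$peak_cm1, g$weight,
                       g$tol_cm1[1L]))
  out[unique(df$compound)]
}

#' Built-in compound library
#'
#' The ten storage and stress compounds tracked by this package: storage
#' polymers PHA, PHB, glycogen and polyphosphate; osmolytes mannitol,
#' ectoine and glycine betaine; general stress metabolites trehalose,
#' proline and glutamate.  Default peak positions are curated from standard
#' published mid-IR band assignments and shipped in an editable CSV
#' (`system.file("extdata", "compound_library.csv", package = "srftir")`);
#' laboratories with their own reference second-derivative spectra should
#' replace them.
#'
#' @param path optional path to an alternative library CSV.
#' @return named list of `compound_reference` objects.
#' @export
builtin_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "compound_library.csv", package = "srftir")
  read_compound_library(path)
}

#' Match a compound's characteristic peaks in a second-derivative spectrum
#'
#' The match fraction is the weight share of reference peaks that have a
#' detected negative d2 minimum within the reference's matching tolerance;
#' a compound is identified when the fraction reaches the 75% threshold
#' (inclusive).
#'
#' @param d2s a `d2_spectrum`.
#' @param ref a `compound_reference`.
#' @param prominence minimal d2 depth for peak detection.
#' @param threshold identification threshold on the match fraction.
#' @return list with `match_fraction`, `identified`, and the logical
#'   `peak_matched` vector.
#' @export
match_compound <- function(d2s, ref, prominence = 0, threshold = 0.75) {
  if (!length(ref$peaks)) stop("compound reference has no peaks")
  found <- detect_d2_peaks(d2s, prominence = prominence)
  matched <- vapply(ref$peaks, function(p)
    any(abs(found - p) <= ref$match_tol + 1e-9), logical(1))
  frac <- sum(ref$weights[matched]) / sum(ref$weights)
  list(match_fraction = frac, identified = frac >= threshold,
       peak_matched = matched)
}

#' Relative compound concentration per spectrum
#'
#' Requires the compound to be identified in the mean second-derivative
#' spectrum of the set (quantitation is refused otherwise).  The relative
#' concentration of each spectrum is the weighted mean of its d2 amplitudes
#' at the reference peaks: arbitrary units, comparable only within one
#' compound and instrument setting.
#'
#' @param d2map a `d2_map` (or list of `d2_spectrum`).
#' @param ref a `compound_reference`.
#' @param prominence peak-detection threshold for the identification check.
#' @param check_identified set `FALSE` to skip the identification gate
#'   (used when the gate was already applied to a pooled set).
#' @return numeric vector of relative concentrations, one per spectrum.
#' @export
quantify_compound <- function(d2map, ref, prominence = 0,
                              check_identified = TRUE) {
  if (is.list(d2map) && !inherits(d2map, "d2_map")) {
    spectra <- d2map
  } else {
    spectra <- lapply(seq_len(nrow(d2map$d2)), function(i)
      d2_map_spectrum(d2map, i))
  }
  if (!length(spectra)) return(numeric(0))
  if (check_identified) {
    pool <- spectra[[1L]]
    pool$d2 <- Reduce(`+`, lapply(spectra, `[[`, "d2")) / length(spectra)
    m <- match_compound(pool, ref, prominence = prominence)
    if (!m$identified)
      stop(sprintf("quantitation refused: '%s' not identified (match fraction %.2f < 0.75)",
                   ref$name, m$match_fraction))
  }
  vapply(spectra, function(s) {
    amps <- vapply(ref$peaks, function(p)
      d2_amplitude(s, p, search_tol = ref$match_tol), numeric(1))
    sum(ref$weights * amps) / sum(ref$weights)
  }, numeric(1))
}

#' Two-sample z-test of treatment versus control concentrations
#'
#' Unpooled (Welch-style) two-sample z statistic
#' \deqn{z = (\bar x_t - \bar x_c) / \sqrt{s_t^2/n_t + s_c^2/n_c}}
#' with a two-sided p-value from the standard normal.  Direction is
#' `"increase"` when z > 0 and p < alpha, `"decrease"` when z < 0 and
#' p < alpha, `"none"` otherwise.
#'
#' @param treatment_vals,control_vals numeric vectors (each n >= 2).
#' @param alpha significance level.
#' @return list with `z`, `p`, `direction`, `n_treatment`, `n_control`.
#' @export
ztest_vs_control <- function(treatment_vals, control_vals, alpha = 0.05) {
  nt <- length(treatment_vals)
  nc <- length(control_vals)
  if (nt < 2L || nc < 2L) stop("z-test needs at least 2 values per group")
  vt <- var(treatment_vals)
  vc <- var(control_vals)
  if (!is.finite(vc) || vc <= 0)
    stop("degenerate control variance; z-test undefined")
  se <- sqrt(vt / nt + vc / nc)
  z <- (mean(treatment_vals) - mean(control_vals)) / se
  p <- 2 * pnorm(-abs(z))
  direction <- if (p < alpha) { if (z > 0) "increase" else "decrease" } else "none"
  list(z = z, p = p, direction = direction, n_treatment = nt, n_control = nc)
}

#' Identify and quantify library compounds across treatments
#'
#' For each compound: match against the treatment's mean second-derivative
#' spectrum (75% threshold), quantify per-spectrum relative concentrations
#' at the characteristic peaks, and z-test the treatment against the
#' control.  Compounds not identified in a treatment get `NA` statistics
#' for it.  Uncertainty columns follow the 2-sigma convention of the
#' exported results.
#'
#' @param d2_by_treatment named list of `d2_map`s, one per treatment,
#'   including `"control"`.
#' @param library list of `compound_reference`s (default
#'   [builtin_library()]).
#' @param prominence peak-detection threshold.
#' @param alpha z-test significance level.
#' @return a `data.frame` with one row per treatment x compound: columns
#'   `treatment`, `compound`, `class`, `match_fraction`, `identified`,
#'   `rel_conc_mean`, `rel_conc_2sigma`, `z`, `p`, `direction`,
#'   `n_treatment`, `n_control`.
#' @export
identify_compounds <- function(d2_by_treatment, library = builtin_library(),
                               prominence = 0, alpha = 0.05) {
  if (!"control" %in% names(d2_by_treatment))
    stop("a 'control' d2 map is required as the z-test baseline")
  ctrl <- d2_by_treatment$control
  rows <- list()
  for (tr in names(d2_by_treatment)) {
    d2m <- d2_by_treatment[[tr]]
    for (ref in library) {
      m <- match_compound(mean_d2_spectrum(d2m), ref, prominence = prominence)
      row <- data.frame(treatment = tr, compound = ref$name,
                        class = ref$class,
                        match_fraction = m$match_fraction,
                        identified = m$identified,
                        rel_conc_mean = NA_real_, rel_conc_2sigma = NA_real_,
                        z = NA_real_, p = NA_real_,
                        direction = NA_character_,
                        n_treatment = nrow(d2m$d2),
                        n_control = nrow(ctrl$d2),
                        stringsAsFactors = FALSE)
      if (m$identified) {
        vals <- quantify_compound(d2m, ref, prominence = prominence,
                                  check_identified = FALSE)
        row$rel_conc_mean <- mean(vals)
        row$rel_conc_2sigma <- 2 * sd(vals)
        if (tr != "control") {
          cm <- match_compound(mean_d2_spectrum(ctrl), ref,
                               prominence = prominence)
          if (cm$identified) {
            cvals <- quantify_compound(ctrl, ref, prominence = prominence,
                                       check_identified = FALSE)
            zt <- ztest_vs_control(vals, cvals, alpha = alpha)
            row$z <- zt$z
            row$p <- zt$p
            row$direction <- zt$direction
          }
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
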
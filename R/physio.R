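# Osmotic-stress physiology: van 't Hoff solute potential, specific growth
# rates from OD660 time series, quadratic rate-vs-potential fits, and
# per-level isolate comparisons.

#' Solute potential from the van 't Hoff relation
#'
#' \eqn{\Psi_s = -iCRT}, with the pressure constant R in
#' L bar K^-1 mol^-1 so that \eqn{iCRT} is an osmotic pressure in bar; the
#' result is converted to megapascals (1 MPa = 10 bar).  For NaCl the
#' dissociation count i is 2.  The default temperature is 288.15 K (15 C,
#' the culture temperature this analysis targets).  At C = 0.75 mol/L NaCl
#' and 15 C this gives -3.6 MPa, the upper end of the 2--750 mM gradient.
#'
#' @param C solute concentration, mol/L (>= 0).
#' @param i dissociated particles per formula unit (2 for NaCl).
#' @param T_K absolute temperature, kelvin.
#' @param R pressure constant, L bar K^-1 mol^-1.
#' @return solute potential in MPa (<= 0).
#' @examples
#' solute_potential(0.75)          # -3.59 MPa
#' @export
solute_potential <- function(C, i = 2, T_K = 288.15, R = 0.0831) {
  if (any(C < 0)) stop("concentration must be >= 0")
  if (any(T_K <= 0)) stop("temperature must be positive kelvin")
  if (any(i < 1)) stop("dissociation count must be >= 1")
  -(i * C * R * T_K) / 10
}

#' Specific growth rate from an OD660 time series
#'
#' Finds the exponential phase as the sliding window (default 5 points) of
#' `log(od - od_floor)` versus time with the steepest least-squares slope;
#' that slope is the specific growth rate mu (per hour for hourly inputs).
#'
#' @param times time points, hours (>= 5).
#' @param od OD660 readings, positive after floor subtraction.
#' @param window_points sliding-window width in points.
#' @param od_floor detection floor subtracted before the log.
#' @return a `growth_fit`: `mu` (per hour), `window` = c(t_start, t_end),
#'   `r2` of the window's linear fit, `od_floor`.
#' @export
specific_growth_rate <- function(times, od, window_points = 5, od_floor = 0) {
  if (length(times) != length(od)) stop("times and od lengths differ")
  if (length(times) < 5L) stop("need at least 5 time points")
  if (window_points < 3L || window_points > length(times))
    stop("window_points must be between 3 and the series length")
  y <- od - od_floor
  if (any(y <= 0)) stop("nonpositive OD after floor subtraction")
  ly <- log(y)
  best <- list(mu = -Inf)
  for (s in seq_len(length(times) - window_points + 1L)) {
    idx <- s:(s + window_points - 1L)
    t <- times[idx]
    v <- ly[idx]
    tc <- t - mean(t)
    sxx <- sum(tc^2)
    slope <- sum(tc * v) / sxx
    fitted <- mean(v) + slope * tc
    sse <- sum((v - fitted)^2)
    sst <- sum((v - mean(v))^2)
    r2 <- if (sst > 0) 1 - sse / sst else 1
    if (slope > best$mu)
      best <- list(mu = slope, window = c(t[1L], t[length(t)]), r2 = r2)
  }
  if (!is.finite(best$mu)) stop("no finite growth-rate window found")
  structure(list(mu = best$mu,
                 window = best$window, r2 = max(0, min(1, best$r2)),
                 od_floor = od_floor),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> mu = %.4g / h over t = [%g, %g] h (R2 = %.3f)\n",
              x$mu, x$window[1L], x$window[2L], x$r2))
  invisible(x)
}

#' Quadratic fit of growth rate against solute potential
#'
#' Ordinary least-squares second-order polynomial
#' `rate ~ potential + potential^2`, the standard summary of how growth
#' declines along a solute-potential gradient.
#'
#' @param potentials solute potentials, MPa (>= 3 distinct values).
#' @param rates specific growth rates, per hour.
#' @return list with `coefficients` (intercept, linear, quadratic), `r2`,
#'   and the `lm` fit.
#' @export
rate_vs_potential_fit <- function(potentials, rates) {
  if (length(potentials) != length(rates)) stop("lengths differ")
  if (length(unique(potentials)) < 3L)
    stop("need at least 3 distinct potential values for a quadratic fit")
  fit <- lm(rates ~ potentials + I(potentials^2))
  co <- unname(coef(fit))
  list(coefficients = c(intercept = co[1L], linear = co[2L],
                        quadratic = co[3L]),
       r2 = suppressWarnings(summary(fit)$r.squared),
       fit = fit)
}

#' Compare two isolates' growth rates per potential level
#'
#' Welch's two-sample two-sided t-test at each shared potential level, with
#' a significance flag at `p < alpha`.
#'
#' @param rates_a,rates_b `data.frame`s with columns `potential` and
#'   `rate`; replicate rates per potential level (>= 2 per group per
#'   level).
#' @param alpha significance level.
#' @return `data.frame` with `potential`, `p`, `flag`.
#' @export
compare_isolates <- function(rates_a, rates_b, alpha = 0.05) {
  need <- c("potential", "rate")
  if (!all(need %in% names(rates_a)) || !all(need %in% names(rates_b)))
    stop("inputs need columns 'potential' and 'rate'")
  levels <- sort(intersect(unique(rates_a$potential), unique(rates_b$potential)))
  if (!length(levels)) stop("no shared potential levels")
  out <- lapply(levels, function(lv) {
    a <- rates_a$rate[rates_a$potential == lv]
    b <- rates_b$rate[rates_b$potential == lv]
    if (length(a) < 2L || length(b) < 2L)
      stop("need >= 2 replicates per group at potential ", lv)
    p <- if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) 1
         else t.test(a, b, var.equal = FALSE)$p.value
    data.frame(potential = lv, p = p, flag = p < alpha)
  })
  do.call(rbind, out)
}
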
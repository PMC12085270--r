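# shared fixtures: grids, bands, and the trace-metabolite scenario used by
# the recovery tests

h_fingerprint <- function() seq(900, 1800, by = 4)

# fingerprint grid extended so the QC noise window (1800-1900) exists
h_extended <- function() seq(900, 1900, by = 4)

h_gauss <- function(w, center, height, sigma)
  height * exp(-(w - center)^2 / (2 * sigma^2))

# analytic second derivative of a Gaussian band
h_gauss_d2 <- function(w, center, height, sigma)
  height * ((w - center)^2 / sigma^4 - 1 / sigma^2) *
    exp(-(w - center)^2 / (2 * sigma^2))

# biomass background (amide I, amide II, bulk carbohydrate) used by the
# group-structure scenarios
h_background <- function()
  list(band_shape(1655, 1.0, 12), band_shape(1545, 0.6, 10),
       band_shape(1035, 0.4, 14))

# two trace compounds over the biomass background; compound X doubled in
# the stress class, Y fixed
h_two_treatment_spec <- function(seed, n_per_class = 30) {
  X <- compound_reference("cmpdX", "osmolyte", c(1150, 1105))
  Y <- compound_reference("cmpdY", "general_stress", c(1250, 1220))
  conc <- rbind(control = c(0.02, 0.02), OS3 = c(0.04, 0.02))
  list(spec = scenario_spec(list(X, Y), conc, n_per_class = n_per_class,
                            background = h_background(), noise_sd = 0.01,
                            seed = seed),
       library = list(cmpdX = X, cmpdY = Y))
}

h_split_by_treatment <- function(map) {
  trs <- unique(map$meta$treatment)
  out <- lapply(trs, function(tr) subset_map(map, map$meta$treatment == tr))
  names(out) <- trs
  out
}
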
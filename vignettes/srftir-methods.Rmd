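---
title: "Methods: SR-FTIR chemometrics for microbial stress phenotyping"
author: "srftir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SR-FTIR chemometrics for microbial stress phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srftir)
```

# The measurement and the model

Synchrotron-radiation FTIR (SR-FTIR) spectromicroscopy raster-scans a
bacterial monolayer at a few-micron step and records, at every spot, a
mid-infrared absorbance spectrum (650--4000 cm^-1^ at 4 cm^-1^ nominal
resolution; each spot averages on the order of twenty cells).  Under the
Beer--Lambert law the absorbance at wavenumber $\omega$ is

$$A(\omega) = \alpha(\omega)\, I\, c,$$

with $\alpha$ the absorptivity, $I$ the pathlength and $c$ the
concentration of the absorbing species.  Differentiating twice in
$\omega$,

$$\frac{d^2 A}{d\omega^2} = \frac{d^2 \alpha}{d\omega^2}\, I\, c,$$

so the second derivative stays **linear in concentration** while constant
and linear baseline structure vanishes.  Absorbance bands appear in the
second derivative as *negative* lobes; the package quantifies the depth of
the negative lobe at a band center as a relative concentration proxy
(`d2_amplitude()`), comparable within one compound and instrument setting
but not across compounds (pathlength and absorptivity never separate).

Analysis is restricted to the 900--1800 cm^-1^ fingerprint region, which
carries the fatty-acid carbonyl (1680--1770), amide I (1600--1700), amide
II (1519--1544), phosphate $\nu PO_2^-$ (1200--1230) and carbohydrate
(1000--1300) bands (`band_regions()`).

# The preprocessing chain and its assumptions

The fixed order is: quality filter → EMSC → vector normalization → (a)
mean-centering and PC-LDA, (b) second derivative and quantitation.

**Quality filter.**  Spot spectra from non-monolayer regions or with poor
signal-to-noise are removed.  SNR is defined here as the amide I peak
height above a straight line through the 1600--1700 cm^-1^ window
endpoints, divided by the RMS of linearly detrended absorbance in the
signal-free 1800--1900 cm^-1^ window; the default threshold is 10.  Both
windows and the threshold are package conventions (configurable): upstream
practice for this instrument class is in-house and unpublished, so the rule
is a stated stand-in.  Because the noise window lies above the fingerprint
crop, `run_experiment()` applies QC on the *uncropped* grid before
cropping; QC is skipped (and logged) when a pre-cropped map lacks the
windows.

**EMSC.**  Scatter from imperfect monolayers distorts line shape
multiplicatively and adds smooth baseline.  The basic Kohler extended
multiplicative signal correction fits, by least squares,

$$A_{obs}(\omega) = \sum_{j=0}^{q} d_j P_j(\omega) + b\,R(\omega) + e(\omega),$$

with $P_j$ polynomial baseline terms (on $\omega$ rescaled to $[-1,1]$ for
conditioning), $R$ a reference spectrum and $b$ the scatter scale; the
corrected spectrum is $R + e/b$.  Defaults: polynomial order $q = 2$; the
reference is the mean control-treatment spectrum after QC, the standard
chemometric anchor that also serves as the z-test baseline.  No
wavelength-dependent (resonant Mie) extension is included.  The model is
exact on any input generated as polynomial-plus-scaled-reference: the test
suite verifies recovery of the reference to below 1e-8 over 100 seeded
distortion triples.  Degenerate fits ($|b|$ at machine scale, rank-deficient
design) raise errors rather than returning garbage.

**Vector normalization** divides each spectrum by its Euclidean norm over
the fingerprint region, removing residual overall-intensity differences
(cell density per spot).  It is a *closure* operation: increasing one
constituent necessarily depresses every other normalized band.  This
matters for interpretation — see the generator section.

**Mean-centering** precedes ordination only.

# Second-derivative spectroscopy

The derivative uses the 7-point, order-3 Savitzky--Golay filter, scaled by
the physical 4 cm^-1^ grid step, so output units are absorbance per
(cm^-1^)^2^.  The filter is exact on polynomials up to cubic (the
quadratic check holds at machine precision).  Two numerical choices:

* **Edges.**  The three points at each end have no full window.  They are
  filled by replicating the nearest interior value, flagged, and excluded
  from peak detection and quantitation; no curvature is fabricated at the
  boundaries.
* **Attenuation.**  A least-squares cubic over a 24 cm^-1^ footprint
  under-reads the curvature of bands that are narrow relative to the
  window: the curvature estimate at a Gaussian band center is attenuated by
  roughly 37% at $\sigma = 8$ cm^-1^ and 21% at $\sigma = 12$ cm^-1^,
  converging toward the analytic value only for much broader bands.  This
  is an inherent property of Savitzky--Golay differentiation (the package's
  filter agrees with independent implementations to all printed digits),
  not an implementation artifact.  It is why d2 amplitudes are *relative*
  concentrations: attenuation is constant for a fixed band shape and
  filter, so linearity in concentration — the property quantitation relies
  on — is preserved exactly, as the 1:2:3:4:5 linearity check (R^2^ >
  0.999) shows.

Peak detection reports negative local minima (strict on the left,
non-strict on the right, so plateaus count once) deeper than a prominence
threshold, at interior points only.

# Compound identification and significance

Each compound is represented by two or more characteristic peaks with
weights and a matching tolerance (default 8 cm^-1^ = two grid steps; the
instrument's much finer peak-position accuracy refers to calibration, not
biological band variation).  The match fraction is the weight share of
reference peaks with a detected minimum within tolerance; identification
requires **at least 75%**, read inclusively.  Quantitation is refused for
compounds not identified in the set's mean second-derivative spectrum.

Treatment-vs-control shifts use a two-sample unpooled z statistic

$$z = \frac{\bar x_t - \bar x_c}{\sqrt{s_t^2/n_t + s_c^2/n_c}},$$

two-sided against the standard normal, $\alpha = 0.05$, no
multiple-testing correction (matching reporting practice for this assay);
exports carry mean ± 2σ.  With group sizes near 20 the normal reference
makes the test slightly anticonservative (true null rejection ≈ 0.057);
the Monte-Carlo calibration check covers this.  The built-in library ships
ten compounds — storage polymers PHA, PHB, glycogen, polyphosphate;
osmolytes mannitol, ectoine, glycine betaine; general stress metabolites
trehalose, proline, glutamate — with peak positions curated from published
band assignments in an editable CSV; laboratories should substitute their
own reference second-derivative peak lists.

# PC-LDA ordination

Spectra are projected onto principal components (default: the smallest
number explaining ≥ 95% of variance, capped at $n - g$ for $g$ classes —
the cap keeps the within-class scatter invertible), then linear
discriminant axes are found from the generalized eigenproblem of
between-class versus within-class scatter, solved by Cholesky whitening
for numerical stability.  Per-axis "variance explained" is reported two
ways, because the denominator is genuinely ambiguous in common usage:
discriminant-eigenvalue fractions (the default) and the variance of each
LD score as a fraction of total data variance (`pc_axis_variance`).
Discriminant directions are back-projected through the PC loadings to
wavenumber space; each axis is oriented so its largest-magnitude spectral
loading is positive, making plots reproducible.  Cluster-vector spectra —
the displacement of each class centroid from the grand centroid,
reconstructed through the retained PCs — attribute separation to molecular
bands.  Separation is read visually (score plots) or by nearest-centroid
assignment; no permutation significance testing is attempted.

# Physiology calculations

Solute potential uses the van 't Hoff relation $\Psi_s = -iCRT$ with $R =
0.0831$ L·bar·K^-1^·mol^-1^ and the result converted to MPa.  The bar
interpretation of $R$ is deliberate: it is the only reading under which
the 2--750 mM NaCl design spans ~0 to −3.6 MPa at the 15 °C culture
temperature, so the package treats the gradient endpoint as the anchoring
worked example.  The per-treatment potential estimates quoted in the
design table (`treatment_design()`) are recorded as free-text metadata
only; they are not reproducible from the formula and are never used in
computation.

Specific growth rates are the steepest sliding-window slope (default 5
points) of log OD~660~ versus time — an operational definition of
"exponential phase" chosen because windowed log-linear fitting is
transparent, and exact on noiseless exponentials.  Rate-versus-potential
curves are summarized by an ordinary least-squares quadratic, and isolate
pairs are compared per potential level with Welch's two-sided t-test at
$\alpha = 0.05$.

# The synthetic-data generator

Real beamline maps for this assay are not redistributable at desk scale,
so validation runs on a generator that emulates the acquisition's
*statistical* structure: spectra are Beer--Lambert mixtures (compound band
signatures scaled by concentration, Gaussian or pseudo-Voigt shapes,
default $\sigma = 10$ cm^-1^) over an optional fixed biomass background,
corrupted by a uniform multiplicative scale (default 0.7--1.3), a random
polynomial baseline on the rescaled wavenumber, optional out-of-model
sinusoidal distortion, and white noise.  A single seeded stream with a
documented draw order makes every scenario bit-reproducible, down to
byte-identical CSV exports.  The scatter model matches the EMSC family on
purpose, so exact recovery at zero noise is a meaningful correctness
check; the sinusoidal term exists to probe behavior outside that family.

The end-to-end recovery scenario is built the way the assay is actually
used: trace metabolite signals (band heights a few percent of amide I)
riding on a dominant biomass background, with one compound doubled in the
stress class, 30 spectra per class, and white noise at 1% of the maximum
band.  The trace-over-background regime is a scientific choice, not a
convenience: because vector normalization is a closure, doubling a
*dominant* constituent would depress every other normalized band and
manufacture spurious "decreases"; trace constituents leave the norm —
hence the unchanged compounds — essentially untouched.  Users analyzing
compounds that dominate total absorbance should interpret directions of
change with compositional-data caution.

What the generator does *not* emulate: resonant Mie scattering, water-vapor
and CO~2~ rotational-vibrational interference, detector nonlinearity,
band-position shifts with chemical environment, and spatial correlation
between neighboring raster spots.  Passing tests therefore demonstrate the
correctness of the algorithms under the stated noise model, not robustness
to every artifact of real acquisitions.

Growth curves are logistic ($K = 1$ OD, $od_0 = 0.005$, hourly sampling
over 72 h) with multiplicative lognormal noise at 1%; $K = \infty$ yields
the exact exponential limit used for closed-form checks.

# Problem sizes and runtime choices

Validation suites run at deliberately modest sizes that keep every check
sharp: 100 seeded EMSC triples; 10,000 null replicates for z-test
calibration (n = 20 per group); 2,000 null levels for the Welch-test
calibration (n = 5); 100 end-to-end pipeline runs at 30 spectra per class
on the 900--1900 cm^-1^ grid (251 points); 100 seeded growth curves.  The
tiny 6×4 two-class matrix for the LDA oracle is solved against a dense
generalized-eigenproblem solution in the original variable space, which is
feasible exactly because the instance is small.

# Known limitations

* Relative quantitation only; no absolute calibration, no spectral
  unmixing or band deconvolution of overlapping mixtures.
* The shipped compound peak lists are literature-curated defaults, not
  instrument-specific reference spectra.
* The z-test is anticonservative at small n and uncorrected for multiple
  compounds; treat borderline p-values accordingly.
* Narrow-band curvature attenuation (above) caps the accuracy of absolute
  d2 values; all quantitative claims are linearity-based.
* QC criteria are a package convention standing in for unpublished
  in-house rules.
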
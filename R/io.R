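#' @importFrom stats approx lm median coef pnorm pt qnorm rnorm runif sd var
#'   prcomp t.test setNames aggregate
#' @importFrom utils read.csv write.csv head tail
NULL

# mid-IR acquisition range of the instrument, cm^-1
.WN_MIN <- 650
.WN_MAX <- 4000

#' Validate and canonicalize a wavenumber grid
#'
#' Wavenumber grids are plain numeric vectors in reciprocal centimeters
#' (cm^-1).  A valid grid is strictly monotonic (descending input is
#' reversed to the canonical ascending orientation), uniformly spaced to a
#' relative tolerance of 1e-6 (nominally 4 cm^-1 steps), and bounded within
#' the mid-infrared acquisition range 650--4000 cm^-1.
#'
#' @param wavenumber numeric vector of positions in cm^-1.
#' @return the canonical ascending numeric grid, with attribute `"step"`.
#' @examples
#' validate_wavenumbers(seq(900, 1800, by = 4))
#' @export
validate_wavenumbers <- function(wavenumber) {
  w <- as.numeric(wavenumber)
  if (length(w) < 2L) stop("a wavenumber grid needs at least 2 points")
  if (anyNA(w) || any(!is.finite(w))) stop("wavenumber grid contains non-finite values")
  d <- diff(w)
  if (all(d < 0)) {
    w <- rev(w)
    d <- diff(w)
  }
  if (any(d <= 0)) stop("wavenumber grid is not strictly monotonic")
  step <- median(d)
  if (any(abs(d - step) > 1e-6 * abs(step)))
    stop("wavenumber grid spacing is not uniform (relative tolerance 1e-6)")
  if (w[1L] < .WN_MIN - 1e-9 || w[length(w)] > .WN_MAX + 1e-9)
    stop(sprintf("wavenumber grid extends outside the mid-IR range %g-%g cm^-1",
                 .WN_MIN, .WN_MAX))
  attr(w, "step") <- step
  w
}

#' Single infrared absorbance spectrum
#'
#' @param wavenumber wavenumber grid, cm^-1 (see [validate_wavenumbers()]).
#' @param absorbance numeric absorbance (dimensionless), one value per grid
#'   point.
#' @param id spectrum identifier.
#' @param isolate,treatment metadata labels.
#' @param x_um,y_um raster position in micrometers.
#' @return an object of class `ir_spectrum`.
#' @export
ir_spectrum <- function(wavenumber, absorbance, id = "s1",
                        isolate = NA_character_, treatment = NA_character_,
                        x_um = NA_real_, y_um = NA_real_) {
  worig <- as.numeric(wavenumber)
  w <- validate_wavenumbers(worig)
  a <- as.numeric(absorbance)
  if (length(worig) >= 2L && worig[1L] > worig[length(worig)] &&
      length(a) == length(worig))
    a <- rev(a)                     # descending input reversed with its grid
  if (length(a) != length(w))
    stop("absorbance length (", length(a), ") does not match grid length (",
         length(w), ")")
  if (any(!is.finite(a))) stop("absorbance contains non-finite values")
  structure(list(wavenumber = as.numeric(w), absorbance = a, id = id,
                 isolate = isolate, treatment = treatment,
                 x_um = x_um, y_um = y_um),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum '%s'> %d points, %g-%g cm^-1", x$id,
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  if (!is.na(x$isolate) || !is.na(x$treatment))
    cat(sprintf(" [%s / %s]", x$isolate, x$treatment))
  cat("\n")
  invisible(x)
}

.default_meta <- function(ids, raster_step = 5) {
  data.frame(spectrum_id = ids,
             isolate = rep(NA_character_, length(ids)),
             treatment = rep(NA_character_, length(ids)),
             x_um = raster_step * (seq_along(ids) - 1),
             y_um = rep(0, length(ids)),
             stringsAsFactors = FALSE)
}

#' Raster map of spectra on a shared wavenumber grid
#'
#' A `spectral_map` stores a collection of absorbance spectra acquired on a
#' common grid, as a spectra-by-wavenumber matrix, together with a metadata
#' table (spectrum id, isolate, treatment, raster position).  Raster
#' positions default to a 5 micrometer step, the acquisition step of the
#' transflection maps this package targets.
#'
#' @param wavenumber shared grid, cm^-1.
#' @param absorbance numeric matrix, one row per spectrum, one column per
#'   grid point (a single vector is promoted to one row).
#' @param meta optional `data.frame` with columns `spectrum_id`, `isolate`,
#'   `treatment`, `x_um`, `y_um`; one row per spectrum.
#' @param raster_step nominal raster step in micrometers.
#' @return an object of class `spectral_map`.
#' @examples
#' m <- spectral_map(seq(900, 1800, 4), matrix(0, 2, 226))
#' n_spectra(m)
#' @export
spectral_map <- function(wavenumber, absorbance, meta = NULL, raster_step = 5) {
  worig <- as.numeric(wavenumber)
  w <- validate_wavenumbers(worig)
  if (is.null(dim(absorbance))) absorbance <- matrix(absorbance, nrow = 1L)
  absorbance <- as.matrix(absorbance)
  if (length(worig) >= 2L && worig[1L] > worig[length(worig)] &&
      ncol(absorbance) == length(worig))
    absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
  if (ncol(absorbance) != length(w))
    stop("absorbance has ", ncol(absorbance), " columns but the grid has ",
         length(w), " points")
  if (nrow(absorbance) > 0L && any(!is.finite(absorbance)))
    stop("absorbance contains non-finite values")
  if (is.null(meta)) {
    ids <- if (nrow(absorbance) > 0L) paste0("s", seq_len(nrow(absorbance))) else character(0)
    meta <- .default_meta(ids, raster_step)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "isolate", "treatment", "x_um", "y_um")
  for (nm in setdiff(need, names(meta))) meta[[nm]] <- if (nm %in% c("x_um", "y_um")) NA_real_ else NA_character_
  meta <- meta[, need]
  if (nrow(meta) != nrow(absorbance))
    stop("meta has ", nrow(meta), " rows but the map has ", nrow(absorbance),
         " spectra")
  if (anyDuplicated(meta$spectrum_id)) stop("duplicate spectrum_id in meta")
  pos <- paste(meta$x_um, meta$y_um)
  if (!anyNA(meta$x_um) && nrow(meta) > 0L && anyDuplicated(pos))
    stop("duplicate raster positions in meta")
  rownames(absorbance) <- meta$spectrum_id
  structure(list(wavenumber = as.numeric(w), absorbance = absorbance,
                 meta = meta, raster_step = raster_step),
            class = "spectral_map")
}

#' Number of spectra in a map
#' @param map a `spectral_map`.
#' @return integer count.
#' @export
n_spectra <- function(map) nrow(map$absorbance)

#' @export
print.spectral_map <- function(x, ...) {
  cat(sprintf("<spectral_map> %d spectra x %d wavenumbers (%g-%g cm^-1, step %g)\n",
              n_spectra(x), length(x$wavenumber), min(x$wavenumber),
              max(x$wavenumber), attr(validate_wavenumbers(x$wavenumber), "step")))
  tr <- unique(stats::na.omit(x$meta$treatment))
  if (length(tr)) cat("  treatments:", paste(tr, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one spectrum from a map
#' @param map a `spectral_map`.
#' @param i row index or spectrum id.
#' @return an `ir_spectrum`.
#' @export
map_spectrum <- function(map, i) {
  if (is.character(i)) i <- match(i, map$meta$spectrum_id)
  if (is.na(i) || i < 1L || i > n_spectra(map)) stop("no such spectrum in map")
  m <- map$meta[i, ]
  ir_spectrum(map$wavenumber, map$absorbance[i, ], id = m$spectrum_id,
              isolate = m$isolate, treatment = m$treatment,
              x_um = m$x_um, y_um = m$y_um)
}

#' Subset a spectral map by row
#' @param map a `spectral_map`.
#' @param keep logical or integer row selector.
#' @return a `spectral_map` with the selected spectra.
#' @export
subset_map <- function(map, keep) {
  spectral_map(map$wavenumber,
               map$absorbance[keep, , drop = FALSE],
               map$meta[keep, , drop = FALSE],
               raster_step = map$raster_step)
}

#' Restrict a map to a wavenumber window
#'
#' Returns the map restricted to grid points w with `lo <= w <= hi`, both
#' ends inclusive.  The canonical fingerprint crop for this analysis is
#' 900--1800 cm^-1.
#'
#' @param map a `spectral_map`.
#' @param lo,hi window bounds in cm^-1, `lo < hi`.
#' @return the cropped `spectral_map`.
#' @export
crop_region <- function(map, lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("crop bounds must satisfy lo < hi")
  sel <- map$wavenumber >= lo - 1e-9 & map$wavenumber <= hi + 1e-9
  if (sum(sel) < 2L)
    stop(sprintf("crop window [%g, %g] does not overlap the grid", lo, hi))
  spectral_map(map$wavenumber[sel], map$absorbance[, sel, drop = FALSE],
               map$meta, raster_step = map$raster_step)
}

#' Resample a map onto a new grid by linear interpolation
#'
#' Provided for aligning acquisitions made on different grids.  It is never
#' applied silently by any other function in this package: grid mismatches
#' always raise errors so that acquisition problems surface.
#'
#' @param map a `spectral_map`.
#' @param wavenumber target grid (must lie within the source grid's range).
#' @return resampled `spectral_map`.
#' @export
resample_to_grid <- function(map, wavenumber) {
  w <- validate_wavenumbers(wavenumber)
  if (w[1L] < map$wavenumber[1L] - 1e-9 ||
      w[length(w)] > map$wavenumber[length(map$wavenumber)] + 1e-9)
    stop("target grid requires extrapolation beyond the source grid")
  a <- t(apply(map$absorbance, 1L, function(y)
    approx(map$wavenumber, y, xout = as.numeric(w))$y))
  if (n_spectra(map) == 1L) a <- matrix(a, nrow = 1L)
  spectral_map(as.numeric(w), a, map$meta, raster_step = map$raster_step)
}

# ---------------------------------------------------------------------------
# readers / writers

.fmt9 <- function(x) sprintf("%.9g", x)

#' Read spectra from wide CSV or single-block JCAMP-DX
#'
#' The wide-CSV dialect is comma-separated UTF-8 with '.' decimals: a first
#' column named `wavenumber` followed by one numeric column per spectrum.
#' Metadata travels in an optional sidecar CSV with columns `spectrum_id`,
#' `isolate`, `treatment`, `x_um`, `y_um`.  JCAMP-DX support covers a single
#' `XYDATA=(X++(Y..Y))` block with AFFN numbers and linear X; descending
#' files are reversed to the canonical ascending grid.
#'
#' @param path file path.
#' @param format `"csv_wide"` or `"jcamp"`.
#' @param meta_path optional sidecar metadata CSV path (csv_wide only).
#' @return a `spectral_map`.
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, format = c("csv_wide", "jcamp"),
                         meta_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv_wide") .read_csv_wide(path, meta_path) else .read_jcamp(path)
}

.read_csv_wide <- function(path, meta_path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("wide CSV needs a wavenumber column plus at least one spectrum column")
  if (names(df)[1L] != "wavenumber")
    stop("first column must be named 'wavenumber', found '", names(df)[1L], "'")
  for (j in seq_len(ncol(df))) {
    v <- df[[j]]
    if (!is.numeric(v)) stop("column '", names(df)[j], "' is not numeric")
    if (anyNA(v)) stop("column '", names(df)[j], "' has missing values (ragged column?)")
  }
  w <- df[[1L]]
  a <- t(as.matrix(df[, -1L, drop = FALSE]))
  if (all(diff(w) < 0)) {           # canonicalize descending files
    w <- rev(w)
    a <- a[, rev(seq_len(ncol(a))), drop = FALSE]
  }
  meta <- NULL
  if (!is.null(meta_path)) {
    if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
    meta <- read.csv(meta_path, stringsAsFactors = FALSE)
    if (!"spectrum_id" %in% names(meta)) stop("metadata CSV lacks 'spectrum_id'")
    idx <- match(rownames(a), meta$spectrum_id)
    if (anyNA(idx)) stop("metadata CSV is missing ids: ",
                         paste(rownames(a)[is.na(idx)], collapse = ", "))
    meta <- meta[idx, ]
  } else {
    meta <- .default_meta(rownames(a))
  }
  spectral_map(w, a, meta)
}

.read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  data_start <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "##")) {
      kv <- sub("^##", "", ln)
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq < 0) next
      key <- toupper(gsub("[ -]", "", substr(kv, 1L, eq - 1L)))
      val <- trimws(substr(kv, eq + 1L, nchar(kv)))
      hdr[[key]] <- val
      if (key == "XYDATA") {
        if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", val))
          stop("unsupported XYDATA form '", val, "' (need (X++(Y..Y)))")
        data_start <- i + 1L
        break
      }
    }
  }
  if (is.na(data_start)) stop("no ##XYDATA block found in ", path)
  need <- c("FIRSTX", "DELTAX", "NPOINTS")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("JCAMP-DX header missing: ", paste(miss, collapse = ", "))
  firstx <- as.numeric(hdr$FIRSTX)
  deltax <- as.numeric(hdr$DELTAX)
  npts <- as.integer(hdr$NPOINTS)
  xf <- if (!is.null(hdr$XFACTOR)) as.numeric(hdr$XFACTOR) else 1
  yf <- if (!is.null(hdr$YFACTOR)) as.numeric(hdr$YFACTOR) else 1
  ys <- numeric(0)
  for (i in data_start:length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "##")) break
    if (!nzchar(ln)) next
    toks <- strsplit(ln, "[ \t,]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) stop("non-AFFN token on JCAMP-DX line ", i, ": '", ln, "'")
    ys <- c(ys, vals[-1L] * yf)     # first token is the line's X
  }
  if (length(ys) != npts)
    stop("JCAMP-DX NPOINTS=", npts, " but ", length(ys), " Y values read")
  w <- (firstx + deltax * (seq_len(npts) - 1L)) * xf
  title <- if (!is.null(hdr$TITLE)) hdr$TITLE else "jcamp"
  if (deltax < 0) { w <- rev(w); ys <- rev(ys) }
  spectral_map(w, matrix(ys, nrow = 1L),
               .default_meta(title))
}

#' Write spectra to wide CSV or single-block JCAMP-DX
#'
#' CSV output carries 9 significant digits, which makes the
#' write-then-read round trip byte-stable.  JCAMP-DX output writes one
#' spectrum per file as an AFFN `(X++(Y..Y))` block.
#'
#' @param map a `spectral_map`.
#' @param path output file path.
#' @param format `"csv_wide"` or `"jcamp"`.
#' @param meta_path optional path for the sidecar metadata CSV.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(map, path, format = c("csv_wide", "jcamp"),
                          meta_path = NULL) {
  format <- match.arg(format)
  if (format == "csv_wide") {
    cols <- c(list(wavenumber = .fmt9(map$wavenumber)),
              setNames(lapply(seq_len(n_spectra(map)),
                              function(i) .fmt9(map$absorbance[i, ])),
                       map$meta$spectrum_id))
    df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    if (!is.null(meta_path))
      write.csv(map$meta, meta_path, row.names = FALSE, quote = FALSE)
  } else {
    if (n_spectra(map) != 1L)
      stop("JCAMP-DX output writes a single-spectrum block; got ",
           n_spectra(map), " spectra")
    w <- map$wavenumber
    y <- map$absorbance[1L, ]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      paste0("##TITLE=", map$meta$spectrum_id[1L]),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=INFRARED SPECTRUM",
      "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
      "##XFACTOR=1", "##YFACTOR=1",
      paste0("##FIRSTX=", .fmt9(w[1L])),
      paste0("##LASTX=", .fmt9(w[length(w)])),
      paste0("##DELTAX=", .fmt9(attr(validate_wavenumbers(w), "step"))),
      paste0("##NPOINTS=", length(w)),
      "##XYDATA=(X++(Y..Y))"), con)
    per <- 6L
    for (k in seq(1L, length(w), by = per)) {
      idx <- k:min(k + per - 1L, length(w))
      writeLines(paste(.fmt9(w[k]), paste(.fmt9(y[idx]), collapse = " ")), con)
    }
    writeLines("##END=", con)
  }
  invisible(path)
}

#' Osmotic and matric stress treatment design
#'
#' Returns the six-treatment design used throughout: an unstressed control,
#' two matric-stress dry-downs (MS-H at 1/5-strength and MS-L at
#' 1/10-strength minimal media dried to half volume), and three osmotic
#' shocks (OS1 = 40 mM NaCl, OS2 = 40 mM then 80 mM sequentially,
#' OS3 = 80 mM).  The `psi_note` column records the study's printed
#' potential estimates verbatim as design metadata; they are not computed
#' from the solute-potential formula (see the methods vignette).
#'
#' @return a `data.frame` with one row per treatment.
#' @export
treatment_design <- function() {
  data.frame(
    name = c("control", "MS-L", "MS-H", "OS1", "OS2", "OS3"),
    nacl_step1_mol_l = c(0, 0, 0, 0.040, 0.040, 0.080),
    nacl_step2_mol_l = c(NA, NA, NA, NA, 0.080, NA),
    media_strength = c(1, 1 / 10, 1 / 5, 1, 1, 1),
    psi_note = c("~21 kPa attachment media",
                 "dry-down -120 to -550 kPa (printed estimate)",
                 "dry-down -220 to -820 kPa (printed estimate)",
                 "40 mM NaCl, printed estimate ~ -2.4 MPa",
                 "40 mM then 80 mM NaCl, sequential 20 min each",
                 "80 mM NaCl, printed estimate ~ -3.6 MPa"),
    stringsAsFactors = FALSE)
}
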
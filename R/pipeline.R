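# End-to-end orchestration: per isolate, a control map plus stress
# treatment maps are QC-filtered, EMSC-corrected against the control mean,
# vector normalized, then (a) mean-centered and ordinated by PC-LDA across
# treatments and (b) second-derivative transformed for compound
# identification, quantitation and z-tests against control.

# small deterministic FNV-1a hash of a deparsed R object; used to stamp
# outputs with the configuration they were produced under
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Validated parameter bundle for [run_experiment()].  Defaults follow the
#' package's analysis conventions: fingerprint crop 900--1800 cm^-1, SNR
#' threshold 10 with the amide I signal window and an 1800--1900 cm^-1
#' noise window, EMSC baseline order 2 with the control mean as reference,
#' 7-point order-3 Savitzky-Golay second derivative, 75% identification
#' threshold, alpha 0.05, and automatic PC count (95% variance, capped).
#'
#' @param crop fingerprint crop `c(lo, hi)`, cm^-1.
#' @param snr_threshold QC threshold (see [qc_filter()]).
#' @param qc_signal_window,qc_noise_window QC windows, cm^-1.
#' @param emsc_poly_order EMSC baseline polynomial order.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @param library compound library (list of `compound_reference`s).
#' @param prominence peak-detection depth threshold.
#' @param alpha z-test significance level.
#' @param n_pcs PC count for PC-LDA (`NULL` = automatic).
#' @param output_dir optional directory for CSV outputs.
#' @param seed integer seed recorded with the run.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(crop = c(900, 1800), snr_threshold = 10,
                            qc_signal_window = c(1600, 1700),
                            qc_noise_window = c(1800, 1900),
                            emsc_poly_order = 2,
                            sg_window = 7, sg_polyorder = 3,
                            library = builtin_library(),
                            prominence = 0, alpha = 0.05, n_pcs = NULL,
                            output_dir = NULL, seed = 1) {
  stopifnot(length(crop) == 2L, crop[1L] < crop[2L],
            snr_threshold >= 0, emsc_poly_order >= 0,
            sg_window %% 2 == 1, sg_polyorder < sg_window,
            alpha > 0, alpha < 1)
  cfg <- structure(list(crop = crop, snr_threshold = snr_threshold,
                        qc_signal_window = qc_signal_window,
                        qc_noise_window = qc_noise_window,
                        emsc_poly_order = emsc_poly_order,
                        sg_window = sg_window, sg_polyorder = sg_polyorder,
                        library = library, prominence = prominence,
                        alpha = alpha, n_pcs = n_pcs,
                        output_dir = output_dir, seed = as.integer(seed)),
                   class = "pipeline_config")
  cfg$hash <- .config_hash(cfg[setdiff(names(cfg), "output_dir")])
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config %s> crop %g-%g, SNR >= %g, EMSC order %d, SG %d/%d, alpha %g\n",
              x$hash, x$crop[1L], x$crop[2L], x$snr_threshold,
              x$emsc_poly_order, x$sg_window, x$sg_polyorder, x$alpha))
  invisible(x)
}

.stage <- function(log, name, t0, msg) {
  c(log, sprintf("[%s] %s (%.2fs)", name, msg,
                 as.numeric(Sys.time()) - t0))
}

#' Run the full per-isolate analysis
#'
#' Takes one spectral map per treatment (the `"control"` map is required:
#' it anchors both the EMSC reference and the z-test baseline) and
#' executes: QC (on the uncropped grid when it covers the QC windows, so
#' the signal-free noise window outside the fingerprint crop is usable)
#' -> crop -> EMSC against the control mean -> vector normalization ->
#' (a) mean-centering and PC-LDA across treatments, and (b) Savitzky-Golay
#' second derivative -> compound identification/quantitation -> z-tests
#' versus control.  CSV outputs (stamped with the config hash) are written
#' when `config$output_dir` is set.
#'
#' @param maps named list of `spectral_map`s keyed by treatment, including
#'   `"control"`.
#' @param config a `pipeline_config`.
#' @return an `experiment_result`: `qc` (reports per treatment),
#'   `preprocessed` (normalized maps), `ordination` (`pc_lda_fit`),
#'   `identification` (results `data.frame`), `config`, `log`.
#' @export
run_experiment <- function(maps, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  if (!"control" %in% names(maps))
    stop("a 'control' map is required (EMSC reference and z-test baseline)")
  log <- character(0)
  t0 <- as.numeric(Sys.time())

  # QC before cropping: the noise window generally lies above the crop
  qc <- list()
  for (tr in names(maps)) {
    m <- maps[[tr]]
    can_qc <- min(m$wavenumber) <= config$qc_signal_window[1L] + 1e-9 &&
      max(m$wavenumber) >= config$qc_noise_window[2L] - 1e-9
    if (can_qc) {
      res <- tryCatch(qc_filter(m, config$snr_threshold,
                                config$qc_signal_window,
                                config$qc_noise_window),
                      error = function(e)
                        stop("stage qc, treatment ", tr, ": ",
                             conditionMessage(e)))
      maps[[tr]] <- res$map
      qc[[tr]] <- res$report
      log <- .stage(log, "qc", t0, sprintf("%s: kept %d/%d", tr,
                                           res$report$n_kept,
                                           res$report$n_in))
    } else {
      qc[[tr]] <- NULL
      log <- .stage(log, "qc", t0,
                    sprintf("%s: skipped (grid lacks QC windows)", tr))
    }
    if (n_spectra(maps[[tr]]) < 2L)
      stop("stage qc, treatment ", tr, ": fewer than 2 spectra survive")
  }

  maps <- lapply(maps, crop_region, lo = config$crop[1L], hi = config$crop[2L])
  log <- .stage(log, "crop", t0, sprintf("restricted to %g-%g cm^-1",
                                         config$crop[1L], config$crop[2L]))

  reference <- mean_spectrum(maps$control, id = "control_mean")
  for (tr in names(maps)) {
    maps[[tr]] <- tryCatch(
      emsc_correct_map(maps[[tr]], reference, config$emsc_poly_order)$map,
      error = function(e) stop("stage emsc, treatment ", tr, ": ",
                               conditionMessage(e)))
  }
  log <- .stage(log, "emsc", t0, sprintf("corrected against control mean (order %d)",
                                         config$emsc_poly_order))

  maps <- lapply(maps, vector_normalize, region = config$crop)
  log <- .stage(log, "normalize", t0, "vector normalized over the crop")

  # (a) ordination branch
  X <- do.call(rbind, lapply(maps, function(m) m$absorbance))
  labels <- unlist(lapply(names(maps), function(tr)
    rep(tr, n_spectra(maps[[tr]]))), use.names = FALSE)
  ord <- tryCatch(
    fit_pc_lda(X, labels, n_pcs = config$n_pcs,
               wavenumber = maps$control$wavenumber),
    error = function(e) stop("stage ordination: ", conditionMessage(e)))
  log <- .stage(log, "ordination", t0,
                sprintf("%d spectra, %d PCs, LD1 %.0f%%", nrow(X),
                        ord$n_pcs_used, 100 * ord$axis_variance[1L]))

  # (b) quantitation branch
  d2 <- lapply(maps, savgol_second_derivative,
               window = config$sg_window, polyorder = config$sg_polyorder)
  ident <- tryCatch(
    identify_compounds(d2, library = config$library,
                       prominence = config$prominence, alpha = config$alpha),
    error = function(e) stop("stage identification: ", conditionMessage(e)))
  log <- .stage(log, "identification", t0,
                sprintf("%d compound x treatment rows", nrow(ident)))

  result <- structure(list(qc = qc, preprocessed = maps, ordination = ord,
                           identification = ident, config = config,
                           log = log),
                      class = "experiment_result")
  if (!is.null(config$output_dir)) .write_bundle(result)
  result
}

.write_bundle <- function(result) {
  dir.create(result$config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(df) {
    df$config_hash <- result$config$hash
    df
  }
  outd <- result$config$output_dir
  write.csv(stamp(result$identification),
            file.path(outd, "identification.csv"), row.names = FALSE)
  sc <- data.frame(spectrum_id = unlist(lapply(result$preprocessed,
                                               function(m) m$meta$spectrum_id),
                                        use.names = FALSE),
                   treatment = result$ordination$labels,
                   result$ordination$scores)
  write.csv(stamp(sc), file.path(outd, "scores.csv"), row.names = FALSE)
  av <- data.frame(axis = colnames(result$ordination$scores),
                   discriminant_variance = result$ordination$axis_variance,
                   pca_variance = result$ordination$pc_axis_variance)
  write.csv(stamp(av), file.path(outd, "axis_variance.csv"), row.names = FALSE)
  ld <- data.frame(wavenumber = result$preprocessed$control$wavenumber,
                   result$ordination$loadings_spectral)
  write.csv(stamp(ld), file.path(outd, "loadings.csv"), row.names = FALSE)
  cv <- data.frame(class = rownames(result$ordination$cluster_vectors),
                   result$ordination$cluster_vectors)
  write.csv(stamp(cv), file.path(outd, "cluster_vectors.csv"),
            row.names = FALSE)
  qc <- do.call(rbind, lapply(names(result$qc), function(tr) {
    r <- result$qc[[tr]]
    if (is.null(r)) return(NULL)
    data.frame(treatment = tr, spectrum_id = names(r$snr), snr = r$snr,
               threshold = r$threshold, kept = r$snr >= r$threshold)
  }))
  if (!is.null(qc))
    write.csv(stamp(qc), file.path(outd, "qc_report.csv"), row.names = FALSE)
  writeLines(c(sprintf("config_hash %s  seed %d", result$config$hash,
                       result$config$seed), result$log),
             file.path(outd, "run_log.txt"))
  invisible(NULL)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result %s> %d treatments, %d spectra; LD1 %.0f%% discriminant variance\n",
              x$config$hash, length(x$preprocessed),
              length(x$ordination$labels),
              100 * x$ordination$axis_variance[1L]))
  sig <- x$identification
  sig <- sig[!is.na(sig$direction) & sig$direction != "none", ]
  if (nrow(sig))
    cat("  significant shifts vs control:",
        paste(sprintf("%s[%s:%s]", sig$compound, sig$treatment,
                      sig$direction), collapse = ", "), "\n")
  invisible(x)
}
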
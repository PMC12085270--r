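# PC-LDA ordination of preprocessed spectra: PCA for dimension reduction,
# then linear discriminant analysis solved as the generalized eigenproblem
# of between-class versus within-class scatter in PC-score space, with
# discriminant directions back-projected to wavenumber space.

#' Principal component analysis of a spectra matrix
#'
#' Thin wrapper over [stats::prcomp()] returning scores, orthonormal
#' loadings and explained-variance fractions in this package's conventions.
#' Centering happens internally (pass an already-centered matrix from
#' [mean_center()] if column means should be reused elsewhere).
#'
#' @param x numeric matrix, spectra in rows.
#' @param n_components number of components to keep (default: all,
#'   `min(nrow - 1, ncol)`).
#' @return a `pca_fit`: `scores` (n x k), `loadings` (p x k, orthonormal
#'   columns), `explained_variance` (fractions of total variance, all
#'   components), `center` (column means), `n_components`.
#' @export
fit_pca <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least 2 spectra")
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- kmax
  if (n_components < 1L || n_components > kmax)
    stop("n_components must be between 1 and min(nrow - 1, ncol) = ", kmax)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev / sum(ev)
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
                 explained_variance = ev,
                 center = pc$center,
                 n_components = n_components,
                 .full = pc),
            class = "pca_fit")
}

#' @export
print.pca_fit <- function(x, ...) {
  cat(sprintf("<pca_fit> %d components; first explains %.1f%% of variance\n",
              x$n_components, 100 * x$explained_variance[1L]))
  invisible(x)
}

.n_pcs_default <- function(explained_variance, n, n_classes,
                           var_target = 0.95) {
  k <- which(cumsum(explained_variance) >= var_target - 1e-12)[1L]
  if (is.na(k)) k <- length(explained_variance)
  max(min(k, n - n_classes), n_classes - 1L)
}

#' PC-LDA ordination of labeled spectra
#'
#' Principal components analysis followed by linear discriminant analysis:
#' spectra are projected onto `n_pcs` principal components, and the
#' between-class versus within-class scatter generalized eigenproblem is
#' solved there (by Cholesky whitening of the within-class scatter).
#' Discriminant axes are back-projected through the PC loadings to
#' wavenumber space, and each axis is oriented so its largest-magnitude
#' spectral loading is positive.
#'
#' By default `n_pcs` is the smallest number of PCs explaining at least 95%
#' of the variance, capped at `n - n_classes` (and at least
#' `n_classes - 1`).
#'
#' @param x numeric matrix of preprocessed spectra (rows) by wavenumber
#'   (columns).
#' @param labels class label per spectrum (>= 2 classes, each with >= 2
#'   members).
#' @param n_pcs number of principal components retained before LDA.
#' @param wavenumber optional grid for labeling spectral loadings.
#' @return a `pc_lda_fit`: `scores` (n x a), `axis_variance`
#'   (discriminant-eigenvalue fractions), `pc_axis_variance` (the
#'   PCA-variance alternative: variance of each LD score over total data
#'   variance), `loadings_spectral` (p x a), `cluster_vectors`
#'   (class x p), `eigenvalues`, `labels`, `n_pcs_used`, plus the
#'   internal PCA fit and discriminant weights used by [predict_pc_lda()].
#' @export
fit_pc_lda <- function(x, labels, n_pcs = NULL, wavenumber = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("one label per spectrum required")
  cls <- unique(labels)
  counts <- table(labels)
  if (length(cls) < 2L) stop("PC-LDA needs at least 2 classes")
  if (any(counts < 2L))
    stop("every class needs >= 2 spectra; offending: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  pca <- fit_pca(x)
  if (is.null(n_pcs))
    n_pcs <- .n_pcs_default(pca$explained_variance, nrow(x), length(cls))
  if (n_pcs < length(cls) - 1L)
    stop("n_pcs must be at least n_classes - 1 = ", length(cls) - 1L)
  if (n_pcs > pca$n_components)
    stop("n_pcs exceeds the available ", pca$n_components, " components")
  T <- pca$scores[, seq_len(n_pcs), drop = FALSE]

  grand <- colMeans(T)
  Sw <- matrix(0, n_pcs, n_pcs)
  Sb <- matrix(0, n_pcs, n_pcs)
  for (g in cls) {
    Tg <- T[labels == g, , drop = FALSE]
    mg <- colMeans(Tg)
    Cg <- sweep(Tg, 2L, mg)
    Sw <- Sw + crossprod(Cg)
    d <- mg - grand
    Sb <- Sb + nrow(Tg) * tcrossprod(d)
  }
  R <- tryCatch(chol(Sw), error = function(e)
    stop("within-class scatter is singular after PC truncation; reduce n_pcs"))
  Ri <- backsolve(R, diag(n_pcs))
  M <- t(Ri) %*% Sb %*% Ri
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_axes <- min(length(cls) - 1L, n_pcs)
  lambda <- pmax(eg$values, 0)
  W <- Ri %*% eg$vectors[, seq_len(n_axes), drop = FALSE]

  loadings_spectral <- pca$loadings[, seq_len(n_pcs), drop = FALSE] %*% W
  # orient each axis: largest |spectral loading| positive
  for (a in seq_len(n_axes)) {
    j <- which.max(abs(loadings_spectral[, a]))
    if (loadings_spectral[j, a] < 0) {
      loadings_spectral[, a] <- -loadings_spectral[, a]
      W[, a] <- -W[, a]
    }
  }
  scores <- T %*% W
  colnames(scores) <- colnames(loadings_spectral) <- paste0("LD", seq_len(n_axes))
  if (!is.null(wavenumber)) rownames(loadings_spectral) <- signif(wavenumber, 8)

  tot_lambda <- sum(lambda[seq_len(n_axes)])
  axis_variance <- if (tot_lambda > 0) lambda[seq_len(n_axes)] / tot_lambda
                   else rep(0, n_axes)
  total_var <- sum(apply(x, 2L, var))
  pc_axis_variance <- apply(scores, 2L, var) / max(total_var, .Machine$double.eps)

  cv <- .cluster_vectors(pca, n_pcs, T, labels, cls)
  structure(list(scores = scores, axis_variance = axis_variance,
                 pc_axis_variance = pc_axis_variance,
                 loadings_spectral = loadings_spectral,
                 cluster_vectors = cv,
                 eigenvalues = lambda[seq_len(n_axes)],
                 labels = labels, n_pcs_used = n_pcs,
                 pca = pca, W = W, wavenumber = wavenumber),
            class = "pc_lda_fit")
}

.cluster_vectors <- function(pca, n_pcs, T, labels, cls) {
  grand <- colMeans(T)
  L <- pca$loadings[, seq_len(n_pcs), drop = FALSE]
  cv <- t(vapply(cls, function(g) {
    d <- colMeans(T[labels == g, , drop = FALSE]) - grand
    as.numeric(L %*% d)
  }, numeric(nrow(L))))
  rownames(cv) <- cls
  cv
}

#' @export
print.pc_lda_fit <- function(x, ...) {
  cat(sprintf("<pc_lda_fit> %d classes, %d PCs, %d LD axes; LD1 %.1f%% / LD2 %s of discriminant variance\n",
              length(unique(x$labels)), x$n_pcs_used, ncol(x$scores),
              100 * x$axis_variance[1L],
              if (length(x$axis_variance) > 1L)
                sprintf("%.1f%%", 100 * x$axis_variance[2L]) else "-"))
  invisible(x)
}

#' Cluster-vector spectra of a fitted ordination
#'
#' For each class, the vector from the grand centroid to the class centroid
#' in retained-PC space, back-projected to wavenumber space.  Its
#' largest-magnitude entries point at the molecular bands that displace the
#' class from the ensemble mean.
#'
#' @param fit a `pc_lda_fit`.
#' @param x the same preprocessed spectra matrix the fit was made on.
#' @param labels the same labels (checked against the fit).
#' @return matrix, classes x wavenumber.
#' @export
cluster_vector_spectra <- function(fit, x, labels = fit$labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (!identical(labels, fit$labels))
    stop("labels do not match the fitted ordination")
  if (nrow(x) != length(labels)) stop("row/label count mismatch")
  xc <- sweep(x, 2L, fit$pca$center)
  T <- xc %*% fit$pca$loadings[, seq_len(fit$n_pcs_used), drop = FALSE]
  .cluster_vectors(fit$pca, fit$n_pcs_used, T, labels, unique(labels))
}

#' Classify spectra by nearest class centroid in LD space
#'
#' @param fit a `pc_lda_fit`.
#' @param newdata spectra matrix on the same wavenumber columns.
#' @return character vector of predicted class labels.
#' @export
predict_pc_lda <- function(fit, newdata) {
  newdata <- as.matrix(newdata)
  xc <- sweep(newdata, 2L, fit$pca$center)
  T <- xc %*% fit$pca$loadings[, seq_len(fit$n_pcs_used), drop = FALSE]
  s <- T %*% fit$W
  cls <- unique(fit$labels)
  cent <- vapply(cls, function(g)
    colMeans(fit$scores[fit$labels == g, , drop = FALSE]), numeric(ncol(s)))
  cent <- t(matrix(cent, nrow = ncol(s)))   # classes x axes, even for 1 axis
  d2 <- outer(rowSums(s^2), rep(1, nrow(cent))) -
    2 * s %*% t(cent) + outer(rep(1, nrow(s)), rowSums(cent^2))
  cls[apply(d2, 1L, which.min)]
}

#' Score plot of a PC-LDA ordination
#'
#' @param x a `pc_lda_fit`.
#' @param axes which two discriminant axes to draw.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.pc_lda_fit <- function(x, axes = c(1, 2), ...) {
  s <- x$scores
  if (ncol(s) == 1L) s <- cbind(s, 0)
  cls <- factor(x$labels)
  graphics::plot(s[, axes[1L]], s[, axes[2L]], col = as.integer(cls),
                 pch = as.integer(cls),
                 xlab = sprintf("LD%d (%.0f%%)", axes[1L],
                                100 * x$axis_variance[axes[1L]]),
                 ylab = if (ncol(x$scores) > 1L)
                   sprintf("LD%d (%.0f%%)", axes[2L],
                           100 * x$axis_variance[axes[2L]]) else "",
                 ...)
  graphics::legend("topright", legend = levels(cls),
                   col = seq_along(levels(cls)), pch = seq_along(levels(cls)),
                   bty = "n")
  invisible(x)
}
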
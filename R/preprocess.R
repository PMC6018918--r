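#' Trim leading volumes
#'
#' Removes the first `n_trim` volumes of a BOLD run, the standard guard
#' against T1 equilibration effects at the start of an acquisition (20
#' volumes at the default study settings).
#'
#' @param series A [bold_series()].
#' @param n_trim Number of leading volumes to drop (`0 <= n_trim < t`).
#' @return A [bold_series()] with `t - n_trim` timepoints; the retained
#'   volumes are bit-identical to the input.
#' @export
trim_volumes <- function(series, n_trim) {
  stopifnot(inherits(series, "bold_series"))
  n_trim <- as.integer(n_trim)
  nt <- n_timepoints(series)
  if (n_trim < 0L || n_trim >= nt) {
    stop(sprintf("`n_trim` must lie in [0, %d); got %d", nt, n_trim),
         call. = FALSE)
  }
  if (n_trim == 0L) return(series)
  series$data <- series$data[, , , (n_trim + 1L):nt, drop = FALSE]
  series
}

#' Despike voxel time series
#'
#' Per voxel: fit a quadratic trend, express residuals in robust SD units
#' (1.4826 x MAD), and hyperbolically compress residuals beyond `c1` robust
#' SDs toward a hard cap of `c2`:
#' `s' = c1 + (c2 - c1) * tanh((|s| - c1) / (c2 - c1))` (sign preserved).
#' Residuals below `c1` and voxels with zero robust SD pass through
#' unchanged. Only in-mask voxels are touched.
#'
#' @param series A [bold_series()] with at least 8 timepoints.
#' @param c1 Compression onset, robust SDs (default 2.5).
#' @param c2 Cap, robust SDs (default 4).
#' @return A despiked [bold_series()].
#' @export
despike <- function(series, c1 = 2.5, c2 = 4) {
  stopifnot(inherits(series, "bold_series"))
  nt <- n_timepoints(series)
  if (nt < 8L) stop("despiking needs at least 8 timepoints", call. = FALSE)
  if (!(c2 > c1 && c1 > 0)) stop("need 0 < c1 < c2", call. = FALSE)
  y <- series_matrix(series)
  vox <- attr(y, "voxels")
  tt <- seq_len(nt)
  basis <- cbind(1, tt - mean(tt), (tt - mean(tt))^2)
  qb <- qr(basis)
  fit <- qr.fitted(qb, y)
  res <- y - fit
  sigma <- apply(res, 2, stats::mad)
  active <- sigma > 0
  if (any(active)) {
    s <- sweep(res[, active, drop = FALSE], 2, sigma[active], `/`)
    a <- abs(s)
    over <- a > c1
    a2 <- a
    a2[over] <- c1 + (c2 - c1) * tanh((a[over] - c1) / (c2 - c1))
    s_new <- sign(s) * a2
    res[, active] <- sweep(s_new, 2, sigma[active], `*`)
  }
  replace_series(series, fit + res, vox)
}

#' Nuisance regressor set
#'
#' Bundles the ventricular reference signal and the six motion traces that
#' are regressed out of every voxel time series, matching the run length
#' after trimming.
#'
#' @param motion t x 6 numeric matrix of motion parameters.
#' @param ventricular Length-t numeric vector (mean ventricular signal), or
#'   `NULL` to omit.
#' @param include_intercept Always augment the design with an intercept
#'   (default `TRUE`; downstream correlation is mean-invariant).
#' @return An object of class `nuisance_set`.
#' @export
nuisance_set <- function(motion, ventricular = NULL, include_intercept = TRUE) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("`motion` must have 6 columns", call. = FALSE)
  if (!is.null(ventricular) && length(ventricular) != nrow(motion)) {
    stop("`ventricular` length must match motion rows", call. = FALSE)
  }
  structure(
    list(motion = motion, ventricular = ventricular,
         include_intercept = isTRUE(include_intercept)),
    class = "nuisance_set"
  )
}

nuisance_design <- function(nuisance, nt) {
  cols <- list()
  if (nuisance$include_intercept) cols$intercept <- rep(1, nt)
  if (!is.null(nuisance$ventricular)) cols$ventricular <- nuisance$ventricular
  for (j in 1:6) cols[[paste0("motion", j)]] <- nuisance$motion[, j]
  X <- do.call(cbind, cols)
  if (nrow(X) != nt) {
    stop(sprintf("nuisance rows (%d) must match timepoints (%d)",
                 nrow(X), nt), call. = FALSE)
  }
  X
}

#' Regress nuisance signals out of every voxel
#'
#' Replaces each in-mask voxel time series with its least-squares residual
#' against the design `[intercept | ventricular | motion]`. Residuals are
#' orthogonal to every design column by construction.
#'
#' @param series A [bold_series()].
#' @param nuisance A [nuisance_set()] with rows matching `t`.
#' @return A [bold_series()] of residuals (in-mask voxels; others
#'   untouched).
#' @export
regress_nuisance <- function(series, nuisance) {
  stopifnot(inherits(series, "bold_series"), inherits(nuisance, "nuisance_set"))
  nt <- n_timepoints(series)
  X <- nuisance_design(nuisance, nt)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop(sprintf("nuisance design is rank-deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  y <- series_matrix(series)
  vox <- attr(y, "voxels")
  res <- qr.resid(qx, y)
  replace_series(series, res, vox)
}

# normalized 1D Gaussian kernel in voxel units; sigma 0 -> identity kernel
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 1e-8) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# zero-padded separable convolution of a 3D array along one axis
conv_axis <- function(vol, kernel, axis) {
  if (length(kernel) == 1L) return(vol * kernel)
  d <- dim(vol)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  dp <- dim(v)
  m <- matrix(v, dp[1], dp[2] * dp[3])
  r <- (length(kernel) - 1L) / 2L
  padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  out <- matrix(0, dp[1], ncol(m))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * padded[j:(j + dp[1] - 1L), , drop = FALSE]
  }
  v <- array(out, dp)
  aperm(v, order(perm))
}

conv3d <- function(vol, kernels) {
  for (ax in 1:3) vol <- conv_axis(vol, kernels[[ax]], ax)
  vol
}

#' Masked spatial Gaussian smoothing
#'
#' Smooths each volume with a separable Gaussian of the given full width at
#' half maximum (`sigma_mm = fwhm / (2 * sqrt(2 * log(2)))`, converted to
#' voxel units per axis). Smoothing is mask-normalized: values outside the
#' brain mask contribute nothing, and in-mask values are renormalized by
#' the smoothed mask, so a constant field stays constant and out-of-mask
#' voxels are never modified.
#'
#' @param series A [bold_series()].
#' @param fwhm_mm Full width at half maximum in mm (>= 0; 0 = identity;
#'   default 0.6, the study's kernel).
#' @return A smoothed [bold_series()].
#' @export
smooth_spatial <- function(series, fwhm_mm = 0.6) {
  stopifnot(inherits(series, "bold_series"))
  if (fwhm_mm < 0) stop("`fwhm_mm` must be nonnegative", call. = FALSE)
  if (fwhm_mm == 0) return(series)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  kernels <- lapply(1:3, function(ax) {
    gaussian_kernel_1d(sigma_mm / series$voxel_size_mm[ax])
  })
  mask <- series$brain_mask
  w <- conv3d(array(as.numeric(mask), dim(mask)), kernels)
  nt <- n_timepoints(series)
  out <- series$data
  for (t in seq_len(nt)) {
    vt <- out[, , , t]
    num <- conv3d(vt * mask, kernels)
    sm <- vt
    sm[mask] <- num[mask] / w[mask]
    out[, , , t] <- sm
  }
  series$data <- out
  series
}

# odd-reflection padded forward-backward Butterworth
filtfilt_padded <- function(filt, x, padlen) {
  n <- length(x)
  p <- min(padlen, n - 1L)
  if (p > 0) {
    pre <- 2 * x[1] - x[(p + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - p)]
    y <- signal::filtfilt(filt, c(pre, x, post))
    y[(p + 1):(p + n)]
  } else {
    signal::filtfilt(filt, x)
  }
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering of every in-mask
#' voxel within `[low_hz, high_hz]` (default 0.01-0.1 Hz, the study's
#' window). The voxel mean (DC) is removed; output series are zero-mean.
#'
#' @param series A [bold_series()].
#' @param low_hz,high_hz Passband edges in Hz;
#'   `0 <= low_hz < high_hz < 1 / (2 * tr)`.
#' @param order Butterworth order of the underlying one-pass filter
#'   (default 2).
#' @return A filtered [bold_series()].
#' @export
bandpass_filter <- function(series, low_hz = 0.01, high_hz = 0.1, order = 2) {
  stopifnot(inherits(series, "bold_series"))
  nyq <- 1 / (2 * series$tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz)) {
    stop("need 0 <= low_hz < high_hz", call. = FALSE)
  }
  if (high_hz >= nyq) {
    stop(sprintf("`high_hz` (%.4g Hz) must be below Nyquist (%.4g Hz at TR %.3g s)",
                 high_hz, nyq, series$tr_seconds), call. = FALSE)
  }
  bf <- if (low_hz > 0) {
    signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  } else {
    signal::butter(order, high_hz / nyq, type = "low")
  }
  y <- series_matrix(series)
  vox <- attr(y, "voxels")
  nt <- nrow(y)
  padlen <- min(nt - 1L, 3L * (2L * order + 1L) * 3L)
  out <- y
  for (j in seq_len(ncol(y))) {
    v <- y[, j]
    out[, j] <- filtfilt_padded(bf, v - mean(v), padlen)
  }
  replace_series(series, out, vox)
}

#' Fluctuation amplitude of an ROI
#'
#' Temporal standard deviation of the ROI-mean band-passed signal — the
#' quality-control readout used to verify comparable anesthesia depth
#' across groups (cortical BOLD fluctuation amplitude).
#'
#' @param series A (band-passed) [bold_series()].
#' @param roi_mask 3D logical ROI; intersected with the brain mask.
#' @return Nonnegative scalar.
#' @export
fluctuation_amplitude <- function(series, roi_mask) {
  stopifnot(inherits(series, "bold_series"))
  m <- roi_mask & series$brain_mask
  if (!any(m)) stop("ROI does not intersect the brain mask", call. = FALSE)
  stats::sd(mean_signal(series, m))
}

#' Full preprocessing pipeline
#'
#' Applies the study's stages in their fixed order: trim leading volumes,
#' despike, regress nuisance signals (intercept + ventricular mean + six
#' motion traces), masked spatial smoothing, zero-phase band-pass. Motion
#' traces are supplied per acquired volume; the first `n_trim` rows are
#' dropped alongside the trimmed volumes and the ventricular signal is
#' extracted after despiking.
#'
#' @param series A raw [bold_series()].
#' @param motion t x 6 motion-trace matrix (one row per acquired volume).
#' @param ventricle_mask 3D logical ventricular reference mask, or `NULL`
#'   to skip the ventricular regressor.
#' @param n_trim Leading volumes to drop (default 20).
#' @param despike_c1,despike_c2 Despiking constants (robust SDs).
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 0.6).
#' @param band_hz Passband in Hz (default `c(0.01, 0.1)`).
#' @return A preprocessed [bold_series()].
#' @export
preprocess_bold <- function(series, motion, ventricle_mask = NULL,
                            n_trim = 20, despike_c1 = 2.5, despike_c2 = 4,
                            fwhm_mm = 0.6, band_hz = c(0.01, 0.1)) {
  stopifnot(inherits(series, "bold_series"))
  motion <- as.matrix(motion)
  if (nrow(motion) != n_timepoints(series)) {
    stop("`motion` must have one row per acquired volume", call. = FALSE)
  }
  out <- trim_volumes(series, n_trim)
  motion <- motion[(n_trim + 1):nrow(motion), , drop = FALSE]
  out <- despike(out, c1 = despike_c1, c2 = despike_c2)
  vent <- if (!is.null(ventricle_mask)) mean_signal(out, ventricle_mask) else NULL
  out <- regress_nuisance(out, nuisance_set(motion, ventricular = vent))
  out <- smooth_spatial(out, fwhm_mm = fwhm_mm)
  bandpass_filter(out, low_hz = band_hz[1], high_hz = band_hz[2])
}
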
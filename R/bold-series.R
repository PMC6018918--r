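#' BOLD time-series container
#'
#' Wraps one subject's 4D blood-oxygen-level-dependent (BOLD) signal grid
#' together with its acquisition geometry: the repetition time (TR, the
#' sampling interval of the time series), the physical voxel dimensions, and
#' a brain mask restricting which voxels carry signal. Every preprocessing
#' stage takes and returns one of these.
#'
#' @param data 4D numeric array `(x, y, z, t)`, arbitrary signal units.
#' @param tr_seconds Repetition time in seconds (> 0).
#' @param voxel_size_mm Numeric length-3, physical voxel edge lengths in mm.
#' @param brain_mask 3D logical array matching the spatial grid, or `NULL`
#'   for an all-`TRUE` mask.
#'
#' @return An object of class `bold_series`.
#' @export
#' @examples
#' b <- bold_series(array(rnorm(4 * 4 * 2 * 30), c(4, 4, 2, 30)), tr_seconds = 1.2)
#' b
bold_series <- function(data, tr_seconds, voxel_size_mm = c(1, 1, 1),
                        brain_mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    stop("`data` must be a 4D array (x, y, z, t)", call. = FALSE)
  }
  if (dim(data)[4] < 2L) {
    stop("a BOLD series needs at least 2 timepoints", call. = FALSE)
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop("`tr_seconds` must be a single positive number", call. = FALSE)
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop("`voxel_size_mm` must be 3 positive numbers", call. = FALSE)
  }
  spatial <- dim(data)[1:3]
  if (is.null(brain_mask)) {
    brain_mask <- array(TRUE, spatial)
  }
  if (!identical(as.integer(dim(brain_mask)), as.integer(spatial))) {
    stop("`brain_mask` shape must equal the spatial grid of `data`",
         call. = FALSE)
  }
  structure(
    list(
      data = data,
      tr_seconds = tr_seconds,
      voxel_size_mm = voxel_size_mm,
      brain_mask = array(as.logical(brain_mask), spatial)
    ),
    class = "bold_series"
  )
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<bold_series> %d x %d x %d voxels, %d timepoints (TR %.3g s)\n",
    d[1], d[2], d[3], d[4], x$tr_seconds
  ))
  cat(sprintf("  voxel size: %s mm; %d / %d voxels in brain mask\n",
              paste(signif(x$voxel_size_mm, 3), collapse = " x "),
              sum(x$brain_mask), prod(d[1:3])))
  invisible(x)
}

#' Number of timepoints of a BOLD series
#' @param series A [bold_series()].
#' @return Integer timepoint count.
#' @export
n_timepoints <- function(series) {
  stopifnot(inherits(series, "bold_series"))
  dim(series$data)[4]
}

# in-mask voxel time series as a t x V matrix; attr "voxels" holds linear
# spatial indices so maps can be written back into the grid
series_matrix <- function(series, mask = series$brain_mask) {
  vox <- which(mask)
  d <- dim(series$data)
  m <- matrix(series$data, prod(d[1:3]), d[4])[vox, , drop = FALSE]
  out <- t(m)
  attr(out, "voxels") <- vox
  out
}

# write a t x V matrix (columns = voxels at linear indices `vox`) back
replace_series <- function(series, mat, vox) {
  d <- dim(series$data)
  flat <- matrix(series$data, prod(d[1:3]), d[4])
  flat[vox, ] <- t(mat)
  series$data <- array(flat, d)
  series
}

#' Mean time course within a mask
#'
#' Averages the BOLD signal over all voxels of `mask` at each timepoint,
#' e.g. to extract the reference ventricular signal used as a nuisance
#' regressor.
#'
#' @param series A [bold_series()].
#' @param mask 3D logical array on the series' spatial grid.
#' @return Numeric vector of length `t`.
#' @export
mean_signal <- function(series, mask) {
  if (!identical(as.integer(dim(mask)), as.integer(dim(series$data)[1:3]))) {
    stop("mask shape must match the series' spatial grid", call. = FALSE)
  }
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  colMeans(t(series_matrix(series, mask = array(as.logical(mask), dim(mask)))))
}

#' Read / write BOLD series as NIfTI
#'
#' Thin wrappers over RNifti for the package's on-disk interchange format.
#' `read_bold()` takes the TR from the NIfTI header unless overridden.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param series A [bold_series()] (for writing).
#' @param brain_mask Optional 3D logical mask to attach on read.
#' @param tr_seconds Optional TR override on read.
#' @return `read_bold()` a [bold_series()]; `write_bold()` the path,
#'   invisibly.
#' @export
read_bold <- function(path, brain_mask = NULL, tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)
  dat <- array(as.numeric(img), dim(img))
  if (length(dim(dat)) == 3L) dim(dat) <- c(dim(dat), 1L)
  tr <- tr_seconds %||% (if (length(pix) >= 4) pix[4] else 1)
  bold_series(dat, tr_seconds = tr, voxel_size_mm = pix[1:3],
              brain_mask = brain_mask)
}

#' @rdname read_bold
#' @export
write_bold <- function(series, path) {
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size_mm, series$tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# write/read a 3D numeric or logical volume
write_volume <- function(vol, path, voxel_size_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
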
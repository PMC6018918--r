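#' Connectivity map container
#'
#' Per-subject 3D map of correlation-derived values: either Pearson r
#' (`metric = "r"`) or Fisher z (`metric = "fisher_z"`, the atanh
#' transform). Values are defined only inside the brain mask (`NA`
#' elsewhere).
#'
#' @param values 3D numeric array (`NA` outside the mask).
#' @param metric `"r"` or `"fisher_z"`.
#' @param brain_mask 3D logical array.
#' @param subject_id Identifier.
#' @param seed_name Seed identifier, or `"global"`.
#' @return An object of class `connectivity_map`.
#' @export
connectivity_map <- function(values, metric = c("r", "fisher_z"), brain_mask,
                             subject_id = "subject", seed_name = "global") {
  metric <- match.arg(metric)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array", call. = FALSE)
  }
  if (!identical(dim(values), dim(brain_mask))) {
    stop("`brain_mask` shape must match `values`", call. = FALSE)
  }
  v <- values[brain_mask]
  if (metric == "r" && any(abs(v[is.finite(v)]) > 1 + 1e-12)) {
    stop("r values must lie in [-1, 1]", call. = FALSE)
  }
  structure(
    list(values = values, metric = metric,
         brain_mask = array(as.logical(brain_mask), dim(brain_mask)),
         subject_id = subject_id, seed_name = seed_name),
    class = "connectivity_map"
  )
}

#' @export
print.connectivity_map <- function(x, ...) {
  v <- x$values[x$brain_mask]
  cat(sprintf("<connectivity_map> %s [%s] subject %s, %d voxels, range [%.3f, %.3f]\n",
              x$seed_name, x$metric, x$subject_id, sum(x$brain_mask),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.connectivity_map <- function(x, ...) {
  map <- x
  idx <- which(map$brain_mask, arr.ind = TRUE)
  tibble::tibble(
    x = idx[, 1], y = idx[, 2], z = idx[, 3],
    value = map$values[map$brain_mask],
    metric = map$metric, subject_id = map$subject_id,
    seed_name = map$seed_name
  )
}

# t x V matrix of in-mask, nonzero-variance voxels; zero-variance voxels
# are excluded from both target and reference sets and reported
usable_series_matrix <- function(series) {
  y <- series_matrix(series)
  vox <- attr(y, "voxels")
  sds <- apply(y, 2, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    message(sprintf("excluding %d zero-variance voxel(s) from correlation",
                    sum(drop)))
    y <- y[, !drop, drop = FALSE]
    vox <- vox[!drop]
  }
  attr(y, "voxels") <- vox
  y
}

#' Global connectivity map
#'
#' For each in-mask voxel, the average Pearson correlation with every other
#' in-mask voxel — the "r score" of long-range connectivity mapping.
#' Averaging is done in Fisher-z space (atanh, mean over the other voxels,
#' tanh back), which variance-stabilizes the mean; the reported metric is
#' r. Zero-variance voxels are excluded from both the targets and the
#' reference set.
#'
#' @param series A preprocessed [bold_series()] with >= 2 usable voxels.
#' @param subject_id Identifier stored in the result.
#' @return A [connectivity_map()] with `metric = "r"`,
#'   `seed_name = "global"`.
#' @export
global_connectivity_map <- function(series, subject_id = "subject") {
  stopifnot(inherits(series, "bold_series"))
  y <- usable_series_matrix(series)
  vox <- attr(y, "voxels")
  if (ncol(y) < 2L) stop("need at least 2 usable in-mask voxels", call. = FALSE)
  cc <- stats::cor(y)
  z <- suppressWarnings(atanh(cc))   # r = +/-1 off-diagonal -> +/-Inf, kept
  diag(z) <- 0
  r_score <- tanh(rowSums(z) / (ncol(y) - 1L))
  vals <- array(NA_real_, dim(series$data)[1:3])
  vals[vox] <- r_score
  mask_used <- array(FALSE, dim(series$data)[1:3])
  mask_used[vox] <- TRUE
  connectivity_map(vals, metric = "r", brain_mask = mask_used,
                   subject_id = subject_id, seed_name = "global")
}

#' Seed specification
#'
#' A named region-of-interest mask (possibly bilateral) whose mean time
#' series is correlated against every brain voxel.
#'
#' @param name Identifier (e.g. `"Au1"`, `"HPC"`).
#' @param mask 3D logical array; must be nonempty.
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(name, mask) {
  if (!any(mask)) stop("seed mask is empty", call. = FALSE)
  structure(list(name = name, mask = array(as.logical(mask), dim(mask))),
            class = "seed_spec")
}

#' Seed-based connectivity map
#'
#' Pearson correlation between each in-mask voxel's time series and the
#' mean series of the seed mask.
#'
#' @param series A preprocessed [bold_series()].
#' @param seed A [seed_spec()] (or a 3D logical mask).
#' @param subject_id Identifier stored in the result.
#' @return A [connectivity_map()] with `metric = "r"`.
#' @export
seed_connectivity_map <- function(series, seed, subject_id = "subject") {
  stopifnot(inherits(series, "bold_series"))
  if (!inherits(seed, "seed_spec")) seed <- seed_spec("seed", seed)
  sm <- mean_signal(series, seed$mask & series$brain_mask)
  if (stats::sd(sm) == 0) stop("seed-mean signal is constant", call. = FALSE)
  y <- usable_series_matrix(series)
  vox <- attr(y, "voxels")
  r <- as.numeric(stats::cor(y, sm))
  vals <- array(NA_real_, dim(series$data)[1:3])
  vals[vox] <- r
  mask_used <- array(FALSE, dim(series$data)[1:3])
  mask_used[vox] <- TRUE
  connectivity_map(vals, metric = "r", brain_mask = mask_used,
                   subject_id = subject_id, seed_name = seed$name)
}

#' Fisher z-transform of a connectivity map
#'
#' `z = atanh(r)`, the variance-stabilizing transform applied before group
#' t-tests. Correlations at exactly +/-1 are clipped to
#' `+/-(1 - 1e-7)` with a warning.
#'
#' @param map A [connectivity_map()] with `metric = "r"`.
#' @return The map with `metric = "fisher_z"`.
#' @export
fisher_z <- function(map) {
  stopifnot(inherits(map, "connectivity_map"))
  if (map$metric != "r") stop("map metric must be 'r'", call. = FALSE)
  v <- map$values
  clip <- 1 - 1e-7
  n_clip <- sum(abs(v[map$brain_mask]) > clip, na.rm = TRUE)
  if (n_clip > 0) {
    warning(sprintf("clipping %d correlation(s) at +/-%g before atanh",
                    n_clip, clip))
    v[map$brain_mask] <- pmin(pmax(v[map$brain_mask], -clip), clip)
  }
  map$values[map$brain_mask] <- atanh(v[map$brain_mask])
  map$metric <- "fisher_z"
  map
}

#' Regional connectivity strength
#'
#' Mean map value over each region's in-mask voxels — the per-region "r
#' score" used to quantify connectivity strength in areas of interest.
#'
#' @param map A [connectivity_map()].
#' @param parc A [parcellation()] on the same grid.
#' @param regions Integer labels to summarize (default: all regions). An
#'   empty vector returns an empty table.
#' @return Tibble with `label`, `name`, `n_voxels`, `mean_value`.
#' @export
regional_connectivity_strength <- function(map, parc, regions = NULL) {
  stopifnot(inherits(map, "connectivity_map"), inherits(parc, "parcellation"))
  if (!identical(dim(parc$labels), dim(map$values))) {
    stop("parcellation grid does not match the map", call. = FALSE)
  }
  regions <- if (is.null(regions)) parc$regions$label else as.integer(regions)
  if (length(regions) == 0L) {
    return(tibble::tibble(label = integer(), name = character(),
                          n_voxels = integer(), mean_value = numeric()))
  }
  missing_lab <- setdiff(regions, parc$regions$label)
  if (length(missing_lab) > 0) {
    stop(sprintf("region label(s) %s not in parcellation",
                 paste(missing_lab, collapse = ", ")), call. = FALSE)
  }
  purrr::map_dfr(regions, function(lab) {
    m <- parc$labels == lab & map$brain_mask
    if (!any(m)) {
      stop(sprintf("region %d has no in-mask voxels", lab), call. = FALSE)
    }
    tibble::tibble(
      label = lab,
      name = parc$regions$name[match(lab, parc$regions$label)],
      n_voxels = sum(m),
      mean_value = mean(map$values[m])
    )
  })
}
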
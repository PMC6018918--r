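#' Parcellation container
#'
#' An integer label volume plus a region table, tying voxels to named
#' anatomical regions. Label 0 is background; labels `1..n` are regions.
#' Used for regional connectivity-strength extraction and for summarizing
#' gene-expression volumes into a genes-by-regions matrix.
#'
#' @param labels 3D integer array of region labels (0 = background).
#' @param region_names Optional character vector naming labels `1..n`
#'   (defaults to `"region_<label>"`).
#'
#' @return An object of class `parcellation` with elements `labels` (the
#'   volume) and `regions` (a tibble with `label`, `name`, `n_voxels`).
#' @export
parcellation <- function(labels, region_names = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  lab <- array(as.integer(round(labels)), dim(labels))
  if (any(lab < 0L)) stop("labels must be nonnegative integers", call. = FALSE)
  present <- sort(unique(lab[lab > 0L]))
  if (length(present) == 0L) stop("parcellation has no labelled voxels", call. = FALSE)
  if (is.null(region_names)) {
    region_names <- paste0("region_", present)
  } else if (length(region_names) != length(present)) {
    stop("`region_names` must have one entry per nonzero label", call. = FALSE)
  }
  counts <- tabulate(lab, nbins = max(present))
  structure(
    list(
      labels = lab,
      regions = tibble::tibble(
        label = present,
        name = as.character(region_names),
        n_voxels = counts[present]
      )
    ),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<parcellation> %d x %d x %d grid, %d regions (%d background voxels)\n",
              d[1], d[2], d[3], nrow(x$regions), sum(x$labels == 0L)))
  print(utils::head(x$regions, 10))
  invisible(x)
}

#' Logical mask of one region
#'
#' @param parc A [parcellation()].
#' @param label Integer region label.
#' @return 3D logical array.
#' @export
region_mask <- function(parc, label) {
  stopifnot(inherits(parc, "parcellation"))
  if (!label %in% parc$regions$label) {
    stop(sprintf("region label %s not present in parcellation", label),
         call. = FALSE)
  }
  parc$labels == as.integer(label)
}

#' @export
tidy.parcellation <- function(x, ...) x$regions
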
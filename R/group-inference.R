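#' Two-sided critical t value
#'
#' The cluster-defining threshold used by the group-inference stage: the
#' two-sided Student-t critical value at significance `alpha` for `df`
#' degrees of freedom (e.g. 2.06 at df = 24, alpha = 0.05).
#'
#' @param df Degrees of freedom.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Positive scalar.
#' @export
critical_t <- function(df, alpha = 0.05) {
  stats::qt(1 - alpha / 2, df)
}

# stack connectivity maps into a V x n matrix over their common usable mask
stack_maps <- function(maps) {
  masks <- lapply(maps, `[[`, "brain_mask")
  common <- Reduce(`&`, masks)
  vox <- which(common)
  m <- vapply(maps, function(mp) mp$values[vox], numeric(length(vox)))
  list(mat = matrix(m, nrow = length(vox)), vox = vox, mask = common,
       dim = dim(maps[[1]]$values))
}

# pooled-variance two-sample t per row of a V x n matrix; ia = logical
# group-A indicator over columns
pooled_t_rows <- function(mat, ia) {
  na <- sum(ia); nb <- sum(!ia)
  ma <- rowMeans(mat[, ia, drop = FALSE])
  mb <- rowMeans(mat[, !ia, drop = FALSE])
  va <- rowSums((mat[, ia, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((mat[, !ia, drop = FALSE] - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  t[se == 0] <- 0
  t
}

#' Voxelwise two-sample t-map
#'
#' Pooled-variance two-sided Student t statistic at every voxel of the
#' common mask, comparing group A against group B (positive t = A > B),
#' with `df = n_a + n_b - 2`. Maps must be Fisher-z transformed first
#' (variance stabilization for correlation statistics).
#'
#' @param maps_a,maps_b Lists of [connectivity_map()]s (`metric =
#'   "fisher_z"`, same grid), >= 2 subjects per group.
#' @return List with `t_map` (3D array, `NA` off-mask), `df`, `mask`.
#' @export
group_ttest_map <- function(maps_a, maps_b) {
  maps <- c(maps_a, maps_b)
  if (length(maps_a) < 2L || length(maps_b) < 2L) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  mets <- vapply(maps, `[[`, "", "metric")
  if (!all(mets == "fisher_z")) {
    stop("all maps must have metric 'fisher_z' (apply fisher_z() first)",
         call. = FALSE)
  }
  dims <- lapply(maps, function(m) dim(m$values))
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("maps are on mismatched grids", call. = FALSE)
  }
  st <- stack_maps(maps)
  ia <- c(rep(TRUE, length(maps_a)), rep(FALSE, length(maps_b)))
  tv <- pooled_t_rows(st$mat, ia)
  t_map <- array(NA_real_, st$dim)
  t_map[st$vox] <- tv
  list(t_map = t_map, df = length(maps) - 2L, mask = st$mask)
}

#' 6-connectivity cluster labelling
#'
#' Labels the connected components of a 3D logical mask under
#' face-adjacency (6 neighbours).
#'
#' @param mask 3D logical array.
#' @return 3D integer array; 0 = background, components numbered from 1.
#' @export
label_clusters <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  lab <- array(0L, d)
  remaining <- which(mask)
  if (length(remaining) == 0L) return(lab)
  in_mask <- array(FALSE, d); in_mask[remaining] <- TRUE
  visited <- array(FALSE, d)
  strides <- c(1L, d[1], d[1] * d[2])
  nxt <- 0L
  for (seed in remaining) {
    if (visited[seed]) next
    nxt <- nxt + 1L
    frontier <- seed
    visited[seed] <- TRUE
    while (length(frontier) > 0L) {
      lab[frontier] <- nxt
      coords <- arrayInd(frontier, d)
      nb <- integer(0)
      for (ax in 1:3) {
        ok <- coords[, ax] > 1L
        nb <- c(nb, frontier[ok] - strides[ax])
        ok <- coords[, ax] < d[ax]
        nb <- c(nb, frontier[ok] + strides[ax])
      }
      nb <- unique(nb)
      nb <- nb[in_mask[nb] & !visited[nb]]
      visited[nb] <- TRUE
      frontier <- nb
    }
  }
  lab
}

# max cluster extent over positive and negative suprathreshold masks
max_cluster_extent <- function(tv, vox, dim3, threshold) {
  best <- 0L
  for (sgn in c(1, -1)) {
    sel <- vox[sgn * tv > threshold]
    if (length(sel) == 0L) next
    m <- array(FALSE, dim3); m[sel] <- TRUE
    lab <- label_clusters(m)
    if (any(lab > 0L)) best <- max(best, max(tabulate(lab[lab > 0L])))
  }
  best
}

#' Cluster-corrected group comparison (permutation FWE)
#'
#' Voxelwise two-sample t-test between groups followed by nonparametric
#' family-wise-error cluster correction: suprathreshold voxels
#' (`|t| > cluster_threshold_t`, positive and negative tails clustered
#' separately) are grouped under 6-connectivity, and each observed
#' cluster's corrected p is the proportion of group-label permutations
#' whose maximum cluster extent (over both tails) reaches its extent, with
#' the +1 correction in numerator and denominator. When the requested
#' permutation count reaches the number of distinct relabelings the null is
#' enumerated exhaustively.
#'
#' @param maps_a,maps_b Lists of Fisher-z [connectivity_map()]s.
#' @param cluster_threshold_t Cluster-defining |t| threshold; default the
#'   two-sided critical value at the groups' actual df
#'   ([critical_t()]). The study's printed constant (2.06 at df 24) can be
#'   passed explicitly.
#' @param alpha FWE significance level for the "surviving" flag.
#' @param n_perm Requested permutations (>= 100).
#' @param rng_seed Integer seed for the permutation draws.
#' @return An object of class `fc_group_comparison`; see [tidy()] /
#'   [glance()] methods. Cluster table columns: `cluster_id`, `sign`,
#'   `extent_voxels`, `peak_t`, `p_fwe`, `surviving`, `voxels` (list of
#'   linear indices).
#' @export
cluster_correct_fwe <- function(maps_a, maps_b, cluster_threshold_t = NULL,
                                alpha = 0.05, n_perm = 1000, rng_seed = 1) {
  if (n_perm < 100) stop("`n_perm` must be at least 100", call. = FALSE)
  tt <- group_ttest_map(maps_a, maps_b)
  if (is.null(cluster_threshold_t)) {
    cluster_threshold_t <- critical_t(tt$df, alpha = 0.05)
  }
  if (cluster_threshold_t <= 0) stop("threshold must be positive", call. = FALSE)
  na <- length(maps_a); nb <- length(maps_b); n <- na + nb
  st <- stack_maps(c(maps_a, maps_b))
  dim3 <- st$dim
  obs_ia <- c(rep(TRUE, na), rep(FALSE, nb))
  tv <- st$mat |> pooled_t_rows(obs_ia)

  # observed clusters, per tail
  clusters <- list()
  cid <- 0L
  for (sgn in c(1, -1)) {
    sel <- st$vox[sgn * tv > cluster_threshold_t]
    if (length(sel) == 0L) next
    m <- array(FALSE, dim3); m[sel] <- TRUE
    lab <- label_clusters(m)
    for (k in seq_len(max(lab))) {
      vox_k <- which(lab == k)
      cid <- cid + 1L
      clusters[[cid]] <- list(
        sign = if (sgn > 0) "positive" else "negative",
        voxels = vox_k,
        extent = length(vox_k),
        peak_t = tv[match(vox_k, st$vox)][which.max(abs(tv[match(vox_k, st$vox)]))]
      )
    }
  }

  # permutation null of the maximum cluster extent
  n_distinct <- choose(n, na)
  exhaustive <- n_perm >= n_distinct
  assignments <- if (exhaustive) {
    utils::combn(n, na, simplify = FALSE)
  } else {
    withr::with_seed(as.integer(rng_seed), {
      lapply(seq_len(n_perm), function(i) sample.int(n, na))
    })
  }
  null_max <- vapply(assignments, function(idx) {
    ia <- rep(FALSE, n); ia[idx] <- TRUE
    tp <- pooled_t_rows(st$mat, ia)
    max_cluster_extent(tp, st$vox, dim3, cluster_threshold_t)
  }, numeric(1))

  cluster_tbl <- if (length(clusters) == 0L) {
    tibble::tibble(cluster_id = integer(), sign = character(),
                   extent_voxels = integer(), peak_t = numeric(),
                   p_fwe = numeric(), surviving = logical(),
                   voxels = list())
  } else {
    tibble::tibble(
      cluster_id = seq_along(clusters),
      sign = vapply(clusters, `[[`, "", "sign"),
      extent_voxels = vapply(clusters, `[[`, 0L, "extent"),
      peak_t = vapply(clusters, `[[`, 0, "peak_t"),
      p_fwe = vapply(clusters, function(cl) {
        (1 + sum(null_max >= cl$extent)) / (1 + length(null_max))
      }, numeric(1)),
      voxels = lapply(clusters, `[[`, "voxels")
    ) |>
      dplyr::mutate(surviving = .data$p_fwe <= alpha, .after = "p_fwe") |>
      dplyr::arrange(dplyr::desc(.data$extent_voxels))
  }

  t_map <- array(NA_real_, dim3)
  t_map[st$vox] <- tv
  structure(
    list(
      t_map = t_map, df = tt$df, mask = st$mask,
      cluster_threshold_t = cluster_threshold_t, alpha = alpha,
      clusters = cluster_tbl, n_perm = length(null_max),
      exhaustive = exhaustive, null_max_extent = null_max
    ),
    class = "fc_group_comparison"
  )
}

#' @export
print.fc_group_comparison <- function(x, ...) {
  cat(sprintf(
    "<fc_group_comparison> df = %d, |t| > %.3f, %s null (%d relabelings)\n",
    x$df, x$cluster_threshold_t,
    if (x$exhaustive) "exhaustive" else "sampled", x$n_perm
  ))
  cat(sprintf("  %d cluster(s), %d surviving FWE at alpha = %.2f\n",
              nrow(x$clusters), sum(x$clusters$surviving), x$alpha))
  if (nrow(x$clusters) > 0) {
    print(dplyr::select(x$clusters, -"voxels"))
  }
  invisible(x)
}

#' @export
tidy.fc_group_comparison <- function(x, ...) {
  dplyr::select(x$clusters, -"voxels")
}

#' @export
glance.fc_group_comparison <- function(x, ...) {
  tibble::tibble(
    df = x$df,
    cluster_threshold_t = x$cluster_threshold_t,
    alpha = x$alpha,
    n_clusters = nrow(x$clusters),
    n_surviving = sum(x$clusters$surviving),
    n_perm = x$n_perm,
    exhaustive = x$exhaustive
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1); a thin wrapper over
#' [stats::p.adjust()] so the pipeline's multiple-comparison control is a
#' named, tested stage.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}
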
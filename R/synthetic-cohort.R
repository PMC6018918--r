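#' Synthetic two-group BOLD cohort: configuration
#'
#' Describes a simulated resting-state cohort of two genotype groups with a
#' planted inter-regional over-connectivity effect in one group. The
#' generated data emulate the acquisition this pipeline targets: TR 1.2 s,
#' a run long enough that 20 volumes can be trimmed for T1 equilibration,
#' temporally autocorrelated (AR(1)) noise, a ventricular nuisance signal
#' shared across the brain at low amplitude, and per-subject six-parameter
#' motion traces.
#'
#' Connectivity is planted through a shared latent Gaussian signal mixed
#' into the voxels of the two `planted_pair` regions with weight
#' `sqrt(|rho|)` (the second region carries `sign(rho)` times the latent),
#' so the expected pairwise correlation between voxels of the two regions
#' equals `rho` for that subject's group. Each region additionally carries
#' its own latent at weight `sqrt(local_corr)`, giving every region the
#' within-region coherence real cortical parcels show.
#'
#' @param n_group_a,n_group_b Subjects per group (study scale: 23 and 19;
#'   scaled-down default 6 and 6).
#' @param grid_shape Integer length-3 voxel grid (default `c(20, 20, 4)`).
#' @param n_timepoints Volumes acquired per subject (default 220, so 200
#'   remain after trimming 20).
#' @param tr_seconds Repetition time in seconds (default 1.2).
#' @param ar1_coeff AR(1) coefficient of all temporal noise, in `[0, 1)`.
#' @param n_regions Number of parcellation regions generated.
#' @param planted_pair Two region labels carrying the planted effect.
#' @param planted_corr_a,planted_corr_b Expected cross-region voxel
#'   correlation in groups A and B, each in `(-1, 1)`.
#' @param local_corr Within-region voxel correlation, in `[0, 1)`;
#'   `|planted_corr| + local_corr` must stay below 1.
#' @param nuisance_amplitude Ventricular signal amplitude, in units of the
#'   BOLD fluctuation SD; 0 disables the nuisance channel.
#' @param nuisance_leak Fraction of `nuisance_amplitude` added to every
#'   brain voxel (the global component nuisance regression removes).
#' @param motion_amplitude Innovation SD of the motion random walks.
#' @param voxel_size_mm Physical voxel size (mm).
#' @param rng_seed Integer seed; the whole cohort is a pure function of the
#'   configuration including this seed.
#'
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_group_a = 6, n_group_b = 6,
                          grid_shape = c(20, 20, 4),
                          n_timepoints = 220, tr_seconds = 1.2,
                          ar1_coeff = 0.3, n_regions = 6,
                          planted_pair = c(1, 2),
                          planted_corr_a = 0, planted_corr_b = 0,
                          local_corr = 0.2,
                          nuisance_amplitude = 1, nuisance_leak = 0.3,
                          motion_amplitude = 0.02,
                          voxel_size_mm = c(0.2, 0.2, 0.5),
                          rng_seed = 1) {
  cfg <- list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    grid_shape = as.integer(grid_shape), n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, ar1_coeff = ar1_coeff,
    n_regions = as.integer(n_regions), planted_pair = as.integer(planted_pair),
    planted_corr_a = planted_corr_a, planted_corr_b = planted_corr_b,
    local_corr = local_corr, nuisance_amplitude = nuisance_amplitude,
    nuisance_leak = nuisance_leak, motion_amplitude = motion_amplitude,
    voxel_size_mm = as.numeric(voxel_size_mm),
    rng_seed = as.integer(rng_seed)
  )
  with(cfg, {
    if (n_group_a < 1 || n_group_b < 1) stop("need at least 1 subject per group", call. = FALSE)
    if (length(grid_shape) != 3L || any(grid_shape < 1L)) stop("`grid_shape` must be 3 positive integers", call. = FALSE)
    if (n_timepoints < 8L) stop("`n_timepoints` too small", call. = FALSE)
    if (tr_seconds <= 0) stop("`tr_seconds` must be positive", call. = FALSE)
    if (ar1_coeff < 0 || ar1_coeff >= 1) stop("`ar1_coeff` must lie in [0, 1)", call. = FALSE)
    if (n_regions < 2L || n_regions > prod(grid_shape)) stop("infeasible `n_regions`", call. = FALSE)
    if (length(planted_pair) != 2L || planted_pair[1] == planted_pair[2]) stop("`planted_pair` must be two distinct labels", call. = FALSE)
    for (r in c(planted_corr_a, planted_corr_b)) {
      if (abs(r) >= 1) stop("planted correlations must lie in (-1, 1)", call. = FALSE)
      if (abs(r) + local_corr >= 1) stop("|planted_corr| + local_corr must stay below 1", call. = FALSE)
    }
    if (local_corr < 0 || local_corr >= 1) stop("`local_corr` must lie in [0, 1)", call. = FALSE)
    if (nuisance_amplitude < 0) stop("`nuisance_amplitude` must be nonnegative", call. = FALSE)
  })
  structure(cfg, class = "cohort_config")
}

# unit-variance stationary AR(1) innovations-recursion; matrix version runs
# the recursion across rows (time) for all columns at once
ar1_noise <- function(n, phi, ncol = 1L) {
  innov <- matrix(stats::rnorm(n * ncol), n, ncol)
  if (phi == 0) return(innov)
  x <- innov                               # stationary start, var 1
  s <- sqrt(1 - phi^2)
  for (t in 2:n) x[t, ] <- phi * x[t - 1, ] + s * innov[t, ]
  x
}

# smoothed random walks emulating rigid-body motion estimates:
# 3 translations (mm) + 3 rotations (rad, 1/10 the amplitude)
motion_traces <- function(n_timepoints, amplitude) {
  scale <- rep(c(1, 1, 1, 0.1, 0.1, 0.1), length.out = 6)
  raw <- apply(matrix(stats::rnorm(n_timepoints * 6), n_timepoints, 6), 2, cumsum)
  k <- rep(1 / 5, 5)
  sm <- apply(raw, 2, function(v) {
    f <- stats::filter(v, k, sides = 2)
    f[is.na(f)] <- v[is.na(f)]
    as.numeric(f)
  })
  sweep(sm, 2, amplitude * scale, `*`)
}

#' Generate a synthetic parcellation of connected blocks
#'
#' Recursively bisects the voxel grid into `n_regions` rectangular blocks,
#' each a 6-connected region covering at least one voxel, then randomly
#' permutes which block receives which label. Stands in for an
#' atlas-defined segmentation; all voxels are labelled (no background).
#'
#' @param grid_shape Integer length-3 grid.
#' @param n_regions Number of regions, `2 <= n_regions <= prod(grid_shape)`.
#' @param rng_seed Integer seed (controls only the label permutation).
#' @return A [parcellation()].
#' @export
generate_parcellation <- function(grid_shape, n_regions, rng_seed = 1) {
  grid_shape <- as.integer(grid_shape)
  n_regions <- as.integer(n_regions)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stop("`grid_shape` must be 3 positive integers", call. = FALSE)
  }
  if (n_regions < 1L || n_regions > prod(grid_shape)) {
    stop(sprintf("infeasible region count: %d regions for %d voxels",
                 n_regions, prod(grid_shape)), call. = FALSE)
  }
  lab <- array(0L, grid_shape)
  next_label <- 0L
  # split `k` regions across the box [lo, hi] (inclusive voxel ranges)
  split_box <- function(lo, hi, k) {
    if (k == 1L) {
      next_label <<- next_label + 1L
      lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <<- next_label
      return(invisible(NULL))
    }
    len <- hi - lo + 1L
    ax <- which.max(len)
    s <- max(1L, len[ax] %/% 2L)            # voxels on the low side
    A <- prod(len[-ax])
    k1 <- max(1L, min(k - 1L, round(k * s / len[ax])))
    k1 <- max(k1, k - (len[ax] - s) * A)    # high side must fit k - k1
    k1 <- min(k1, s * A)                    # low side must fit k1
    mid_lo <- lo; mid_hi <- hi
    mid_hi[ax] <- lo[ax] + s - 1L
    split_box(lo, mid_hi, as.integer(k1))
    mid_lo[ax] <- lo[ax] + s
    split_box(mid_lo, hi, as.integer(k - k1))
  }
  split_box(c(1L, 1L, 1L), grid_shape, n_regions)
  withr::with_seed(as.integer(rng_seed), {
    perm <- sample.int(n_regions)
  })
  lab[] <- perm[lab]
  parcellation(lab)
}

# small central block used as the ventricular compartment
ventricle_block <- function(grid_shape) {
  mask <- array(FALSE, grid_shape)
  ctr <- pmax(1L, grid_shape %/% 2L)
  half <- pmax(0L, pmin(1L, (grid_shape - 1L) %/% 4L))
  mask[(ctr[1] - half[1]):(ctr[1] + half[1]),
       (ctr[2] - half[2]):(ctr[2] + half[2]),
       ctr[3]] <- TRUE
  mask
}

#' Generate a synthetic two-group BOLD cohort
#'
#' Simulates every subject of a two-group resting-state experiment on a
#' common grid: AR(1) temporal noise, within-region coherent latents, a
#' planted cross-region latent whose mixing yields the configured expected
#' correlation between the two `planted_pair` regions (group-specific), a
#' ventricular nuisance signal leaked at low amplitude into all brain
#' voxels, and six-column motion-trace tables. Identical configuration
#' (including `rng_seed`) reproduces the cohort bit for bit.
#'
#' @param config A [cohort_config()].
#' @param parc Optional [parcellation()] on `config$grid_shape`; generated
#'   from the config when `NULL`.
#' @return An object of class `bold_cohort`: list with `subjects` (each a
#'   list of `subject_id`, `group`, `series` ([bold_series()]), `motion`
#'   (t x 6 matrix)), `parcellation`, `ventricle_mask`, `config`.
#' @export
generate_bold_cohort <- function(config, parc = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(parc)) {
    parc <- generate_parcellation(config$grid_shape, config$n_regions,
                                  rng_seed = config$rng_seed)
  }
  if (!identical(as.integer(dim(parc$labels)), config$grid_shape)) {
    stop("parcellation grid does not match `config$grid_shape`", call. = FALSE)
  }
  missing_lab <- setdiff(config$planted_pair, parc$regions$label)
  if (length(missing_lab) > 0) {
    stop(sprintf("planted label(s) %s missing from parcellation",
                 paste(missing_lab, collapse = ", ")), call. = FALSE)
  }

  grid <- config$grid_shape
  nt <- config$n_timepoints
  phi <- config$ar1_coeff
  vent <- ventricle_block(grid)
  labels_flat <- as.integer(parc$labels)
  n_vox <- prod(grid)
  groups <- c(rep("a", config$n_group_a), rep("b", config$n_group_b))
  bold_sd <- 2       # fluctuation SD in signal units
  baseline <- 100    # raw-signal offset

  subjects <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    seed_i <- (config$rng_seed %% 100000L) * 10000L + i
    rho <- if (groups[i] == "a") config$planted_corr_a else config$planted_corr_b
    lam <- config$local_corr
    sub <- withr::with_seed(as.integer(seed_i), {
      g_pair <- ar1_noise(nt, phi)                      # shared planted latent
      h_reg <- ar1_noise(nt, phi, ncol = config$n_regions)
      vsig <- ar1_noise(nt, 0.95)                       # slow ventricular drift
      e <- ar1_noise(nt, phi, ncol = n_vox)
      w_pair <- numeric(config$n_regions)
      w_pair[config$planted_pair[1]] <- sqrt(abs(rho))
      w_pair[config$planted_pair[2]] <- sign(rho) * sqrt(abs(rho))
      w_loc <- sqrt(lam)
      # residual weight keeps each voxel at unit variance
      w_res <- sqrt(1 - w_pair[labels_flat]^2 - lam)
      x <- e * rep(w_res, each = nt) +
        h_reg[, labels_flat, drop = FALSE] * w_loc +
        g_pair %*% t(w_pair[labels_flat])
      x <- x * bold_sd + baseline
      amp <- config$nuisance_amplitude * bold_sd
      if (amp > 0) {
        leak <- config$nuisance_leak * amp
        x <- x + vsig %*% t(ifelse(as.logical(vent), amp, leak))
      }
      list(
        data = array(t(x), c(grid, nt)),
        motion = motion_traces(nt, config$motion_amplitude)
      )
    })
    subjects[[i]] <- list(
      subject_id = sprintf("sub-%s%02d", groups[i], sum(groups[1:i] == groups[i])),
      group = groups[i],
      series = bold_series(sub$data, tr_seconds = config$tr_seconds,
                           voxel_size_mm = config$voxel_size_mm),
      motion = sub$motion
    )
  }
  names(subjects) <- vapply(subjects, `[[`, "", "subject_id")
  structure(
    list(subjects = subjects, parcellation = parc, ventricle_mask = vent,
         config = config),
    class = "bold_cohort"
  )
}

#' @export
print.bold_cohort <- function(x, ...) {
  grp <- vapply(x$subjects, `[[`, "", "group")
  cat(sprintf("<bold_cohort> %d subjects (A: %d, B: %d), grid %s, %d timepoints\n",
              length(grp), sum(grp == "a"), sum(grp == "b"),
              paste(x$config$grid_shape, collapse = "x"),
              x$config$n_timepoints))
  invisible(x)
}

#' Write / read a synthetic cohort as NIfTI + TSV + JSON
#'
#' Serializes each subject's 4D BOLD run (`.nii.gz`), its motion traces
#' (six-column TSV, one row per acquired volume), the parcellation, brain
#' and ventricle masks, and a JSON manifest mapping subject id to group and
#' file paths.
#'
#' @param cohort A `bold_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` the manifest path invisibly; `read_cohort()` a
#'   `bold_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bold_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vx <- cohort$config$voxel_size_mm
  write_volume(cohort$parcellation$labels, file.path(dir, "parcellation.nii.gz"), vx)
  write_volume(cohort$ventricle_mask, file.path(dir, "ventricle_mask.nii.gz"), vx)
  write_volume(cohort$subjects[[1]]$series$brain_mask,
               file.path(dir, "brain_mask.nii.gz"), vx)
  manifest <- list(seed = cohort$config$rng_seed, subjects = list())
  for (s in cohort$subjects) {
    bold_path <- file.path(dir, paste0(s$subject_id, "_bold.nii.gz"))
    mot_path <- file.path(dir, paste0(s$subject_id, "_motion.tsv"))
    write_bold(s$series, bold_path)
    readr::write_tsv(
      tibble::as_tibble(s$motion, .name_repair = ~ paste0("mot", 1:6)),
      mot_path, col_names = FALSE
    )
    manifest$subjects[[s$subject_id]] <-
      list(group = s$group, bold = basename(bold_path), motion = basename(mot_path))
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  parc <- parcellation(read_volume(file.path(dir, "parcellation.nii.gz")))
  vent <- read_volume(file.path(dir, "ventricle_mask.nii.gz")) > 0.5
  mask <- read_volume(file.path(dir, "brain_mask.nii.gz")) > 0.5
  subjects <- lapply(names(manifest$subjects), function(id) {
    entry <- manifest$subjects[[id]]
    series <- read_bold(file.path(dir, entry$bold), brain_mask = mask)
    motion <- as.matrix(readr::read_tsv(file.path(dir, entry$motion),
                                        col_names = FALSE,
                                        show_col_types = FALSE))
    dimnames(motion) <- NULL
    list(subject_id = id, group = entry$group, series = series, motion = motion)
  })
  names(subjects) <- names(manifest$subjects)
  structure(
    list(subjects = subjects, parcellation = parc, ventricle_mask = vent,
         config = NULL),
    class = "bold_cohort"
  )
}
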
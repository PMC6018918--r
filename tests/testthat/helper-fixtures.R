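# shared fixtures and independent oracles ------------------------------------

# small bold series from a t x V matrix laid out on a given grid
toy_series <- function(mat, grid = NULL, tr = 1.2, voxel = c(1, 1, 1),
                       mask = NULL) {
  v <- ncol(mat)
  if (is.null(grid)) grid <- c(v, 1, 1)
  stopifnot(prod(grid) == v)
  dat <- array(t(mat), c(grid, nrow(mat)))
  bold_series(dat, tr_seconds = tr, voxel_size_mm = voxel, brain_mask = mask)
}

# brute-force global connectivity oracle: all-pairs correlation matrix,
# Fisher-z averaged off the diagonal, back-transformed
brute_global_map <- function(mat) {
  cc <- stats::cor(mat)
  z <- suppressWarnings(atanh(cc))
  diag(z) <- 0
  tanh(rowSums(z) / (ncol(mat) - 1))
}

# FFT amplitude of a series at frequency f (Hz)
fft_amplitude <- function(x, f, tr) {
  n <- length(x)
  sp <- Mod(stats::fft(x))
  freqs <- (0:(n - 1)) / (n * tr)
  sp[which.min(abs(freqs - f))]
}

# minimum-hypergeometric statistic recomputed from scratch for an indicator
mhg_stat_oracle <- function(ind) {
  N <- length(ind); B <- sum(ind)
  b <- cumsum(ind)
  min(stats::phyper(b - 1, B, N - B, seq_len(N), lower.tail = FALSE))
}

# exact mHG p-value by full enumeration of target placements (N <= ~10)
mhg_enum_p <- function(N, B, s) {
  cmb <- utils::combn(N, B)
  hit <- 0
  for (j in seq_len(ncol(cmb))) {
    ind <- rep(FALSE, N); ind[cmb[, j]] <- TRUE
    if (mhg_stat_oracle(ind) <= s * (1 + 1e-10)) hit <- hit + 1
  }
  hit / ncol(cmb)
}

# fisher-z group maps on a shared 1-voxel-per-value grid, for t-test oracles
scalar_z_maps <- function(values) {
  lapply(values, function(v) {
    connectivity_map(array(v, c(1, 1, 1)), metric = "fisher_z",
                     brain_mask = array(TRUE, c(1, 1, 1)))
  })
}

# z maps over an arbitrary grid from a voxel-value vector
grid_z_map <- function(v, grid) {
  connectivity_map(array(v, grid), metric = "fisher_z",
                   brain_mask = array(TRUE, grid))
}
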
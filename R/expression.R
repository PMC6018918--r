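#' Expression matrix container
#'
#' Genes-by-regions matrix of nonnegative expression energies (the
#' Allen-style regional summary: sum of expressing-pixel intensities
#' divided by total pixels in a subdivision), with a flag recording whether
#' rows have been normalized to unit total.
#'
#' @param energies Numeric genes x regions matrix, nonnegative; rownames =
#'   gene ids (unique), colnames = region labels.
#' @param normalized Logical; `TRUE` after [normalize_by_total()].
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(energies, normalized = FALSE) {
  energies <- as.matrix(energies)
  if (is.null(rownames(energies)) || is.null(colnames(energies))) {
    stop("`energies` needs gene-id rownames and region-label colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(energies))) {
    stop("duplicate gene ids", call. = FALSE)
  }
  if (any(energies < 0)) stop("energies must be nonnegative", call. = FALSE)
  if (normalized) {
    rs <- rowSums(energies)
    if (any(abs(rs - 1) > 1e-9)) {
      stop("normalized matrix rows must sum to 1", call. = FALSE)
    }
  }
  structure(
    list(gene_ids = rownames(energies),
         region_labels = colnames(energies),
         energies = energies,
         normalized = isTRUE(normalized)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d regions (%s)\n",
              length(x$gene_ids), length(x$region_labels),
              if (x$normalized) "normalized" else "raw energies"))
  invisible(x)
}

#' @export
tidy.expression_matrix <- function(x, ...) {
  tibble::as_tibble(x$energies, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "region", values_to = "energy")
}

region_column <- function(matrix, label) {
  label <- as.character(label)
  j <- match(label, matrix$region_labels)
  if (is.na(j)) {
    stop(sprintf("region label '%s' not in expression matrix", label),
         call. = FALSE)
  }
  matrix$energies[, j]
}

#' Summarize per-gene expression volumes under a parcellation
#'
#' Computes entry `(g, r)` as the mean of gene `g`'s expression-energy
#' volume over the voxels labelled `r` — the regional extraction step that
#' turns atlas-aligned expression images into a genes-by-regions matrix.
#'
#' @param volumes Named list of 3D nonnegative arrays, one per gene, all on
#'   the parcellation's grid.
#' @param parc A [parcellation()].
#' @param regions Labels to extract (default: all in the parcellation); an
#'   unknown label is an error naming it.
#' @return A raw (unnormalized) [expression_matrix()].
#' @export
expression_energy_by_region <- function(volumes, parc, regions = NULL) {
  stopifnot(inherits(parc, "parcellation"))
  if (is.null(names(volumes)) || anyDuplicated(names(volumes))) {
    stop("`volumes` must be a uniquely named list (gene ids)", call. = FALSE)
  }
  regions <- if (is.null(regions)) parc$regions$label else as.integer(regions)
  missing_lab <- setdiff(regions, parc$regions$label)
  if (length(missing_lab) > 0) {
    stop(sprintf("region label(s) %s absent from parcellation",
                 paste(missing_lab, collapse = ", ")), call. = FALSE)
  }
  d <- dim(parc$labels)
  masks <- lapply(regions, function(lab) which(parc$labels == lab))
  energies <- t(vapply(volumes, function(vol) {
    if (!identical(dim(vol), d)) {
      stop("expression volume grid does not match the parcellation",
           call. = FALSE)
    }
    if (any(vol < 0)) stop("expression energies must be nonnegative", call. = FALSE)
    vapply(masks, function(ix) mean(vol[ix]), numeric(1))
  }, numeric(length(regions))))
  rownames(energies) <- names(volumes)
  colnames(energies) <- as.character(regions)
  expression_matrix(energies)
}

#' Normalize each gene by its total expression
#'
#' Divides every gene's row by its sum over regions, removing probe-
#' affinity differences in overall signal; rows with zero total are dropped
#' with a message (they carry no ranking information).
#'
#' @param matrix A raw [expression_matrix()].
#' @return A normalized [expression_matrix()]; retained rows sum to 1.
#' @export
normalize_by_total <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$normalized) stop("matrix is already normalized", call. = FALSE)
  totals <- rowSums(matrix$energies)
  drop <- totals == 0
  if (any(drop)) {
    message(sprintf("dropping %d gene(s) with zero total expression", sum(drop)))
  }
  e <- matrix$energies[!drop, , drop = FALSE] / totals[!drop]
  expression_matrix(e, normalized = TRUE)
}

# top ceil(q * N) gene ids of one region, ties broken by gene id ascending
top_genes_of_region <- function(matrix, label, q) {
  v <- region_column(matrix, label)
  ids <- matrix$gene_ids
  k <- ceiling(q * length(ids))
  ord <- order(-v, ids)
  ids[ord[seq_len(k)]]
}

#' Dual-region top-quantile gene selection
#'
#' Genes whose normalized expression ranks within the top `ceil(q * N)`
#' positions in *both* regions of the pair — the fixed-threshold candidate
#' selection ("top 20% of genes for both regions"). Ties are broken by
#' gene id (ascending) for determinism.
#'
#' @param matrix A normalized [expression_matrix()].
#' @param pair Two region labels.
#' @param q Quantile in `(0, 1]` (default 0.20).
#' @param require_normalized Set `FALSE` to select on raw energies.
#' @return Character vector of gene ids (sorted).
#' @export
top_quantile_intersection <- function(matrix, pair, q = 0.20,
                                      require_normalized = TRUE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (require_normalized && !matrix$normalized) {
    stop("matrix must be normalized (see normalize_by_total())", call. = FALSE)
  }
  if (!(q > 0 && q <= 1)) stop("`q` must lie in (0, 1]", call. = FALSE)
  if (length(pair) != 2L) stop("`pair` must be two region labels", call. = FALSE)
  sort(intersect(top_genes_of_region(matrix, pair[1], q),
                 top_genes_of_region(matrix, pair[2], q)))
}

#' L1 ranking of genes over a region pair
#'
#' Scores each gene by the sum of its normalized expression in the two
#' regions (the L1 distance from zero restricted to the pair) and ranks
#' descending; this favors genes high in both regions but also genes very
#' high in just one. Ties are broken by gene id.
#'
#' @param matrix A normalized [expression_matrix()].
#' @param pair Two region labels.
#' @param require_normalized Set `FALSE` to rank raw energies.
#' @return Tibble `(rank, gene_id, score)`, best first, scores
#'   nonincreasing.
#' @export
l1_rank <- function(matrix, pair, require_normalized = TRUE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (require_normalized && !matrix$normalized) {
    stop("matrix must be normalized (see normalize_by_total())", call. = FALSE)
  }
  if (length(pair) != 2L) stop("`pair` must be two region labels", call. = FALSE)
  score <- region_column(matrix, pair[1]) + region_column(matrix, pair[2])
  ord <- order(-score, matrix$gene_ids)
  tibble::tibble(
    rank = seq_along(ord),
    gene_id = matrix$gene_ids[ord],
    score = as.numeric(score[ord])
  )
}

#' Hypergeometric upper-tail probability
#'
#' `P[X >= k]` for `X` hypergeometric with population `N`, `B` successes,
#' `n` draws; evaluated through the stable distribution-function routines.
#' The building block of both the fixed-threshold and the flexible-
#' threshold enrichment statistics.
#'
#' @param k Observed successes (0 <= k <= n).
#' @param N Population size.
#' @param B Successes in the population (B <= N).
#' @param n Draws (n <= N).
#' @return Probability in `[0, 1]`.
#' @export
hypergeometric_tail <- function(k, N, B, n) {
  if (any(k < 0 | n < 0 | B < 0) || any(k > n) || any(n > N) || any(B > N)) {
    stop("require 0 <= k <= n <= N and B <= N", call. = FALSE)
  }
  stats::phyper(k - 1, B, N - B, n, lower.tail = FALSE)
}

# exact p-value for the minimum-hypergeometric statistic via the
# path-counting dynamic programme: probability, over uniform random
# orderings of B targets among N genes, that some prefix attains a
# hypergeometric tail <= s. Mass is propagated along the lattice of
# (prefix length n, targets seen b); any cell whose tail is <= s absorbs
# its mass (those orderings are "at least as extreme").
mhg_exact_p <- function(N, B, s, tol = 1e-10) {
  if (B == 0) stop("empty target set", call. = FALSE)
  if (s >= 1) return(1)
  f <- numeric(B + 1)            # f[b+1] = mass at (n, b)
  f[1] <- 1
  bs <- 0:B
  for (n in 0:(N - 1)) {
    p_take <- (B - bs) / (N - n)
    p_stay <- 1 - p_take
    f_next <- f * p_stay
    f_next[-1] <- f_next[-1] + f[-(B + 1)] * p_take[-(B + 1)]
    np <- n + 1
    lo <- max(0, np - (N - B)); hi <- min(np, B)
    bb <- lo:hi
    tails <- stats::phyper(bb - 1, B, N - B, np, lower.tail = FALSE)
    sig <- bb[tails <= s * (1 + tol)]
    f_next[sig + 1] <- 0
    f <- f_next
  }
  max(0, min(1, 1 - f[B + 1]))
}

#' Minimum-hypergeometric (mHG) ranked-list enrichment
#'
#' The flexible-threshold enrichment test: for every prefix length `n` of
#' the ranked list, compute the hypergeometric tail of the target count in
#' the top `n`; the statistic is the minimum over prefixes (the optimal
#' threshold is found automatically, per set), and the exact p-value
#' corrects that minimum for threshold optimization by dynamic-programming
#' path counting over all orderings.
#'
#' @param ranked A ranked gene list as returned by [l1_rank()] (tibble with
#'   `gene_id`, best first) or a character vector of ordered gene ids.
#' @param target_set Character vector of target gene ids (nonempty after
#'   intersection with the list).
#' @param universe Optional universe (default: the genes in the list);
#'   the list must cover it.
#' @return An object of class `enrichment_result`: list with `statistic`
#'   (minimum tail, in (0, 1]), `optimal_rank`, `b_at_optimum`, `exact_p`,
#'   `n_universe`, `n_targets`.
#' @export
mhg_enrichment <- function(ranked, target_set, universe = NULL) {
  genes <- if (is.data.frame(ranked)) ranked$gene_id else as.character(ranked)
  if (anyDuplicated(genes)) stop("ranked list contains duplicates", call. = FALSE)
  if (!is.null(universe)) {
    if (!all(universe %in% genes)) {
      stop("ranked list must cover the universe", call. = FALSE)
    }
    genes <- genes[genes %in% universe]
  }
  N <- length(genes)
  ind <- genes %in% target_set
  B <- sum(ind)
  if (B == 0L) stop("target set is empty within the ranked list", call. = FALSE)
  b <- cumsum(ind)
  n_seq <- seq_len(N)
  tails <- stats::phyper(b - 1, B, N - B, n_seq, lower.tail = FALSE)
  opt <- which.min(tails)
  s <- tails[opt]
  structure(
    list(statistic = s, optimal_rank = opt, b_at_optimum = b[opt],
         exact_p = mhg_exact_p(N, B, s), n_universe = N, n_targets = B),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> mHG = %.3g at rank %d (%d/%d targets), exact p = %.3g\n",
    x$statistic, x$optimal_rank, x$b_at_optimum, x$n_targets, x$exact_p
  ))
  invisible(x)
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, optimal_rank = x$optimal_rank,
    b_at_optimum = x$b_at_optimum, exact_p = x$exact_p,
    n_universe = x$n_universe, n_targets = x$n_targets
  )
}

#' Decode a region pair against gene-set annotations
#'
#' Runs both candidate-selection modes of the transcriptomic decoding step
#' for every annotation set and FDR-corrects within each mode:
#' \describe{
#'   \item{`intersection`}{dual-region top-`q` selection
#'     ([top_quantile_intersection()]) followed by a fixed-threshold
#'     hypergeometric tail test of the set's overlap with the selection.}
#'   \item{`ranked`}{L1 ranking over the pair ([l1_rank()]) followed by
#'     flexible-threshold [mhg_enrichment()].}
#' }
#' The gene universe is the (normalized, retained) matrix.
#'
#' @param matrix A normalized [expression_matrix()].
#' @param pair Two region labels (the connectivity hotspot pair).
#' @param gene_sets Named list of gene-id vectors (e.g. from [read_gmt()]);
#'   genes outside the universe are ignored.
#' @param q Top-quantile for the intersection mode (default 0.20).
#' @param alpha_fdr FDR level used only for downstream significance counts.
#' @return Tibble `(set_name, mode, n_set, statistic, optimal_rank,
#'   p_value, q_value)` sorted by `q_value` then `p_value`.
#' @export
decode_pair <- function(matrix, pair, gene_sets, q = 0.20, alpha_fdr = 0.05) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!matrix$normalized) {
    stop("matrix must be normalized (see normalize_by_total())", call. = FALSE)
  }
  if (length(gene_sets) == 0L || is.null(names(gene_sets))) {
    stop("`gene_sets` must be a nonempty named list", call. = FALSE)
  }
  universe <- matrix$gene_ids
  N <- length(universe)
  selection <- top_quantile_intersection(matrix, pair, q = q)
  ranked <- l1_rank(matrix, pair)

  fixed <- purrr::imap_dfr(gene_sets, function(set, nm) {
    set_u <- intersect(set, universe)
    k <- length(intersect(set_u, selection))
    tibble::tibble(
      set_name = nm, mode = "intersection", n_set = length(set_u),
      statistic = hypergeometric_tail(k, N, length(set_u), length(selection)),
      optimal_rank = NA_integer_
    ) |>
      dplyr::mutate(p_value = .data$statistic)
  })
  flexible <- purrr::imap_dfr(gene_sets, function(set, nm) {
    set_u <- intersect(set, universe)
    res <- mhg_enrichment(ranked, set_u)
    tibble::tibble(
      set_name = nm, mode = "ranked", n_set = length(set_u),
      statistic = res$statistic, optimal_rank = res$optimal_rank,
      p_value = res$exact_p
    )
  })
  dplyr::bind_rows(fixed, flexible) |>
    dplyr::group_by(.data$mode) |>
    dplyr::mutate(q_value = fdr_adjust(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$q_value, .data$p_value)
}

#' Random-region-pair specificity control
#'
#' Repeats the full decoding on randomly drawn region pairs (excluding the
#' focal pair) and counts, per pair, how many set-mode results reach the
#' FDR threshold; a decoding specific to the focal hotspot pair should
#' exceed the control counts.
#'
#' @param matrix A normalized [expression_matrix()].
#' @param gene_sets Named list of gene-id vectors.
#' @param focal_pair The hotspot pair (always reported first).
#' @param n_pairs Number of control pairs drawn uniformly without
#'   replacement (default 10; 0 = focal row only).
#' @param q,alpha_fdr Passed to [decode_pair()]; `alpha_fdr` is the
#'   significance cutoff on `q_value`.
#' @param rng_seed Integer seed for the pair draws.
#' @return Tibble `(region_1, region_2, focal, n_significant_sets)`.
#' @export
random_pair_control <- function(matrix, gene_sets, focal_pair, n_pairs = 10,
                                q = 0.20, alpha_fdr = 0.05, rng_seed = 1) {
  stopifnot(inherits(matrix, "expression_matrix"))
  labels <- matrix$region_labels
  focal <- as.character(focal_pair)
  all_pairs <- utils::combn(labels, 2, simplify = FALSE)
  is_focal <- vapply(all_pairs, function(p) setequal(p, focal), logical(1))
  candidates <- all_pairs[!is_focal]
  if (n_pairs > length(candidates)) {
    stop(sprintf("only %d non-focal pairs exist; cannot draw %d",
                 length(candidates), n_pairs), call. = FALSE)
  }
  chosen <- if (n_pairs > 0) {
    withr::with_seed(as.integer(rng_seed), {
      candidates[sample.int(length(candidates), n_pairs)]
    })
  } else {
    list()
  }
  count_sig <- function(pair) {
    res <- decode_pair(matrix, pair, gene_sets, q = q, alpha_fdr = alpha_fdr)
    sum(res$q_value <= alpha_fdr)
  }
  rows <- c(list(focal), chosen)
  tibble::tibble(
    region_1 = vapply(rows, `[[`, "", 1L),
    region_2 = vapply(rows, `[[`, "", 2L),
    focal = c(TRUE, rep(FALSE, length(chosen))),
    n_significant_sets = vapply(rows, count_sig, numeric(1))
  )
}
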
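#' Synthetic regional expression matrix: configuration
#'
#' Describes a genes-by-regions "expression energy" matrix (the Allen-style
#' regional summary: expressing-pixel intensity normalized by region size)
#' with one planted gene set whose members are boosted multiplicatively in
#' a chosen focal region pair, plus decoy annotation sets.
#'
#' @param n_genes Number of genes (study scale: ~4082 unique coronal-atlas
#'   genes; scaled-down default 500).
#' @param n_regions Number of regions (default 20).
#' @param focal_pair Two region labels receiving the boost.
#' @param enriched_set_size Genes in the planted set (default 50).
#' @param enrichment_effect Multiplicative expression boost of planted
#'   genes in the focal regions; 1 = no effect.
#' @param n_decoy_sets Decoy annotation sets of the same size (default 9,
#'   so 10 sets total mirror a small GO collection).
#' @param rng_seed Integer seed.
#' @return A validated `planted_expression_config` list.
#' @export
planted_expression_config <- function(n_genes = 500, n_regions = 20,
                                      focal_pair = c(1, 2),
                                      enriched_set_size = 50,
                                      enrichment_effect = 5,
                                      n_decoy_sets = 9,
                                      rng_seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_regions = as.integer(n_regions),
    focal_pair = as.integer(focal_pair),
    enriched_set_size = as.integer(enriched_set_size),
    enrichment_effect = enrichment_effect,
    n_decoy_sets = as.integer(n_decoy_sets),
    rng_seed = as.integer(rng_seed)
  )
  with(cfg, {
    if (n_genes < 2L || n_regions < 2L) stop("need >= 2 genes and regions", call. = FALSE)
    if (enriched_set_size >= n_genes) stop("`enriched_set_size` must be < `n_genes`", call. = FALSE)
    if (length(focal_pair) != 2L || focal_pair[1] == focal_pair[2] ||
        any(focal_pair < 1L) || any(focal_pair > n_regions)) {
      stop("`focal_pair` must be two distinct labels in 1..n_regions", call. = FALSE)
    }
    if (enrichment_effect <= 0) stop("`enrichment_effect` must be positive", call. = FALSE)
  })
  structure(cfg, class = "planted_expression_config")
}

#' Generate an expression matrix with a planted enriched gene set
#'
#' Baseline energies are `base_g * gamma` noise (gene-specific log-normal
#' level times mean-1 gamma variation per region), so per-gene totals vary
#' the way probe affinities do; planted genes are multiplied by
#' `enrichment_effect` in both focal regions. Gene-set annotations contain
#' the planted set plus size-matched decoy sets drawn from the remaining
#' genes.
#'
#' @param config A [planted_expression_config()].
#' @return List with `matrix` (an [expression_matrix()], raw energies),
#'   `gene_sets` (named list of gene-id vectors; the planted one is
#'   `"planted_set"`), `planted_genes`, and `config`.
#' @export
generate_expression_matrix <- function(config) {
  stopifnot(inherits(config, "planted_expression_config"))
  withr::with_seed(config$rng_seed, {
    ng <- config$n_genes
    nr <- config$n_regions
    gene_ids <- sprintf("gene%04d", seq_len(ng))
    base <- stats::rlnorm(ng, meanlog = 0, sdlog = 0.5)
    energies <- matrix(base, ng, nr) *
      matrix(stats::rgamma(ng * nr, shape = 5, rate = 5), ng, nr)
    planted <- sort(sample(gene_ids, config$enriched_set_size))
    idx <- match(planted, gene_ids)
    energies[idx, config$focal_pair] <-
      energies[idx, config$focal_pair] * config$enrichment_effect
    rownames(energies) <- gene_ids
    colnames(energies) <- as.character(seq_len(nr))
    sets <- list(planted_set = planted)
    pool <- setdiff(gene_ids, planted)
    for (k in seq_len(config$n_decoy_sets)) {
      sets[[sprintf("decoy_set_%02d", k)]] <-
        sort(sample(pool, config$enriched_set_size))
    }
    list(
      matrix = expression_matrix(energies),
      gene_sets = sets,
      planted_genes = planted,
      config = config
    )
  })
}

#' Generate a DEG table and risk-gene list with exact overlap counts
#'
#' Builds a gene universe, a set of differentially expressed genes (DEGs),
#' and a risk-gene list realizing exactly the requested 2x2 overlap, then
#' dresses the DEG table with the schema downstream consumers expect
#' (`gene_id`, `log2fc`, `pvalue`, `padj`; DEGs have `padj < 0.05`, and
#' about two-thirds are down-regulated, as in the neonatal-cortex data this
#' emulates).
#'
#' @param n_universe,n_deg,risk_list_size,overlap Counts; must satisfy
#'   `overlap <= min(n_deg, risk_list_size)` and
#'   `n_deg, risk_list_size <= n_universe`.
#' @param rng_seed Integer seed.
#' @return List with `deg_table` (tibble over the whole universe),
#'   `deg_genes`, `risk_genes`, `universe`.
#' @export
generate_deg_table <- function(n_universe, n_deg, risk_list_size, overlap,
                               rng_seed = 1) {
  n_universe <- as.integer(n_universe); n_deg <- as.integer(n_deg)
  risk_list_size <- as.integer(risk_list_size); overlap <- as.integer(overlap)
  if (overlap > min(n_deg, risk_list_size)) {
    stop("`overlap` cannot exceed min(n_deg, risk_list_size)", call. = FALSE)
  }
  if (n_deg > n_universe || risk_list_size > n_universe) {
    stop("set sizes cannot exceed `n_universe`", call. = FALSE)
  }
  if (n_deg + risk_list_size - overlap > n_universe) {
    stop("infeasible counts: union exceeds the universe", call. = FALSE)
  }
  withr::with_seed(as.integer(rng_seed), {
    universe <- sprintf("gene%05d", seq_len(n_universe))
    deg <- sort(sample(universe, n_deg))
    risk_in <- sort(sample(deg, overlap))
    risk_out <- sort(sample(setdiff(universe, deg), risk_list_size - overlap))
    risk <- sort(c(risk_in, risk_out))
    is_deg <- universe %in% deg
    lfc <- ifelse(is_deg,
                  stats::rnorm(n_universe, 1, 0.3) *
                    ifelse(stats::runif(n_universe) < 2 / 3, -1, 1),
                  stats::rnorm(n_universe, 0, 0.1))
    padj <- ifelse(is_deg, stats::runif(n_universe, 0, 0.049),
                   stats::runif(n_universe, 0.05, 1))
    tbl <- tibble::tibble(
      gene_id = universe,
      log2fc = lfc,
      pvalue = pmin(1, padj * stats::runif(n_universe, 0.2, 1)),
      padj = padj
    )
    list(deg_table = tbl, deg_genes = deg, risk_genes = risk,
         universe = universe)
  })
}

#' Write / read an expression matrix as TSV
#'
#' Header: `gene_id`, then one column per region label.
#'
#' @param matrix An [expression_matrix()].
#' @param path TSV path.
#' @return `write_expression_matrix()` the path invisibly;
#'   `read_expression_matrix()` an [expression_matrix()].
#' @export
write_expression_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "expression_matrix"))
  tbl <- tibble::as_tibble(matrix$energies, .name_repair = "minimal")
  names(tbl) <- matrix$region_labels
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(gene_id = matrix$gene_ids), tbl),
                   path)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl$gene_id
  expression_matrix(m)
}

#' Write / read gene sets in GMT format
#'
#' GMT: one set per line, tab-separated `name`, `description`, members.
#' Reading uses fgsea's parser when available.
#'
#' @param sets Named list of character gene-id vectors.
#' @param path GMT path.
#' @return `write_gmt()` the path invisibly; `read_gmt()` a named list.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}
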
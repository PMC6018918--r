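test_that("cohort generation is a pure function of its seed", {
  cfg <- cohort_config(n_group_a = 2, n_group_b = 2, grid_shape = c(6, 6, 2),
                       n_timepoints = 40, rng_seed = 7)
  a <- generate_bold_cohort(cfg)
  b <- generate_bold_cohort(cfg)
  expect_identical(a$subjects[[1]]$series$data, b$subjects[[1]]$series$data)
  expect_identical(a$subjects[[3]]$motion, b$subjects[[3]]$motion)
  expect_identical(a$parcellation$labels, b$parcellation$labels)
  cfg2 <- cohort_config(n_group_a = 2, n_group_b = 2, grid_shape = c(6, 6, 2),
                        n_timepoints = 40, rng_seed = 8)
  expect_false(identical(generate_bold_cohort(cfg2)$subjects[[1]]$series$data,
                         a$subjects[[1]]$series$data))
})

test_that("planted correlation is calibrated at long runs", {
  cfg <- cohort_config(n_group_a = 1, n_group_b = 1, grid_shape = c(6, 6, 2),
                       n_timepoints = 2000, planted_corr_a = 0,
                       planted_corr_b = 0.6, nuisance_amplitude = 0,
                       rng_seed = 7)
  co <- generate_bold_cohort(cfg)
  m1 <- which(co$parcellation$labels == 1)
  m2 <- which(co$parcellation$labels == 2)
  cross_corr <- function(series) {
    d <- dim(series$data)
    flat <- matrix(series$data, prod(d[1:3]), d[4])
    mean(stats::cor(t(flat[m1, ]), t(flat[m2, ])))
  }
  expect_lt(abs(cross_corr(co$subjects[[1]]$series) - 0), 0.1)
  expect_lt(abs(cross_corr(co$subjects[[2]]$series) - 0.6), 0.1)
})

test_that("cohort emits 6-column motion traces and a ventricular compartment", {
  cfg <- cohort_config(n_group_a = 1, n_group_b = 1, grid_shape = c(8, 8, 2),
                       n_timepoints = 60, rng_seed = 3)
  co <- generate_bold_cohort(cfg)
  for (s in co$subjects) {
    expect_equal(dim(s$motion), c(60L, 6L))
  }
  expect_true(any(co$ventricle_mask))
  # the ventricular signal is shared: mean corr between ventricle voxels and
  # the ventricle mean should exceed the brain-wide average
  s <- co$subjects[[1]]$series
  vent_mean <- mean_signal(s, co$ventricle_mask)
  d <- dim(s$data)
  flat <- matrix(s$data, prod(d[1:3]), d[4])
  r_vent <- mean(stats::cor(t(flat[which(co$ventricle_mask), , drop = FALSE]),
                            vent_mean))
  r_all <- mean(stats::cor(t(flat), vent_mean))
  expect_gt(r_vent, r_all)
})

test_that("cohort rejects a planted pair missing from the parcellation", {
  cfg <- cohort_config(n_group_a = 1, n_group_b = 1, grid_shape = c(6, 6, 1),
                       n_timepoints = 40, n_regions = 4, rng_seed = 1)
  parc <- generate_parcellation(c(6, 6, 1), 2, rng_seed = 1)
  cfg$planted_pair <- c(1L, 4L)
  expect_error(generate_bold_cohort(cfg, parc = parc), "missing")
  expect_error(cohort_config(planted_corr_a = 1.2), "\\(-1, 1\\)")
  expect_error(cohort_config(grid_shape = c(0, 4, 4)), "positive")
})

test_that("parcellation covers the grid with connected labelled blocks", {
  p <- generate_parcellation(c(4, 4, 1), 2, rng_seed = 1)
  expect_setequal(unique(as.integer(p$labels)), c(1L, 2L))
  expect_true(all(p$regions$n_voxels >= 1))
  # pigeonhole: as many regions as voxels -> singletons
  p1 <- generate_parcellation(c(4, 4, 1), 16, rng_seed = 2)
  expect_true(all(tabulate(p1$labels) == 1L))
  # determinism
  expect_identical(generate_parcellation(c(5, 4, 3), 7, rng_seed = 9)$labels,
                   generate_parcellation(c(5, 4, 3), 7, rng_seed = 9)$labels)
  # every region is one 6-connected component, across shapes and counts
  for (shape in list(c(7, 5, 3), c(20, 20, 4), c(3, 3, 1))) {
    for (k in c(2, 5, min(9, prod(shape)))) {
      parc <- generate_parcellation(shape, k, rng_seed = k)
      for (lab in parc$regions$label) {
        comp <- label_clusters(parc$labels == lab)
        expect_equal(max(comp), 1L)
      }
    }
  }
  expect_error(generate_parcellation(c(2, 2, 1), 5, rng_seed = 1), "infeasible")
})

test_that("expression generator plants a recoverable enriched set", {
  cfg <- planted_expression_config(n_genes = 500, enrichment_effect = 5,
                                   rng_seed = 5)
  ex <- generate_expression_matrix(cfg)
  expect_true(all(ex$matrix$energies >= 0))
  expect_true(all(unlist(ex$gene_sets) %in% ex$matrix$gene_ids))
  nm <- normalize_by_total(ex$matrix)
  # brute-force re-selection: top 20% of each focal column, intersected
  top20 <- function(label) {
    v <- nm$energies[, label]
    names(sort(v, decreasing = TRUE))[seq_len(ceiling(0.2 * length(v)))]
  }
  sel <- intersect(top20("1"), top20("2"))
  expect_gte(mean(ex$planted_genes %in% sel), 0.8)
  # determinism
  ex2 <- generate_expression_matrix(cfg)
  expect_identical(ex$matrix$energies, ex2$matrix$energies)
  expect_identical(ex$gene_sets, ex2$gene_sets)
})

test_that("a unit enrichment effect plants nothing detectable", {
  cfg <- planted_expression_config(n_genes = 400, enrichment_effect = 1,
                                   rng_seed = 11)
  ex <- generate_expression_matrix(cfg)
  nm <- normalize_by_total(ex$matrix)
  focal <- rowMeans(nm$energies[, c("1", "2")])
  in_set <- nm$gene_ids %in% ex$planted_genes
  se <- stats::sd(focal) * sqrt(1 / sum(in_set) + 1 / sum(!in_set))
  expect_lt(abs(mean(focal[in_set]) - mean(focal[!in_set])), 2 * se)
})

test_that("DEG tables realize the requested overlap exactly", {
  gen <- generate_deg_table(100, 20, 10, 5, rng_seed = 4)
  tab <- build_contingency(gen$deg_genes, gen$risk_genes, gen$universe)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(5, 15, 5, 75))
  # the table's padj column reproduces the DEG set
  expect_setequal(gen$deg_table$gene_id[gen$deg_table$padj < 0.05],
                  gen$deg_genes)
  g0 <- generate_deg_table(50, 10, 8, 0, rng_seed = 1)
  expect_length(intersect(g0$deg_genes, g0$risk_genes), 0)
  gfull <- generate_deg_table(50, 10, 8, 8, rng_seed = 1)
  expect_true(all(gfull$risk_genes %in% gfull$deg_genes))
  expect_error(generate_deg_table(50, 10, 8, 9, rng_seed = 1), "overlap")
  expect_error(generate_deg_table(10, 8, 8, 0, rng_seed = 1), "infeasible")
})

test_that("cohort round-trips through NIfTI + TSV + JSON", {
  cfg <- cohort_config(n_group_a = 1, n_group_b = 1, grid_shape = c(5, 4, 2),
                       n_timepoints = 30, rng_seed = 2)
  co <- generate_bold_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$subjects[[1]]$series$data, co$subjects[[1]]$series$data,
               tolerance = 1e-6)
  expect_equal(back$subjects[[2]]$motion, co$subjects[[2]]$motion,
               tolerance = 1e-6)
  expect_identical(back$parcellation$labels, co$parcellation$labels)
  expect_equal(vapply(back$subjects, `[[`, "", "group"),
               vapply(co$subjects, `[[`, "", "group"))
})

test_that("expression matrix and gene sets round-trip through TSV / GMT", {
  ex <- generate_expression_matrix(planted_expression_config(
    n_genes = 40, n_regions = 5, enriched_set_size = 8, n_decoy_sets = 2,
    rng_seed = 3))
  dir <- withr::local_tempdir()
  write_expression_matrix(ex$matrix, file.path(dir, "expr.tsv"))
  back <- read_expression_matrix(file.path(dir, "expr.tsv"))
  expect_equal(back$energies, ex$matrix$energies, tolerance = 1e-12)
  write_gmt(ex$gene_sets, file.path(dir, "sets.gmt"))
  expect_equal(read_gmt(file.path(dir, "sets.gmt")), ex$gene_sets,
               ignore_attr = TRUE)
})
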
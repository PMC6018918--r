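test_that("regional energy extraction averages volumes under the parcellation", {
  labels <- array(c(1L, 1L, 2L, 2L, 2L, 1L), c(3, 2, 1))
  parc <- parcellation(labels)
  vol_u <- array(3, c(3, 2, 1))
  vol_v <- array(c(1, 2, 3, 4, 5, 6), c(3, 2, 1))
  em <- expression_energy_by_region(list(gU = vol_u, gV = vol_v), parc)
  expect_equal(unname(em$energies["gU", ]), c(3, 3))
  expect_equal(unname(em$energies["gV", c("1", "2")]),
               c(mean(c(1, 2, 6)), mean(c(3, 4, 5))))
  expect_error(expression_energy_by_region(list(g = vol_u), parc, regions = 7),
               "7")
  expect_error(expression_energy_by_region(list(g = array(1, c(2, 2, 1))), parc),
               "grid")
})

test_that("per-gene normalization divides by row totals and drops zero rows", {
  e <- rbind(gA = c(1, 1, 1, 1), gB = c(2, 0, 0, 2), gZ = c(0, 0, 0, 0))
  colnames(e) <- paste0("r", 1:4)
  em <- expression_matrix(e)
  expect_message(nm <- normalize_by_total(em), "zero total")
  expect_equal(unname(nm$energies["gA", ]), rep(0.25, 4))
  expect_false("gZ" %in% nm$gene_ids)
  expect_true(all(abs(rowSums(nm$energies) - 1) < 1e-9))
  # elementwise oracle on a random matrix
  set.seed(17)
  r <- matrix(rexp(60), 12, 5,
              dimnames = list(sprintf("g%02d", 1:12), paste0("r", 1:5)))
  nr <- normalize_by_total(expression_matrix(r))
  expect_equal(nr$energies, r / rowSums(r), tolerance = 1e-12)
  expect_error(normalize_by_total(nr), "already")
})

test_that("top-quantile intersection matches a brute-force double sort", {
  set.seed(23)
  e <- matrix(runif(20), 10, 2,
              dimnames = list(sprintf("g%02d", 1:10), c("1", "2")))
  nm <- normalize_by_total(expression_matrix(e))
  got <- top_quantile_intersection(nm, c("1", "2"), q = 0.3)
  k <- ceiling(0.3 * 10)
  brute <- intersect(
    rownames(e)[order(-nm$energies[, "1"], rownames(e))][1:k],
    rownames(e)[order(-nm$energies[, "2"], rownames(e))][1:k]
  )
  expect_setequal(got, brute)
  # q = 1 keeps everything; identical columns reduce to a single top list
  expect_setequal(top_quantile_intersection(nm, c("1", "2"), q = 1),
                  rownames(e))
  e2 <- cbind(e[, 1], e[, 1]); colnames(e2) <- c("1", "2")
  nm2 <- normalize_by_total(expression_matrix(e2))
  expect_setequal(top_quantile_intersection(nm2, c("1", "2"), q = 0.2),
                  rownames(e)[order(-nm2$energies[, "1"], rownames(e))][1:2])
  expect_error(top_quantile_intersection(nm, c("1", "9")), "9")
  expect_error(top_quantile_intersection(expression_matrix(e), c("1", "2")),
               "normalized")
})

test_that("L1 ranking is the descending pair-sum with deterministic ties", {
  e <- rbind(gOnly1 = c(10, 0, 0), gBoth = c(3, 3, 4), gLow = c(1, 1, 8))
  colnames(e) <- c("1", "2", "3")
  nm <- normalize_by_total(expression_matrix(e))
  rl <- l1_rank(nm, c("1", "2"))
  expect_equal(rl$gene_id[1], "gOnly1")      # score 1 beats any total < 1
  expect_equal(rl$score, sort(rl$score, decreasing = TRUE))
  # permutation invariance of input row order
  nm2 <- normalize_by_total(expression_matrix(e[c(3, 1, 2), ]))
  expect_equal(l1_rank(nm2, c("1", "2")), rl)
  # independent sort oracle on a random matrix
  set.seed(29)
  r <- matrix(runif(40), 8, 5,
              dimnames = list(sprintf("g%02d", 1:8), as.character(1:5)))
  nr <- normalize_by_total(expression_matrix(r))
  rl2 <- l1_rank(nr, c("2", "4"))
  sc <- nr$energies[, "2"] + nr$energies[, "4"]
  expect_equal(rl2$gene_id, names(sort(sc, decreasing = TRUE)))
})

test_that("hypergeometric tails match enumeration", {
  expect_equal(hypergeometric_tail(0, 10, 4, 3), 1)
  expect_equal(hypergeometric_tail(3, 10, 2, 3), 0)
  expect_equal(hypergeometric_tail(2, 10, 4, 3), 1 / 3, tolerance = 1e-12)
  expect_error(hypergeometric_tail(4, 10, 4, 3), "require")
})

test_that("mHG statistic and exact p match full enumeration for small lists", {
  # targets at the very top of a 4-list
  r <- mhg_enrichment(c("a", "b", "c", "d"), c("a", "b"))
  expect_equal(r$statistic, 1 / 6, tolerance = 1e-12)
  expect_equal(r$optimal_rank, 2L)
  expect_equal(r$exact_p, 1 / 6, tolerance = 1e-12)
  # targets at the bottom are unenriched
  rb <- mhg_enrichment(paste0("g", 1:8), c("g7", "g8"))
  expect_gte(rb$exact_p, 0.5)
  expect_equal(rb$exact_p, mhg_enum_p(8, 2, rb$statistic), tolerance = 1e-12)
  # random placements, N <= 8: DP equals enumeration exactly
  set.seed(37)
  for (i in 1:12) {
    N <- sample(4:8, 1); B <- sample(2:(N - 1), 1)
    genes <- paste0("g", 1:N)
    targets <- sample(genes, B)
    r2 <- mhg_enrichment(genes, targets)
    expect_equal(r2$exact_p, mhg_enum_p(N, B, r2$statistic), tolerance = 1e-12)
  }
})

test_that("mHG exact p agrees with a permutation estimate and obeys its bounds", {
  set.seed(43)
  N <- 60; B <- 8
  genes <- paste0("g", 1:N)
  targets <- sample(genes, B)
  res <- mhg_enrichment(genes, targets)
  n_sh <- 10000
  hits <- withr::with_seed(7, {
    sum(replicate(n_sh, {
      ind <- rep(FALSE, N); ind[sample(N, B)] <- TRUE
      mhg_stat_oracle(ind) <= res$statistic * (1 + 1e-10)
    }))
  })
  p_mc <- hits / n_sh
  se <- sqrt(p_mc * (1 - p_mc) / n_sh)
  expect_lt(abs(res$exact_p - p_mc), 3 * se + 1e-12)
  # bounds: statistic <= exact_p <= N * statistic
  for (i in 1:8) {
    tg <- sample(genes, sample(3:10, 1))
    r <- mhg_enrichment(genes, tg)
    expect_gte(r$exact_p, r$statistic - 1e-12)
    expect_lte(r$exact_p, min(1, N * r$statistic) + 1e-12)
  }
})

test_that("adding a target at rank 1 never increases the exact p", {
  set.seed(47)
  for (i in 1:6) {
    N <- 30
    genes <- paste0("g", 1:N)
    targets <- sample(genes[2:N], 5)
    p0 <- mhg_enrichment(genes, targets)$exact_p
    p1 <- mhg_enrichment(genes, c(genes[1], targets))$exact_p
    expect_lte(p1, p0 + 1e-12)
  }
})

test_that("decode_pair favors a set equal to the selection and ranks the planted set first", {
  ex <- generate_expression_matrix(planted_expression_config(rng_seed = 5))
  nm <- normalize_by_total(ex$matrix)
  sel <- top_quantile_intersection(nm, c("1", "2"))
  sets <- list(exact_match = sel,
               random_same_size = sample(nm$gene_ids, length(sel)))
  res <- decode_pair(nm, c("1", "2"), sets)
  fixed <- res[res$mode == "intersection", ]
  expect_lt(fixed$p_value[fixed$set_name == "exact_match"],
            fixed$p_value[fixed$set_name == "random_same_size"])
  # planted matrix: smallest q in both modes
  res2 <- decode_pair(nm, c("1", "2"), ex$gene_sets)
  for (m in c("intersection", "ranked")) {
    sub <- res2[res2$mode == m, ]
    expect_equal(sub$set_name[which.min(sub$q_value)], "planted_set")
  }
})

test_that("random pair control is seeded and keeps the focal row first", {
  ex <- generate_expression_matrix(planted_expression_config(
    n_genes = 120, n_regions = 8, enriched_set_size = 20, n_decoy_sets = 3,
    rng_seed = 9))
  nm <- normalize_by_total(ex$matrix)
  ctl <- random_pair_control(nm, ex$gene_sets, c("1", "2"), n_pairs = 4,
                             rng_seed = 11)
  ctl2 <- random_pair_control(nm, ex$gene_sets, c("1", "2"), n_pairs = 4,
                              rng_seed = 11)
  expect_equal(ctl, ctl2)
  expect_true(ctl$focal[1])
  expect_equal(nrow(ctl), 5L)
  # no control row repeats the focal pair
  expect_false(any(ctl$region_1[-1] %in% "1" & ctl$region_2[-1] %in% "2"))
  # n_pairs = 0 -> focal row only
  solo <- random_pair_control(nm, ex$gene_sets, c("1", "2"), n_pairs = 0)
  expect_equal(nrow(solo), 1L)
  expect_error(random_pair_control(nm, ex$gene_sets, c("1", "2"),
                                   n_pairs = 999), "cannot draw")
})
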
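test_that("site filters remove low-coverage and low-MAF sites by allele count", {
  # m1: 10% called -> dropped; m2: monomorphic AA -> MAF 0, dropped;
  # m3: 1 AB in 100 AA plants -> MAF 0.005 dropped; m4: 2 AB -> 0.01 kept
  calls <- cbind(c(1L, rep(NA_integer_, 99)),
                 rep(1L, 100),
                 c(2L, rep(1L, 99)),
                 c(2L, 2L, rep(1L, 98)))
  gm <- make_gm(calls)
  kept <- site_filters(gm, filter_config())
  expect_equal(marker_map(kept)$marker, "m4")
})

test_that("missingness filter drops > 20% and imputes the rest to AB, idempotently", {
  calls <- cbind(c(rep(NA_integer_, 3), rep(1L, 7)),   # 30% missing -> drop
                 c(rep(NA_integer_, 2), rep(3L, 8)),   # 20% missing -> keep + impute
                 rep(1L, 10))                          # complete -> unchanged
  gm <- make_gm(calls)
  out <- missingness_filter_impute(gm, filter_config())
  expect_equal(ncol(out), 2)
  expect_false(anyNA(unclass(out)))
  expect_equal(unname(unclass(out)[1:2, 1]), c(2L, 2L))  # imputed het
  expect_equal(unname(unclass(out)[, 2]), rep(1L, 10))
  twice <- missingness_filter_impute(out, filter_config())
  expect_identical(unclass(twice), unclass(out))
})

test_that("model filter: exact-fit SNP kept with chi2 = 0; BB regrowth plant forces rejection", {
  # 12 R plants split (4 AA, 8 AB, 0 BB); 14 NR split (2, 4, 8): exact 9:7 fit
  calls_fit <- c(rep(1L, 4), rep(2L, 8), rep(1L, 2), rep(2L, 4), rep(3L, 8))
  # same but one R plant is BB: expected count 0 cell occupied
  calls_bad <- calls_fit; calls_bad[1] <- 3L
  gm <- make_gm(cbind(calls_fit, calls_bad), pos = c(1e6, 2e6))
  ph <- pheno_table(rownames(gm), c(rep("R", 12), rep("NR", 14)))
  d <- make_dataset(gm, ph, quiet = TRUE)
  fits <- model_fit_filter(d, cfg = filter_config())
  expect_equal(fits$chi2[1], 0)
  expect_true(fits$keep[1])
  expect_equal(fits$chi2[2], Inf)
  expect_false(fits$keep[2])
})

test_that("an unlinked 1:2:1 SNP is rejected through the empty BB-regrowth cell", {
  calls <- c(rep(1L, 16), rep(2L, 31), rep(3L, 16),  # R: 16/31/16
             rep(1L, 12), rep(2L, 25), rep(3L, 12))  # NR: 12/25/12
  gm <- make_gm(matrix(calls, ncol = 1))
  ph <- pheno_table(rownames(gm), c(rep("R", 63), rep("NR", 49)))
  fits <- model_fit_filter(make_dataset(gm, ph, quiet = TRUE))
  expect_equal(fits$chi2, Inf)
  expect_false(fits$keep)
})

test_that("model-filter chi2 agrees with a brute-force six-cell oracle", {
  set.seed(77)
  n_R <- 46; n_NR <- 37
  for (i in 1:200) {
    g_R <- sample(1:3, n_R, replace = TRUE, prob = c(0.33, 0.66, 0.01))
    g_NR <- sample(1:3, n_NR, replace = TRUE)
    gm <- make_gm(matrix(c(g_R, g_NR), ncol = 1))
    ph <- pheno_table(rownames(gm), rep(c("R", "NR"), c(n_R, n_NR)))
    fits <- model_fit_filter(make_dataset(gm, ph, quiet = TRUE))
    oracle <- chi2_6cell_oracle(tabulate(g_R, 3), tabulate(g_NR, 3))
    if (is.infinite(oracle)) expect_equal(fits$chi2, Inf)
    else expect_equal(fits$chi2, oracle, tolerance = 1e-9)
  }
})

test_that("model filter requires imputed input and both phenotype classes", {
  gm <- make_gm(matrix(c(1L, NA), 2, 1))
  ph <- pheno_table(rownames(gm), c("R", "NR"))
  expect_error(model_fit_filter(make_dataset(gm, ph, quiet = TRUE)), "missing calls")
  gm2 <- make_gm(matrix(1L, 2, 1))
  expect_error(model_fit_filter(make_dataset(gm2, pheno_table(rownames(gm2), c("R", "R")),
                                             quiet = TRUE)),
               "phenotype classes")
})

test_that("cluster collapsing follows the first-member window rule", {
  v <- c(1L, 2L, 3L, 2L)
  # identical vectors at 100/180/195 -> one cluster anchored at 100
  gm <- make_gm(matrix(v, 4, 3), pos = c(100, 180, 195))
  cc <- collapse_clusters(gm, filter_config())
  expect_equal(ncol(cc$geno), 1)
  expect_equal(marker_map(cc$geno)$pos_bp, 100)
  expect_equal(cc$clusters$n_members, 3)

  # 100/150/260: 260 is beyond 100 bp from the anchor -> two clusters
  gm2 <- make_gm(matrix(v, 4, 3), pos = c(100, 150, 260))
  cc2 <- collapse_clusters(gm2, filter_config())
  expect_equal(marker_map(cc2$geno)$pos_bp, c(100, 260))

  # differing vectors never collapse, however close
  w <- c(1L, 2L, 3L, 3L)
  gm3 <- make_gm(unname(cbind(v, w)), pos = c(100, 101))
  expect_equal(ncol(collapse_clusters(gm3, filter_config())$geno), 2)
})

test_that("collapsed output has no identical adjacent columns within the window", {
  set.seed(99)
  for (i in 1:5) {
    calls <- matrix(sample(1:3, 30 * 40, replace = TRUE, prob = c(1, 2, 1)), 30, 40)
    calls[, 2] <- calls[, 1]; calls[, 17] <- calls[, 16]
    gm <- make_gm(calls, pos = sort(sample.int(2000, 40)))
    out <- collapse_clusters(gm, filter_config())$geno
    oc <- unclass(out); om <- marker_map(out)
    for (j in seq_len(ncol(oc) - 1)) {
      if (om$chrom[j] == om$chrom[j + 1] &&
          om$pos_bp[j + 1] - om$pos_bp[j] <= 100)
        expect_false(identical(oc[, j], oc[, j + 1]))
    }
  }
})

test_that("the cascade runs in order, only removing or imputing, with stable counts", {
  sim <- simulate_f2_population(120, tiny_genome(markers_per_chrom = 15),
                                tiny_causal(), noise_spec(), seed = 61)
  casc <- run_filter_cascade(sim$dataset)
  cn <- casc$counts
  expect_true(all(cn$n_stage1 <= cn$n_input))
  expect_true(all(cn$n_stage2 <= cn$n_stage1))
  expect_true(all(cn$n_stage3 <= cn$n_stage2))
  expect_true(all(cn$n_stage4 <= cn$n_stage3))
  # stage 2 output fully called; surviving calls unaltered except imputation
  g2 <- unclass(casc$dataset_stage2$geno)
  expect_false(anyNA(g2))
  g0 <- unclass(sim$dataset$geno)
  common <- intersect(colnames(g0), colnames(g2))
  was_called <- !is.na(g0[, common])
  expect_identical(g2[, common][was_called], g0[, common][was_called])
  # deterministic
  casc2 <- run_filter_cascade(sim$dataset)
  expect_identical(casc$counts, casc2$counts)
  # complete data: stage 2 removes nothing
  sim_c <- simulate_f2_population(60, tiny_genome(markers_per_chrom = 10),
                                  tiny_causal(), no_noise(), seed = 62)
  cc <- run_filter_cascade(sim_c$dataset)
  expect_equal(cc$counts$n_stage2, cc$counts$n_stage1)
})
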
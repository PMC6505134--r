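test_that("Haldane conversions match the closed form and invert each other", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(10), (1 - exp(-0.2)) / 2, tolerance = 1e-12)
  d <- seq(0, 200, by = 7.3)
  expect_equal(haldane_cM(haldane_r(d)), d, tolerance = 1e-9)
  expect_error(haldane_cM(0.5), "0.5")
})

test_that("physical map mode converts at 1 cM per Mbp; single markers are fine", {
  mp <- data.frame(marker = c("a", "b"), chrom = c("1", "2"),
                   pos_bp = c(5e6, 1e6))
  gmap <- build_genetic_map(mp)
  expect_equal(gmap$pos_cM, c(5, 1))
  one <- build_genetic_map(data.frame(marker = "a", chrom = "1", pos_bp = 2e6))
  expect_equal(nrow(one), 1)
})

test_that("EM-estimated adjacent recombination matches the simulation truth", {
  sim <- simulate_f2_population(4000, tiny_genome(n_chrom = 1, markers_per_chrom = 6),
                                causal_model(loci = data.frame(chrom = "1", pos_bp = 5e7)),
                                no_noise(), seed = 71)
  g <- sim$dataset$geno
  gmap <- build_genetic_map(marker_map(g), mode = "em_estimated", g = g)
  true_cM <- marker_map(g)$pos_bp * 1e-6
  d_est <- diff(gmap$pos_cM); d_true <- diff(true_cM)
  # each adjacent distance within 3 SE of truth (delta method on binomial r)
  for (a in seq_along(d_est)) {
    r <- haldane_r(d_true[a])
    se_r <- sqrt(r * (1 - r) / (2 * 4000))
    se_d <- se_r * 100 / (1 - 2 * r)
    expect_lt(abs(d_est[a] - d_true[a]), 3 * se_d + 0.05)
  }
})

test_that("genotype probabilities: single-site posteriors match the Bayes oracle", {
  gm <- make_gm(matrix(c(1L, NA), 2, 1))
  d <- make_dataset(gm, pheno_table(rownames(gm), c("R", "NR")), quiet = TRUE)
  eps <- 1e-4
  gp <- calc_genoprob(d, cfg = scan_config(error_prob = eps))
  post <- gp$chrom[["1"]]$probs
  prior <- c(0.25, 0.5, 0.25)
  lik_AA <- c(1 - eps, eps / 2, eps / 2)
  oracle <- prior * lik_AA / sum(prior * lik_AA)
  expect_equal(unname(post[1, 1, ]), oracle, tolerance = 1e-12)
  expect_equal(unname(post[2, 1, ]), prior)  # missing call: the prior
})

test_that("genotype probability triples normalize and sharpen as error vanishes", {
  sim <- simulate_f2_population(40, tiny_genome(markers_per_chrom = 8),
                                tiny_causal(), no_noise(), seed = 81)
  gp <- calc_genoprob(sim$dataset, cfg = scan_config(error_prob = 1e-8))
  for (blk in gp$chrom) {
    sums <- apply(blk$probs, c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    # at real markers with complete data the posterior concentrates on the call
    mk <- which(blk$grid$is_marker)
    calls <- unclass(sim$dataset$geno)[, marker_map(sim$dataset$geno)$chrom ==
                                         blk$grid$chrom[1], drop = FALSE]
    for (i in 1:5) for (jm in seq_along(mk)) {
      expect_gt(blk$probs[i, mk[jm], calls[i, jm]], 1 - 1e-4)
    }
  }
})

test_that("pseudomarkers keep grid spacing at or under the step", {
  sim <- simulate_f2_population(10, tiny_genome(markers_per_chrom = 5),
                                tiny_causal(), no_noise(), seed = 82)
  gp <- calc_genoprob(sim$dataset, cfg = scan_config(step = 1))
  for (blk in gp$chrom) {
    expect_true(all(diff(blk$grid$pos_cM) <= 1 + 1e-9))
    expect_false(any(blk$grid$is_marker & is.na(blk$grid$pos_bp)))
  }
})

test_that("scan LOD at a fully informative marker equals the closed form", {
  geno <- matrix(c(rep(1L, 4), rep(2L, 8), rep(3L, 4)), ncol = 1,
                 dimnames = list(sprintf("p%d", 1:16), NULL))
  y <- as.integer(geno[, 1] != 3L)  # R iff carries a Zd allele
  gp <- degenerate_genoprob(geno)
  sc <- scan_binary_em(gp, pheno_table(rownames(geno), ifelse(y == 1, "R", "NR")),
                       scan_config())
  lod_closed <- (-12 * log(0.75) - 4 * log(0.25)) / log(10)
  expect_equal(sc$lod, lod_closed, tolerance = 1e-6)
  # grid oracle resolves pi to 1e-4, so agreement is at grid resolution
  expect_equal(sc$lod, binary_lod_oracle(geno[, 1], y), tolerance = 1e-3)
  # penetrance estimates recover the deterministic rule
  expect_gt(sc$pi_AA, 0.999); expect_gt(sc$pi_AB, 0.999); expect_lt(sc$pi_BB, 0.001)
})

test_that("constant phenotype yields an identically zero LOD profile", {
  sim <- simulate_f2_population(30, tiny_genome(markers_per_chrom = 6),
                                tiny_causal(), no_noise(), seed = 83)
  ph <- pheno_table(sim$dataset$pheno$plant, rep("R", 30))
  gp <- calc_genoprob(sim$dataset, cfg = scan_config())
  sc <- scan_binary_em(gp, ph, scan_config())
  expect_true(all(sc$lod == 0))
  th <- suppressWarnings(permutation_threshold(gp, ph, scan_config(n_permutations = 20)))
  expect_equal(th$threshold, 0)
})

test_that("permutation thresholds are seeded, monotone in alpha, and id-invariant", {
  sim <- simulate_f2_population(50, tiny_genome(markers_per_chrom = 6),
                                tiny_causal(), noise_spec(), seed = 84)
  d <- sim$dataset
  gp <- calc_genoprob(d, cfg = scan_config())
  cfg5 <- scan_config(n_permutations = 40, alpha = 0.05, seed = 9)
  cfg10 <- scan_config(n_permutations = 40, alpha = 0.10, seed = 9)
  t5 <- suppressWarnings(permutation_threshold(gp, d$pheno, cfg5))
  t5b <- suppressWarnings(permutation_threshold(gp, d$pheno, cfg5))
  t10 <- suppressWarnings(permutation_threshold(gp, d$pheno, cfg10))
  expect_identical(t5$maxima, t5b$maxima)
  expect_gte(t5$threshold, t10$threshold)
  # relabeling plants consistently changes nothing
  d2 <- d
  new_ids <- paste0("plant_", seq_len(nrow(d2$geno)))
  rownames(attr(d2$geno, "map")) <- NULL
  g2 <- unclass(d2$geno); rownames(g2) <- new_ids
  d2 <- make_dataset(geno_matrix(g2, marker_map(d2$geno)),
                     pheno_table(new_ids, as.character(d$pheno$phenotype)),
                     quiet = TRUE)
  gp2 <- calc_genoprob(d2, cfg = scan_config())
  t5c <- suppressWarnings(permutation_threshold(gp2, d2$pheno, cfg5))
  expect_equal(t5$threshold, t5c$threshold)
})

test_that("interval calling selects first/last significant SNP and leftmost peak", {
  geno <- matrix(rep(c(1L, 2L, 3L), length.out = 10 * 5), 10, 5,
                 dimnames = list(sprintf("p%d", 1:10), NULL))
  gp <- degenerate_genoprob(geno, pos_bp = (1:5) * 1e6)
  sc <- scan_binary_em(gp, pheno_table(rownames(geno), rep(c("R", "NR"), 5)),
                       scan_config())
  fake <- sc
  fake$lod <- c(1.0, 6.0, 7.0, 6.0, 2.0)
  iv <- call_intervals(fake, 5.23)
  expect_equal(iv$start_bp, 2e6)
  expect_equal(iv$end_bp, 4e6)
  expect_equal(iv$peak_bp, 3e6)
  expect_equal(nrow(call_intervals(fake, 99)), 0)
  # leftmost peak on ties
  fake$lod <- c(1.0, 7.0, 7.0, 6.0, 2.0)
  expect_equal(call_intervals(fake, 5)$peak_bp, 2e6)
})

test_that("scan recovers both planted loci on clean simulated data", {
  sim <- simulate_f2_population(250, tiny_genome(markers_per_chrom = 20),
                                tiny_causal(), no_noise(), seed = 85)
  d <- sim$dataset
  cfg <- scan_config(n_permutations = 100, seed = 3)
  gp <- calc_genoprob(d, cfg = cfg)
  sc <- scan_binary_em(gp, d$pheno, cfg)
  th <- permutation_threshold(gp, d$pheno, cfg)
  iv <- call_intervals(sc, th)
  expect_equal(sort(iv$chrom), c("1", "2"))
  for (k in 1:2) {
    pk <- iv$peak_bp[iv$chrom == tiny_causal()$loci$chrom[k]]
    expect_lt(abs(pk - tiny_causal()$loci$pos_bp[k]) * 1e-6, 15)
  }
})
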
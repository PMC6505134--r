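test_that("gametes from a zero-length map are one unrecombined parental haplotype", {
  haps <- rbind(rep(1L, 5), rep(2L, 5))
  set.seed(3)
  for (i in 1:10) {
    g <- simulate_gamete(haps, seq(0, 0, length.out = 5), 0)
    expect_true(all(g == 1L) || all(g == 2L))
  }
})

test_that("recombinant fraction over 10 cM matches Haldane's closed form", {
  haps <- rbind(c(1L, 1L), c(2L, 2L))
  set.seed(7)
  n <- 40000
  rec <- logical(n)
  for (i in seq_len(n)) {
    g <- simulate_gamete(haps, c(0, 10), 10)
    rec[i] <- g[1] != g[2]
  }
  r_exp <- (1 - exp(-0.2)) / 2
  expect_lt(abs(mean(rec) - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / n))
})

test_that("same seed gives identical gametes and byte-identical populations", {
  haps <- rbind(rep(1L, 8), rep(2L, 8))
  set.seed(42); g1 <- simulate_gamete(haps, 1:8 * 10, 90)
  set.seed(42); g2 <- simulate_gamete(haps, 1:8 * 10, 90)
  expect_identical(g1, g2)
  s1 <- simulate_f2_population(30, tiny_genome(), tiny_causal(), noise_spec(), seed = 5)
  s2 <- simulate_f2_population(30, tiny_genome(), tiny_causal(), noise_spec(), seed = 5)
  expect_identical(unclass(s1$dataset$geno), unclass(s2$dataset$geno))
  expect_identical(s1$dataset$pheno, s2$dataset$pheno)
  expect_identical(s1$truth$causal_genotypes, s2$truth$causal_genotypes)
})

test_that("F2 regrowth fraction matches (3/4)^k and the misclassification algebra", {
  n <- 20000
  # k = 2, clean: 9/16
  s2 <- simulate_f2_population(n, tiny_genome(markers_per_chrom = 2), tiny_causal(),
                               no_noise(), seed = 11)
  p <- 9 / 16
  expect_lt(abs(mean(s2$dataset$pheno$phenotype == "R") - p),
            3 * sqrt(p * (1 - p) / n))
  # k = 1: 3/4
  c1 <- causal_model(loci = data.frame(chrom = "1", pos_bp = 3e7))
  s1 <- simulate_f2_population(n, tiny_genome(markers_per_chrom = 2), c1,
                               no_noise(), seed = 12)
  expect_lt(abs(mean(s1$dataset$pheno$phenotype == "R") - 3 / 4),
            3 * sqrt(3 / 4 * 1 / 4 / n))
  # delta and reverse error shift the observed fraction to
  # (3/4)^k (1 - delta) + (1 - (3/4)^k) reverse
  cm <- causal_model(loci = tiny_causal()$loci,
                     misclassification_delta = 0.2, reverse_error = 0.1)
  sm <- simulate_f2_population(n, tiny_genome(markers_per_chrom = 2), cm,
                               no_noise(), seed = 13)
  pexp <- 9 / 16 * 0.8 + 7 / 16 * 0.1
  expect_lt(abs(mean(sm$dataset$pheno$phenotype == "R") - pexp),
            3 * sqrt(pexp * (1 - pexp) / n))
  # any plant BB at a causal locus is NR when delta = 0
  expect_true(all(s2$dataset$pheno$phenotype[
    apply(s2$truth$causal_genotypes == 3L, 1, any)] == "NR"))
})

test_that("neutral markers segregate 1:2:1 in a large F2", {
  s <- simulate_f2_population(8000, tiny_genome(n_chrom = 1, markers_per_chrom = 3),
                              causal_model(loci = data.frame(chrom = "1", pos_bp = 99e6)),
                              no_noise(), seed = 21)
  calls <- unclass(s$dataset$geno)
  for (j in 1:ncol(calls)) {
    frac <- tabulate(calls[, j], 3) / nrow(calls)
    expect_lt(max(abs(frac - c(0.25, 0.5, 0.25))), 3 * sqrt(0.5 * 0.5 / nrow(calls)))
  }
})

test_that("adjacent-marker recombination decays per Haldane (slope ~ 1)", {
  s <- simulate_f2_population(3000, tiny_genome(n_chrom = 2, markers_per_chrom = 12),
                              tiny_causal(), no_noise(), seed = 31)
  calls <- unclass(s$dataset$geno)
  map <- marker_map(s$dataset$geno)
  obs <- c(); expd <- c()
  for (ch in unique(map$chrom)) {
    jj <- which(map$chrom == ch)
    for (a in seq_len(length(jj) - 1)) {
      obs <- c(obs, est_rf_f2(calls[, jj[a]], calls[, jj[a + 1]]))
      d_cM <- (map$pos_bp[jj[a + 1]] - map$pos_bp[jj[a]]) * 1e-6
      expd <- c(expd, haldane_r(d_cM))
    }
  }
  expect_gte(length(obs), 20)
  slope <- coef(lm(obs ~ expd))[2]
  expect_lt(abs(slope - 1), 0.15)
})

test_that("backcrosses: all regrow toward Zd; about 1/4 toward maize for k = 2", {
  bz <- simulate_backcross(500, tiny_genome(markers_per_chrom = 2), tiny_causal(),
                           "to_Zd", seed = 41)
  expect_true(all(bz$dataset$pheno$phenotype == "R"))
  n <- 20000
  bm <- simulate_backcross(n, tiny_genome(markers_per_chrom = 2), tiny_causal(),
                           "to_maize", seed = 42)
  expect_lt(abs(mean(bm$dataset$pheno$phenotype == "R") - 0.25),
            3 * sqrt(0.25 * 0.75 / n))
})

test_that("transmission distortion toward maize depresses backcross regrowth", {
  n <- 8000
  noise_d <- noise_spec(site_missing = 0, genotype_error_rate = 0,
                        distortion = list(chrom = "1", pos_bp = 3e7, beta = 0.9))
  bm <- simulate_backcross(n, tiny_genome(markers_per_chrom = 2), tiny_causal(),
                           "to_maize", noise = noise_d, seed = 43)
  frac <- mean(bm$dataset$pheno$phenotype == "R")
  # distorted locus transmits Zd with prob 0.1, the other 0.5: expect ~0.05
  expect_lt(frac, 0.25 - 3 * sqrt(0.25 * 0.75 / n))
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("GBS noise hits its target rates and zero noise is the identity", {
  gm <- make_gm(matrix(2L, 2000, 4), pos = c(1e6, 2e6, 3e6, 4e6))
  set.seed(51)
  noisy <- apply_gbs_noise(gm, noise_spec(site_missing = 0.5,
                                          genotype_error_rate = 0))
  miss <- colMeans(is.na(unclass(noisy)))
  expect_true(all(abs(miss - 0.5) < 3 * sqrt(0.25 / 2000)))

  expect_identical(calls_of(apply_gbs_noise(gm, no_noise())), calls_of(gm))

  set.seed(52)
  flipped <- apply_gbs_noise(gm, noise_spec(site_missing = 0, genotype_error_rate = 1))
  expect_true(all(calls_of(flipped) %in% c(1L, 3L)))  # no AB survives
})
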
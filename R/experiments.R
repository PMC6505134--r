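#' Parameter-recovery experiment for the genome scan
#'
#' Simulates replicate F2 populations under the two-locus complementary
#' dominant model (no phenotype misclassification; GBS-like missingness and
#' epsilon-level genotyping error), runs the pipeline's scan path on each
#' (site/missingness filters with heterozygote imputation, HMM genotype
#' probabilities, EM scan, permutation threshold), and scores whether the
#' called significant intervals sit on exactly the two planted chromosomes
#' with peaks within `tol_cM` of the planted loci.
#'
#' @param n_reps number of replicate simulations.
#' @param n plants per replicate.
#' @param markers_per_chrom markers per chromosome (default 50, i.e. 500
#'   markers over the 10 default chromosomes).
#' @param n_permutations permutation replicates per scan.
#' @param tol_cM peak-distance tolerance in cM.
#' @param seed master seed; replicate seeds derive from it.
#' @return data.frame, one row per replicate: chromosomes called, peak
#'   distances (cM) to each planted locus, `success`.
#' @export
parameter_recovery_experiment <- function(n_reps = 20, n = 200,
                                          markers_per_chrom = 50,
                                          n_permutations = 200,
                                          tol_cM = 10, seed = 1L) {
  causal <- causal_model()
  genome <- default_genome(markers_per_chrom)
  noise <- noise_spec()  # Beta(1,9) missingness, 1e-4 genotype error
  fcfg <- filter_config()
  out <- vector("list", n_reps)
  for (rep in seq_len(n_reps)) {
    rseed <- stage_seed(seed, 100L + rep)
    sim <- simulate_f2_population(n, genome, causal, noise, seed = rseed)
    scfg <- scan_config(n_permutations = n_permutations,
                        seed = stage_seed(rseed, 5L))
    g2 <- missingness_filter_impute(site_filters(sim$dataset$geno, fcfg), fcfg)
    d2 <- make_dataset(g2, sim$dataset$pheno, quiet = TRUE)
    gp <- calc_genoprob(d2, cfg = scfg)
    sc <- scan_binary_em(gp, d2$pheno, scfg)
    th <- permutation_threshold(gp, d2$pheno, scfg)
    iv <- call_intervals(sc, th)
    called <- sort(iv$chrom)
    planted <- sort(causal$loci$chrom)
    right_chroms <- identical(called, planted)
    peak_dist <- rep(NA_real_, nrow(causal$loci))
    if (right_chroms) {
      for (k in seq_len(nrow(causal$loci))) {
        pk <- iv$peak_bp[iv$chrom == causal$loci$chrom[k]]
        peak_dist[k] <- abs(pk - causal$loci$pos_bp[k]) * 1e-6  # 1 cM/Mbp
      }
    }
    out[[rep]] <- data.frame(rep = rep, seed = rseed,
                             n_intervals = nrow(iv),
                             chroms_called = paste(called, collapse = ","),
                             threshold = th$threshold,
                             peak_dist_1 = peak_dist[1],
                             peak_dist_2 = peak_dist[2],
                             success = right_chroms &&
                               all(peak_dist <= tol_cM))
  }
  do.call(rbind, out)
}

#' Type-I-error calibration of the permutation threshold
#'
#' Scaled-down null replicates: each simulates an F2 population, then
#' permutes the phenotype labels so phenotype and genotype are independent,
#' computes that dataset's own permutation threshold, and records whether
#' the (null) data's genome-wide maximum LOD exceeds it. The exceedance
#' rate estimates the genome-wide type-I error and should match `alpha`.
#'
#' @param n_reps number of null replicates.
#' @param n plants per replicate.
#' @param n_chrom,chrom_cM,markers_per_chrom scaled-down genome: chromosomes
#'   of `chrom_cM` cM (and Mbp, at 1 cM/Mbp).
#' @param n_permutations permutation replicates per dataset.
#' @param alpha genome-wide level under test.
#' @param seed master seed.
#' @return list: `exceed_rate`, `n_exceed`, `n_reps`, `alpha`, `per_rep`.
#' @export
type1_calibration_experiment <- function(n_reps = 200, n = 100, n_chrom = 2,
                                         chrom_cM = 80, markers_per_chrom = 20,
                                         n_permutations = 100, alpha = 0.05,
                                         seed = 1L) {
  genome <- genome_spec(data.frame(chrom = as.character(seq_len(n_chrom)),
                                   length_bp = chrom_cM * 1e6,
                                   map_length_cM = chrom_cM),
                        markers_per_chrom = markers_per_chrom)
  causal <- causal_model(loci = data.frame(chrom = "1", pos_bp = chrom_cM * 5e5))
  exceed <- logical(n_reps)
  for (rep in seq_len(n_reps)) {
    rseed <- stage_seed(seed, 200L + rep)
    sim <- simulate_f2_population(n, genome, causal, no_noise(), seed = rseed)
    d <- sim$dataset
    set.seed(stage_seed(rseed, 6L))
    d$pheno$phenotype <- sample(d$pheno$phenotype)  # break the association
    scfg <- scan_config(n_permutations = n_permutations, alpha = alpha,
                        seed = stage_seed(rseed, 7L))
    gp <- calc_genoprob(d, cfg = scfg)
    sc <- scan_binary_em(gp, d$pheno, scfg)
    th <- suppressWarnings(permutation_threshold(gp, d$pheno, scfg))
    exceed[rep] <- max(sc$lod) > th$threshold
  }
  list(exceed_rate = mean(exceed), n_exceed = sum(exceed), n_reps = n_reps,
       alpha = alpha, per_rep = exceed)
}

#' Positional enrichment of model-filter survivors near causal loci
#'
#' Simulates replicate F2 populations, runs the cascade through the
#' model-constrained chi-square filter, and classifies every tested SNP as
#' near (within `near_cM` of a planted causal locus) or far. Counts are
#' pooled across replicates and tested for enrichment of survivors among
#' near SNPs with a one-sided Fisher exact test.
#'
#' @param n_reps replicates.
#' @param n plants per replicate.
#' @param markers_per_chrom markers per chromosome.
#' @param near_cM distance (cM = Mbp) defining the causal neighbourhood.
#' @param seed master seed.
#' @return list: pooled 2x2 `table` (near/far x kept/removed), `p_value`
#'   (one-sided, enrichment), `odds_ratio`, per-replicate keep counts.
#' @export
filter_enrichment_experiment <- function(n_reps = 20, n = 200,
                                         markers_per_chrom = 50,
                                         near_cM = 10, seed = 1L) {
  causal <- causal_model()
  genome <- default_genome(markers_per_chrom)
  noise <- noise_spec()
  fcfg <- filter_config()
  tab <- matrix(0, 2, 2, dimnames = list(c("near", "far"), c("kept", "removed")))
  per_rep <- vector("list", n_reps)
  for (rep in seq_len(n_reps)) {
    rseed <- stage_seed(seed, 300L + rep)
    sim <- simulate_f2_population(n, genome, causal, noise, seed = rseed)
    g2 <- missingness_filter_impute(site_filters(sim$dataset$geno, fcfg), fcfg)
    d2 <- make_dataset(g2, sim$dataset$pheno, quiet = TRUE)
    fits <- model_fit_filter(d2, cfg = fcfg)
    near <- rep(FALSE, nrow(fits))
    for (k in seq_len(nrow(causal$loci))) {
      near <- near | (fits$chrom == causal$loci$chrom[k] &
                        abs(fits$pos_bp - causal$loci$pos_bp[k]) * 1e-6 <= near_cM)
    }
    tab["near", "kept"] <- tab["near", "kept"] + sum(near & fits$keep)
    tab["near", "removed"] <- tab["near", "removed"] + sum(near & !fits$keep)
    tab["far", "kept"] <- tab["far", "kept"] + sum(!near & fits$keep)
    tab["far", "removed"] <- tab["far", "removed"] + sum(!near & !fits$keep)
    per_rep[[rep]] <- data.frame(rep = rep, kept_near = sum(near & fits$keep),
                                 n_near = sum(near),
                                 kept_far = sum(!near & fits$keep),
                                 n_far = sum(!near))
  }
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(table = tab, p_value = ft$p.value, odds_ratio = unname(ft$estimate),
       per_rep = do.call(rbind, per_rep))
}
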
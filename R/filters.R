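#' Filter cascade configuration
#'
#' Defaults mirror the four-stage SNP filtration used for the regrowth scan:
#' site coverage >= 0.2 and minor allele frequency >= 0.01 (stage 1, applied
#' at the genotype-matrix level), removal of sites missing in more than 20%
#' of plants with heterozygote imputation of the remainder (stage 2), the
#' 9:7-model-constrained contingency chi-square keep rule chi2 < 9.49
#' (= upper-5% point of chi-square with 4 df; stage 3), and 100-bp
#' same-haplotype cluster collapsing (stage 4).
#'
#' @param min_site_coverage minimum called fraction per site.
#' @param min_maf minimum minor allele frequency.
#' @param max_missing maximum missing fraction tolerated at stage 2
#'   (strictly greater is removed).
#' @param model_chi2_threshold keep rule: chi2 strictly below this value.
#' @param cluster_window_bp maximum span of a collapsed cluster.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_site_coverage = 0.2, min_maf = 0.01,
                          max_missing = 0.2,
                          model_chi2_threshold = chi2_critical(4, 0.05),
                          cluster_window_bp = 100L) {
  fr <- c(min_site_coverage, min_maf, max_missing)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  if (cluster_window_bp < 0) stop("cluster_window_bp must be >= 0")
  structure(list(min_site_coverage = min_site_coverage, min_maf = min_maf,
                 max_missing = max_missing,
                 model_chi2_threshold = model_chi2_threshold,
                 cluster_window_bp = as.integer(cluster_window_bp)),
            class = "filter_config")
}

#' Stage 1: site coverage and minor allele frequency filters
#'
#' Removes sites whose called fraction is below `min_site_coverage` or whose
#' minor allele frequency is below `min_maf`. Alleles are counted from calls
#' (AA = 2 Zd alleles, AB = 1 of each, BB = 2 maize; missing excluded).
#'
#' @param g a [geno_matrix()].
#' @param cfg a [filter_config()].
#' @return the filtered [geno_matrix()].
#' @export
site_filters <- function(g, cfg = filter_config()) {
  stopifnot(inherits(g, "geno_matrix"))
  calls <- unclass(g)
  cov <- colMeans(!is.na(calls))
  n_aa <- colSums(calls == 1L, na.rm = TRUE)
  n_ab <- colSums(calls == 2L, na.rm = TRUE)
  n_bb <- colSums(calls == 3L, na.rm = TRUE)
  zd <- 2 * n_aa + n_ab
  mz <- 2 * n_bb + n_ab
  tot <- zd + mz
  maf <- ifelse(tot > 0, pmin(zd, mz) / tot, 0)
  keep <- cov >= cfg$min_site_coverage & maf >= cfg$min_maf
  subset_markers(g, keep)
}

#' Stage 2: missingness removal and heterozygote imputation
#'
#' Sites with missing data in strictly more than `max_missing` of the plants
#' are removed; every remaining missing call is imputed as the heterozygote
#' AB (either allele may be present, and AB is the intermediate). The output
#' contains no missing calls; the operation is idempotent.
#'
#' @inheritParams site_filters
#' @return the filtered, fully imputed [geno_matrix()].
#' @export
missingness_filter_impute <- function(g, cfg = filter_config()) {
  stopifnot(inherits(g, "geno_matrix"))
  calls <- unclass(g)
  miss <- colMeans(is.na(calls))
  g <- subset_markers(g, miss <= cfg$max_missing)
  calls <- unclass(g)
  calls[is.na(calls)] <- 2L  # AB
  geno_matrix(calls, marker_map(g))
}

#' Stage 3: segregation-model-constrained contingency chi-square filter
#'
#' For each SNP, tabulates observed counts over the six cells (R/NR x
#' AA/AB/BB) and compares them with the counts expected under the 9:7
#' complementary dominant model at a fully linked marker: the regrowth
#' subpopulation expected at (1/3, 2/3, 0) and the non-regrowth at
#' (1/7, 2/7, 4/7) of their sizes. chi2 = sum (O-E)^2/E over cells with
#' E > 0; a cell with E = 0 but O > 0 makes the statistic infinite (the
#' limit of the Pearson term), forcing rejection. df = 4 (six cells minus
#' the two subpopulation-total constraints), matching the 9.49 critical
#' value. A SNP is kept iff chi2 < `model_chi2_threshold`.
#'
#' @param d a `regrow_dataset` whose genotypes contain no missing calls
#'   (run after [missingness_filter_impute()]).
#' @param dist_R,dist_NR [conditional_genotype_probs()] distributions.
#' @param cfg a [filter_config()].
#' @return data.frame of class `snp_model_fit`: marker, chrom, pos_bp, the
#'   six observed counts, `chi2`, `df`, `keep`.
#' @export
model_fit_filter <- function(d, dist_R = conditional_genotype_probs("R"),
                             dist_NR = conditional_genotype_probs("NR"),
                             cfg = filter_config()) {
  stopifnot(inherits(d, "regrow_dataset"))
  calls <- unclass(d$geno)
  if (anyNA(calls))
    stop("genotypes contain missing calls; run missingness_filter_impute first")
  is_R <- d$pheno$phenotype[match(rownames(calls), d$pheno$plant)] == "R"
  n_R <- sum(is_R); n_NR <- sum(!is_R)
  if (n_R < 1 || n_NR < 1) stop("both phenotype classes must be non-empty")
  obs <- matrix(0, ncol(calls), 6)
  for (gclass in 1:3) {
    obs[, gclass] <- colSums(calls[is_R, , drop = FALSE] == gclass)
    obs[, 3 + gclass] <- colSums(calls[!is_R, , drop = FALSE] == gclass)
  }
  expd <- c(n_R * dist_R$probs, n_NR * dist_NR$probs)
  chi2 <- numeric(ncol(calls))
  for (cell in 1:6) {
    if (expd[cell] > 0) {
      chi2 <- chi2 + (obs[, cell] - expd[cell])^2 / expd[cell]
    } else {
      chi2[obs[, cell] > 0] <- Inf
    }
  }
  map <- marker_map(d$geno)
  out <- data.frame(map,
                    O_R_AA = obs[, 1], O_R_AB = obs[, 2], O_R_BB = obs[, 3],
                    O_NR_AA = obs[, 4], O_NR_AB = obs[, 5], O_NR_BB = obs[, 6],
                    chi2 = chi2, df = 4L,
                    keep = chi2 < cfg$model_chi2_threshold)
  class(out) <- c("snp_model_fit", "data.frame")
  out
}

#' Stage 4: collapse same-haplotype SNP clusters
#'
#' Left-to-right sweep within each chromosome over markers sorted by
#' position: a marker joins the open cluster iff its genotype vector is
#' identical (across all plants) to the cluster's signature *and* it lies
#' within `cluster_window_bp` of the cluster's first member; otherwise a new
#' cluster opens. One column per cluster survives — the first member.
#'
#' @inheritParams site_filters
#' @return list: `geno` (collapsed [geno_matrix()]), `clusters` (data.frame:
#'   representative, chrom, start_bp, end_bp, n_members, members
#'   (comma-separated ids)).
#' @export
collapse_clusters <- function(g, cfg = filter_config()) {
  stopifnot(inherits(g, "geno_matrix"))
  map <- marker_map(g)
  calls <- unclass(g)
  rep_idx <- integer(0)
  cl_of <- integer(ncol(calls))
  open_first <- -1L; open_chrom <- ""; open_sig <- NULL; cl <- 0L
  for (j in seq_len(ncol(calls))) {
    same <- cl > 0L &&
      map$chrom[j] == open_chrom &&
      (map$pos_bp[j] - map$pos_bp[open_first]) <= cfg$cluster_window_bp &&
      identical(calls[, j], open_sig)
    if (!same) {
      cl <- cl + 1L
      open_first <- j; open_chrom <- map$chrom[j]; open_sig <- calls[, j]
      rep_idx <- c(rep_idx, j)
    }
    cl_of[j] <- cl
  }
  clusters <- do.call(rbind, lapply(seq_len(cl), function(k) {
    members <- which(cl_of == k)
    data.frame(representative = map$marker[members[1]],
               chrom = map$chrom[members[1]],
               start_bp = map$pos_bp[members[1]],
               end_bp = map$pos_bp[members[length(members)]],
               n_members = length(members),
               members = paste(map$marker[members], collapse = ","))
  }))
  list(geno = subset_markers(g, rep_idx), clusters = clusters)
}

#' Run the full four-stage filter cascade
#'
#' [site_filters()] then [missingness_filter_impute()] then
#' [model_fit_filter()] then [collapse_clusters()], in that order, with a
#' per-chromosome survivor-count report after each stage.
#'
#' @param d a `regrow_dataset`.
#' @param cfg a [filter_config()].
#' @return list: `dataset_stage2` (post-imputation dataset, the input to the
#'   unconstrained scan), `dataset_stage4` (model-filtered, cluster-collapsed
#'   dataset), `model_fits`, `clusters`, and `counts` (data.frame: chrom,
#'   n_input, n_stage1, n_stage2, n_stage3, n_stage4).
#' @export
run_filter_cascade <- function(d, cfg = filter_config()) {
  stopifnot(inherits(d, "regrow_dataset"))
  count_by_chrom <- function(g) table(factor(marker_map(g)$chrom,
                                             levels = unique(marker_map(d$geno)$chrom)))
  g0 <- d$geno
  g1 <- site_filters(g0, cfg)
  g2 <- missingness_filter_impute(g1, cfg)
  d2 <- structure(list(geno = g2, pheno = d$pheno, join_log = d$join_log),
                  class = "regrow_dataset")
  fits <- model_fit_filter(d2, cfg = cfg)
  g3 <- subset_markers(g2, fits$keep)
  cc <- collapse_clusters(g3, cfg)
  d4 <- structure(list(geno = cc$geno, pheno = d$pheno, join_log = d$join_log),
                  class = "regrow_dataset")
  counts <- data.frame(chrom = unique(marker_map(g0)$chrom),
                       n_input = as.integer(count_by_chrom(g0)),
                       n_stage1 = as.integer(count_by_chrom(g1)),
                       n_stage2 = as.integer(count_by_chrom(g2)),
                       n_stage3 = as.integer(count_by_chrom(g3)),
                       n_stage4 = as.integer(count_by_chrom(cc$geno)))
  list(dataset_stage2 = d2, dataset_stage4 = d4,
       model_fits = fits, clusters = cc$clusters, counts = counts)
}
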
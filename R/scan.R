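#' Genome-scan configuration
#'
#' @param step maximum spacing (cM) of the evaluation grid; pseudomarkers
#'   are inserted evenly within marker intervals so no gap exceeds it.
#' @param error_prob genotyping error probability epsilon used by the HMM
#'   emissions.
#' @param em_tolerance EM stop rule: log-likelihood improvement below this.
#' @param em_max_iter maximum EM iterations per position.
#' @param n_permutations permutation replicates for the genome-wide
#'   threshold.
#' @param alpha genome-wide significance level.
#' @param seed seed for the permutation stream.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(step = 1.0, error_prob = 1e-4, em_tolerance = 1e-8,
                        em_max_iter = 1000L, n_permutations = 1000L,
                        alpha = 0.05, seed = 1L) {
  if (step <= 0) stop("step must be > 0")
  if (error_prob <= 0 || error_prob >= 0.5) stop("error_prob must be in (0, 0.5)")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  structure(list(step = step, error_prob = error_prob,
                 em_tolerance = em_tolerance,
                 em_max_iter = as.integer(em_max_iter),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, seed = as.integer(seed)),
            class = "scan_config")
}

## Evaluation grid for one chromosome: markers plus pseudomarkers inserted
## evenly so adjacent spacing <= step. Pseudomarkers carry no observation
## and no physical position.
make_grid <- function(chrom, marker, pos_cM, pos_bp, step) {
  stopifnot(!is.unsorted(pos_cM))
  if (length(pos_cM) == 1)
    return(data.frame(chrom = chrom, marker = marker, pos_cM = pos_cM,
                      pos_bp = pos_bp, is_marker = TRUE, obs_col = 1L))
  out_pos <- pos_cM[1]; out_marker <- marker[1]; out_bp <- pos_bp[1]
  out_real <- TRUE; out_obs <- 1L
  for (j in 2:length(pos_cM)) {
    gap <- pos_cM[j] - pos_cM[j - 1]
    if (gap > step) {
      k <- ceiling(gap / step) - 1
      ins <- pos_cM[j - 1] + gap * seq_len(k) / (k + 1)
      out_pos <- c(out_pos, ins)
      out_marker <- c(out_marker, sprintf("c%s.loc%.3f", chrom, ins))
      out_bp <- c(out_bp, rep(NA_real_, k))
      out_real <- c(out_real, rep(FALSE, k))
      out_obs <- c(out_obs, rep(0L, k))
    }
    out_pos <- c(out_pos, pos_cM[j]); out_marker <- c(out_marker, marker[j])
    out_bp <- c(out_bp, pos_bp[j]); out_real <- c(out_real, TRUE)
    out_obs <- c(out_obs, j)
  }
  data.frame(chrom = chrom, marker = out_marker, pos_cM = out_pos,
             pos_bp = out_bp, is_marker = out_real, obs_col = out_obs)
}

#' Conditional genotype probabilities along the genome
#'
#' Hidden Markov model over the three F2 genotype states (prior 1/4 AA :
#' 1/2 AB : 1/4 BB; transitions from the Haldane recombination fraction of
#' each grid interval via two independent meioses) evaluated by
#' forward-backward, with a symmetric genotyping-error emission model: the
#' observed call is correct with probability 1 - epsilon and each wrong call
#' has probability epsilon/2; missing calls and pseudomarkers are
#' uninformative. Pseudomarkers are inserted so that adjacent evaluation
#' positions are at most `cfg$step` cM apart.
#'
#' @param d a `regrow_dataset` (genotypes may include missing calls).
#' @param map a [build_genetic_map()] result covering all markers of `d`.
#' @param cfg a [scan_config()].
#' @return object of class `genoprob`: list with `chrom` (per chromosome:
#'   `probs` n x P x 3 array, `grid` data.frame), `plants`, `error_prob`.
#' @export
calc_genoprob <- function(d, map = build_genetic_map(marker_map(d$geno)),
                          cfg = scan_config()) {
  stopifnot(inherits(d, "regrow_dataset"))
  calls <- unclass(d$geno)
  mm <- marker_map(d$geno)
  if (!all(mm$marker %in% map$marker))
    stop("genetic map does not cover all markers")
  res <- list()
  for (ch in unique(mm$chrom)) {
    jj <- which(mm$chrom == ch)
    pos_cM <- map$pos_cM[match(mm$marker[jj], map$marker)]
    ord <- order(pos_cM)
    jj <- jj[ord]; pos_cM <- pos_cM[ord]
    grid <- make_grid(ch, mm$marker[jj], pos_cM, mm$pos_bp[jj], cfg$step)
    obs <- matrix(0L, nrow(calls), nrow(grid))
    has_obs <- grid$obs_col > 0L
    raw <- calls[, jj, drop = FALSE]
    raw[is.na(raw)] <- 0L
    obs[, has_obs] <- raw[, grid$obs_col[has_obs], drop = FALSE]
    rf <- haldane_r(diff(grid$pos_cM))
    pr <- fb_genoprob_cpp(obs, rf, cfg$error_prob)
    dimnames(pr) <- list(rownames(calls), grid$marker, c("AA", "AB", "BB"))
    res[[ch]] <- list(probs = pr, grid = grid)
  }
  structure(list(chrom = res, plants = rownames(calls),
                 error_prob = cfg$error_prob),
            class = "genoprob")
}

pheno_as_binary <- function(gp, pheno) {
  y <- pheno$phenotype[match(gp$plants, pheno$plant)]
  if (anyNA(y)) stop("phenotype missing for some genotyped plants")
  as.integer(y == "R")
}

scan_core <- function(gp, y, cfg) {
  null_ll <- NA_real_
  out <- lapply(names(gp$chrom), function(ch) {
    blk <- gp$chrom[[ch]]
    fit <- scan_binary_em_cpp(blk$probs, y, cfg$em_tolerance, cfg$em_max_iter)
    null_ll <<- fit$null_ll
    cbind(blk$grid[, c("chrom", "marker", "pos_cM", "pos_bp", "is_marker")],
          lod = fit$lod, pi_AA = fit$pi[, 1], pi_AB = fit$pi[, 2],
          pi_BB = fit$pi[, 3], em_iter = fit$niter,
          em_converged = fit$niter < cfg$em_max_iter)
  })
  df <- do.call(rbind, out)
  attr(df, "null_ll") <- null_ll
  df
}

#' Binary-trait single-locus genome scan by EM
#'
#' At each evaluation position maximizes the binary single-QTL mixture
#' likelihood `sum_i log sum_g w_ig pi_g^y_i (1-pi_g)^(1-y_i)` over the
#' genotype-specific penetrances pi = (pi_AA, pi_AB, pi_BB) by EM (E-step:
#' posterior genotype membership weighted by the Bernoulli likelihood;
#' M-step: penetrance = weighted phenotype mean). The null model has one
#' common penetrance, whose MLE is the phenotype mean. LOD = (l1 - l0) /
#' ln 10.
#'
#' @param gp a [calc_genoprob()] result.
#' @param pheno a [pheno_table()] covering all genotyped plants.
#' @param cfg a [scan_config()].
#' @return data.frame of class `scan_result`: chrom, marker, pos_cM, pos_bp
#'   (NA at pseudomarkers), is_marker, lod, penetrance estimates, EM
#'   diagnostics. Attribute `null_ll` carries the null log-likelihood.
#' @export
scan_binary_em <- function(gp, pheno, cfg = scan_config()) {
  stopifnot(inherits(gp, "genoprob"))
  y <- pheno_as_binary(gp, pheno)
  out <- scan_core(gp, y, cfg)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes phenotype labels across plants (genotypes fixed), reruns the
#' full EM scan, and records the genome-wide maximum LOD of each replicate.
#' The threshold is the empirical (1 - alpha) quantile of the maxima taken
#' as the order statistic `ceiling((1 - alpha) * n)` (no interpolation, so
#' the value is platform-stable). Seeded and reproducible.
#'
#' @inheritParams scan_binary_em
#' @return list of class `perm_threshold`: `threshold`, `maxima` (sorted),
#'   `alpha`, `n_permutations`, `seed`.
#' @export
permutation_threshold <- function(gp, pheno, cfg = scan_config()) {
  stopifnot(inherits(gp, "genoprob"))
  if (cfg$n_permutations < 1 / cfg$alpha)
    warning(sprintf("only %d permutations for alpha = %g: quantile is unstable",
                    cfg$n_permutations, cfg$alpha))
  y <- pheno_as_binary(gp, pheno)
  set.seed(cfg$seed)
  yperm <- vapply(seq_len(cfg$n_permutations), function(rep) sample(y),
                  integer(length(y)))
  maxima <- perm_max_lod_cpp(lapply(gp$chrom, `[[`, "probs"), yperm,
                             cfg$em_tolerance, cfg$em_max_iter)
  maxima <- sort(maxima)
  k <- ceiling((1 - cfg$alpha) * cfg$n_permutations)
  structure(list(threshold = maxima[k], maxima = maxima, alpha = cfg$alpha,
                 n_permutations = cfg$n_permutations, seed = cfg$seed),
            class = "perm_threshold")
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf("permutation threshold: LOD %.2f (alpha = %g, %d replicates)\n",
              x$threshold, x$alpha, x$n_permutations))
  invisible(x)
}

#' Call significant intervals from a scan
#'
#' Per chromosome, collects the real SNP markers (pseudomarkers excluded)
#' with LOD at or above the threshold; the interval runs from the first to
#' the last such marker (closed, bp), with the peak at the marker of
#' maximal LOD (leftmost on ties). Chromosomes with no significant marker
#' yield no interval.
#'
#' @param scan a [scan_binary_em()] result.
#' @param threshold numeric LOD threshold or a [permutation_threshold()]
#'   result.
#' @return data.frame: chrom, start_bp, end_bp, peak_bp, peak_marker,
#'   peak_lod, n_significant.
#' @export
call_intervals <- function(scan, threshold) {
  stopifnot(inherits(scan, "scan_result"))
  if (inherits(threshold, "perm_threshold")) threshold <- threshold$threshold
  real <- scan[scan$is_marker, , drop = FALSE]
  out <- list()
  for (ch in unique(real$chrom)) {
    sig <- real[real$chrom == ch & real$lod >= threshold, , drop = FALSE]
    if (nrow(sig) == 0) next
    peak <- sig[which.max(sig$lod), ]  # which.max: leftmost on ties
    out[[ch]] <- data.frame(chrom = ch,
                            start_bp = min(sig$pos_bp), end_bp = max(sig$pos_bp),
                            peak_bp = peak$pos_bp, peak_marker = peak$marker,
                            peak_lod = peak$lod, n_significant = nrow(sig))
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), peak_bp = numeric(0),
                      peak_marker = character(0), peak_lod = numeric(0),
                      n_significant = integer(0)))
  ret <- do.call(rbind, out)
  rownames(ret) <- NULL
  ret
}
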
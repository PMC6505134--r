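#' Segregation model for k dominant complementary loci
#'
#' Under complementary dominant epistasis, the phenotype requires at least
#' one dominant (Zd) allele at *each* of k unlinked loci, so the expected
#' regrowth fraction in an F2 is (3/4)^k: 3:1 for k = 1, 9:7 for k = 2,
#' 27:37 for k = 3.
#'
#' @param k positive integer number of loci.
#' @return list of class `seg_model`: `k`, `expected_R_fraction`, `label`.
#' @examples
#' seg_model(2)$label  # "9:7"
#' @export
seg_model <- function(k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k != as.integer(k))
    stop("k must be a positive integer")
  k <- as.integer(k)
  label <- if (k <= 10) {
    num <- 3^k
    den <- 4^k - num
    sprintf("%d:%d", num, den)
  } else NA_character_
  structure(list(k = k, expected_R_fraction = (3 / 4)^k, label = label),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("seg_model: %d dominant complementary locus/loci (%s), E[R] = %.4f\n",
              x$k, x$label, x$expected_R_fraction))
  invisible(x)
}

#' Expected F2 regrowth fraction under k complementary dominant loci
#'
#' @param k positive integer.
#' @return `(3/4)^k`.
#' @examples
#' expected_regrowth_fraction(2)  # 9/16
#' @export
expected_regrowth_fraction <- function(k) seg_model(k)$expected_R_fraction

#' Expected backcross regrowth fraction
#'
#' An F1 backcrossed to the Zd parent transmits at least one Zd allele at
#' every locus, so all progeny regrow; backcrossed to the maize parent, each
#' of the k loci independently has probability 1/2 of receiving a Zd allele
#' from the F1.
#'
#' @param direction `"to_Zd"` or `"to_maize"`.
#' @param k positive integer number of loci.
#' @return expected regrowth fraction.
#' @export
backcross_expected_fraction <- function(direction = c("to_Zd", "to_maize"), k) {
  direction <- match.arg(direction)
  if (k < 1) stop("k must be >= 1")
  if (direction == "to_Zd") 1.0 else (1 / 2)^k
}

#' Chi-square goodness-of-fit test of a segregation model
#'
#' Pearson chi-square of observed R/NR counts against the model's expected
#' split, two classes, df = 1, no continuity correction (the convention that
#' reproduces the published per-population p-values).
#'
#' @param n_R,n_NR observed regrowth / non-regrowth counts.
#' @param model a [seg_model()].
#' @return list of class `gof_result`: `chi2`, `df`, `p`, `observed`,
#'   `expected`, `model`.
#' @examples
#' gof_test(92, 68, seg_model(2))$p  # ~0.7499
#' @export
gof_test <- function(n_R, n_NR, model) {
  stopifnot(inherits(model, "seg_model"))
  n <- n_R + n_NR
  if (n < 1) stop("zero total count")
  pr <- model$expected_R_fraction
  ## Pearson X^2 on two classes = chisq.test(..., p = ...) with no correction
  res <- suppressWarnings(
    stats::chisq.test(c(n_R, n_NR), p = c(pr, 1 - pr), correct = FALSE))
  structure(list(chi2 = unname(res$statistic), df = 1L,
                 p = unname(res$p.value),
                 observed = c(n_R = n_R, n_NR = n_NR),
                 expected = c(e_R = n * pr, e_NR = n * (1 - pr)),
                 model = model),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("gof: %s model, obs %d:%d, chi2 = %.4f (df=%d), p = %.4f\n",
              x$model$label, x$observed[1], x$observed[2], x$chi2, x$df, x$p))
  invisible(x)
}

#' Select the best-fitting segregation model
#'
#' Tests each candidate with [gof_test()] and returns the one with the
#' largest p-value; ties break toward smaller k. Invariant to candidate
#' ordering.
#'
#' @param n_R,n_NR observed counts.
#' @param candidates list of [seg_model()]s (default k = 1, 2, 3).
#' @return list: `best` (a `seg_model`), `fits` (one `gof_result` per
#'   candidate, in increasing-k order).
#' @export
best_fit_model <- function(n_R, n_NR, candidates = lapply(1:3, seg_model)) {
  if (length(candidates) < 1) stop("at least one candidate model required")
  ks <- vapply(candidates, `[[`, integer(1), "k")
  candidates <- candidates[order(ks)]
  fits <- lapply(candidates, function(m) gof_test(n_R, n_NR, m))
  ps <- vapply(fits, `[[`, numeric(1), "p")
  best <- candidates[[which.max(ps)]]  # which.max: first max, i.e. smallest k
  list(best = best, fits = fits)
}

#' Conditional marker-genotype distribution given phenotype class (9:7 model)
#'
#' For a marker fully linked to one of the two complementary dominant loci,
#' the F2 1:2:1 segregation at that locus combines with the independent 3:1
#' dominance at the other locus. Regrowth plants must carry a Zd allele at
#' the linked locus: P(AA,AB,BB | R) = (1/3, 2/3, 0). Non-regrowth plants:
#' P(AA,AB,BB | NR) = (1/7, 2/7, 4/7). Probabilities are built from integer
#' numerators over a common denominator so expected counts downstream carry
#' no decimal drift.
#'
#' @param phenotype_class `"R"` or `"NR"`.
#' @param model a [seg_model()] with `k = 2` (the only derived case).
#' @return list of class `cond_geno_dist`: `phenotype_class`, `probs` (named
#'   numeric, AA/AB/BB), `numerators`, `denominator`.
#' @export
conditional_genotype_probs <- function(phenotype_class = c("R", "NR"),
                                       model = seg_model(2)) {
  phenotype_class <- match.arg(phenotype_class)
  stopifnot(inherits(model, "seg_model"))
  if (model$k != 2)
    stop("conditional genotype distributions are derived only for k = 2 (9:7)")
  ## Joint over (linked-locus genotype in 1:2:1) x (other locus dominant 3:1):
  ## R requires A_ at both; of 16 F2 cells, R cells: AA&A_ (3) + AB&A_ (6) = 9.
  if (phenotype_class == "R") {
    num <- c(AA = 3L, AB = 6L, BB = 0L); den <- 9L
  } else {
    ## NR cells: AA&bb (1) + AB&bb (2) + BB&anything (4) = 7
    num <- c(AA = 1L, AB = 2L, BB = 4L); den <- 7L
  }
  structure(list(phenotype_class = phenotype_class,
                 probs = num / den, numerators = num, denominator = den),
            class = "cond_geno_dist")
}

#' @export
print.cond_geno_dist <- function(x, ...) {
  cat(sprintf("P(AA, AB, BB | %s) = %d/%d, %d/%d, %d/%d\n",
              x$phenotype_class, x$numerators[1], x$denominator,
              x$numerators[2], x$denominator, x$numerators[3], x$denominator))
  invisible(x)
}

#' Upper-alpha chi-square critical value
#'
#' @param df degrees of freedom (>= 1).
#' @param alpha tail probability in (0, 1).
#' @return the value c with P(X2_df >= c) = alpha.
#' @examples
#' round(chi2_critical(4, 0.05), 2)  # 9.49
#' @export
chi2_critical <- function(df, alpha) {
  if (df < 1 || df != as.integer(df)) stop("df must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stats::qchisq(alpha, df = df, lower.tail = FALSE)
}

#' Segregation test report over candidate models
#'
#' Convenience wrapper producing one row per population with p-values for
#' each candidate k and the best fit flagged — the shape of a published
#' segregation-test table.
#'
#' @param counts data.frame with columns `population`, `n_R`, `n_NR`.
#' @param ks integer vector of candidate locus counts.
#' @return data.frame: population, total, n_R, n_NR, `p_<label>` columns,
#'   `best_fit` (model label).
#' @export
segregation_report <- function(counts, ks = 1:3) {
  stopifnot(all(c("population", "n_R", "n_NR") %in% names(counts)))
  models <- lapply(ks, seg_model)
  out <- data.frame(population = counts$population,
                    total = counts$n_R + counts$n_NR,
                    n_R = counts$n_R, n_NR = counts$n_NR)
  pcols <- matrix(NA_real_, nrow(counts), length(models))
  for (i in seq_len(nrow(counts))) {
    bf <- best_fit_model(counts$n_R[i], counts$n_NR[i], models)
    pcols[i, ] <- vapply(bf$fits, `[[`, numeric(1), "p")
    out$best_fit[i] <- bf$best$label
  }
  colnames(pcols) <- paste0("p_", vapply(models, `[[`, "", "label"))
  cbind(out[, c("population", "total", "n_R", "n_NR")], pcols,
        best_fit = out$best_fit)
}
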
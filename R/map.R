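#' Haldane map function
#'
#' Converts between map distance and recombination fraction under no
#' crossover interference: `r = (1 - exp(-2d/100)) / 2`,
#' `d = -50 log(1 - 2r)` (d in cM).
#'
#' @param d map distance in cM (>= 0).
#' @param r recombination fraction in `[0, 0.5)`.
#' @return the converted quantity.
#' @examples
#' haldane_r(10)            # ~0.0906
#' haldane_cM(haldane_r(10))  # 10
#' @export
haldane_r <- function(d) {
  if (any(d < 0)) stop("map distance must be >= 0")
  (1 - exp(-2 * d / 100)) / 2
}

#' @rdname haldane_r
#' @export
haldane_cM <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("recombination fraction must be in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' Build a genetic map for a marker set
#'
#' Two modes. `physical_1cM_per_Mbp` (default): genetic position is physical
#' position times 1e-6 — the declared physical-to-genetic convention, since
#' the scan is driven by bp coordinates. `em_estimated`: adjacent-pair
#' recombination fractions estimated from a complete genotype matrix by the
#' classic F2 EM (the double heterozygote's phase is the latent variable),
#' converted to cM via Haldane and accumulated; used to validate simulated
#' data against the generator's map.
#'
#' @param markers marker map data.frame (`marker`, `chrom`, `pos_bp`),
#'   sorted by (chrom, pos_bp).
#' @param mode `"physical_1cM_per_Mbp"` or `"em_estimated"`.
#' @param g a complete [geno_matrix()] (required for `em_estimated`).
#' @return data.frame of class `genetic_map`: `marker`, `chrom`, `pos_bp`,
#'   `pos_cM`.
#' @export
build_genetic_map <- function(markers,
                              mode = c("physical_1cM_per_Mbp", "em_estimated"),
                              g = NULL) {
  mode <- match.arg(mode)
  markers <- validate_marker_map(markers)
  if (!markers_sorted(markers))
    stop("markers must be sorted by (chrom, pos_bp)")
  if (mode == "physical_1cM_per_Mbp") {
    pos_cM <- markers$pos_bp * 1e-6
  } else {
    if (is.null(g)) stop("em_estimated mode needs a genotype matrix")
    calls <- unclass(g)
    if (anyNA(calls)) stop("em_estimated mode needs a complete genotype matrix")
    idx <- match(markers$marker, colnames(calls))
    if (anyNA(idx)) stop("markers absent from genotype matrix")
    pos_cM <- numeric(nrow(markers))
    for (ch in unique(markers$chrom)) {
      jj <- which(markers$chrom == ch)
      if (length(jj) > 1) {
        d <- vapply(seq_len(length(jj) - 1), function(a) {
          r <- est_rf_f2(calls[, idx[jj[a]]], calls[, idx[jj[a + 1]]])
          haldane_cM(min(r, 0.4999))
        }, numeric(1))
        pos_cM[jj] <- cumsum(c(0, d))
      } else pos_cM[jj] <- 0
    }
  }
  out <- cbind(markers, pos_cM = pos_cM)
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Pairwise recombination fraction in an F2 by EM
#'
#' Maximum-likelihood recombination fraction between two completely genotyped
#' F2 markers. The recombinant-gamete count is observed for all genotype
#' pairs except the double heterozygote, whose phase (coupling: 0
#' recombinant gametes; repulsion: 2) is latent; EM iterates
#' `r <- E[recombinant gametes | data, r] / (2N)`.
#'
#' @param g1,g2 integer vectors of calls (1 = AA, 2 = AB, 3 = BB), no NA.
#' @param tol,max_iter convergence controls.
#' @return estimated recombination fraction.
#' @export
est_rf_f2 <- function(g1, g2, tol = 1e-10, max_iter = 2000) {
  stopifnot(length(g1) == length(g2), !anyNA(g1), !anyNA(g2))
  counts <- table(factor(g1, 1:3), factor(g2, 1:3))
  n <- sum(counts)
  ## recombinant gametes contributed by each of the 9 classes (NA = latent)
  rec <- matrix(c(0, 1, 2,
                  1, NA, 1,
                  2, 1, 0), 3, 3, byrow = TRUE)
  r <- 0.25
  for (it in seq_len(max_iter)) {
    e_dd <- 2 * r^2 / ((1 - r)^2 + r^2)  # E[rec | double het]
    w <- rec; w[2, 2] <- e_dd
    r_new <- sum(counts * w) / (2 * n)
    r_new <- min(max(r_new, 1e-12), 0.5 - 1e-12)
    if (abs(r_new - r) < tol) return(r_new)
    r <- r_new
  }
  r
}
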
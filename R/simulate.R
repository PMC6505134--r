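#' Genome specification for simulation
#'
#' Describes the chromosomes of the simulated genome and where markers sit.
#' The default emulates the ten maize chromosomes (approximate physical
#' lengths) with the package's 1 cM/Mbp physical-to-genetic coupling, so
#' simulated positions are directly consumable by the scan's default map.
#'
#' @param chromosomes data.frame with columns `chrom`, `length_bp`,
#'   `map_length_cM`.
#' @param markers_per_chrom integer; number of marker positions drawn
#'   uniformly per chromosome when explicit positions are not supplied.
#' @param marker_positions optional data.frame (`chrom`, `pos_bp`) of
#'   explicit marker positions overriding `markers_per_chrom`.
#' @return list of class `genome_spec`.
#' @export
genome_spec <- function(chromosomes, markers_per_chrom = 50,
                        marker_positions = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length_bp", "map_length_cM") %in% names(chromosomes)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  if (any(chromosomes$length_bp <= 0) || any(chromosomes$map_length_cM < 0))
    stop("chromosome lengths must be positive")
  if (!is.null(marker_positions)) {
    stopifnot(all(c("chrom", "pos_bp") %in% names(marker_positions)))
    bad <- !marker_positions$chrom %in% chromosomes$chrom
    if (any(bad)) stop("marker positions on unknown chromosome")
    len <- chromosomes$length_bp[match(marker_positions$chrom, chromosomes$chrom)]
    if (any(marker_positions$pos_bp < 1 | marker_positions$pos_bp > len))
      stop("marker position outside chromosome")
  }
  structure(list(chromosomes = chromosomes,
                 markers_per_chrom = as.integer(markers_per_chrom),
                 marker_positions = marker_positions),
            class = "genome_spec")
}

#' @rdname genome_spec
#' @export
default_genome <- function(markers_per_chrom = 50) {
  lengths_mbp <- c(301, 244, 236, 247, 224, 174, 182, 181, 160, 151)
  genome_spec(data.frame(chrom = as.character(1:10),
                         length_bp = lengths_mbp * 1e6,
                         map_length_cM = lengths_mbp),  # 1 cM / Mbp
              markers_per_chrom = markers_per_chrom)
}

#' Causal model for the regrowth phenotype
#'
#' Complementary dominant epistasis over k loci: a plant is truly regrowable
#' iff it carries at least one Zd allele at *every* causal locus.
#' `misclassification_delta` is the probability that a truly regrowable
#' plant is scored NR (dormancy at scoring time, transplant loss);
#' `reverse_error` the probability a truly non-regrowable plant is scored R.
#'
#' @param loci data.frame (`chrom`, `pos_bp`) of the causal loci; default two
#'   loci on chromosomes 2 and 7, mirroring the mapped regrowth loci.
#' @param misclassification_delta,reverse_error probabilities in `[0, 1]`.
#' @return list of class `causal_model`.
#' @export
causal_model <- function(loci = data.frame(chrom = c("2", "7"),
                                           pos_bp = c(33041409, 4284633)),
                         misclassification_delta = 0,
                         reverse_error = 0) {
  stopifnot(all(c("chrom", "pos_bp") %in% names(loci)), nrow(loci) >= 1)
  if (misclassification_delta < 0 || misclassification_delta > 1 ||
      reverse_error < 0 || reverse_error > 1)
    stop("misclassification probabilities must be in [0, 1]")
  loci$chrom <- as.character(loci$chrom)
  structure(list(loci = loci, mode = "complementary_dominant",
                 misclassification_delta = misclassification_delta,
                 reverse_error = reverse_error),
            class = "causal_model")
}

#' GBS-like noise specification
#'
#' Missingness is per-site (GBS read depth varies by locus, not by plant):
#' each site draws its own missing rate, then plant calls at that site go
#' missing independently at that rate. `site_missing` is either a length-2
#' vector of Beta(a, b) parameters (default Beta(1, 9), mean 10%) or a single
#' fixed rate applied to every site. `genotype_error_rate` is the per-call
#' probability that a true call is replaced (AB to a random homozygote, a
#' homozygote to AB). `distortion` optionally biases F1 transmission: a list
#' `(chrom, pos_bp, beta)` where `beta` is the probability a heterozygous
#' parent transmits the maize allele at that locus (0.5 = Mendelian).
#'
#' @param site_missing Beta parameters `c(a, b)` or a single fixed rate.
#' @param genotype_error_rate per-call error probability.
#' @param distortion `NULL` or `list(chrom =, pos_bp =, beta =)`.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(site_missing = c(1, 9), genotype_error_rate = 1e-4,
                       distortion = NULL) {
  if (!length(site_missing) %in% 1:2 || any(site_missing < 0))
    stop("site_missing must be Beta(a,b) parameters or one fixed rate")
  if (length(site_missing) == 1 && site_missing > 1)
    stop("fixed site missing rate must be in [0, 1]")
  if (genotype_error_rate < 0 || genotype_error_rate > 1)
    stop("genotype_error_rate must be in [0, 1]")
  if (!is.null(distortion)) {
    stopifnot(all(c("chrom", "pos_bp", "beta") %in% names(distortion)))
    if (distortion$beta <= 0 || distortion$beta >= 1)
      stop("distortion beta must be in (0, 1)")
  }
  structure(list(site_missing = site_missing,
                 genotype_error_rate = genotype_error_rate,
                 distortion = distortion),
            class = "noise_spec")
}

#' @rdname noise_spec
#' @export
no_noise <- function() noise_spec(site_missing = 0, genotype_error_rate = 0)

## Deterministic per-stage sub-seeds from the one user seed (kept < 2^31).
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage) %% 2147483647L)
}

#' Simulate one gamete from a phased chromosome pair
#'
#' Standard no-interference meiosis: the crossover count is Poisson with
#' mean equal to the map length in Morgans, crossover positions are uniform,
#' and the starting strand is fair — so the recombination fraction between
#' any two positions equals Haldane's r(d) in expectation. Uses the current
#' RNG state; seed externally for reproducibility.
#'
#' @param haps 2 x L matrix: the two parental haplotypes (allele codes) at
#'   `pos_cM`.
#' @param pos_cM increasing numeric vector of the L locus positions (cM).
#' @param map_length_cM total chromosome map length (cM).
#' @return vector of L allele codes (the gamete haplotype).
#' @examples
#' set.seed(1)
#' simulate_gamete(rbind(rep(1, 3), rep(2, 3)), c(0, 50, 100), 100)
#' @export
simulate_gamete <- function(haps, pos_cM, map_length_cM) {
  stopifnot(is.matrix(haps), nrow(haps) == 2, ncol(haps) == length(pos_cM))
  if (is.unsorted(pos_cM)) stop("pos_cM must be increasing")
  n_xo <- stats::rpois(1, map_length_cM / 100)
  strand <- sample.int(2L, 1L)
  if (n_xo == 0) return(haps[strand, ])
  xo <- sort(stats::runif(n_xo, 0, map_length_cM))
  ## strand at position p flips once per crossover left of p
  flips <- findInterval(pos_cM, xo)
  idx <- 1L + (strand - 1L + flips) %% 2L
  haps[cbind(idx, seq_along(pos_cM))]
}

## Gamete from an F1 (hap1 = all Zd, hap2 = all maize) for every chromosome.
## loci: list per chromosome of cM positions. Returns list of allele vectors
## (1 = Zd, 2 = maize). Optional transmission distortion by rejection
## sampling, preserving linkage.
f1_gamete <- function(loci, map_lengths, distortion_idx = NULL, beta = 0.5) {
  lapply(seq_along(loci), function(ci) {
    pos <- loci[[ci]]
    haps <- rbind(rep(1L, length(pos)), rep(2L, length(pos)))
    if (is.null(distortion_idx) || is.na(distortion_idx[ci])) {
      simulate_gamete(haps, pos, map_lengths[ci])
    } else {
      pmax_acc <- max(beta, 1 - beta)
      repeat {
        g <- simulate_gamete(haps, pos, map_lengths[ci])
        acc <- if (g[distortion_idx[ci]] == 2L) beta else 1 - beta
        if (stats::runif(1) < acc / pmax_acc) return(g)
      }
    }
  })
}

## Resolve per-chromosome simulation loci: markers plus causal positions.
## Returns list(loci = list of bp vectors per chrom, marker_flag = list of
## logical vectors, causal_index = data.frame(chrom_index, locus_index)).
resolve_sim_loci <- function(genome, causal, seed) {
  chr <- genome$chromosomes
  if (is.null(genome$marker_positions)) {
    set.seed(stage_seed(seed, 1L))
    mk <- do.call(rbind, lapply(seq_len(nrow(chr)), function(ci) {
      data.frame(chrom = chr$chrom[ci],
                 pos_bp = sort(sample.int(chr$length_bp[ci],
                                          genome$markers_per_chrom)))
    }))
  } else {
    mk <- genome$marker_positions[order(genome$marker_positions$chrom,
                                        genome$marker_positions$pos_bp), ]
  }
  bad <- !causal$loci$chrom %in% chr$chrom
  if (any(bad)) stop("causal locus on a chromosome absent from the genome spec")
  clen <- chr$length_bp[match(causal$loci$chrom, chr$chrom)]
  if (any(causal$loci$pos_bp < 1 | causal$loci$pos_bp > clen))
    stop("causal locus position outside its chromosome")
  loci <- vector("list", nrow(chr)); flag <- vector("list", nrow(chr))
  causal_idx <- matrix(NA_integer_, nrow(causal$loci), 2)
  for (ci in seq_len(nrow(chr))) {
    m <- mk$pos_bp[mk$chrom == chr$chrom[ci]]
    cz <- causal$loci$pos_bp[causal$loci$chrom == chr$chrom[ci]]
    all_pos <- sort(unique(c(m, cz)))
    loci[[ci]] <- all_pos
    flag[[ci]] <- all_pos %in% m
    which_c <- which(causal$loci$chrom == chr$chrom[ci])
    for (k in which_c)
      causal_idx[k, ] <- c(ci, match(causal$loci$pos_bp[k], all_pos))
  }
  list(loci = loci, marker_flag = flag, causal_index = causal_idx)
}

bp_to_cM <- function(pos_bp, length_bp, map_length_cM) {
  pos_bp / length_bp * map_length_cM
}

## Shared core: simulate n offspring given a per-plant gamete-pair generator.
sim_population <- function(n, genome, causal, noise, seed, gamete_pair_fun,
                           id_prefix) {
  chr <- genome$chromosomes
  lay <- resolve_sim_loci(genome, causal, seed)
  pos_cM <- lapply(seq_len(nrow(chr)), function(ci)
    bp_to_cM(lay$loci[[ci]], chr$length_bp[ci], chr$map_length_cM[ci]))
  distortion_idx <- NULL; beta <- 0.5
  if (!is.null(noise$distortion)) {
    d <- noise$distortion
    ci <- match(as.character(d$chrom), chr$chrom)
    if (is.na(ci)) stop("distortion locus on unknown chromosome")
    li <- which.min(abs(lay$loci[[ci]] - d$pos_bp))
    distortion_idx <- rep(NA_integer_, nrow(chr)); distortion_idx[ci] <- li
    beta <- d$beta
  }
  set.seed(stage_seed(seed, 2L))
  n_loci <- sum(lengths(lay$loci))
  calls <- matrix(NA_integer_, n, n_loci)
  for (i in seq_len(n)) {
    pair <- gamete_pair_fun(pos_cM, chr$map_length_cM, distortion_idx, beta)
    calls[i, ] <- unlist(pair$g1) + unlist(pair$g2) - 1L  # 1+1-1=1 AA; 1+2-1=2 AB; 2+2-1=3 BB
  }
  rownames(calls) <- sprintf("%s-%04d", id_prefix, seq_len(n))
  offsets <- c(0L, cumsum(lengths(lay$loci)))
  causal_geno <- matrix(NA_integer_, n, nrow(causal$loci))
  for (k in seq_len(nrow(causal$loci)))
    causal_geno[, k] <- calls[, offsets[lay$causal_index[k, 1]] + lay$causal_index[k, 2]]
  colnames(causal_geno) <- sprintf("%s_%d", causal$loci$chrom, causal$loci$pos_bp)

  ## phenotype: R iff >= 1 Zd allele (genotype AA or AB) at every causal locus
  true_R <- rowSums(causal_geno >= 3L) == 0L
  set.seed(stage_seed(seed, 3L))
  observed_R <- true_R
  if (causal$misclassification_delta > 0) {
    flip <- true_R & stats::runif(n) < causal$misclassification_delta
    observed_R[flip] <- FALSE
  }
  if (causal$reverse_error > 0) {
    flip <- !true_R & stats::runif(n) < causal$reverse_error
    observed_R[flip] <- TRUE
  }

  ## keep marker columns only; causal loci stay in the truth record
  keep <- unlist(lay$marker_flag)
  map <- data.frame(
    chrom = rep(chr$chrom, lengths(lay$loci)),
    pos_bp = unlist(lay$loci))
  map$marker <- sprintf("S%s_%d", map$chrom, map$pos_bp)
  mk_calls <- calls[, keep, drop = FALSE]
  colnames(mk_calls) <- map$marker[keep]
  gm <- geno_matrix(mk_calls, map[keep, c("marker", "chrom", "pos_bp")])

  set.seed(stage_seed(seed, 4L))
  gm <- apply_gbs_noise(gm, noise)
  noise_log <- attr(gm, "noise_log")

  ph <- pheno_table(rownames(mk_calls), ifelse(observed_R, "R", "NR"))
  truth <- list(causal = causal, genome = genome, noise = noise, seed = seed,
                causal_genotypes = causal_geno,
                true_regrowable = true_R, observed_R = observed_R,
                noise_log = noise_log)
  list(dataset = make_dataset(gm, ph, quiet = TRUE), truth = truth)
}

#' Simulate an F2 intercross population with GBS-like genotypes
#'
#' Both parents are fully inbred (Zd = AA at every locus, maize = BB), the
#' F1 is uniformly heterozygous, and each F2 plant is formed from two
#' independently simulated F1 gametes (no-interference meiosis, Haldane).
#' The regrowth phenotype follows the complementary dominant model of
#' `causal`, then misclassification; GBS noise (missingness, genotyping
#' error) is applied after phenotyping.
#'
#' @param n number of F2 plants.
#' @param genome a [genome_spec()].
#' @param causal a [causal_model()].
#' @param noise a [noise_spec()].
#' @param seed integer seed; all randomness (marker placement, meiosis,
#'   misclassification, noise) flows deterministically from it.
#' @return list: `dataset` (a `regrow_dataset`), `truth` (ground-truth
#'   record sufficient to recompute the phenotype).
#' @examples
#' sim <- simulate_f2_population(50, default_genome(10), causal_model(),
#'                               no_noise(), seed = 1)
#' sim$dataset
#' @export
simulate_f2_population <- function(n, genome = default_genome(),
                                   causal = causal_model(),
                                   noise = noise_spec(), seed) {
  if (n < 1) stop("n must be >= 1")
  sim_population(n, genome, causal, noise, seed, id_prefix = "F2",
                 gamete_pair_fun = function(pos_cM, mlen, didx, beta) {
                   list(g1 = f1_gamete(pos_cM, mlen, didx, beta),
                        g2 = f1_gamete(pos_cM, mlen, didx, beta))
                 })
}

#' Simulate a backcross population
#'
#' F1 x recurrent parent. Backcrossed to the Zd parent every plant inherits
#' a Zd allele at every locus, so all regrow under the complementary
#' dominant model; backcrossed to maize the expected regrowth fraction is
#' (1/2)^k.
#'
#' @inheritParams simulate_f2_population
#' @param direction `"to_Zd"` or `"to_maize"`.
#' @return as [simulate_f2_population()].
#' @export
simulate_backcross <- function(n, genome = default_genome(),
                               causal = causal_model(),
                               direction = c("to_Zd", "to_maize"),
                               noise = no_noise(), seed) {
  direction <- match.arg(direction)
  if (n < 1) stop("n must be >= 1")
  recurrent <- if (direction == "to_Zd") 1L else 2L
  sim_population(n, genome, causal, noise, seed,
                 id_prefix = if (direction == "to_Zd") "BCZ" else "BCM",
                 gamete_pair_fun = function(pos_cM, mlen, didx, beta) {
                   list(g1 = f1_gamete(pos_cM, mlen, didx, beta),
                        g2 = lapply(pos_cM, function(p) rep(recurrent, length(p))))
                 })
}

#' Apply GBS-like noise to a genotype matrix
#'
#' Per-site missingness (rate drawn per site from the spec's Beta, or fixed)
#' and per-call genotyping error (AB to a random homozygote, homozygote to
#' AB). Uses the current RNG state. The realized per-site rates and error
#' count are attached as the `noise_log` attribute.
#'
#' @param g a [geno_matrix()].
#' @param noise a [noise_spec()].
#' @return a [geno_matrix()] with noise applied.
#' @export
apply_gbs_noise <- function(g, noise) {
  stopifnot(inherits(g, "geno_matrix"), inherits(noise, "noise_spec"))
  calls <- unclass(g)
  n <- nrow(calls); m <- ncol(calls)
  n_err <- 0L
  if (noise$genotype_error_rate > 0) {
    hit <- which(!is.na(calls) & stats::runif(length(calls)) < noise$genotype_error_rate)
    if (length(hit)) {
      old <- calls[hit]
      new <- ifelse(old == 2L, sample(c(1L, 3L), length(hit), replace = TRUE), 2L)
      calls[hit] <- new
      n_err <- length(hit)
    }
  }
  if (length(noise$site_missing) == 1) {
    rates <- rep(noise$site_missing, m)
  } else {
    rates <- stats::rbeta(m, noise$site_missing[1], noise$site_missing[2])
  }
  if (any(rates > 0)) {
    drop <- stats::runif(n * m) < rep(rates, each = n)
    calls[drop] <- NA_integer_
  }
  out <- geno_matrix(calls, marker_map(g))
  attr(out, "noise_log") <- list(site_missing_rates = rates, n_genotype_errors = n_err)
  out
}
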
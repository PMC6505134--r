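# Small builders shared across test files.

tiny_genome <- function(n_chrom = 2, chrom_cM = 100, markers_per_chrom = 10) {
  genome_spec(data.frame(chrom = as.character(seq_len(n_chrom)),
                         length_bp = chrom_cM * 1e6,
                         map_length_cM = chrom_cM),
              markers_per_chrom = markers_per_chrom)
}

tiny_causal <- function() {
  causal_model(loci = data.frame(chrom = c("1", "2"), pos_bp = c(3e7, 6e7)))
}

make_gm <- function(calls, chrom = "1", pos = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) rownames(calls) <- sprintf("p%d", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- sprintf("m%d", seq_len(ncol(calls)))
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 1e6
  storage.mode(calls) <- "integer"
  geno_matrix(calls, data.frame(marker = colnames(calls),
                                chrom = rep(chrom, length.out = ncol(calls)),
                                pos_bp = pos))
}

random_gm <- function(n_plants, n_markers, missing_frac = 0.1, n_chrom = 2) {
  calls <- matrix(sample(c(1:3, NA), n_plants * n_markers, replace = TRUE,
                         prob = c((1 - missing_frac) * c(0.25, 0.5, 0.25),
                                  missing_frac)),
                  n_plants, n_markers,
                  dimnames = list(sprintf("p%d", seq_len(n_plants)),
                                  sprintf("m%d", seq_len(n_markers))))
  chrom <- rep(as.character(seq_len(n_chrom)), length.out = n_markers)
  chrom <- sort(chrom)
  pos <- unlist(tapply(seq_len(n_markers), chrom, function(ix)
    sort(sample.int(2e8, length(ix)))), use.names = FALSE)
  geno_matrix(calls, data.frame(marker = colnames(calls), chrom = chrom,
                                pos_bp = pos))
}

# Hand-built genoprob object with fully informative (degenerate) genotype
# probabilities at real marker positions: one chromosome.
degenerate_genoprob <- function(geno_codes, pos_bp = seq_along(geno_codes[1, ]) * 1e6,
                                chrom = "1") {
  n <- nrow(geno_codes); P <- ncol(geno_codes)
  probs <- array(0, dim = c(n, P, 3),
                 dimnames = list(rownames(geno_codes), NULL, c("AA", "AB", "BB")))
  for (i in seq_len(n)) for (p in seq_len(P)) probs[i, p, geno_codes[i, p]] <- 1
  grid <- data.frame(chrom = chrom, marker = sprintf("m%d", seq_len(P)),
                     pos_cM = pos_bp * 1e-6, pos_bp = pos_bp,
                     is_marker = TRUE, obs_col = seq_len(P))
  structure(list(chrom = setNames(list(list(probs = probs, grid = grid)), chrom),
                 plants = rownames(geno_codes), error_prob = 1e-4),
            class = "genoprob")
}

# Independent oracle: upper-tail p of the chi-square(1) distribution by
# numerical integration of the hand-written density.
chisq1_sf_oracle <- function(x) {
  dens <- function(t) t^(-0.5) * exp(-t / 2) / (sqrt(2) * gamma(0.5))
  if (x <= 0) return(1)
  stats::integrate(dens, x, Inf, rel.tol = 1e-10)$value
}

# Independent oracle: six-cell Pearson statistic computed cell by cell.
chi2_6cell_oracle <- function(obs_R, obs_NR, pR = c(1, 2, 0) / 3,
                              pNR = c(1, 2, 4) / 7) {
  e <- c(sum(obs_R) * pR, sum(obs_NR) * pNR)
  o <- c(obs_R, obs_NR)
  tot <- 0
  for (cell in 1:6) {
    if (e[cell] > 0) tot <- tot + (o[cell] - e[cell])^2 / e[cell]
    else if (o[cell] > 0) return(Inf)
  }
  tot
}

# Independent oracle: binary single-locus LOD at a fully informative marker
# by direct grid maximization of the Bernoulli likelihood per genotype class.
binary_lod_oracle <- function(geno, y, grid_step = 1e-4) {
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  l1 <- 0
  for (g in unique(geno)) {
    yy <- y[geno == g]
    ll <- vapply(grid, function(p) sum(yy * log(p) + (1 - yy) * log(1 - p)),
                 numeric(1))
    l1 <- l1 + max(ll)
  }
  p0 <- mean(y)
  l0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  (l1 - l0) / log(10)
}

# Bare call matrix (all non-matrix attributes stripped) for identity checks.
calls_of <- function(g) {
  x <- unclass(g)
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}
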
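#' Construct a genotype matrix
#'
#' The central marker-data container: an integer matrix of F2 genotype calls
#' (rows = plants, columns = biallelic SNP markers) with a physical marker map
#' attached. Calls are coded `1` = AA (homozygous *Z. diploperennis*), `2` =
#' AB (heterozygous), `3` = BB (homozygous maize), `NA` = missing. This
#' internal coding orders the three HMM states naturally; the legacy file
#' coding (1/2/3 = AA/BB/AB) is an IO dialect only, translated at the
#' boundary by [read_genotype_table()] / [write_genotype_table()].
#'
#' @param calls integer matrix (plants x markers) with values in `c(1,2,3,NA)`;
#'   rownames are plant ids, colnames marker ids.
#' @param map data.frame with columns `marker`, `chrom`, `pos_bp` (1-based
#'   physical coordinate), one row per column of `calls`, in column order.
#' @return An object of class `geno_matrix`: the call matrix with the map as
#'   an attribute.
#' @examples
#' gm <- geno_matrix(
#'   matrix(c(1L, 2L, 3L, NA), 2, 2, dimnames = list(c("p1", "p2"), c("m1", "m2"))),
#'   data.frame(marker = c("m1", "m2"), chrom = "1", pos_bp = c(100L, 200L))
#' )
#' dim(gm)
#' @export
geno_matrix <- function(calls, map) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)) || (ncol(calls) > 0 && is.null(colnames(calls))))
    stop("`calls` must have plant ids as rownames and marker ids as colnames")
  bad <- !(calls %in% c(1L, 2L, 3L) | is.na(calls))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid genotype code at plant '%s', marker '%s'",
                 rownames(calls)[idx[1]], colnames(calls)[idx[2]]))
  }
  map <- validate_marker_map(map)
  cn <- if (is.null(colnames(calls))) character(0) else colnames(calls)
  if (nrow(map) != ncol(calls) || !identical(map$marker, cn))
    stop("map rows must match `calls` columns (same markers, same order)")
  if (!markers_sorted(map))
    stop("markers must be sorted by (chrom, pos_bp): chromosomes contiguous, positions non-decreasing")
  if (anyDuplicated(rownames(calls))) stop("duplicate plant ids")
  structure(calls, map = map, class = c("geno_matrix", "matrix", "array"))
}

## Sorted = each chromosome's markers form one contiguous block with
## non-decreasing positions. Chromosome block order itself is free (so
## numeric labels "2" < "10" never trip a lexicographic comparison).
markers_sorted <- function(map) {
  rank <- match(map$chrom, unique(map$chrom))
  if (is.unsorted(rank)) return(FALSE)
  all(tapply(map$pos_bp, rank, function(p) !is.unsorted(p)))
}

## Natural marker order: chromosomes numerically when all labels are
## numeric-like, else lexicographically; positions within chromosome.
order_markers <- function(map) {
  ch <- map$chrom
  num <- suppressWarnings(as.numeric(ch))
  if (!anyNA(num)) order(num, map$pos_bp) else order(ch, map$pos_bp)
}

validate_marker_map <- function(map) {
  need <- c("marker", "chrom", "pos_bp")
  if (!is.data.frame(map) || !all(need %in% names(map)))
    stop("map must be a data.frame with columns marker, chrom, pos_bp")
  map <- map[, need]
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.numeric(map$pos_bp)
  if (anyDuplicated(map$marker)) {
    stop(sprintf("duplicate marker id '%s'", map$marker[duplicated(map$marker)][1]))
  }
  if (any(map$pos_bp < 1)) stop("pos_bp must be >= 1 (1-based physical coordinate)")
  rownames(map) <- NULL
  map
}

#' @export
print.geno_matrix <- function(x, ...) {
  map <- marker_map(x)
  cat(sprintf("geno_matrix: %d plants x %d markers on %d chromosome(s)\n",
              nrow(x), ncol(x), length(unique(map$chrom))))
  miss <- mean(is.na(x))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Marker map of a genotype matrix
#'
#' @param g a [geno_matrix()].
#' @return data.frame with columns `marker`, `chrom`, `pos_bp`.
#' @export
marker_map <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  attr(g, "map")
}

## Column subset that preserves the map (base `[` drops attributes).
subset_markers <- function(g, j) {
  map <- marker_map(g)
  if (is.logical(j)) j <- which(j)
  geno_matrix(unclass(g)[, j, drop = FALSE], map[j, , drop = FALSE])
}

subset_plants <- function(g, i) {
  geno_matrix(unclass(g)[i, , drop = FALSE], marker_map(g))
}

#' Construct a phenotype table
#'
#' @param plant character vector of plant ids.
#' @param phenotype character/factor vector of `"R"` (regrowth) or `"NR"`
#'   (non-regrowth), or the numeric file coding `1` = R, `2` = NR.
#' @return data.frame of class `pheno_table` with columns `plant`,
#'   `phenotype` (factor with levels R, NR).
#' @export
pheno_table <- function(plant, phenotype) {
  plant <- as.character(plant)
  if (anyDuplicated(plant))
    stop(sprintf("duplicate plant id '%s'", plant[duplicated(plant)][1]))
  phenotype <- decode_phenotype(phenotype)
  out <- data.frame(plant = plant, phenotype = phenotype)
  class(out) <- c("pheno_table", "data.frame")
  out
}

decode_phenotype <- function(x) {
  x <- trimws(as.character(x))
  ok <- x %in% c("R", "NR", "1", "2")
  if (!all(ok)) stop(sprintf("invalid phenotype code '%s' (expected R/NR or 1/2)", x[!ok][1]))
  x[x == "1"] <- "R"
  x[x == "2"] <- "NR"
  factor(x, levels = c("R", "NR"))
}

#' Summarize a phenotype table
#'
#' @param p a [pheno_table()].
#' @return list with `n_total`, `n_R`, `n_NR`.
#' @examples
#' summarize_phenotypes(pheno_table(c("a", "b", "c"), c("R", "R", "NR")))
#' @export
summarize_phenotypes <- function(p) {
  stopifnot(inherits(p, "pheno_table"))
  if (nrow(p) == 0) stop("empty phenotype table")
  n_R <- sum(p$phenotype == "R")
  list(n_total = nrow(p), n_R = n_R, n_NR = nrow(p) - n_R)
}

#' Join genotypes and phenotypes into an analysis dataset
#'
#' Inner join on plant id: plants present in only one component are dropped,
#' with the drops recorded (and messaged) rather than silent.
#'
#' @param genotypes a [geno_matrix()].
#' @param phenotypes a [pheno_table()].
#' @param quiet suppress the join message.
#' @return list of class `regrow_dataset` with elements `geno` (plants
#'   reordered to the join), `pheno`, and `join_log` (counts and ids of
#'   dropped plants).
#' @export
make_dataset <- function(genotypes, phenotypes, quiet = FALSE) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(phenotypes, "pheno_table"))
  gp <- rownames(genotypes)
  pp <- phenotypes$plant
  common <- intersect(gp, pp)
  if (length(common) == 0) stop("no plants in common between genotypes and phenotypes")
  drop_g <- setdiff(gp, common)
  drop_p <- setdiff(pp, common)
  if (!quiet && (length(drop_g) || length(drop_p)))
    message(sprintf("inner join dropped %d genotype-only and %d phenotype-only plant(s)",
                    length(drop_g), length(drop_p)))
  pheno <- phenotypes[match(common, phenotypes$plant), , drop = FALSE]
  rownames(pheno) <- NULL
  class(pheno) <- c("pheno_table", "data.frame")
  structure(list(
    geno = subset_plants(genotypes, match(common, gp)),
    pheno = pheno,
    join_log = list(n_matched = length(common),
                    dropped_genotype_only = drop_g,
                    dropped_phenotype_only = drop_p)
  ), class = "regrow_dataset")
}

#' @export
print.regrow_dataset <- function(x, ...) {
  s <- summarize_phenotypes(x$pheno)
  cat(sprintf("regrow_dataset: %d plants (%d R / %d NR), %d markers\n",
              s$n_total, s$n_R, s$n_NR, ncol(x$geno)))
  invisible(x)
}

#' Validate a dataset without mutating it
#'
#' Report-only diagnostics: plants present in only one component, per-site
#' missingness, and per-site allele counts (Zd allele dose: AA contributes 2,
#' AB contributes 1 of each, BB contributes 2 maize alleles; missing calls
#' excluded).
#'
#' @param genotypes a [geno_matrix()].
#' @param phenotypes a [pheno_table()].
#' @return list with `unmatched_genotype`, `unmatched_phenotype`,
#'   `n_matched`, and `site_report` (data.frame: marker, chrom, pos_bp,
#'   n_called, missing_frac, n_zd_alleles, n_maize_alleles, maf).
#' @export
validate_dataset <- function(genotypes, phenotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(phenotypes, "pheno_table"))
  gp <- rownames(genotypes)
  pp <- phenotypes$plant
  calls <- unclass(genotypes)
  n_called <- colSums(!is.na(calls))
  n_aa <- colSums(calls == 1L, na.rm = TRUE)
  n_ab <- colSums(calls == 2L, na.rm = TRUE)
  n_bb <- colSums(calls == 3L, na.rm = TRUE)
  zd <- 2L * n_aa + n_ab
  mz <- 2L * n_bb + n_ab
  tot <- zd + mz
  maf <- ifelse(tot > 0, pmin(zd, mz) / tot, NA_real_)
  list(
    unmatched_genotype = setdiff(gp, pp),
    unmatched_phenotype = setdiff(pp, gp),
    n_matched = length(intersect(gp, pp)),
    site_report = cbind(marker_map(genotypes),
                        data.frame(n_called = n_called,
                                   missing_frac = 1 - n_called / nrow(calls),
                                   n_zd_alleles = zd, n_maize_alleles = mz,
                                   maf = maf, row.names = NULL))
  )
}
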
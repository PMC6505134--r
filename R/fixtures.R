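#' Packaged phenotype/genotype tables from the B73-Zd and Zd-RF crosses
#'
#' `table2_b73zd()` returns the 134-plant B73 x *Z. diploperennis* F2
#' population: regrowth phenotype, PCR marker genotypes at *gt1*, *tb1* and
#' *id1* (coded 1 = homozygous Zd allele, 2 = homozygous maize allele, 3 =
#' heterozygous, `NA` = missing), and `gbs_included` flagging the 83 plants
#' (46 R, 37 NR) whose GBS SNP calls entered the genome scan.
#'
#' `table3_zdrf()` returns the regrowth phenotypes of the *Z. diploperennis*
#' x Rhee Flint derivatives: one F2 family (ZR2-001) and three F3 families
#' (ZR3-003, ZR3-005, ZR3-009), each F3 family descended from a single
#' regrowth F2 plant.
#'
#' `table4_counts()` returns the observed R/NR segregation counts per
#' population used by the goodness-of-fit tests.
#'
#' @return data.frames; see Details.
#' @examples
#' t2 <- table2_b73zd()
#' table(t2$phenotype)
#' sum(t2$gbs_included)
#' @export
table2_b73zd <- function() {
  path <- system.file("extdata", "table2_b73zd_f2.tsv", package = "regrowqtl",
                      mustWork = TRUE)
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         na.strings = "NA", stringsAsFactors = FALSE)
  d$phenotype <- factor(d$phenotype, levels = c("R", "NR"))
  for (m in c("gt1", "tb1", "id1")) d[[m]] <- as.integer(d[[m]])
  d$gbs_included <- as.logical(d$gbs_included)
  d
}

#' @rdname table2_b73zd
#' @export
table3_zdrf <- function() {
  path <- system.file("extdata", "table3_zdrf.tsv", package = "regrowqtl",
                      mustWork = TRUE)
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  d$phenotype <- factor(d$phenotype, levels = c("R", "NR"))
  d
}

#' @rdname table2_b73zd
#' @export
table4_counts <- function() {
  path <- system.file("extdata", "table4_segregation_counts.tsv",
                      package = "regrowqtl", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
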
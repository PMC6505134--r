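io_header <- function() {
  sprintf("# written by regrowqtl %s", as.character(utils::packageVersion("regrowqtl")))
}

#' Read a genotype table
#'
#' Reads a plants-x-markers genotype table in the `numeric123` dialect
#' (tab/comma separated; header row of marker ids; cells `1` = AA homozygous
#' Zd, `2` = BB homozygous maize, `3` = AB heterozygous, `NA`/`-`/empty =
#' missing), together with a sidecar map file giving `marker`, `chrom`,
#' `pos_bp` per marker. Unknown genotype tokens are an error naming the
#' offending row and column, never silently coerced.
#'
#' For VCF input see [read_genotype_vcf()].
#'
#' @param path genotype table path.
#' @param map_path sidecar marker map path (TSV with header
#'   `marker chrom pos_bp`).
#' @param sep field separator (default tab).
#' @return a [geno_matrix()].
#' @export
read_genotype_table <- function(path, map_path, sep = "\t") {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           check.names = FALSE, colClasses = "character",
                           row.names = 1)
  if (anyDuplicated(colnames(tab)))
    stop("malformed header: duplicate marker ids")
  map <- read_marker_map(map_path, sep = sep)
  calls <- matrix(NA_integer_, nrow(tab), ncol(tab),
                  dimnames = list(rownames(tab), colnames(tab)))
  for (j in seq_len(ncol(tab))) {
    v <- trimws(tab[[j]])
    miss <- is.na(v) | v %in% c("NA", "-", "", ".")
    known <- v %in% names(EXTERNAL_TO_INTERNAL)
    if (any(!miss & !known)) {
      i <- which(!miss & !known)[1]
      stop(sprintf("invalid genotype code '%s' at plant '%s', marker '%s'",
                   v[i], rownames(tab)[i], colnames(tab)[j]))
    }
    calls[known, j] <- EXTERNAL_TO_INTERNAL[v[known]]
  }
  map <- map[match(colnames(calls), map$marker), , drop = FALSE]
  if (anyNA(map$marker)) stop("map file is missing markers present in the genotype table")
  ord <- order_markers(map)
  geno_matrix(calls[, ord, drop = FALSE], map[ord, , drop = FALSE])
}

read_marker_map <- function(map_path, sep = "\t") {
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  map <- utils::read.table(map_path, header = TRUE, sep = sep,
                           comment.char = "#", check.names = FALSE)
  validate_marker_map(map)
}

#' Write a genotype table (numeric123 dialect)
#'
#' Inverse of [read_genotype_table()]: emits the genotype table and the
#' sidecar map as UTF-8 TSV with a commented header line recording the tool
#' version. `write_genotype_table` then `read_genotype_table` is the
#' identity.
#'
#' @param g a [geno_matrix()].
#' @param path,map_path output paths.
#' @return invisibly, `path`.
#' @export
write_genotype_table <- function(g, path, map_path) {
  stopifnot(inherits(g, "geno_matrix"))
  ext <- matrix(INTERNAL_TO_EXTERNAL[unclass(g)], nrow(g), ncol(g),
                dimnames = dimnames(g))
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(io_header(), con)
  writeLines(paste(c("plant", colnames(ext)), collapse = "\t"), con)
  utils::write.table(ext, con, sep = "\t", quote = FALSE, na = "NA",
                     col.names = FALSE, row.names = TRUE)
  close(con)
  con <- file(map_path, "w", encoding = "UTF-8")
  writeLines(io_header(), con)
  map <- marker_map(g)
  map$pos_bp <- format(map$pos_bp, scientific = FALSE, trim = TRUE)
  utils::write.table(map, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read genotypes from a minimal VCF
#'
#' Accepts a VCF (v4.x) restricted to biallelic sites and uses only the GT
#' field. Multi-allelic records are rejected. Allele orientation is declared,
#' not guessed: with `zd_is_ref = TRUE` (default) the REF allele is taken as
#' the *Z. diploperennis* parent allele and the single ALT as the maize
#' allele, so `0/0` maps to AA, `0/1` to AB and `1/1` to BB; with
#' `zd_is_ref = FALSE` the mapping is flipped.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param zd_is_ref logical; which parent carries the REF allele.
#' @return a [geno_matrix()] (marker ids `chrom_pos` unless the VCF has IDs).
#' @export
read_genotype_vcf <- function(path, zd_is_ref = TRUE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- rbind(vcfR::getFIX(v))  # rbind: keep a 1-row matrix for single records
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt)) || any(is.na(alt)) || any(alt == "."))
    stop("multi-allelic or ALT-less sites are not supported; filter to biallelic SNPs first")
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- sub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 1L
    out[x %in% c("0/1", "1/0")] <- 2L
    out[x %in% c("1/1")] <- 3L
    bad <- !is.na(x) & !x %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
    if (any(bad)) stop(sprintf("unsupported GT value '%s'", x[bad][1]))
    out
  }
  calls <- matrix(code(as.vector(gt)), nrow(gt), ncol(gt),
                  dimnames = dimnames(gt))
  if (!zd_is_ref) calls <- 4L - calls  # swap AA and BB
  ids <- fix[, "ID"]
  ids <- ifelse(is.na(ids) | ids == ".",
                paste0(fix[, "CHROM"], "_", fix[, "POS"]), ids)
  calls <- t(calls)  # vcfR: rows = sites; we want plants x markers
  colnames(calls) <- ids
  map <- data.frame(marker = ids, chrom = fix[, "CHROM"],
                    pos_bp = as.numeric(fix[, "POS"]))
  ord <- order_markers(map)
  geno_matrix(calls[, ord, drop = FALSE], map[ord, , drop = FALSE])
}

#' Read a phenotype table
#'
#' Two-column table (plant id, status). Status accepts both the textual
#' (`R`/`NR`) and numeric (`1` = R, `2` = NR) encodings. An empty file yields
#' an empty table with a warning.
#'
#' @param path file path; TSV with or without header line `plant phenotype`.
#' @return a [pheno_table()].
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty phenotype file: ", path)
    return(pheno_table(character(0), character(0)))
  }
  if (grepl("^plant\\b", lines[1], ignore.case = TRUE)) lines <- lines[-1]
  parts <- strsplit(lines, "[\t,]")
  if (any(lengths(parts) < 2)) stop("phenotype rows must have two columns (plant, status)")
  pheno_table(vapply(parts, `[[`, "", 1), vapply(parts, `[[`, "", 2))
}

#' Write a phenotype table
#'
#' @param p a [pheno_table()].
#' @param path output path (UTF-8 TSV, commented version header).
#' @return invisibly, `path`.
#' @export
write_phenotypes <- function(p, path) {
  stopifnot(inherits(p, "pheno_table"))
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(io_header(), con)
  utils::write.table(p, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
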
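#' End-to-end run configuration
#'
#' Exactly one input source: either file paths (`geno_path` + `map_path` +
#' `pheno_path`, or `pheno_path` alone for a phenotype-only segregation run)
#' or a simulation spec (`sim` = list with `n`, and optionally `genome`,
#' `causal`, `noise`).
#'
#' @param pheno_path,geno_path,map_path input file paths (numeric123
#'   dialect; see [read_genotype_table()]).
#' @param sim simulation spec list, or `NULL`.
#' @param filter a [filter_config()].
#' @param scan a [scan_config()].
#' @param outdir output directory, or `NULL` to skip persisting.
#' @param seed integer seed recorded in every output.
#' @return list of class `run_config`.
#' @export
run_config <- function(pheno_path = NULL, geno_path = NULL, map_path = NULL,
                       sim = NULL, filter = filter_config(),
                       scan = scan_config(), outdir = NULL, seed = 1L) {
  has_files <- !is.null(pheno_path)
  if (has_files == !is.null(sim))
    stop("exactly one input source: file paths xor a simulation spec")
  if (!is.null(geno_path) && is.null(map_path))
    stop("genotype input needs a sidecar map_path")
  structure(list(pheno_path = pheno_path, geno_path = geno_path,
                 map_path = map_path, sim = sim, filter = filter,
                 scan = scan, outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis workflow
#'
#' Phenotype summary and segregation-model fits, then (when genotypes are
#' available) the four-stage filter cascade and *both* genome-scan variants:
#' (a) on the post-stage-2 matrix (all imputed SNPs) and (b) on the
#' post-stage-4 matrix (model-filtered, cluster-collapsed), each with its
#' own permutation threshold and called intervals. With phenotype-only
#' input the filter/scan sections are marked skipped.
#'
#' @param cfg a [run_config()].
#' @return list of class `run_report`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  truth <- NULL
  if (!is.null(cfg$sim)) {
    s <- cfg$sim
    sim <- simulate_f2_population(
      n = s$n,
      genome = if (is.null(s$genome)) default_genome() else s$genome,
      causal = if (is.null(s$causal)) causal_model() else s$causal,
      noise = if (is.null(s$noise)) noise_spec() else s$noise,
      seed = cfg$seed)
    dataset <- sim$dataset
    truth <- sim$truth
    message(sprintf("stage simulate: %d plants x %d markers",
                    nrow(dataset$geno), ncol(dataset$geno)))
  } else {
    pheno <- read_phenotypes(cfg$pheno_path)
    if (is.null(cfg$geno_path)) {
      dataset <- NULL
    } else {
      geno <- read_genotype_table(cfg$geno_path, cfg$map_path)
      dataset <- make_dataset(geno, pheno)
      message(sprintf("stage load: %d plants x %d markers",
                      nrow(dataset$geno), ncol(dataset$geno)))
    }
  }
  ph <- if (is.null(dataset)) pheno else dataset$pheno
  counts <- summarize_phenotypes(ph)
  seg <- segregation_report(data.frame(population = "input",
                                       n_R = counts$n_R, n_NR = counts$n_NR))
  message(sprintf("stage segtest: %d R / %d NR, best fit %s",
                  counts$n_R, counts$n_NR, seg$best_fit[1]))

  report <- list(seed = cfg$seed, phenotype_counts = counts,
                 segregation = seg, truth = truth,
                 filter_counts = NULL, scans = NULL)
  if (is.null(dataset)) {
    report$skipped <- "no genotype matrix: filter cascade and scans skipped"
    class(report) <- "run_report"
    return(report)
  }

  casc <- run_filter_cascade(dataset, cfg$filter)
  message(sprintf("stage filter: %d -> %d -> %d -> %d -> %d markers",
                  sum(casc$counts$n_input), sum(casc$counts$n_stage1),
                  sum(casc$counts$n_stage2), sum(casc$counts$n_stage3),
                  sum(casc$counts$n_stage4)))
  report$filter_counts <- casc$counts
  report$clusters <- casc$clusters

  scans <- list()
  for (variant in c("stage2", "stage4")) {
    dd <- casc[[paste0("dataset_", variant)]]
    if (ncol(dd$geno) == 0) {
      message(sprintf("stage scan (%s): no markers survived; skipped", variant))
      scans[[variant]] <- list(scan = NULL, threshold = NULL,
                               intervals = call_intervals(
                                 structure(data.frame(chrom = character(0),
                                                      marker = character(0),
                                                      pos_cM = numeric(0),
                                                      pos_bp = numeric(0),
                                                      is_marker = logical(0),
                                                      lod = numeric(0)),
                                           class = c("scan_result", "data.frame")),
                                 Inf))
      next
    }
    gp <- calc_genoprob(dd, cfg = cfg$scan)
    sc <- scan_binary_em(gp, dd$pheno, cfg$scan)
    th <- permutation_threshold(gp, dd$pheno, cfg$scan)
    iv <- call_intervals(sc, th)
    message(sprintf("stage scan (%s): %d positions, threshold %.2f, %d interval(s)",
                    variant, nrow(sc), th$threshold, nrow(iv)))
    scans[[variant]] <- list(scan = sc, threshold = th, intervals = iv)
  }
  report$scans <- scans
  class(report) <- "run_report"
  if (!is.null(cfg$outdir)) persist_report(report, casc, cfg)
  report
}

persist_report <- function(report, casc, cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outdir, f)
  write_genotype_table(casc$dataset_stage2$geno, out("genotypes_stage2.tsv"),
                       out("map_stage2.tsv"))
  write_genotype_table(casc$dataset_stage4$geno, out("genotypes_stage4.tsv"),
                       out("map_stage4.tsv"))
  write_phenotypes(casc$dataset_stage2$pheno, out("phenotypes.tsv"))
  for (v in names(report$scans)) {
    sc <- report$scans[[v]]$scan
    if (is.null(sc)) next
    con <- file(out(sprintf("scan_%s.tsv", v)), "w", encoding = "UTF-8")
    writeLines(c(io_header(), sprintf("# seed: %d", cfg$seed)), con)
    utils::write.table(sc, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  writeLines(report_render(report, "tsv"), out("report.tsv"))
  writeLines(report_render(report, "markdown"), out("report.md"))
  invisible(NULL)
}

#' Render a run report
#'
#' Deterministic plain-text rendering: p-values at 4 decimals, LOD at 2.
#' The markdown and TSV renderings carry identical numbers.
#'
#' @param r a [run_all()] report.
#' @param format `"tsv"` or `"markdown"`.
#' @return character vector of lines.
#' @export
report_render <- function(r, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  md <- format == "markdown"
  h <- function(x) if (md) paste0("## ", x) else paste0("[", x, "]")
  lines <- c(h("phenotypes"),
             sprintf(if (md) "- total %d: %d R, %d NR" else "total\t%d\nR\t%d\nNR\t%d",
                     r$phenotype_counts$n_total, r$phenotype_counts$n_R,
                     r$phenotype_counts$n_NR),
             h("segregation models"))
  seg <- r$segregation
  pcols <- grep("^p_", names(seg), value = TRUE)
  for (pc in pcols)
    lines <- c(lines, sprintf(if (md) "- %s: p = %s%s" else "%s\t%s%s",
                              sub("p_", "model ", pc),
                              sprintf("%.4f", seg[[pc]][1]),
                              ifelse(sub("p_", "", pc) == seg$best_fit[1],
                                     " (best fit)", "")))
  if (!is.null(r$skipped)) {
    return(c(lines, h("filters"), "skipped", h("scans"), "skipped",
             sprintf(if (md) "- seed: %d" else "seed\t%d", r$seed)))
  }
  lines <- c(lines, h("filter cascade survivors"))
  fc <- r$filter_counts
  lines <- c(lines,
             if (md) sprintf("- chr%s: %d / %d / %d / %d / %d", fc$chrom,
                             fc$n_input, fc$n_stage1, fc$n_stage2,
                             fc$n_stage3, fc$n_stage4)
             else sprintf("chr%s\t%d\t%d\t%d\t%d\t%d", fc$chrom, fc$n_input,
                          fc$n_stage1, fc$n_stage2, fc$n_stage3, fc$n_stage4))
  for (v in names(r$scans)) {
    s <- r$scans[[v]]
    if (is.null(s$threshold)) {
      lines <- c(lines, h(sprintf("scan (%s)", v)),
                 if (md) "- no markers survived" else "no markers survived")
      next
    }
    lines <- c(lines, h(sprintf("scan (%s)", v)),
               sprintf(if (md) "- threshold: LOD %s" else "threshold\t%s",
                       sprintf("%.2f", s$threshold$threshold)))
    if (nrow(s$intervals) == 0) {
      lines <- c(lines, if (md) "- none significant" else "none significant")
    } else {
      iv <- s$intervals
      lines <- c(lines,
                 sprintf(if (md) "- chr%s: [%d, %d] bp, peak %d bp, LOD %s"
                         else "chr%s\t%d\t%d\t%d\t%s",
                         iv$chrom, iv$start_bp, iv$end_bp, iv$peak_bp,
                         sprintf("%.2f", iv$peak_lod)))
    }
  }
  c(lines, sprintf(if (md) "- seed: %d" else "seed\t%d", r$seed))
}

#' @export
print.run_report <- function(x, ...) {
  writeLines(report_render(x, "markdown"))
  invisible(x)
}
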
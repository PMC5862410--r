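#' Pipeline configuration with the standard thresholds
#'
#' Bundles every tunable threshold of the CSM inference pipeline with
#' its default: 100 bp seed/segment flank, coverage of at least 5 cells
#' with at least 10 cytosine counts each, calls requiring at least 8
#' cells with data, an estimated state difference of at least 0.3 and
#' BH-adjusted significance 0.05, and the EM controls.
#'
#' @param flank,min_cells,min_counts region-construction thresholds.
#' @param min_cells_call,theta_diff_cutoff,alpha calling thresholds.
#' @param restarts,tol,max_iter,seed EM controls.
#' @param pool empirical-Bayes pooling convention (`"sites"` or
#'   `"cells"`).
#' @param autosomes_only restrict input reads to autosomes.
#' @return a named list of class `csm_config`.
#' @export
csm_config <- function(flank = 100L, min_cells = 5L, min_counts = 10L,
                       min_cells_call = 8L, theta_diff_cutoff = 0.3,
                       alpha = 0.05, restarts = 10L, tol = 1e-6,
                       max_iter = 500L, seed = 1L, pool = "cells",
                       autosomes_only = TRUE) {
  cfg <- list(flank = flank, min_cells = min_cells, min_counts = min_counts,
              min_cells_call = min_cells_call,
              theta_diff_cutoff = theta_diff_cutoff, alpha = alpha,
              restarts = restarts, tol = tol, max_iter = max_iter,
              seed = seed, pool = pool, autosomes_only = autosomes_only)
  class(cfg) <- "csm_config"
  cfg
}

#' @export
print.csm_config <- function(x, ...) {
  cat("CSM pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Run the full CSM inference pipeline
#'
#' Executes the stages in order: 4-CpG segment extraction, ASM
#' exclusion, AM detection (single-cell, plus hairpin when provided) and
#' exclusion, bipolar seed finding, seed extension and merging, coverage
#' filtering, empirical-Bayes priors, two-state mixture fits with LRT
#' and BH adjustment, CSM calling, and the cell-to-cell variance table
#' for the called regions.
#'
#' @param reads a `read_patterns` frame (see [read_read_patterns()]).
#' @param asm_loci ASM interval frame, or `NULL`.
#' @param hairpin_reads optional hairpin `read_patterns` frame.
#' @param config a [csm_config()] list.
#' @param variance_ci compute bootstrap CIs in the variance table
#'   (default FALSE).
#' @return a `csm_run` list: `calls` (the [csm_scan()] table),
#'   `variance` (per-region variance table), `regions`, `counts`,
#'   `seeds`, `am_loci`, `stage_counts`, `config`, and a provenance
#'   `manifest`.
#' @export
run_pipeline <- function(reads, asm_loci = NULL, hairpin_reads = NULL,
                         config = csm_config(), variance_ci = FALSE) {
  stopifnot(inherits(config, "csm_config"))
  if (config$autosomes_only && nrow(reads) > 0L) {
    reads <- reads[is_autosome(reads$chrom), , drop = FALSE]
  }
  built <- build_candidate_regions(
    reads, asm_loci = asm_loci, hairpin_reads = hairpin_reads,
    flank = config$flank, min_cells = config$min_cells,
    min_counts = config$min_counts)
  calls <- csm_scan(built$counts, pool = config$pool,
                    restarts = config$restarts, tol = config$tol,
                    max_iter = config$max_iter, seed = config$seed,
                    theta_diff_cutoff = config$theta_diff_cutoff,
                    min_cells_call = config$min_cells_call,
                    alpha = config$alpha)
  var_tab <- if (nrow(calls) > 0L) {
    variance_scan(built$counts[built$counts$region_id %in% calls$region_id, ,
                               drop = FALSE],
                  ci = variance_ci, seed = config$seed, pool = config$pool)
  } else {
    data.frame(region_id = character(), n_cells = integer(), mu = numeric(),
               delta2 = numeric(), V_hat = numeric(), ci_lo = numeric(),
               ci_hi = numeric(), stringsAsFactors = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("csmeth")),
    n_reads = nrow(reads),
    n_hairpin_reads = if (is.null(hairpin_reads)) 0L else nrow(hairpin_reads),
    n_asm_intervals = if (is.null(asm_loci)) 0L else nrow(asm_loci),
    config = unclass(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  out <- list(calls = calls, variance = var_tab, regions = built$regions,
              counts = built$counts, seeds = built$seeds,
              am_loci = built$am_loci, stage_counts = built$stage_counts,
              config = config, manifest = manifest)
  class(out) <- "csm_run"
  out
}

#' @export
print.csm_run <- function(x, ...) {
  cat("CSM pipeline run\n")
  sc <- x$stage_counts
  cat(sprintf("  segments: %d (%d after ASM filter)\n",
              sc[["n_segments"]], sc[["n_segments_after_asm"]]))
  cat(sprintf("  AM loci: %d   seeds: %d\n", sc[["n_am"]], sc[["n_seeds"]]))
  cat(sprintf("  merged regions: %d   candidates after coverage: %d\n",
              sc[["n_merged"]], sc[["n_candidates"]]))
  cat(sprintf("  regions tested: %d   CSM calls: %d\n",
              nrow(x$calls), sum(x$calls$is_csm)))
  invisible(x)
}

#' Write the tables of a pipeline run to a directory
#'
#' Emits `calls.tsv`, `variance.tsv`, `regions.bed`, `counts.tsv` and a
#' plain-text `manifest.txt`.
#'
#' @param run a `csm_run` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_csm_run <- function(run, dir) {
  stopifnot(inherits(run, "csm_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(run$calls), file.path(dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$variance, file.path(dir, "variance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(run$regions)) {
    write_bed(data.frame(chrom = run$regions$chrom, start = run$regions$start,
                         end = run$regions$end, name = run$regions$region_id),
              file.path(dir, "regions.bed"))
  }
  utils::write.table(run$counts, file.path(dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("csmeth %s", run$manifest$package_version),
               sprintf("reads: %d", run$manifest$n_reads),
               sprintf("generated: %s", run$manifest$timestamp),
               "config:",
               sprintf("  %s = %s", names(run$manifest$config),
                       vapply(run$manifest$config, format, ""))),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}
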
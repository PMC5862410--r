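#' Co-methylation modules across samples
#'
#' Computes pairwise Pearson correlations between region methylation
#' profiles across samples, clusters regions hierarchically on the
#' distance `1 - r`, and cuts the tree at the correlation cutoff
#' (height `1 - cutoff`) to form co-methylation modules. Rows with any
#' missing value and rows with zero variance are excluded (the latter
#' with a warning).
#'
#' @param mat numeric matrix, rows = regions, columns = samples, values
#'   = methylation levels in \[0, 1\] (NA allowed, row dropped).
#' @param cutoff correlation cutoff defining modules (default 0.75).
#' @param min_module_size drop modules smaller than this (default 1,
#'   i.e. keep all).
#' @param linkage hierarchical linkage (default `"average"`).
#' @return data frame `region`, `module` (integer ids ordered by
#'   decreasing module size; regions in dropped modules get NA), with
#'   the `hclust` tree in `attr(, "tree")` and the correlation matrix in
#'   `attr(, "cor")`.
#' @export
comethylation_modules <- function(mat, cutoff = 0.75, min_module_size = 1L,
                                  linkage = "average") {
  stopifnot(is.matrix(mat))
  if (is.null(rownames(mat))) rownames(mat) <- paste0("region", seq_len(nrow(mat)))
  complete <- stats::complete.cases(mat)
  mat <- mat[complete, , drop = FALSE]
  sds <- apply(mat, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d constant row(s) excluded from clustering", sum(sds == 0)))
    mat <- mat[sds > 0, , drop = FALSE]
  }
  stopifnot(nrow(mat) >= 2L)
  cc <- stats::cor(t(mat))
  tree <- stats::hclust(stats::as.dist(1 - cc), method = linkage)
  raw <- stats::cutree(tree, h = 1 - cutoff)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  module <- unname(relabel[as.character(raw)])
  module[sizes[module] < min_module_size] <- NA_integer_
  out <- data.frame(region = rownames(mat), module = as.integer(module),
                    stringsAsFactors = FALSE)
  attr(out, "tree") <- tree
  attr(out, "cor") <- cc
  out
}

#' Read a region-by-sample methylation matrix from TSV
#'
#' First column = region id, remaining columns = samples; `NA` or empty
#' cells are missing.
#'
#' @param path input path.
#' @return numeric matrix with region rownames.
#' @export
read_methylation_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' Genomic-feature enrichment of CSM regions over controls
#'
#' For each named feature interval set, computes the fraction of CSM
#' regions overlapping the feature (>= 1 bp) divided by the fraction of
#' control regions overlapping it. A region overlapping a feature set
#' counts once per set.
#'
#' @param csm_regions,control_regions interval frames (`chrom`, `start`,
#'   `end`).
#' @param features named list of interval frames.
#' @return data frame: `feature`, `csm_frac`, `control_frac`,
#'   `fold_change` (`NA` when no control region overlaps).
#' @export
feature_enrichment <- function(csm_regions, control_regions, features) {
  stopifnot(length(names(features)) == length(features))
  csm_gr <- as_granges(csm_regions)
  ctl_gr <- as_granges(control_regions)
  rows <- lapply(names(features), function(fn) {
    f_gr <- as_granges(features[[fn]])
    # disjoint chromosome sets are a legitimate zero-overlap case; the
    # seqlevel mismatch warning is noise here
    cf <- mean(suppressWarnings(IRanges::overlapsAny(csm_gr, f_gr)))
    tf <- mean(suppressWarnings(IRanges::overlapsAny(ctl_gr, f_gr)))
    data.frame(feature = fn, csm_frac = cf, control_frac = tf,
               fold_change = if (tf > 0) cf / tf else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Promoter, CGI shore and shelf intervals from annotations
#'
#' Promoters are the 1 kb upstream of each TSS (strand-aware); shores
#' the 2 kb directly flanking each CpG island; shelves the further 2 kb
#' beyond each shore (2-4 kb from the island).
#'
#' @param genes gene-model frame (`chrom`, `tss`, `tes`, `strand`,
#'   `gene_id`) as from [read_gene_models()].
#' @param cgi CpG-island interval frame.
#' @return named list of interval frames: `promoter`, `cgi`,
#'   `cgi_shore`, `cgi_shelf`.
#' @export
standard_features <- function(genes = NULL, cgi = NULL) {
  out <- list()
  if (!is.null(genes)) {
    up <- ifelse(genes$strand == "+", genes$tss - 1000L, genes$tss)
    dn <- ifelse(genes$strand == "+", genes$tss, genes$tss + 1000L)
    out$promoter <- data.frame(chrom = genes$chrom,
                               start = pmax(0L, as.integer(up)),
                               end = as.integer(dn), stringsAsFactors = FALSE)
  }
  if (!is.null(cgi)) {
    out$cgi <- cgi[, c("chrom", "start", "end")]
    shore <- rbind(
      data.frame(chrom = cgi$chrom, start = pmax(0L, cgi$start - 2000L),
                 end = cgi$start, stringsAsFactors = FALSE),
      data.frame(chrom = cgi$chrom, start = cgi$end, end = cgi$end + 2000L,
                 stringsAsFactors = FALSE))
    shelf <- rbind(
      data.frame(chrom = cgi$chrom, start = pmax(0L, cgi$start - 4000L),
                 end = pmax(0L, cgi$start - 2000L), stringsAsFactors = FALSE),
      data.frame(chrom = cgi$chrom, start = cgi$end + 2000L,
                 end = cgi$end + 4000L, stringsAsFactors = FALSE))
    out$cgi_shore <- shore[shore$start < shore$end, , drop = FALSE]
    out$cgi_shelf <- shelf[shelf$start < shelf$end, , drop = FALSE]
  }
  out
}

#' Positional profile of regions along scaled peaks
#'
#' Each peak is divided into `n_bins` equal-sized bins; a region
#' increments every bin it overlaps, and bin counts are normalized by
#' the number of peaks.
#'
#' @param regions interval frame.
#' @param peaks interval frame (non-empty).
#' @param n_bins number of bins per peak (default 100).
#' @return numeric vector of length `n_bins` (frequency per bin).
#' @export
peak_profile <- function(regions, peaks, n_bins = 100L) {
  stopifnot(nrow(peaks) > 0L, n_bins >= 1L)
  prof <- numeric(n_bins)
  for (p in seq_len(nrow(peaks))) {
    w <- peaks$end[p] - peaks$start[p]
    edges <- peaks$start[p] + (0:n_bins) * (w / n_bins)
    hit <- vapply(seq_len(n_bins), function(bi) {
      any(regions$chrom == peaks$chrom[p] &
            regions$start < edges[bi + 1L] & regions$end > edges[bi])
    }, TRUE)
    prof <- prof + hit
  }
  prof / nrow(peaks)
}

#' GC content and CpG density of regions
#'
#' GC content is (G + C) / length; CpG density is the observed/expected
#' ratio `#CG * length / (#C * #G)` (0 when `#C * #G = 0`).
#'
#' @param regions interval frame (0-based half-open).
#' @param genome a named `DNAStringSet` (chromosome -> sequence).
#' @return data frame: `chrom`, `start`, `end`, `gc`, `cpg_oe`.
#' @export
seq_features <- function(regions, genome) {
  rows <- lapply(seq_len(nrow(regions)), function(k) {
    chrom <- regions$chrom[k]
    if (!chrom %in% names(genome)) {
      stop(sprintf("region %s:%d-%d outside the genome", chrom,
                   regions$start[k], regions$end[k]))
    }
    seq <- genome[[chrom]]
    if (regions$end[k] > length(seq) || regions$start[k] < 0L) {
      stop(sprintf("region %s:%d-%d outside contig bounds", chrom,
                   regions$start[k], regions$end[k]))
    }
    sub <- Biostrings::subseq(seq, start = regions$start[k] + 1L,
                              end = regions$end[k])
    len <- length(sub)
    freq <- Biostrings::alphabetFrequency(sub)
    nC <- freq[["C"]]; nG <- freq[["G"]]
    nCG <- Biostrings::countPattern("CG", sub)
    data.frame(chrom = chrom, start = regions$start[k], end = regions$end[k],
               gc = (nC + nG) / len,
               cpg_oe = if (nC * nG > 0) nCG * len / (nC * nG) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
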
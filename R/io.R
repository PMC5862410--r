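#' Read read-level CpG methylation calls
#'
#' Parses a per-read TSV of CpG methylation calls into a `read_patterns`
#' data frame, the package's canonical read-level representation. Each row
#' is one sequenced read from one cell, carrying the ordered CpG positions
#' it covers and the binary methylation call at each.
#'
#' The `readtsv` dialect has TAB-separated columns
#' `cell_id`, `chrom`, `strand`, comma-joined positions, a `0`/`1` call
#' string, and an optional sixth `pair_id` column linking the two strands
#' of a hairpin read pair. Lines starting with `#` are comments. The
#' `bismark_per_read` dialect accepts the same geometry with a leading
#' read-id column (read id, cell, chrom, strand, positions, calls).
#'
#' Positions are normalized to the forward-strand C of the CpG dyad:
#' calls reported on the minus strand (the G of the dyad, one base
#' downstream) are shifted by -1 so that both strands of a dyad pool into
#' one site. Hairpin analyses keep `strand` and `pair_id` so the two
#' strands of a molecule are never pooled there.
#'
#' @param path path to the TSV file.
#' @param dialect input dialect, `"readtsv"` (canonical) or
#'   `"bismark_per_read"`.
#' @param autosomes_only drop reads on non-autosomal chromosomes
#'   (chrX/chrY/chrM and any non-numeric contig name). Default `TRUE`.
#' @param genome optional `DNAStringSet` (named by chromosome); when
#'   given, positions that are not the C of a CpG dyad after
#'   normalization trigger a warning but the records are kept.
#' @return a `read_patterns` data frame with columns `cell_id`, `chrom`,
#'   `strand`, `pair_id` and list-columns `pos` (integer vectors) and
#'   `states` (integer 0/1 vectors). The number of malformed lines that
#'   were rejected is attached as attribute `n_rejected`.
#' @export
read_read_patterns <- function(path, dialect = c("readtsv", "bismark_per_read"),
                               autosomes_only = TRUE, genome = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(empty_read_patterns())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "bismark_per_read") {
    # strip the leading read-id column; remainder matches readtsv
    fields <- lapply(fields, function(f) f[-1L])
  }
  n_min <- 5L
  ok <- vapply(fields, length, 1L) >= n_min
  recs <- lapply(fields[ok], function(f) {
    pos <- suppressWarnings(as.integer(strsplit(f[4L], ",", fixed = TRUE)[[1L]]))
    st <- suppressWarnings(as.integer(strsplit(f[5L], "", fixed = TRUE)[[1L]]))
    if (anyNA(pos) || anyNA(st) || length(pos) != length(st) ||
        length(pos) < 1L || is.unsorted(pos, strictly = TRUE) ||
        !all(st %in% c(0L, 1L)) || !f[3L] %in% c("+", "-")) {
      return(NULL)
    }
    list(cell_id = f[1L], chrom = f[2L], strand = f[3L],
         pair_id = if (length(f) >= 6L && nzchar(f[6L])) f[6L] else NA_character_,
         pos = pos, states = st)
  })
  bad <- vapply(recs, is.null, TRUE)
  n_rejected <- sum(!ok) + sum(bad)
  recs <- recs[!bad]
  if (n_rejected > 0L) {
    warning(sprintf("%d malformed line(s) rejected in '%s'", n_rejected, path))
  }
  if (length(recs) == 0L) {
    out <- empty_read_patterns()
    attr(out, "n_rejected") <- n_rejected
    return(out)
  }
  out <- data.frame(
    cell_id = vapply(recs, `[[`, "", "cell_id"),
    chrom = vapply(recs, `[[`, "", "chrom"),
    strand = vapply(recs, `[[`, "", "strand"),
    pair_id = vapply(recs, `[[`, "", "pair_id"),
    stringsAsFactors = FALSE
  )
  out$pos <- lapply(recs, `[[`, "pos")
  out$states <- lapply(recs, `[[`, "states")
  out <- normalize_cpg_coords(out)
  if (autosomes_only) {
    out <- out[is_autosome(out$chrom), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(genome)) {
    check_cpg_positions(out, genome)
  }
  class(out) <- c("read_patterns", "data.frame")
  attr(out, "n_rejected") <- n_rejected
  out
}

empty_read_patterns <- function() {
  out <- data.frame(cell_id = character(), chrom = character(),
                    strand = character(), pair_id = character(),
                    stringsAsFactors = FALSE)
  out$pos <- list()
  out$states <- list()
  class(out) <- c("read_patterns", "data.frame")
  attr(out, "n_rejected") <- 0L
  out
}

is_autosome <- function(chrom) {
  grepl("^(chr)?[0-9]+$", chrom)
}

#' Normalize CpG coordinates to the forward-strand C of the dyad
#'
#' Minus-strand calls report the G of the CpG dyad, one base downstream of
#' the forward-strand C; they are shifted by -1 so both strands of a dyad
#' share one coordinate. Idempotent: already-normalized input is returned
#' unchanged (tracked by the `coord_normalized` attribute).
#'
#' @param reads a `read_patterns` data frame.
#' @return the same data frame with normalized `pos` and
#'   `coord_normalized = TRUE`.
#' @export
normalize_cpg_coords <- function(reads) {
  if (isTRUE(attr(reads, "coord_normalized"))) {
    return(reads)
  }
  minus <- which(reads$strand == "-")
  if (length(minus)) {
    reads$pos[minus] <- lapply(reads$pos[minus], function(p) p - 1L)
  }
  attr(reads, "coord_normalized") <- TRUE
  reads
}

check_cpg_positions <- function(reads, genome) {
  bad <- 0L
  for (k in seq_len(nrow(reads))) {
    chrom <- reads$chrom[k]
    if (!chrom %in% names(genome)) next
    seq <- genome[[chrom]]
    p <- reads$pos[[k]]
    p <- p[p >= 1L & p + 1L <= length(seq)]
    if (!length(p)) next
    di <- as.character(Biostrings::extractAt(
      seq, IRanges::IRanges(start = p, width = 2L)))
    bad <- bad + sum(di != "CG")
  }
  if (bad > 0L) {
    warning(sprintf("%d position(s) are not the C of a CpG dyad; records kept", bad))
  }
  invisible(bad)
}

#' Write read patterns in the canonical readtsv dialect
#'
#' On-disk positions are per-strand (minus-strand calls at the G of the
#' dyad), so normalized coordinates are shifted back by +1 on minus
#' strands; a write/read cycle is the identity.
#'
#' @param reads a `read_patterns` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_read_patterns <- function(reads, path) {
  denorm <- isTRUE(attr(reads, "coord_normalized"))
  lines <- vapply(seq_len(nrow(reads)), function(k) {
    p <- reads$pos[[k]]
    if (denorm && reads$strand[k] == "-") p <- p + 1L
    base <- paste(reads$cell_id[k], reads$chrom[k], reads$strand[k],
                  paste(p, collapse = ","),
                  paste(reads$states[[k]], collapse = ""), sep = "\t")
    if (!is.na(reads$pair_id[k])) paste(base, reads$pair_id[k], sep = "\t") else base
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' Reads a BED3+ file into a data frame of 0-based half-open intervals,
#' sorted by chromosome and start. Records with `start >= end` are
#' rejected with a warning. Overlapping records are preserved as-is (no
#' merging).
#'
#' @param path path to a BED file (3 or more columns; `#` comments and
#'   `track` lines skipped).
#' @return data frame with columns `chrom`, `start`, `end` (and `name` if
#'   a 4th column is present).
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                   nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  name <- vapply(fields, function(f) if (length(f) >= 4L) f[4L] else NA_character_, "")
  bad <- is.na(start) | is.na(end) | start >= end
  if (any(bad)) {
    warning(sprintf("%d BED record(s) rejected (start >= end or unparsable)", sum(bad)))
  }
  out <- data.frame(chrom = chrom[!bad], start = start[!bad], end = end[!bad],
                    stringsAsFactors = FALSE)
  if (!all(is.na(name[!bad]))) out$name <- name[!bad]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write intervals as BED3(+name)
#'
#' @param x data frame with `chrom`, `start`, `end` and optionally `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end")
  df <- x[, cols, drop = FALSE]
  if (!is.null(x$name)) df$name <- x$name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF-lite TSV
#'
#' Columns: chrom, tss, tes, strand, gene_id (TAB-separated, `#` comments).
#' TSS/TES are given in genomic coordinates; for minus-strand genes the
#' TSS is the larger coordinate.
#'
#' @param path input path.
#' @return data frame with columns `chrom`, `tss`, `tes`, `strand`,
#'   `gene_id`.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "tss", "tes", "strand", "gene_id"))
  df
}

#' Pooled methylation level of a set of CpG site counts
#'
#' The methylation level is the ratio of methylated cytosine counts to
#' total cytosine counts, pooled over sites.
#'
#' @param meth methylated counts per site.
#' @param total total counts per site (same length).
#' @return `sum(meth)/sum(total)`, or `NA_real_` when the total count is
#'   zero (undefined level).
#' @export
methylation_level <- function(meth, total) {
  stopifnot(length(meth) == length(total), all(meth <= total),
            all(meth >= 0), all(total >= 0))
  n <- sum(total)
  if (n == 0) return(NA_real_)
  sum(meth) / n
}

# GRanges helpers -------------------------------------------------------

as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
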
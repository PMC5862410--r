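#' Extract 4-CpG segments from read-level calls
#'
#' Every run of four consecutive CpG sites observed within a single read
#' yields one sliding 4-CpG window, so a read covering c CpGs contributes
#' max(0, c - 3) windows. Windows with identical position quadruples are
#' collapsed across reads and cells into one segment with per-cell
#' 4-bit pattern tallies.
#'
#' "Consecutive" means consecutive as observed on the read; by default no
#' cap is placed on the genomic span of a window (`max_span = Inf`).
#'
#' @param reads a `read_patterns` data frame.
#' @param max_span optional maximum genomic span (bp) of a window,
#'   measured pos4 - pos1; windows wider than this are skipped.
#' @return a `segment_tally` data frame with one row per
#'   (segment, cell, pattern): columns `chrom`, `pos1`..`pos4`,
#'   `cell_id`, `pattern` (4-char 0/1 string), `count`.
#' @export
extract_4cpg_segments <- function(reads, max_span = Inf) {
  if (nrow(reads) == 0L) return(empty_segment_tally())
  c_r <- lengths(reads$pos)
  n_win <- pmax(0L, c_r - 3L)
  if (sum(n_win) == 0L) return(empty_segment_tally())
  # flatten all reads; window g starts at flat index off[read] + within-read
  flat_pos <- unlist(reads$pos, use.names = FALSE)
  flat_st <- unlist(reads$states, use.names = FALSE)
  ridx <- rep.int(seq_len(nrow(reads)), n_win)
  off <- cumsum(c(0L, c_r))[ridx]
  g <- off + sequence(n_win[n_win > 0L])
  win <- data.frame(
    chrom = reads$chrom[ridx],
    pos1 = flat_pos[g], pos2 = flat_pos[g + 1L],
    pos3 = flat_pos[g + 2L], pos4 = flat_pos[g + 3L],
    cell_id = reads$cell_id[ridx],
    pattern = paste0(flat_st[g], flat_st[g + 1L], flat_st[g + 2L],
                     flat_st[g + 3L]),
    stringsAsFactors = FALSE)
  if (is.finite(max_span)) {
    win <- win[win$pos4 - win$pos1 <= max_span, , drop = FALSE]
  }
  if (nrow(win) == 0L) return(empty_segment_tally())
  key <- paste(win$chrom, win$pos1, win$pos2, win$pos3, win$pos4,
               win$cell_id, win$pattern, sep = "\t")
  cnt <- rowsum(rep(1L, nrow(win)), key, reorder = FALSE)
  first <- !duplicated(key)
  agg <- win[first, , drop = FALSE]
  agg$count <- as.integer(cnt[match(key[first], rownames(cnt)), 1L])
  agg <- agg[order(agg$chrom, agg$pos1, agg$pos2, agg$pos3, agg$pos4,
                   agg$cell_id, agg$pattern), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("segment_tally", "data.frame")
  agg
}

empty_segment_tally <- function() {
  out <- data.frame(chrom = character(), pos1 = integer(), pos2 = integer(),
                    pos3 = integer(), pos4 = integer(), cell_id = character(),
                    pattern = character(), count = integer(),
                    stringsAsFactors = FALSE)
  class(out) <- c("segment_tally", "data.frame")
  out
}

#' Segment identity key (chrom + position quadruple)
#'
#' @param segments a `segment_tally` data frame (or any frame with
#'   `chrom`, `pos1`..`pos4`).
#' @return character vector of keys, one per row.
#' @export
segment_key <- function(segments) {
  paste(segments$chrom, segments$pos1, segments$pos2, segments$pos3,
        segments$pos4, sep = ":")
}

#' Summarize 4-CpG segments
#'
#' @param segments a `segment_tally` data frame.
#' @return list with `per_segment` (one row per distinct segment:
#'   `chrom`, `pos1`..`pos4`, `n_cells` covering cells, `mean_depth`
#'   reads per covering cell) and `per_cell` (`cell_id`, `n_segments`).
#'   Both deterministically ordered.
#' @export
segment_summary <- function(segments) {
  if (nrow(segments) == 0L) {
    return(list(
      per_segment = data.frame(chrom = character(), pos1 = integer(),
                               pos2 = integer(), pos3 = integer(),
                               pos4 = integer(), n_cells = integer(),
                               mean_depth = numeric(), stringsAsFactors = FALSE),
      per_cell = data.frame(cell_id = character(), n_segments = integer(),
                            stringsAsFactors = FALSE)))
  }
  key <- segment_key(segments)
  cell_depth <- stats::aggregate(
    list(depth = segments$count),
    by = list(key = key, chrom = segments$chrom, pos1 = segments$pos1,
              pos2 = segments$pos2, pos3 = segments$pos3,
              pos4 = segments$pos4, cell_id = segments$cell_id),
    FUN = sum)
  sp <- split(cell_depth, cell_depth$key)
  per_segment <- do.call(rbind, lapply(sp, function(d) {
    data.frame(chrom = d$chrom[1L], pos1 = d$pos1[1L], pos2 = d$pos2[1L],
               pos3 = d$pos3[1L], pos4 = d$pos4[1L],
               n_cells = nrow(d), mean_depth = mean(d$depth),
               stringsAsFactors = FALSE)
  }))
  per_segment <- per_segment[order(per_segment$chrom, per_segment$pos1,
                                   per_segment$pos2, per_segment$pos3,
                                   per_segment$pos4), , drop = FALSE]
  rownames(per_segment) <- NULL
  per_cell <- stats::aggregate(
    list(n_segments = rep(1L, nrow(cell_depth))),
    by = list(cell_id = cell_depth$cell_id), FUN = sum)
  per_cell <- per_cell[order(per_cell$cell_id), , drop = FALSE]
  rownames(per_cell) <- NULL
  list(per_segment = per_segment, per_cell = per_cell)
}

#' Per-cell pattern tallies of one segment, as a named list
#'
#' @param segments a `segment_tally` data frame.
#' @return named list keyed by segment key; each element a named list
#'   keyed by cell_id of named integer vectors (pattern -> count).
#' @export
segment_tallies <- function(segments) {
  if (nrow(segments) == 0L) return(list())
  key <- segment_key(segments)
  lapply(split(segments, key), function(d) {
    lapply(split(d, d$cell_id), function(dd) {
      stats::setNames(dd$count, dd$pattern)
    })
  })
}
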
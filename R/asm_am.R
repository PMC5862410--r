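#' Filter 4-CpG segments overlapping known ASM loci
#'
#' A segment is removed when any of its four CpG positions falls inside
#' any annotated allele-specific methylation (ASM) interval. Position
#' membership (not span overlap) is the criterion: ASM annotations are
#' CpG-resolved, so a segment is tainted exactly when it reads out an
#' annotated CpG.
#'
#' @param segments a `segment_tally` data frame.
#' @param asm_loci data frame of ASM intervals (`chrom`, `start`, `end`;
#'   0-based half-open).
#' @return list with `kept` and `removed` `segment_tally` frames; an
#'   exact partition of the input rows.
#' @export
filter_asm <- function(segments, asm_loci) {
  if (nrow(segments) == 0L || is.null(asm_loci) || nrow(asm_loci) == 0L) {
    return(list(kept = segments, removed = segments[0, , drop = FALSE]))
  }
  asm_gr <- as_granges(asm_loci)
  hit <- rep(FALSE, nrow(segments))
  for (col in c("pos1", "pos2", "pos3", "pos4")) {
    pos_gr <- GenomicRanges::GRanges(
      seqnames = segments$chrom,
      ranges = IRanges::IRanges(start = segments[[col]] + 1L, width = 1L))
    hit <- hit | IRanges::overlapsAny(pos_gr, asm_gr)
  }
  kept <- segments[!hit, , drop = FALSE]
  removed <- segments[hit, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Detect asymmetric methylation (AM) from hairpin read pairs
#'
#' Hairpin bisulfite sequencing reads both strands of one molecule; a
#' 4-CpG segment is called AM when at least one read pair shows the
#' completely methylated pattern (`1111`) on one strand and the
#' completely unmethylated pattern (`0000`) on the mate strand. Pairing
#' is by `pair_id` over identical (coordinate-normalized) 4-CpG windows
#' on complementary strands; pairs whose windows only partially overlap
#' are ignored, and unpaired reads are skipped with a warning.
#'
#' @param hairpin_reads a `read_patterns` data frame carrying `pair_id`.
#' @return data frame of AM loci: `chrom`, `pos1`..`pos4`, `key`,
#'   `evidence = "hairpin"`.
#' @export
detect_am_hairpin <- function(hairpin_reads) {
  reads <- hairpin_reads[!is.na(hairpin_reads$pair_id), , drop = FALSE]
  n_unpaired <- nrow(hairpin_reads) - nrow(reads)
  loci <- list()
  if (nrow(reads) > 0L) {
    for (pr in split(seq_len(nrow(reads)), reads$pair_id)) {
      if (length(pr) != 2L) {
        n_unpaired <- n_unpaired + length(pr)
        next
      }
      i <- pr[1L]; j <- pr[2L]
      if (reads$strand[i] == reads$strand[j]) next
      # windows over the pair's common 4-CpG runs
      wi <- read_windows(reads$pos[[i]], reads$states[[i]], reads$chrom[i])
      wj <- read_windows(reads$pos[[j]], reads$states[[j]], reads$chrom[j])
      if (is.null(wi) || is.null(wj)) next
      m <- merge(wi, wj, by = c("chrom", "pos1", "pos2", "pos3", "pos4"))
      if (nrow(m) == 0L) next
      am <- (m$pattern.x == "1111" & m$pattern.y == "0000") |
        (m$pattern.x == "0000" & m$pattern.y == "1111")
      if (any(am)) {
        loci[[length(loci) + 1L]] <-
          m[am, c("chrom", "pos1", "pos2", "pos3", "pos4"), drop = FALSE]
      }
    }
  }
  if (n_unpaired > 0L) {
    warning(sprintf("%d hairpin read(s) without a complete pair skipped", n_unpaired))
  }
  am_locus_frame(loci, "hairpin")
}

read_windows <- function(pos, states, chrom) {
  c_r <- length(pos)
  if (c_r < 4L) return(NULL)
  idx <- seq_len(c_r - 3L)
  data.frame(chrom = chrom,
             pos1 = pos[idx], pos2 = pos[idx + 1L],
             pos3 = pos[idx + 2L], pos4 = pos[idx + 3L],
             pattern = paste0(states[idx], states[idx + 1L],
                              states[idx + 2L], states[idx + 3L]),
             stringsAsFactors = FALSE)
}

#' Detect AM candidates from single-cell pattern tallies
#'
#' A 4-CpG segment is flagged AM when some single cell carries both at
#' least one completely methylated read (`1111`) and at least one
#' completely unmethylated read (`0000`). Bipolarity across different
#' cells is not AM (it is the CSM seed signal).
#'
#' @param segments a `segment_tally` data frame.
#' @return data frame of AM loci: `chrom`, `pos1`..`pos4`, `key`,
#'   `evidence = "single_cell"`.
#' @export
detect_am_single_cell <- function(segments) {
  if (nrow(segments) == 0L) return(am_locus_frame(list(), "single_cell"))
  key_cell <- paste(segment_key(segments), segments$cell_id, sep = "|")
  has11 <- segments$pattern == "1111" & segments$count > 0L
  has00 <- segments$pattern == "0000" & segments$count > 0L
  am_cells <- intersect(unique(key_cell[has11]), unique(key_cell[has00]))
  if (length(am_cells) == 0L) return(am_locus_frame(list(), "single_cell"))
  keys <- unique(sub("\\|[^|]*$", "", am_cells))
  sel <- segments[match(keys, segment_key(segments)),
                  c("chrom", "pos1", "pos2", "pos3", "pos4"), drop = FALSE]
  am_locus_frame(list(sel), "single_cell")
}

am_locus_frame <- function(pieces, evidence) {
  if (length(pieces) == 0L) {
    out <- data.frame(chrom = character(), pos1 = integer(), pos2 = integer(),
                      pos3 = integer(), pos4 = integer(), key = character(),
                      evidence = character(), stringsAsFactors = FALSE)
    return(out)
  }
  df <- unique(do.call(rbind, pieces))
  df$key <- segment_key(df)
  df <- df[!duplicated(df$key), , drop = FALSE]
  df$evidence <- evidence
  df <- df[order(df$chrom, df$pos1, df$pos2, df$pos3, df$pos4), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Merge hairpin- and single-cell-derived AM locus sets
#'
#' Set union keyed by the 4-CpG segment; loci present in both inputs get
#' `evidence = "both"`.
#'
#' @param hairpin_set,sc_set AM locus frames from [detect_am_hairpin()]
#'   and [detect_am_single_cell()].
#' @return merged AM locus frame with provenance in `evidence`.
#' @export
merge_am <- function(hairpin_set, sc_set) {
  both <- rbind(hairpin_set, sc_set)
  if (nrow(both) == 0L) return(am_locus_frame(list(), "none")[0, , drop = FALSE])
  sp <- split(both, both$key)
  out <- do.call(rbind, lapply(sp, function(d) {
    ev <- sort(unique(d$evidence))
    d <- d[1L, , drop = FALSE]
    d$evidence <- if (length(ev) > 1L) "both" else ev
    d
  }))
  out <- out[order(out$chrom, out$pos1, out$pos2, out$pos3, out$pos4), , drop = FALSE]
  rownames(out) <- NULL
  out
}
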
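#' Find bipolar CSM seed segments
#'
#' After ASM exclusion, a 4-CpG segment is a CSM seed when some cell
#' carries at least one completely methylated read (`1111`) and a
#' *different* cell carries at least one completely unmethylated read
#' (`0000`), and the segment is not an annotated AM locus. Within-cell
#' bipolarity is AM, not CSM, and takes precedence.
#'
#' @param segments a `segment_tally` data frame (ASM-filtered).
#' @param am_loci AM locus frame (from [merge_am()] or either detector);
#'   may be `NULL`.
#' @return the subset of distinct segments that are seeds, one row per
#'   segment (`chrom`, `pos1`..`pos4`, `key`).
#' @export
find_bipolar_seeds <- function(segments, am_loci = NULL) {
  empty <- data.frame(chrom = character(), pos1 = integer(), pos2 = integer(),
                      pos3 = integer(), pos4 = integer(), key = character(),
                      stringsAsFactors = FALSE)
  if (nrow(segments) == 0L) return(empty)
  key <- segment_key(segments)
  meth_cells <- unique(paste0(key, "|", segments$cell_id)[
    segments$pattern == "1111" & segments$count > 0L])
  unmeth_cells <- unique(paste0(key, "|", segments$cell_id)[
    segments$pattern == "0000" & segments$count > 0L])
  strip <- function(x) sub("\\|[^|]*$", "", x)
  cell_of <- function(x) sub("^.*\\|", "", x)
  # bipolar: keys with a fully-methylated cell and a *different*
  # fully-unmethylated cell
  cand <- intersect(unique(strip(meth_cells)), unique(strip(unmeth_cells)))
  cand <- cand[vapply(cand, function(k) {
    mcell <- cell_of(meth_cells[strip(meth_cells) == k])
    ucell <- cell_of(unmeth_cells[strip(unmeth_cells) == k])
    any(outer(mcell, ucell, `!=`))
  }, TRUE)]
  if (!is.null(am_loci) && nrow(am_loci) > 0L) {
    cand <- setdiff(cand, am_loci$key)
  }
  if (length(cand) == 0L) return(empty)
  sel <- segments[match(cand, key), c("chrom", "pos1", "pos2", "pos3", "pos4"),
                  drop = FALSE]
  sel$key <- cand
  sel <- sel[order(sel$chrom, sel$pos1, sel$pos2, sel$pos3, sel$pos4), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Extend segment spans and merge overlaps into regions
#'
#' Each segment span `[pos1, pos4 + 1)` is widened by `flank` bp on both
#' sides; transitively overlapping widened intervals are unioned into one
#' region. When `seeds` is given, only merged regions containing at least
#' one seed segment are returned (the candidate universe); with
#' `seeds = NULL` all merged regions are returned (the control universe).
#'
#' @param segments a `segment_tally` data frame (ASM-filtered); distinct
#'   segments are taken from its position quadruples.
#' @param seeds seed frame from [find_bipolar_seeds()], or `NULL`.
#' @param flank extension in bp on each side (default 100).
#' @return data frame of regions: `region_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `n_seeds`.
#' @export
extend_and_merge <- function(segments, seeds = NULL, flank = 100L) {
  stopifnot(flank >= 0L)
  empty <- data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(), n_seeds = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(segments) == 0L) return(empty)
  segs <- unique(segments[, c("chrom", "pos1", "pos4"), drop = FALSE])
  ext <- data.frame(chrom = segs$chrom,
                    start = pmax(0L, segs$pos1 - as.integer(flank)),
                    end = segs$pos4 + 1L + as.integer(flank),
                    stringsAsFactors = FALSE)
  merged_gr <- GenomicRanges::reduce(as_granges(ext), min.gapwidth = 0L)
  merged <- granges_to_df(merged_gr)
  if (!is.null(seeds)) {
    if (nrow(seeds) == 0L) return(empty)
    seed_pt <- GenomicRanges::GRanges(
      seqnames = seeds$chrom,
      ranges = IRanges::IRanges(start = seeds$pos1 + 1L, end = seeds$pos4 + 1L))
    cnt <- GenomicRanges::countOverlaps(merged_gr, seed_pt, type = "any")
    merged$n_seeds <- as.integer(cnt)
    merged <- merged[merged$n_seeds >= 1L, , drop = FALSE]
  } else {
    merged$n_seeds <- 0L
  }
  if (nrow(merged) == 0L) return(empty)
  merged <- merged[order(merged$chrom, merged$start, merged$end), , drop = FALSE]
  merged <- data.frame(
    region_id = sprintf("%s:%d-%d", merged$chrom, merged$start, merged$end),
    merged, stringsAsFactors = FALSE)
  rownames(merged) <- NULL
  merged
}

#' Rebuild per-region, per-cell CpG site counts from reads
#'
#' Site-level methylated and total counts (m, n per CpG per cell) are
#' aggregated from *all* reads overlapping each region, not only from the
#' reads that contributed 4-CpG windows, since the downstream
#' beta-binomial layer operates on per-CpG counts.
#'
#' @param regions region frame from [extend_and_merge()].
#' @param reads a `read_patterns` data frame.
#' @return long data frame: `region_id`, `cell_id`, `position`, `meth`,
#'   `total`.
#' @export
region_site_counts <- function(regions, reads) {
  empty <- data.frame(region_id = character(), cell_id = character(),
                      position = integer(), meth = integer(), total = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(regions) == 0L || nrow(reads) == 0L) return(empty)
  # flatten reads to site-level observations
  nsite <- lengths(reads$pos)
  obs <- data.frame(
    chrom = rep(reads$chrom, nsite),
    position = unlist(reads$pos),
    cell_id = rep(reads$cell_id, nsite),
    state = unlist(reads$states),
    stringsAsFactors = FALSE)
  obs_gr <- GenomicRanges::GRanges(
    seqnames = obs$chrom,
    ranges = IRanges::IRanges(start = obs$position + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(obs_gr, as_granges(regions))
  if (length(hits) == 0L) return(empty)
  qh <- S4Vectors::queryHits(hits)
  rid <- regions$region_id[S4Vectors::subjectHits(hits)]
  cid <- obs$cell_id[qh]
  pos <- obs$position[qh]
  key <- paste(rid, cid, pos, sep = "\t")
  sums <- rowsum(cbind(meth = obs$state[qh], total = rep(1L, length(qh))),
                 key, reorder = FALSE)
  first <- !duplicated(key)
  ord <- match(key[first], rownames(sums))
  agg <- data.frame(region_id = rid[first], cell_id = cid[first],
                    position = pos[first],
                    meth = as.integer(sums[ord, "meth"]),
                    total = as.integer(sums[ord, "total"]),
                    stringsAsFactors = FALSE)
  agg <- agg[order(agg$region_id, agg$cell_id, agg$position), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Coverage filter for candidate regions
#'
#' A cell covers a region when its summed total CpG count in the region
#' is at least `min_counts`; a region is kept when at least `min_cells`
#' cells cover it. Non-covering cells are dropped from the returned
#' counts.
#'
#' @param regions region frame.
#' @param counts site-count frame from [region_site_counts()].
#' @param min_cells minimum number of covering cells (default 5).
#' @param min_counts minimum per-cell total cytosine count (default 10).
#' @return list with `regions` (kept rows, plus `n_cells` column) and
#'   `counts` (rows restricted to kept regions and covering cells).
#' @export
coverage_filter <- function(regions, counts, min_cells = 5L, min_counts = 10L) {
  if (nrow(regions) == 0L || nrow(counts) == 0L) {
    out_r <- regions[0, , drop = FALSE]
    out_r$n_cells <- integer(0)
    return(list(regions = out_r, counts = counts[0, , drop = FALSE]))
  }
  percell <- stats::aggregate(
    list(n_total = counts$total),
    by = counts[, c("region_id", "cell_id")], FUN = sum)
  covering <- percell[percell$n_total >= min_counts, , drop = FALSE]
  ncell <- table(covering$region_id)
  keep_ids <- names(ncell)[ncell >= min_cells]
  kept <- regions[regions$region_id %in% keep_ids, , drop = FALSE]
  kept$n_cells <- as.integer(ncell[kept$region_id])
  ck <- paste(counts$region_id, counts$cell_id, sep = "|")
  keep_pairs <- paste(covering$region_id, covering$cell_id, sep = "|")
  kept_counts <- counts[ck %in% keep_pairs & counts$region_id %in% keep_ids, ,
                        drop = FALSE]
  rownames(kept) <- rownames(kept_counts) <- NULL
  list(regions = kept, counts = kept_counts)
}

#' Build candidate CSM regions from reads
#'
#' Convenience wrapper running the full region-construction path:
#' 4-CpG segment extraction, ASM exclusion, AM detection and exclusion,
#' bipolar seed finding, extension/merging, per-cell count assembly and
#' the coverage filter.
#'
#' @param reads a `read_patterns` data frame.
#' @param asm_loci ASM interval frame (or `NULL`).
#' @param hairpin_reads optional hairpin `read_patterns` for AM
#'   detection.
#' @param flank,min_cells,min_counts thresholds, defaults 100 bp / 5
#'   cells / 10 counts.
#' @return list with `regions`, `counts`, `seeds`, `am_loci`,
#'   `segments_kept` and per-stage tallies in `stage_counts`.
#' @export
build_candidate_regions <- function(reads, asm_loci = NULL, hairpin_reads = NULL,
                                    flank = 100L, min_cells = 5L,
                                    min_counts = 10L) {
  segments <- extract_4cpg_segments(reads)
  asm_part <- filter_asm(segments, asm_loci)
  am_sc <- detect_am_single_cell(asm_part$kept)
  am_hp <- if (!is.null(hairpin_reads) && nrow(hairpin_reads) > 0L) {
    detect_am_hairpin(hairpin_reads)
  } else {
    am_sc[0, , drop = FALSE]
  }
  am <- merge_am(am_hp, am_sc)
  seeds <- find_bipolar_seeds(asm_part$kept, am)
  regions <- extend_and_merge(asm_part$kept, seeds = seeds, flank = flank)
  counts <- region_site_counts(regions, reads)
  filt <- coverage_filter(regions, counts, min_cells = min_cells,
                          min_counts = min_counts)
  list(regions = filt$regions, counts = filt$counts, seeds = seeds,
       am_loci = am, segments_kept = asm_part$kept,
       stage_counts = c(
         n_segment_rows = nrow(segments),
         n_segments = length(unique(segment_key(segments))),
         n_segments_after_asm = length(unique(segment_key(asm_part$kept))),
         n_am = nrow(am), n_seeds = nrow(seeds),
         n_merged = nrow(regions), n_candidates = nrow(filt$regions)))
}

#' Build the control region universe
#'
#' Same extension, merging and coverage filtering as the candidate path,
#' applied to *all* ASM-filtered segments without the seed requirement.
#' Every candidate region is by construction contained in some control
#' region.
#'
#' @inheritParams build_candidate_regions
#' @param segments ASM-filtered `segment_tally` frame (e.g.
#'   `build_candidate_regions(...)$segments_kept`).
#' @return list with `regions` and `counts` as in [coverage_filter()].
#' @export
build_control_regions <- function(segments, reads, flank = 100L,
                                  min_cells = 5L, min_counts = 10L) {
  regions <- extend_and_merge(segments, seeds = NULL, flank = flank)
  counts <- region_site_counts(regions, reads)
  coverage_filter(regions, counts, min_cells = min_cells,
                  min_counts = min_counts)
}
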
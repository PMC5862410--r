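test_that("bipolar seeds need full methylation and full unmethylation in different cells", {
  seeds <- function(reads, am = NULL) {
    find_bipolar_seeds(extract_4cpg_segments(reads), am)
  }
  expect_equal(nrow(seeds(rbind_reads(
    locus_read("c1", "1111"), locus_read("c1", "1111"),
    locus_read("c2", "0000")))), 1L)

  # the same cell carrying both patterns alone is AM territory, not a seed
  expect_equal(nrow(seeds(rbind_reads(
    locus_read("c1", "1111"), locus_read("c1", "0000")))), 0L)

  # near-complete patterns do not qualify
  expect_equal(nrow(seeds(rbind_reads(
    locus_read("c1", "1110"), locus_read("c1", "1110"), locus_read("c1", "1110"),
    locus_read("c2", "0000"), locus_read("c2", "0000"), locus_read("c2", "0000")))), 0L)

  # an AM annotation vetoes the seed
  sg <- extract_4cpg_segments(rbind_reads(locus_read("c1", "1111"),
                                          locus_read("c2", "0000")))
  am <- detect_am_single_cell(extract_4cpg_segments(rbind_reads(
    locus_read("cX", "1111"), locus_read("cX", "0000"))))
  expect_equal(nrow(find_bipolar_seeds(sg, am)), 0L)
})

test_that("seed extension and merging follows interval arithmetic", {
  # seed span [1000, 1031) widened by 100 -> [900, 1131)
  sg <- extract_4cpg_segments(rbind_reads(locus_read("c1", "1111"),
                                          locus_read("c2", "0000")))
  sd <- find_bipolar_seeds(sg, NULL)
  r <- extend_and_merge(sg, seeds = sd, flank = 100L)
  expect_equal(r$start, 900L)
  expect_equal(r$end, 1131L)
  expect_equal(r$n_seeds, 1L)

  # a non-seed segment whose extension overlaps is absorbed
  sg2 <- extract_4cpg_segments(rbind_reads(
    locus_read("c1", "1111"), locus_read("c2", "0000"),
    locus_read("c3", "1010", start = 1200L)))
  r2 <- extend_and_merge(sg2, seeds = sd, flank = 100L)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$end, 1331L)

  # two distant seeds with no bridge stay separate
  far <- rbind_reads(locus_read("c1", "1111"), locus_read("c2", "0000"),
                     locus_read("c1", "1111", start = 5000L),
                     locus_read("c2", "0000", start = 5000L))
  sg3 <- extract_4cpg_segments(far)
  r3 <- extend_and_merge(sg3, seeds = find_bipolar_seeds(sg3, NULL))
  expect_equal(nrow(r3), 2L)

  # flank = 0 with non-overlapping segments returns the raw spans
  r0 <- extend_and_merge(sg3, seeds = NULL, flank = 0L)
  expect_equal(r0$start, c(1000L, 5000L))
  expect_equal(r0$end, c(1031L, 5031L))
})

test_that("merging equals the O(n^2) union oracle and ignores input order", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(3:25, 1)
    start <- sample(seq(0L, 3000L, by = 10L), n, replace = TRUE)
    segs <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                       pos1 = start, pos2 = start + 5L, pos3 = start + 9L,
                       pos4 = start + sample(12:200, n, replace = TRUE),
                       cell_id = "c", pattern = "1111", count = 1L,
                       stringsAsFactors = FALSE)
    flank <- sample(c(0L, 30L, 100L), 1)
    got <- extend_and_merge(segs, seeds = NULL, flank = flank)
    want <- bf_merge_intervals(data.frame(
      chrom = segs$chrom,
      start = pmax(0L, segs$pos1 - flank),
      end = segs$pos4 + 1L + flank))
    expect_equal(got[, c("chrom", "start", "end")], want)
    # permutation invariance
    perm <- segs[sample(nrow(segs)), ]
    expect_equal(extend_and_merge(perm, seeds = NULL, flank = flank)[,
                 c("chrom", "start", "end")], want)
  }
})

test_that("coverage filter applies the >=5 cells / >=10 counts rule exactly", {
  reg <- data.frame(region_id = "r1", chrom = "chr1", start = 0L, end = 100L,
                    n_seeds = 1L)
  mk_counts <- function(totals) {
    do.call(rbind, lapply(seq_along(totals), function(i) {
      data.frame(region_id = "r1", cell_id = sprintf("c%02d", i),
                 position = 10L, meth = 0L, total = totals[i],
                 stringsAsFactors = FALSE)
    }))
  }
  kept <- coverage_filter(reg, mk_counts(c(12, 11, 10, 10, 10)))
  expect_equal(nrow(kept$regions), 1L)
  expect_equal(kept$regions$n_cells, 5L)

  dropped <- coverage_filter(reg, mk_counts(c(12, 11, 10, 10, 9)))
  expect_equal(nrow(dropped$regions), 0L)

  # a cell at exactly the threshold covers; cells below are removed
  mixed <- coverage_filter(reg, mk_counts(c(10, 10, 10, 10, 10, 3)))
  expect_equal(mixed$regions$n_cells, 5L)
  expect_false("c06" %in% mixed$counts$cell_id)
})

test_that("site counts are rebuilt from all overlapping reads", {
  reads <- rbind_reads(
    locus_read("c1", "1111", start = 1000L),
    # a 2-CpG read (no segment) still contributes counts
    make_reads("c1", "chr1", pos = list(c(1000L, 1010L)),
               states = list(c(0L, 1L))),
    locus_read("c2", "0101", start = 1000L))
  reg <- data.frame(region_id = "r", chrom = "chr1", start = 900L,
                    end = 1131L, n_seeds = 1L)
  cnt <- region_site_counts(reg, reads)
  c1_1000 <- cnt[cnt$cell_id == "c1" & cnt$position == 1000L, ]
  expect_equal(c1_1000$total, 2L)
  expect_equal(c1_1000$meth, 1L)
  expect_equal(sum(cnt$total), 4L + 2L + 4L)
})

test_that("candidates are contained in the control universe", {
  syn <- make_synthetic_methylome(n_csm = 6, n_asm = 2, n_am = 2,
                                  n_null = 20, seed = 9)
  built <- build_candidate_regions(syn$reads, asm_loci = syn$truth$asm)
  ctl <- build_control_regions(built$segments_kept, syn$reads)
  for (i in seq_len(nrow(built$regions))) {
    inside <- any(ctl$regions$chrom == built$regions$chrom[i] &
                    ctl$regions$start <= built$regions$start[i] &
                    ctl$regions$end >= built$regions$end[i])
    expect_true(inside)
  }
  # every candidate contains at least one seed
  expect_true(all(built$regions$n_seeds >= 1L))
})
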
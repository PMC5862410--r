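test_that("ASM filtering removes segments by CpG position membership", {
  seg <- extract_4cpg_segments(rbind_reads(
    locus_read("c1", "1111", start = 100L),   # CpGs 100,110,120,130
    locus_read("c1", "0000", start = 700L)))
  # interval covering one CpG of the first segment
  asm <- data.frame(chrom = "chr1", start = 125L, end = 200L)
  part <- filter_asm(seg, asm)
  expect_equal(unique(part$removed$pos1), 100L)
  expect_equal(unique(part$kept$pos1), 700L)
  expect_equal(nrow(part$kept) + nrow(part$removed), nrow(seg))

  # disjoint interval removes nothing; empty set is the identity
  expect_equal(nrow(filter_asm(seg, data.frame(chrom = "chr1", start = 500L,
                                               end = 600L))$removed), 0L)
  expect_equal(filter_asm(seg, NULL)$kept, seg)
})

test_that("kept segments never touch an ASM interval (random property)", {
  set.seed(31)
  for (rep in 1:10) {
    reads <- rbind_reads(do.call(rbind, lapply(1:30, function(i) {
      locus_read("c", paste(rbinom(4, 1, 0.5), collapse = ""),
                 start = sample(seq(0L, 2000L, by = 40L), 1))
    })))
    seg <- extract_4cpg_segments(reads)
    asm <- data.frame(chrom = "chr1",
                      start = ss <- sort(sample(0:2000, 3)),
                      end = ss + sample(20:120, 3, replace = TRUE))
    kept <- filter_asm(seg, asm)$kept
    if (nrow(kept) == 0L) next
    for (col in c("pos1", "pos2", "pos3", "pos4")) {
      inside <- outer(kept[[col]], asm$start, `>=`) &
        outer(kept[[col]], asm$end, `<`)
      expect_false(any(inside))
    }
  }
})

test_that("hairpin AM needs 1111 on one strand and 0000 on the mate", {
  hp <- function(p1, p2) {
    rbind_reads(
      make_reads("hp", "chr1", pos = list(c(0L, 10L, 20L, 30L)),
                 states = list(as.integer(strsplit(p1, "")[[1]])),
                 strand = "+", pair_id = "pair1"),
      make_reads("hp", "chr1", pos = list(c(0L, 10L, 20L, 30L)),
                 states = list(as.integer(strsplit(p2, "")[[1]])),
                 strand = "-", pair_id = "pair1"))
  }
  expect_equal(nrow(detect_am_hairpin(hp("1111", "0000"))), 1L)
  expect_equal(nrow(detect_am_hairpin(hp("0000", "1111"))), 1L)
  expect_equal(nrow(detect_am_hairpin(hp("1111", "1110"))), 0L)
  expect_equal(nrow(detect_am_hairpin(hp("0000", "0000"))), 0L)

  unpaired <- make_reads("hp", "chr1", pos = list(c(0L, 10L, 20L, 30L)),
                         states = list(rep(1L, 4)), strand = "+",
                         pair_id = "lone")
  expect_warning(out <- detect_am_hairpin(unpaired), "unpaired|pair")
  expect_equal(nrow(out), 0L)
})

test_that("single-cell AM requires both extremes within one cell", {
  am <- detect_am_single_cell(extract_4cpg_segments(rbind_reads(
    locus_read("cellA", "1111"), locus_read("cellA", "0000"),
    locus_read("cellA", "0000"))))
  expect_equal(nrow(am), 1L)
  expect_equal(am$evidence, "single_cell")

  # cross-cell bipolarity is a CSM seed, not AM
  cross <- detect_am_single_cell(extract_4cpg_segments(rbind_reads(
    locus_read("cellA", "1111"), locus_read("cellB", "0000"))))
  expect_equal(nrow(cross), 0L)

  expect_equal(nrow(detect_am_single_cell(extract_4cpg_segments(
    locus_read("cellA", "1010")))), 0L)
})

test_that("AM detection is monotone in added reads", {
  base <- rbind_reads(locus_read("cellA", "1111"), locus_read("cellA", "0000"))
  am0 <- detect_am_single_cell(extract_4cpg_segments(base))
  more <- rbind_reads(base, locus_read("cellB", "1010"),
                      locus_read("cellA", "1100"))
  am1 <- detect_am_single_cell(extract_4cpg_segments(more))
  expect_true(all(am0$key %in% am1$key))
})

test_that("merging AM sets is a keyed union with provenance", {
  mk <- function(starts, ev) {
    df <- do.call(rbind, lapply(starts, function(s) {
      data.frame(chrom = "chr1", pos1 = s, pos2 = s + 10L, pos3 = s + 20L,
                 pos4 = s + 30L, stringsAsFactors = FALSE)
    }))
    df$key <- segment_key(df)
    df$evidence <- ev
    df
  }
  disjoint <- merge_am(mk(c(0L, 100L), "hairpin"),
                       mk(c(200L, 300L, 400L), "single_cell"))
  expect_equal(nrow(disjoint), 5L)

  same <- merge_am(mk(0L, "hairpin"), mk(0L, "single_cell"))
  expect_equal(nrow(same), 1L)
  expect_equal(same$evidence, "both")

  # random overlap: |A union B| = |A| + |B| - |A intersect B|
  set.seed(5)
  for (rep in 1:10) {
    sa <- sample(seq(0L, 1000L, by = 50L), 8)
    sb <- sample(seq(0L, 1000L, by = 50L), 8)
    u <- merge_am(mk(sa, "hairpin"), mk(sb, "single_cell"))
    expect_equal(nrow(u), length(union(sa, sb)))
    expect_equal(sum(u$evidence == "both"), length(intersect(sa, sb)))
  }
})
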
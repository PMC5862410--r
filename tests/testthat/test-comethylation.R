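test_that("co-methylation clustering recovers planted correlation blocks", {
  set.seed(61)
  n_samp <- 17
  latent1 <- runif(n_samp)
  latent2 <- runif(n_samp)
  block1 <- t(sapply(1:8, function(i) latent1 + rnorm(n_samp, 0, 0.05)))
  block2 <- t(sapply(1:7, function(i) latent2 + rnorm(n_samp, 0, 0.05)))
  mat <- rbind(block1, block2)
  rownames(mat) <- paste0("r", 1:15)
  mod <- comethylation_modules(mat, cutoff = 0.75)
  expect_equal(length(unique(mod$module)), 2L)
  expect_equal(length(unique(mod$module[1:8])), 1L)
  expect_equal(length(unique(mod$module[9:15])), 1L)
  expect_false(mod$module[1] == mod$module[9])

  # identical rows always share a module
  two <- matrix(rep(latent1, 2), nrow = 2, byrow = TRUE)
  rownames(two) <- c("a", "b")
  m2 <- comethylation_modules(two)
  expect_equal(m2$module[1], m2$module[2])

  # row permutation does not change the partition
  o <- sample(15)
  mp <- comethylation_modules(mat[o, ], cutoff = 0.75)
  lab <- mod$module[match(mp$region, mod$region)]
  expect_equal(length(unique(paste(mp$module, lab))), 2L)
})

test_that("rows with missing values or zero variance are excluded", {
  set.seed(62)
  mat <- matrix(runif(40), nrow = 4,
                dimnames = list(paste0("r", 1:4), NULL))
  mat[1, 3] <- NA
  mat[2, ] <- 0.5
  expect_warning(mod <- comethylation_modules(mat), "constant")
  expect_setequal(mod$region, c("r3", "r4"))
})

test_that("feature enrichment is a ratio of overlap fractions", {
  regions <- data.frame(chrom = "chr1", start = c(0L, 100L, 200L, 300L),
                        end = c(50L, 150L, 250L, 350L))
  feat <- list(inside = data.frame(chrom = "chr1", start = 0L, end = 400L),
               half = data.frame(chrom = "chr1", start = 0L, end = 160L))
  # identical CSM and control sets: every fold-change is 1
  fe <- feature_enrichment(regions, regions, feat)
  expect_equal(fe$fold_change, c(1, 1))

  # CSM all inside, controls half inside: fold 2
  csm <- regions[1:2, ]
  fe2 <- feature_enrichment(csm, regions, list(f = feat$half))
  expect_equal(fe2$csm_frac, 1)
  expect_equal(fe2$control_frac, 0.5)
  expect_equal(fe2$fold_change, 2)

  # zero control overlap: undefined sentinel
  off <- list(f = data.frame(chrom = "chr9", start = 0L, end = 10L))
  expect_true(is.na(feature_enrichment(csm, regions, off)$fold_change))

  # scale-free: duplicating every region leaves folds unchanged
  dup <- rbind(csm, csm)
  expect_equal(feature_enrichment(dup, rbind(regions, regions),
                                  list(f = feat$half))$fold_change, 2)
})

test_that("enrichment fractions match a brute-force overlap counter", {
  set.seed(63)
  rnd_iv <- function(n) {
    s <- sample(0:5000, n)
    data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
               start = s, end = s + sample(10:400, n, replace = TRUE))
  }
  csm <- rnd_iv(40); ctl <- rnd_iv(60); fset <- rnd_iv(15)
  fe <- feature_enrichment(csm, ctl, list(f = fset))
  bf_frac <- function(rg) {
    mean(vapply(seq_len(nrow(rg)), function(i) {
      any(fset$chrom == rg$chrom[i] & fset$start < rg$end[i] &
            fset$end > rg$start[i])
    }, TRUE))
  }
  expect_equal(fe$csm_frac, bf_frac(csm))
  expect_equal(fe$control_frac, bf_frac(ctl))
})

test_that("peak profiles register regions in the bins they overlap", {
  peaks <- data.frame(chrom = "chr1", start = 1000L, end = 2000L)
  whole <- data.frame(chrom = "chr1", start = 900L, end = 2100L)
  expect_equal(peak_profile(whole, peaks), rep(1, 100))

  nothing <- data.frame(chrom = "chr1", start = 5000L, end = 5100L)
  expect_equal(peak_profile(nothing, peaks), rep(0, 100))

  # base-resolution oracle on a random fixture
  set.seed(64)
  peaks <- data.frame(chrom = "chr1", start = c(0L, 3000L),
                      end = c(1000L, 3500L))
  s <- sample(0:4000, 30)
  regions <- data.frame(chrom = "chr1", start = s,
                        end = s + sample(5:300, 30, replace = TRUE))
  got <- peak_profile(regions, peaks, n_bins = 50)
  want <- numeric(50)
  for (p in 1:2) {
    w <- (peaks$end[p] - peaks$start[p]) / 50
    for (b in 1:50) {
      lo <- peaks$start[p] + (b - 1) * w
      hi <- peaks$start[p] + b * w
      want[b] <- want[b] + any(regions$start < hi & regions$end > lo)
    }
  }
  expect_equal(got, want / 2)
})

test_that("sequence features follow the GC and CpG observed/expected formulas", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "CGCGCGAAATTTACGT"))
  sf <- seq_features(data.frame(chrom = "chr1", start = 0L, end = 6L), genome)
  expect_equal(sf$gc, 1.0)
  expect_equal(sf$cpg_oe, 3 * 6 / (3 * 3))   # = 2.0

  sf2 <- seq_features(data.frame(chrom = "chr1", start = 6L, end = 12L), genome)
  expect_equal(sf2$gc, 0)
  expect_equal(sf2$cpg_oe, 0)

  # random sequence against a direct string counter
  set.seed(65)
  seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
  g2 <- Biostrings::DNAStringSet(c(chrZ = seq))
  sf3 <- seq_features(data.frame(chrom = "chrZ", start = 100L, end = 900L), g2)
  sub <- substr(seq, 101, 900)
  nC <- lengths(regmatches(sub, gregexpr("C", sub)))
  nG <- lengths(regmatches(sub, gregexpr("G", sub)))
  nCG <- lengths(regmatches(sub, gregexpr("(?=CG)", sub, perl = TRUE)))
  expect_equal(sf3$gc, (nC + nG) / 800)
  expect_equal(sf3$cpg_oe, nCG * 800 / (nC * nG))

  expect_error(seq_features(data.frame(chrom = "chr1", start = 0L, end = 99L),
                            genome), "bounds|outside")
})

test_that("promoter, shore and shelf geometry follows the definitions", {
  genes <- data.frame(chrom = "chr1", tss = c(10000L, 20000L),
                      tes = c(15000L, 18000L), strand = c("+", "-"),
                      gene_id = c("g1", "g2"))
  cgi <- data.frame(chrom = "chr1", start = 50000L, end = 51000L)
  ft <- standard_features(genes, cgi)
  expect_equal(ft$promoter$start, c(9000L, 20000L))
  expect_equal(ft$promoter$end, c(10000L, 21000L))
  expect_setequal(ft$cgi_shore$start, c(48000L, 51000L))
  expect_setequal(ft$cgi_shelf$start, c(46000L, 53000L))
  # shelves sit 2-4 kb out: disjoint from shores and island
  shore_iv <- ft$cgi_shore; shelf_iv <- ft$cgi_shelf
  for (i in seq_len(nrow(shelf_iv))) {
    expect_false(any(shore_iv$start < shelf_iv$end[i] &
                       shore_iv$end > shelf_iv$start[i]))
  }
})
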
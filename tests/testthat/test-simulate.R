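test_that("region simulator honours its degenerate limits and seeds", {
  # deterministic states at theta = (1, 0) and high depth
  sim <- simulate_region(n_cells = 10, mean_depth = 200, lambda = 0.5,
                         theta = c(1, 0), seed = 1)
  lev <- rowSums(sim$m) / rowSums(sim$n)
  expect_true(all(lev %in% c(0, 1)))
  expect_equal(lev == 1, sim$truth$states == 1L)

  # zero depth = fully missing region
  empty <- simulate_region(mean_depth = 0, seed = 2)
  expect_true(all(empty$n == 0L))

  # seeded determinism is byte-identical
  s1 <- simulate_region(seed = 77)
  s2 <- simulate_region(seed = 77)
  expect_identical(s1, s2)
  # and the global RNG stream is left untouched
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(simulate_region(seed = 5)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("simulated methylation fractions match the mixture mean", {
  lam <- 0.3; th <- c(0.8, 0.1)
  lev <- vapply(1:2000, function(r) {
    sim <- simulate_region(n_cells = 1, n_sites = 4, mean_depth = 20,
                           lambda = lam, theta = th, seed = 10000 + r)
    if (sum(sim$n) == 0) NA_real_ else sum(sim$m) / sum(sim$n)
  }, 0)
  lev <- lev[!is.na(lev)]
  want <- lam * th[1] + (1 - lam) * th[2]
  se <- sd(lev) / sqrt(length(lev))
  expect_lt(abs(mean(lev) - want), 3 * se + 1e-3)
})

test_that("missing-data masking blanks sites at the requested rate", {
  sim <- simulate_region(n_cells = 50, n_sites = 10, mean_depth = 20,
                         missing_rate = 0.3, seed = 4)
  frac0 <- mean(sim$n == 0)
  expect_gt(frac0, 0.25)
  expect_lt(frac0, 0.36)
  expect_true(all(sim$m[sim$n == 0] == 0))
})

test_that("evaluation applies the accuracy rule at its boundary", {
  df <- data.frame(true_lambda = c(0.5, 0.4), param_lambda = c(0.5, 0.4),
                   true_theta1 = c(0.9, 0.8), true_theta2 = c(0.1, 0.2),
                   true_theta_diff = c(0.8, 0.6),
                   n_state1 = c(10L, 8L), n_state2 = c(10L, 12L),
                   est_lambda = c(0.5, 0.42), est_theta1 = c(0.9, 0.82),
                   est_theta2 = c(0.1, 0.22), est_theta_diff = c(0.8, 0.6),
                   statistic = c(100, 100), p_value = c(1e-10, 1e-10),
                   null = FALSE)
  ev <- evaluate_fits(df)
  expect_equal(ev$accuracy, 0.5)        # perfect rep passes, +0.02 rep fails
  expect_equal(ev$per_rep$accurate, c(TRUE, FALSE))

  # empty realized state: its theta is excluded from the rule
  df$n_state2[2] <- 0L
  df$est_theta2[2] <- 0.9
  ev2 <- evaluate_fits(df)
  expect_false(ev2$per_rep$accurate[2])  # est_lambda still off by 0.02
  df$est_lambda[2] <- 0.4
  df$est_theta1[2] <- 0.8
  ev3 <- evaluate_fits(df)
  expect_true(ev3$per_rep$accurate[2])
})

test_that("classification metrics count the confusion table", {
  m <- classification_metrics(called = c(TRUE, TRUE, FALSE, FALSE),
                              truth = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(m[c("TP", "FP", "FN", "TN")]), c(1, 1, 1, 1))
  expect_equal(unname(m["FDR"]), 0.5)
  expect_equal(unname(m["TPR"]), 0.5)
  perfect <- classification_metrics(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(unname(perfect["FDR"]), 0)
  expect_equal(unname(perfect["PPV"]), 1)
})

test_that("recovery harness output is reproducible and well-formed", {
  d1 <- simulate_recovery(5, seed = 3, restarts = 2, lambda = 0.5,
                          min_theta_diff = 0.5)
  d2 <- simulate_recovery(5, seed = 3, restarts = 2, lambda = 0.5,
                          min_theta_diff = 0.5)
  expect_identical(d1, d2)
  expect_true(all(d1$true_theta_diff >= 0.5))
  expect_true(all(d1$est_theta1 >= d1$est_theta2))
})

test_that("synthetic methylome plants the advertised locus types", {
  syn <- make_synthetic_methylome(n_csm = 3, n_asm = 2, n_am = 2, n_null = 5,
                                  n_cells = 8, depth = 10, seed = 55)
  syn2 <- make_synthetic_methylome(n_csm = 3, n_asm = 2, n_am = 2, n_null = 5,
                                   n_cells = 8, depth = 10, seed = 55)
  expect_identical(syn$reads, syn2$reads)
  expect_equal(nrow(syn$truth$csm), 3L)
  expect_equal(nrow(syn$truth$am), 2L)

  seg <- filter_asm(extract_4cpg_segments(syn$reads), syn$truth$asm)$kept
  am_sc <- detect_am_single_cell(seg)
  am_keys <- paste(syn$truth$am$chrom, syn$truth$am$start, sep = ":")
  det_keys <- paste(am_sc$chrom, am_sc$pos1, sep = ":")
  # every planted AM locus shows the within-cell signature; nothing else does
  expect_setequal(det_keys, am_keys)

  # planted CSM loci are bipolar across the two cell subsets
  for (i in seq_len(nrow(syn$truth$csm))) {
    s <- syn$truth$csm$start[i]
    rows <- seg[seg$pos1 == s, ]
    hyper <- rows$cell_id[rows$pattern == "1111"]
    hypo <- rows$cell_id[rows$pattern == "0000"]
    expect_gt(length(hyper), 0)
    expect_gt(length(hypo), 0)
    expect_equal(length(intersect(hyper, hypo)), 0L)
  }

  # hairpin pairs at AM loci carry opposite full patterns
  hp <- syn$hairpin_reads
  expect_true(all(table(hp$pair_id) == 2L))
  one <- hp[hp$pair_id == hp$pair_id[1], ]
  expect_setequal(vapply(one$states, paste, "", collapse = ""),
                  c("1111", "0000"))

  # files written on request, in canonical formats
  d <- withr::local_tempdir()
  make_synthetic_methylome(n_csm = 2, n_asm = 1, n_am = 1, n_null = 2,
                           n_cells = 4, depth = 5, seed = 5, dir = d)
  expect_true(file.exists(file.path(d, "reads.tsv")))
  back <- read_read_patterns(file.path(d, "reads.tsv"))
  expect_gt(nrow(back), 0)
  expect_equal(nrow(read_bed(file.path(d, "truth_csm.bed"))), 2L)
})
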
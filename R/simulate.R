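#' Simulate one region of per-cell CpG counts from the two-state model
#'
#' Each cell is assigned the hyper-methylated state with probability
#' `lambda`; per-site read depths are Poisson with mean `mean_depth`
#' (depth 0 encodes a missing site) and methylated counts are binomial
#' with the state's methylation probability. An extra independent
#' masking rate can blank additional sites for stress tests.
#'
#' @param n_cells number of cells (default 20).
#' @param n_sites CpG sites per region (default 4).
#' @param mean_depth Poisson mean read depth per site (default 20).
#' @param lambda proportion of the hyper-methylated state, or
#'   `"random"` for U(0, 1).
#' @param theta length-2 methylation probabilities (hyper, hypo), or
#'   `"random"` for two independent U(0, 1) draws (ordered), or
#'   `"null"` for a single shared U(0, 1) state.
#' @param min_theta_diff when `theta = "random"`, redraw until
#'   `theta[1] - theta[2]` is at least this (default 0).
#' @param missing_rate extra independent per-site masking probability
#'   (default 0).
#' @param seed integer seed (RNG state preserved).
#' @return list with matrices `m`, `n` (cells x sites) and `truth`:
#'   `lambda` (sampled parameter), `lambda_realized` (fraction of cells
#'   in state 1), `theta` (ordered, `theta[1] >= theta[2]`), `states`
#'   (per-cell 1/2), `null` (single-state flag).
#' @export
simulate_region <- function(n_cells = 20L, n_sites = 4L, mean_depth = 20,
                            lambda = "random", theta = "random",
                            min_theta_diff = 0, missing_rate = 0,
                            seed = NULL) {
  stopifnot(missing_rate >= 0, missing_rate < 1, n_cells >= 1, n_sites >= 1)
  out <- NULL
  with_preserved_rng(seed, {
    is_null <- identical(theta, "null")
    th <- if (is_null) {
      rep(stats::runif(1L), 2L)
    } else if (identical(theta, "random")) {
      repeat {
        t2 <- sort(stats::runif(2L), decreasing = TRUE)
        if (t2[1L] - t2[2L] >= min_theta_diff) break
      }
      t2
    } else {
      sort(as.numeric(theta), decreasing = TRUE)
    }
    lam <- if (identical(lambda, "random")) stats::runif(1L) else as.numeric(lambda)
    states <- 1L + (stats::runif(n_cells) > lam)
    if (is_null) states <- rep(1L, n_cells)
    n <- matrix(stats::rpois(n_cells * n_sites, mean_depth),
                nrow = n_cells, ncol = n_sites)
    m <- matrix(stats::rbinom(n_cells * n_sites, as.vector(n),
                              rep(th[states], n_sites)),
                nrow = n_cells, ncol = n_sites)
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(n_cells * n_sites) < missing_rate,
                     nrow = n_cells)
      n[mask] <- 0L
      m[mask] <- 0L
    }
    out <- list(m = m, n = n,
                 truth = list(lambda = lam,
                              lambda_realized = mean(states == 1L),
                              theta = th, states = states, null = is_null))
  })
  out
}

#' Fit the mixture model to one simulated region
#'
#' Estimates per-cell empirical-Bayes priors from the site-level counts
#' and fits [fit_beta_mixture()] on the pooled per-cell counts.
#'
#' @param sim output of [simulate_region()].
#' @param pool prior convention: one shared prior from the cells' pooled
#'   counts (`"cells"`, default) or per-cell priors from each cell's
#'   sites (`"sites"`).
#' @param ... passed to [fit_beta_mixture()].
#' @return a `beta_mixture` fit, or `NULL` when fewer than 2 cells have
#'   data.
#' @export
fit_simulated_region <- function(sim, pool = c("cells", "sites"), ...) {
  pool <- match.arg(pool)
  keep <- rowSums(sim$n) > 0
  if (sum(keep) < 2L) return(NULL)
  sm <- rowSums(sim$m)[keep]
  sn <- rowSums(sim$n)[keep]
  if (pool == "cells") {
    pr <- estimate_prior(sm, sn)
    al <- pr$alpha
    be <- pr$beta
  } else {
    pri <- lapply(which(keep), function(i) estimate_prior(sim$m[i, ], sim$n[i, ]))
    al <- vapply(pri, `[[`, 0, "alpha")
    be <- vapply(pri, `[[`, 0, "beta")
  }
  fit_beta_mixture(sum_m = sm, sum_n = sn, alpha = al, beta = be, ...)
}

#' Parameter-recovery harness
#'
#' Simulates `n_reps` regions, fits each, and tabulates true versus
#' estimated parameters. The truth used for the mixing proportion is the
#' realized fraction of cells in the hyper-methylated state (the
#' identifiable quantity at finite cell number); state methylation
#' probabilities are compared to the values the simulation set.
#'
#' @param n_reps number of simulated regions.
#' @param restarts,seed EM controls; region seeds are derived from
#'   `seed` so runs are reproducible.
#' @param ... passed to [simulate_region()] (conditions: `n_cells`,
#'   `n_sites`, `mean_depth`, `theta`, `min_theta_diff`, ...).
#' @return data frame, one row per replicate: truth
#'   (`true_lambda`, `param_lambda`, `true_theta1`, `true_theta2`),
#'   estimates (`est_lambda`, `est_theta1`, `est_theta2`), `p_value`,
#'   `statistic`, `null` flag.
#' @export
simulate_recovery <- function(n_reps, restarts = 10L, seed = 1L, ...) {
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sim <- simulate_region(seed = derive_seed(seed, paste0("sim", r)), ...)
    fit <- fit_simulated_region(sim, restarts = restarts,
                                seed = derive_seed(seed, paste0("fit", r)))
    if (is.null(fit)) next
    tr <- sim$truth
    rows[[r]] <- data.frame(
      rep = r,
      param_lambda = tr$lambda, true_lambda = tr$lambda_realized,
      true_theta1 = tr$theta[1L], true_theta2 = tr$theta[2L],
      true_theta_diff = tr$theta[1L] - tr$theta[2L],
      n_state1 = sum(tr$states == 1L), n_state2 = sum(tr$states == 2L),
      est_lambda = fit$lambda[1L], est_theta1 = fit$theta[1L],
      est_theta2 = fit$theta[2L], est_theta_diff = fit$theta_diff,
      statistic = fit$statistic, p_value = fit$p_value,
      null = tr$null)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate estimates against simulation truth
#'
#' Applies the accuracy rule (every reported parameter within `tol` of
#' its true value, default 1e-2) per replicate, and aggregates accuracy,
#' pooled parameter errors and the correlation between true and
#' estimated state differences. When calls and truth labels are
#' supplied, also computes FDR, TPR, FPR and PPV at the operating point.
#'
#' @param df recovery frame from [simulate_recovery()].
#' @param tol accuracy threshold (default 1e-2).
#' @param alpha significance level used for the rejection summary.
#' @return list: `per_rep` (with `err_*`, `max_err`, `accurate`,
#'   `both_states`), `accuracy` (fraction accurate), `median_error`
#'   (median of pooled absolute parameter errors), `pearson_theta_diff`
#'   (over replicates with both states realized), `rejection_rate`
#'   (BH-adjusted at `alpha`).
#' @export
evaluate_fits <- function(df, tol = 1e-2, alpha = 0.05) {
  stopifnot(nrow(df) > 0L)
  df$err_lambda <- abs(df$est_lambda - df$true_lambda)
  df$err_theta1 <- abs(df$est_theta1 - df$true_theta1)
  df$err_theta2 <- abs(df$est_theta2 - df$true_theta2)
  df$err_theta_diff <- abs(df$est_theta_diff - df$true_theta_diff)
  # a state no cell was drawn from carries no information about its
  # theta; such parameters are excluded from the accuracy rule
  if (!is.null(df$n_state1)) {
    df$err_theta1[df$n_state1 == 0L] <- NA_real_
    df$err_theta2[df$n_state2 == 0L] <- NA_real_
  }
  df$max_err <- pmax(df$err_lambda, df$err_theta1, df$err_theta2, na.rm = TRUE)
  df$accurate <- df$max_err < tol
  df$both_states <- if (is.null(df$n_state1)) TRUE else
    df$n_state1 > 0L & df$n_state2 > 0L
  p_adj <- bh_adjust(df$p_value)
  both <- df[df$both_states, , drop = FALSE]
  list(per_rep = df,
       accuracy = mean(df$accurate),
       median_error = stats::median(c(df$err_lambda, df$err_theta1,
                                      df$err_theta2), na.rm = TRUE),
       pearson_theta_diff = if (nrow(both) > 2L &&
                                  stats::sd(both$true_theta_diff) > 0 &&
                                  stats::sd(both$est_theta_diff) > 0) {
         stats::cor(both$true_theta_diff, both$est_theta_diff)
       } else NA_real_,
       rejection_rate = mean(p_adj < alpha))
}

#' Accuracy as a function of the true state difference
#'
#' Simulates regions with the true `theta` difference stratified into
#' bins and reports the fraction of accurate fits per bin (accuracy rule
#' of [evaluate_fits()]).
#'
#' @param n_per_bin replicates per bin.
#' @param bin_width width of the difference bins (default 0.05).
#' @param tol accuracy threshold (default 1e-2).
#' @param restarts,seed EM controls.
#' @param ... simulation conditions passed to [simulate_region()].
#' @return data frame: `bin_lo`, `bin_hi`, `bin_mid`, `n`, `accuracy`.
#' @export
accuracy_curve <- function(n_per_bin = 200L, bin_width = 0.05, tol = 1e-2,
                           restarts = 10L, seed = 1L, ...) {
  lo <- seq(0, 1 - bin_width, by = bin_width)
  rows <- lapply(seq_along(lo), function(bi) {
    acc <- logical(n_per_bin)
    for (r in seq_len(n_per_bin)) {
      s <- derive_seed(seed, sprintf("bin%d_%d", bi, r))
      # draw a difference uniformly inside the bin, then a feasible theta2
      d_th <- NULL
      with_preserved_rng(s, {
        d <- stats::runif(1L, lo[bi], lo[bi] + bin_width)
        t2 <- stats::runif(1L, 0, 1 - d)
        d_th <- c(t2 + d, t2)
      })
      sim <- simulate_region(theta = d_th,
                             seed = derive_seed(s, "sim"), ...)
      fit <- fit_simulated_region(sim, restarts = restarts,
                                  seed = derive_seed(s, "fit"))
      if (is.null(fit)) next
      tr <- sim$truth
      errs <- c(abs(fit$lambda[1L] - tr$lambda_realized),
                if (any(tr$states == 1L)) abs(fit$theta[1L] - tr$theta[1L]),
                if (any(tr$states == 2L)) abs(fit$theta[2L] - tr$theta[2L]))
      acc[r] <- max(errs) < tol
    }
    data.frame(bin_lo = lo[bi], bin_hi = lo[bi] + bin_width,
               bin_mid = lo[bi] + bin_width / 2, n = n_per_bin,
               accuracy = mean(acc))
  })
  do.call(rbind, rows)
}

#' Classification metrics of CSM calls against planted truth
#'
#' @param called logical vector of calls.
#' @param truth logical vector of true positives (same length).
#' @return named vector: `TP`, `FP`, `FN`, `TN`, `FDR`, `TPR`, `FPR`,
#'   `PPV`.
#' @export
classification_metrics <- function(called, truth) {
  stopifnot(length(called) == length(truth))
  tp <- sum(called & truth); fp <- sum(called & !truth)
  fn <- sum(!called & truth); tn <- sum(!called & !truth)
  c(TP = tp, FP = fp, FN = fn, TN = tn,
    FDR = if (tp + fp > 0) fp / (tp + fp) else 0,
    TPR = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    FPR = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' ROC-style sweep of the state-difference cutoff
#'
#' At a fixed significance level, sweeps the `theta_diff` calling cutoff
#' and reports TPR/FPR at each operating point.
#'
#' @param results scan results (with `p_adjusted`, `theta_diff`,
#'   `n_cells`).
#' @param truth logical truth per region.
#' @param cutoffs cutoffs to sweep (default `seq(0, 1, 0.05)`).
#' @param alpha significance level (default 0.05).
#' @param min_cells_call minimum cells criterion (default 8).
#' @return data frame with one row per cutoff and the metrics of
#'   [classification_metrics()].
#' @export
roc_theta_diff <- function(results, truth, cutoffs = seq(0, 1, by = 0.05),
                           alpha = 0.05, min_cells_call = 8L) {
  rows <- lapply(cutoffs, function(ct) {
    called <- results$p_adjusted < alpha & results$theta_diff >= ct &
      results$n_cells >= min_cells_call
    data.frame(cutoff = ct, t(classification_metrics(called, truth)))
  })
  do.call(rbind, rows)
}

#' Generate a synthetic single-cell methylome with planted loci
#'
#' Emits read-level CpG calls (the canonical readtsv geometry) for a set
#' of planted locus types laid out along one synthetic chromosome:
#'
#' * `csm`: a fixed subset of cells draws per-CpG calls at
#'   `theta_csm[1]`, the rest at `theta_csm[2]` (bipolar across cells),
#' * `asm`: every cell is heterozygous; each read picks one allele
#'   (methylation near 1 on one allele, near 0 on the other); planted
#'   intervals are reported in the ASM truth set for annotation-based
#'   exclusion,
#' * `am`: within every cell, reads are fully methylated or fully
#'   unmethylated molecules (within-cell bipolarity); matching hairpin
#'   read pairs (`1111`/`0000` on complementary strands) are emitted,
#' * `null`: one shared methylation level per locus for all cells.
#'
#' Loci are 4-CpG windows (10 bp spacing) placed `locus_gap` bp apart so
#' flank extension never merges neighbouring loci; types are interleaved
#' randomly. Reads per cell and locus are Poisson(`depth`); every read
#' covers the full window. Deterministic for a given seed.
#'
#' @param n_csm,n_asm,n_am,n_null planted locus counts.
#' @param n_cells number of cells (default 20).
#' @param depth Poisson mean reads per cell per locus (default 15).
#' @param theta_csm hyper/hypo methylation probabilities of CSM loci
#'   (default `c(0.8, 0.2)`).
#' @param theta_asm per-allele probabilities of ASM loci
#'   (default `c(0.95, 0.05)`).
#' @param csm_cells number of hyper-methylated cells per CSM locus
#'   (default half).
#' @param null_theta_range range of the shared level of null loci
#'   (default `c(0.2, 0.8)`).
#' @param locus_gap distance between locus starts in bp (default 1000).
#' @param hairpin_pairs hairpin read pairs emitted per AM locus
#'   (default 5).
#' @param seed integer seed.
#' @param dir optional directory; when given, writes `reads.tsv`,
#'   `hairpin.tsv` and `truth_<type>.bed` files there.
#' @return list: `reads` and `hairpin_reads` (`read_patterns` frames),
#'   `truth` (named list of BED-style frames per type), `layout` (locus
#'   table).
#' @export
make_synthetic_methylome <- function(n_csm = 50L, n_asm = 20L, n_am = 20L,
                                     n_null = 200L, n_cells = 20L,
                                     depth = 15, theta_csm = c(0.8, 0.2),
                                     theta_asm = c(0.95, 0.05),
                                     csm_cells = ceiling(n_cells / 2),
                                     null_theta_range = c(0.2, 0.8),
                                     locus_gap = 1000L, hairpin_pairs = 5L,
                                     seed = 1L, dir = NULL) {
  types <- rep(c("csm", "asm", "am", "null"), c(n_csm, n_asm, n_am, n_null))
  n_loci <- length(types)
  stopifnot(n_loci > 0L, locus_gap >= 300L)
  chrom <- "chr1"
  cells <- sprintf("cell%02d", seq_len(n_cells))
  res <- NULL
  with_preserved_rng(seed, {
    types <- sample(types)
    start <- 1000L + (seq_len(n_loci) - 1L) * as.integer(locus_gap)
    cpg <- cbind(start, start + 10L, start + 20L, start + 30L)
    layout <- data.frame(locus_id = sprintf("locus%04d", seq_len(n_loci)),
                         type = types, chrom = chrom,
                         start = start, end = start + 31L,
                         stringsAsFactors = FALSE)
    rd_cell <- list(); rd_pos <- list(); rd_states <- list()
    hp_cell <- character(); hp_strand <- character(); hp_pair <- character()
    hp_pos <- list(); hp_states <- list()
    pat_of <- function(states) {
      apply(states, 1L, function(r) paste0(r, collapse = ""))
    }
    # molecules within one cell are epigenetically coherent: a cell never
    # carries both a fully methylated and a fully unmethylated molecule
    # unless the locus is planted as AM; offending reads are redrawn
    resample_forbidden <- function(states, th, forbid) {
      repeat {
        bad <- which(pat_of(states) %in% forbid)
        if (length(bad) == 0L) break
        states[bad, ] <- matrix(stats::rbinom(4L * length(bad), 1L, th),
                                nrow = length(bad))
      }
      states
    }
    for (l in seq_len(n_loci)) {
      ty <- types[l]
      null_theta <- stats::runif(1L, null_theta_range[1L], null_theta_range[2L])
      for (ci in seq_len(n_cells)) {
        k <- stats::rpois(1L, depth)
        if (k == 0L) next
        states <- switch(ty,
          csm = {
            hyper <- ci <= csm_cells
            th <- if (hyper) theta_csm[1L] else theta_csm[2L]
            resample_forbidden(
              matrix(stats::rbinom(4L * k, 1L, th), nrow = k), th,
              forbid = if (hyper) "0000" else "1111")
          },
          asm = {
            allele <- sample(1:2, k, replace = TRUE)
            matrix(stats::rbinom(4L * k, 1L, rep(theta_asm[allele], 4L)),
                   nrow = k)
          },
          am = {
            full <- stats::rbinom(k, 1L, 0.5)
            matrix(rep(full, 4L), nrow = k)
          },
          null = {
            st <- matrix(stats::rbinom(4L * k, 1L, null_theta), nrow = k)
            pats <- pat_of(st)
            if ("1111" %in% pats && "0000" %in% pats) {
              # keep the majority extreme, redraw the rarer one
              rare <- if (sum(pats == "1111") >= sum(pats == "0000"))
                "0000" else "1111"
              bad <- which(pats == rare)
              st[bad, ] <- resample_forbidden(
                matrix(stats::rbinom(4L * length(bad), 1L, null_theta),
                       nrow = length(bad)),
                null_theta, forbid = c("1111", "0000"))
            }
            st
          })
        for (rr in seq_len(k)) {
          rd_cell[[length(rd_cell) + 1L]] <- cells[ci]
          rd_pos[[length(rd_pos) + 1L]] <- cpg[l, ]
          rd_states[[length(rd_states) + 1L]] <- as.integer(states[rr, ])
        }
      }
      if (ty == "am" && hairpin_pairs > 0L) {
        for (hh in seq_len(hairpin_pairs)) {
          pid <- sprintf("hp_%04d_%d", l, hh)
          for (sgn in c("+", "-")) {
            hp_cell <- c(hp_cell, "hairpin")
            hp_strand <- c(hp_strand, sgn)
            hp_pair <- c(hp_pair, pid)
            hp_pos[[length(hp_pos) + 1L]] <- cpg[l, ]
            hp_states[[length(hp_states) + 1L]] <-
              if (sgn == "+") rep(1L, 4L) else rep(0L, 4L)
          }
        }
      }
    }
    reads <- data.frame(cell_id = unlist(rd_cell),
                        chrom = chrom,
                        strand = "+",
                        pair_id = NA_character_,
                        stringsAsFactors = FALSE)
    reads$pos <- rd_pos
    reads$states <- rd_states
    attr(reads, "coord_normalized") <- TRUE
    class(reads) <- c("read_patterns", "data.frame")
    hairpin <- data.frame(cell_id = hp_cell,
                          chrom = rep_len(chrom, length(hp_cell)),
                          strand = hp_strand, pair_id = hp_pair,
                          stringsAsFactors = FALSE)
    hairpin$pos <- hp_pos
    hairpin$states <- hp_states
    attr(hairpin, "coord_normalized") <- TRUE
    class(hairpin) <- c("read_patterns", "data.frame")
    truth <- lapply(split(layout, layout$type), function(d) {
      data.frame(chrom = d$chrom, start = d$start, end = d$end,
                 name = d$locus_id, stringsAsFactors = FALSE)
    })
    res <- list(reads = reads, hairpin_reads = hairpin, truth = truth,
                 layout = layout)
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_read_patterns(res$reads, file.path(dir, "reads.tsv"))
    write_read_patterns(res$hairpin_reads, file.path(dir, "hairpin.tsv"))
    for (ty in names(res$truth)) {
      write_bed(res$truth[[ty]], file.path(dir, sprintf("truth_%s.bed", ty)))
    }
  }
  res
}
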
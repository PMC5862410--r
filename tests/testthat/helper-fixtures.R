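# Shared fixture builders and independent brute-force oracles.

# Build a read_patterns frame from parallel lists/vectors.
make_reads <- function(cell_id, chrom, pos, states, strand = "+",
                       pair_id = NA_character_, normalized = TRUE) {
  n <- length(cell_id)
  df <- data.frame(cell_id = cell_id,
                   chrom = rep_len(chrom, n),
                   strand = rep_len(strand, n),
                   pair_id = rep_len(pair_id, n),
                   stringsAsFactors = FALSE)
  df$pos <- lapply(pos, as.integer)
  df$states <- lapply(states, as.integer)
  if (normalized) attr(df, "coord_normalized") <- TRUE
  class(df) <- c("read_patterns", "data.frame")
  df
}

# One read covering a 4-CpG locus at `start` (10 bp spacing).
locus_read <- function(cell, pattern, start = 1000L, chrom = "chr1") {
  make_reads(cell, chrom,
             pos = list(start + c(0L, 10L, 20L, 30L)),
             states = list(as.integer(strsplit(pattern, "")[[1]])))
}

rbind_reads <- function(...) {
  out <- do.call(rbind, list(...))
  attr(out, "coord_normalized") <- TRUE
  class(out) <- c("read_patterns", "data.frame")
  out
}

# O(n^2) interval-union oracle: repeatedly merge any overlapping pair.
bf_merge_intervals <- function(df) {
  iv <- df[, c("chrom", "start", "end")]
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i < nrow(iv)) {
      j <- i + 1L
      while (j <= nrow(iv)) {
        if (iv$chrom[i] == iv$chrom[j] &&
            iv$start[i] < iv$end[j] && iv$end[i] > iv$start[j]) {
          iv$start[i] <- min(iv$start[i], iv$start[j])
          iv$end[i] <- max(iv$end[i], iv$end[j])
          iv <- iv[-j, , drop = FALSE]
          merged_any <- TRUE
        } else {
          j <- j + 1L
        }
      }
      i <- i + 1L
    }
    if (!merged_any) break
  }
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

# Textbook step-up Benjamini-Hochberg, written independently.
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Grid-integration Bayes oracle: binomial likelihood x beta prior,
# normalized on a midpoint grid.
grid_posterior <- function(alpha, beta, meth, total, n_grid = 1e4) {
  th <- (seq_len(n_grid) - 0.5) / n_grid
  lp <- stats::dbeta(th, alpha, beta, log = TRUE)
  for (j in seq_along(meth)) {
    lp <- lp + stats::dbinom(meth[j], total[j], th, log = TRUE)
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  mu <- sum(w * th)
  list(mean = mu, var = sum(w * (th - mu)^2))
}

# Mixture log-likelihood evaluated directly (same pseudo-likelihood the
# model defines), for grid-search oracles.
mix_loglik <- function(lambda, theta1, theta2, a, b) {
  const <- lgamma(a) + lgamma(b) - lgamma(a + b)
  f1 <- const + (a - 1) * log(theta1) + (b - 1) * log1p(-theta1)
  f2 <- const + (a - 1) * log(theta2) + (b - 1) * log1p(-theta2)
  mx <- pmax(f1 + log(lambda), f2 + log1p(-lambda))
  sum(mx + log(exp(f1 + log(lambda) - mx) + exp(f2 + log1p(-lambda) - mx)))
}

# Pool-adjacent-violators isotonic fit (least squares, equal weights).
pava <- function(y) {
  n <- length(y)
  val <- as.numeric(y)
  wt <- rep(1, n)
  i <- 1L
  while (i < length(val)) {
    if (val[i] > val[i + 1L] + 1e-12) {
      new_val <- (wt[i] * val[i] + wt[i + 1L] * val[i + 1L]) / (wt[i] + wt[i + 1L])
      val[i] <- new_val
      wt[i] <- wt[i] + wt[i + 1L]
      val <- val[-(i + 1L)]
      wt <- wt[-(i + 1L)]
      if (i > 1L) i <- i - 1L
    } else {
      i <- i + 1L
    }
  }
  rep(val, wt)
}
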
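#' Empirical-Bayes beta prior for one region-cell
#'
#' Per region and cell, the methylated count at CpG site j is modelled as
#' Binomial(n_j, theta) with a Beta(alpha, beta) prior on theta. The
#' prior is estimated by the method of moments from the site-level
#' observed levels e_j = m_j / n_j, reparameterized by mean mu and
#' precision M = alpha + beta:
#'
#' * `mu = sum(n_j e_j) / sum(n_j)` (count-weighted mean level),
#' * `s2 = sum(n_j (e_j - mu)^2) / sum(n_j)` (weighted sample variance),
#' * `M  = (mu(1-mu) - s2) / (s2 - mu(1-mu)/c * sum(1/n_j))` over the
#'   `c` replicate groups,
#' * `alpha = mu * M`, `beta = (1-mu) * M`.
#'
#' When the moment estimate of M is negative, zero or non-finite (e.g.
#' a single site, or all sites at the same level so `s2 = 0`), the flat
#' prior `alpha = beta = 1` is used. Sites with missing data enter with
#' zero methylated and zero total counts, so they do not perturb the
#' moments.
#'
#' The replicate groups are simply the elements of `meth`/`total`: pass
#' per-site counts of one cell to get a per-cell prior, or per-cell
#' pooled counts of one region to get a prior shared across the region's
#' cells (what [region_posteriors()] does by default).
#'
#' @param meth methylated counts per group (site or cell).
#' @param total total counts, same length.
#' @return a `beta_prior` list: `alpha`, `beta`, `mu`, `precision`
#'   (`NA` when the moment estimate was invalid), `s2`, `site_levels`
#'   (observed group levels), `fallback` (flat-prior flag), `no_data`
#'   (all totals zero).
#' @export
estimate_prior <- function(meth, total) {
  stopifnot(length(meth) == length(total), all(total >= 0), all(meth >= 0),
            all(meth <= total))
  use <- total > 0
  m <- meth[use]; n <- total[use]
  if (length(n) == 0L) {
    return(structure(list(alpha = 1, beta = 1, mu = NA_real_,
                          precision = NA_real_, s2 = NA_real_,
                          site_levels = numeric(0), fallback = TRUE,
                          no_data = TRUE), class = "beta_prior"))
  }
  e <- m / n
  mu <- sum(n * e) / sum(n)
  s2 <- sum(n * (e - mu)^2) / sum(n)
  c_g <- length(n)
  denom_corr <- mu * (1 - mu) / c_g * sum(1 / n)
  M <- (mu * (1 - mu) - s2) / (s2 - denom_corr)
  fallback <- !is.finite(M) || M <= 0
  if (fallback) {
    alpha <- beta <- 1
    M <- NA_real_
  } else {
    alpha <- mu * M
    beta <- (1 - mu) * M
  }
  structure(list(alpha = alpha, beta = beta, mu = mu, precision = M,
                 s2 = s2, site_levels = e, fallback = fallback,
                 no_data = FALSE), class = "beta_prior")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat("Empirical-Bayes beta prior\n")
  cat(sprintf("  alpha = %.4g, beta = %.4g%s\n", x$alpha, x$beta,
              if (x$fallback) " (flat-prior fallback)" else ""))
  if (!is.na(x$mu)) {
    cat(sprintf("  mu = %.4g, s2 = %.4g, precision M = %s\n",
                x$mu, x$s2,
                if (is.na(x$precision)) "invalid" else sprintf("%.4g", x$precision)))
  } else {
    cat("  no data\n")
  }
  invisible(x)
}

#' Conjugate beta posterior of the methylation probability
#'
#' With the binomial likelihood over the region-cell's sites and the
#' Beta(alpha, beta) prior, the posterior of theta is
#' `Beta(sum(m) + alpha, sum(n) - sum(m) + beta)`; its mean and variance
#' follow in closed form.
#'
#' @param prior a `beta_prior` (or any list with `alpha`, `beta`).
#' @param meth,total site-level counts of the region-cell.
#' @return a `beta_posterior` list: shape parameters `a`, `b`, `mean`,
#'   `var`, and the pooled counts `sum_m`, `sum_n`.
#' @export
beta_posterior <- function(prior, meth, total) {
  stopifnot(length(meth) == length(total), all(meth <= total))
  sm <- sum(meth); sn <- sum(total)
  a <- sm + prior$alpha
  b <- sn - sm + prior$beta
  structure(list(a = a, b = b,
                 mean = a / (a + b),
                 var = a * b / ((a + b)^2 * (a + b + 1)),
                 sum_m = sm, sum_n = sn), class = "beta_posterior")
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("Beta posterior: Beta(%.4g, %.4g), mean %.4g, var %.4g\n",
              x$a, x$b, x$mean, x$var))
  invisible(x)
}

#' Per-cell priors and posteriors for one region
#'
#' Applies [estimate_prior()] and [beta_posterior()] to every cell of a
#' region's site-count table. With `pool = "cells"` (default) one prior
#' is estimated per region from the cells' pooled counts (replicate
#' groups = cells, matching the precision estimator's average of
#' `1/sum_j n_ji` over cells) and shared by all cells; with
#' `pool = "sites"` each cell gets its own prior estimated from its
#' site-level counts.
#'
#' @param counts data frame with columns `cell_id`, `meth`, `total`
#'   (one row per site; e.g. a single region's rows from
#'   [region_site_counts()]).
#' @param pool replicate-group convention, `"cells"` (default) or
#'   `"sites"`.
#' @return data frame, one row per cell: `cell_id`, `alpha`, `beta`,
#'   `sum_m`, `sum_n`, `post_a`, `post_b`, `post_mean`, `post_var`,
#'   `fallback`.
#' @export
region_posteriors <- function(counts, pool = c("cells", "sites")) {
  pool <- match.arg(pool)
  sp <- split(counts, counts$cell_id)
  shared <- NULL
  if (pool == "cells") {
    cm <- vapply(sp, function(d) sum(d$meth), 0)
    cn <- vapply(sp, function(d) sum(d$total), 0)
    shared <- estimate_prior(cm, cn)
  }
  out <- do.call(rbind, lapply(names(sp), function(cid) {
    d <- sp[[cid]]
    pr <- if (is.null(shared)) estimate_prior(d$meth, d$total) else shared
    po <- beta_posterior(pr, d$meth, d$total)
    data.frame(cell_id = cid, alpha = pr$alpha, beta = pr$beta,
               sum_m = po$sum_m, sum_n = po$sum_n,
               post_a = po$a, post_b = po$b,
               post_mean = po$mean, post_var = po$var,
               fallback = pr$fallback, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
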
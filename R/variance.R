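#' Cell-to-cell methylation variance of a region (random-effects model)
#'
#' Treats each cell's posterior mean methylation probability `theta_i`
#' (with posterior variance `V_i`) as an observation of an abstract
#' region-level methylation probability `mu` plus a cell-level random
#' deviation with between-cell variance `Delta^2`. The model is resolved
#' non-iteratively with the DerSimonian-Laird moment estimator familiar
#' from random-effects meta-analysis:
#'
#' * fixed-effect weights `w_i = 1 / V_i`, heterogeneity statistic
#'   `Q = sum w_i (theta_i - mu_FE)^2`,
#' * `Delta^2 = max(0, (Q - (N - 1)) / (sum w - sum w^2 / sum w))`,
#' * adjusted weights `w*_i = 1 / (V_i + Delta^2)`,
#' * `mu = sum(w* theta) / sum(w*)` and `V = 1 / sum(w*)`.
#'
#' @param theta per-cell posterior mean methylation probabilities
#'   (e.g. `post_mean` from [region_posteriors()]).
#' @param V per-cell posterior variances (`post_var`).
#' @param cell_id optional labels.
#' @return an object of class `csm_variance`: `mu` (weighted mean
#'   methylation), `delta2` (between-cell variance, truncated at 0),
#'   `V_hat` (variance of the mean, `1 / sum w*`), `weights`, `Q`,
#'   `n_cells`, and the inputs.
#' @export
variance_fit <- function(theta, V, cell_id = NULL) {
  stopifnot(length(theta) == length(V))
  n <- length(theta)
  if (n < 2L) {
    return(structure(list(mu = if (n) theta else NA_real_, delta2 = NA_real_,
                          V_hat = NA_real_, weights = rep(NA_real_, n),
                          Q = NA_real_, ci95 = NULL, n_cells = n,
                          theta = theta, V = V, cell_id = cell_id,
                          undefined = TRUE), class = "csm_variance"))
  }
  stopifnot(all(V > 0))
  if (is.null(cell_id)) cell_id <- paste0("cell", seq_len(n))
  w <- 1 / V
  mu_fe <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - mu_fe)^2)
  delta2 <- max(0, (Q - (n - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (V + delta2)
  mu <- sum(w_star * theta) / sum(w_star)
  V_hat <- 1 / sum(w_star)
  structure(list(mu = mu, delta2 = delta2, V_hat = V_hat,
                 weights = stats::setNames(w_star, cell_id), Q = Q,
                 ci95 = NULL, n_cells = n, theta = theta, V = V,
                 cell_id = cell_id, undefined = FALSE),
            class = "csm_variance")
}

#' @export
print.csm_variance <- function(x, ...) {
  cat("Random-effects methylation variance\n")
  if (isTRUE(x$undefined)) {
    cat(sprintf("  undefined (%d cell(s) with data; need >= 2)\n", x$n_cells))
    return(invisible(x))
  }
  cat(sprintf("  cells %d   mu = %.4f   Delta2 = %.3g   V = %.3g\n",
              x$n_cells, x$mu, x$delta2, x$V_hat))
  if (!is.null(x$ci95)) {
    cat(sprintf("  95%% bootstrap CI of V: [%.3g, %.3g] (%d resamples)\n",
                x$ci95[1L], x$ci95[2L], attr(x$ci95, "n_boot")))
  }
  invisible(x)
}

#' @method coef csm_variance
#' @export
coef.csm_variance <- function(object, ...) {
  c(mu = object$mu, delta2 = object$delta2, V_hat = object$V_hat)
}

#' Bootstrap confidence interval for the variance estimator
#'
#' Percentile 95% interval of `V_hat` from resampling cells with
#' replacement and refitting the random-effects model. Deterministic for
#' a given seed; the global RNG state is preserved.
#'
#' @param fit a `csm_variance` fit.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return the fit with `ci95` filled in (2-vector, attributes `n_boot`
#'   and `boot_v` with the resampled estimates).
#' @export
variance_ci <- function(fit, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "csm_variance"))
  if (isTRUE(fit$undefined)) return(fit)
  n <- fit$n_cells
  v_star <- numeric(n_boot)
  with_preserved_rng(seed, {
    for (bb in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      f <- variance_fit(fit$theta[idx], fit$V[idx])
      v_star[bb] <- f$V_hat
    }
  })
  ci <- stats::quantile(v_star, c(0.025, 0.975), names = FALSE, type = 7)
  attr(ci, "n_boot") <- n_boot
  attr(ci, "boot_v") <- v_star
  fit$ci95 <- ci
  fit
}

#' Per-region variance table
#'
#' Applies [variance_fit()] (and optionally [variance_ci()]) to every
#' region of a site-count table, using the empirical-Bayes posterior
#' means and variances as inputs.
#'
#' @param counts site-count frame (`region_id`, `cell_id`, `position`,
#'   `meth`, `total`).
#' @param ci compute bootstrap CIs (default FALSE).
#' @param n_boot,seed bootstrap controls.
#' @param pool prior pooling convention, see [region_posteriors()].
#' @return data frame: `region_id`, `n_cells`, `mu`, `delta2`, `V_hat`,
#'   `ci_lo`, `ci_hi`.
#' @export
variance_scan <- function(counts, ci = FALSE, n_boot = 1000L, seed = 1L,
                          pool = "cells") {
  rids <- unique(counts$region_id)
  rows <- lapply(rids, function(rid) {
    d <- counts[counts$region_id == rid, , drop = FALSE]
    po <- region_posteriors(d, pool = pool)
    po <- po[po$sum_n > 0, , drop = FALSE]
    f <- variance_fit(po$post_mean, po$post_var, cell_id = po$cell_id)
    lo <- hi <- NA_real_
    if (ci && !isTRUE(f$undefined)) {
      f <- variance_ci(f, n_boot = n_boot, seed = derive_seed(seed, rid))
      lo <- f$ci95[1L]; hi <- f$ci95[2L]
    }
    data.frame(region_id = rid, n_cells = f$n_cells, mu = f$mu,
               delta2 = f$delta2, V_hat = f$V_hat, ci_lo = lo, ci_hi = hi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
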
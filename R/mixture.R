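#' Fit the two-state beta mixture model to one region
#'
#' Cells within a candidate region are modelled as a K-component mixture
#' over latent methylation states. Cell i contributes its pooled counts
#' (sum_m_i, sum_n_i) and its empirical-Bayes prior (alpha_i, beta_i);
#' writing `a_i = sum_m_i + alpha_i` and `b_i = sum_n_i - sum_m_i +
#' beta_i`, the component density of cell i under state methylation
#' probability theta is
#'
#' `Pr(i | theta) = Gamma(a_i) Gamma(b_i) / Gamma(a_i + b_i) *
#'   theta^(a_i - 1) (1 - theta)^(b_i - 1)`
#'
#' and the mixture likelihood is `prod_i sum_k lambda_k Pr(i |
#' theta_k)`. Parameters are estimated by EM: the E-step computes state
#' memberships `Pr(Y_i = k | i, Theta)`, the M-step updates `lambda_k`
#' as the mean membership and `theta_k` as the membership-weighted
#' posterior-mode ratio `sum_i g_ik (a_i - 1) / sum_i g_ik (a_i + b_i -
#' 2)`. States are relabelled so `theta[1] >= theta[2]`.
#'
#' The one-state null (single shared theta, closed-form maximizer) is
#' fitted alongside and the likelihood ratio statistic `2 (l2 - l1)` is
#' referred to a chi-squared distribution with `df = 2` by default (3
#' free parameters vs 1); note the usual caveat that mixture LRT
#' regularity fails on the boundary, making the chi-squared reference
#' conservative. A parametric bootstrap reference is available via
#' [lrt()].
#'
#' Initialization: the first restart splits cells at the median
#' posterior mean; remaining restarts draw memberships uniformly. The
#' RNG state is preserved; randomness is derived from `seed` (plus a
#' stable hash of `region_id` when given, so scans are reproducible
#' region by region).
#'
#' @param sum_m,sum_n per-cell pooled methylated / total counts.
#' @param alpha,beta per-cell beta prior parameters (recycled).
#' @param cell_id optional cell labels.
#' @param K number of states (only 2 supported).
#' @param restarts number of EM initializations (default 10).
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param seed integer seed for the restart draws.
#' @param region_id optional region label, mixed into the seed.
#' @return an object of class `beta_mixture`.
#' @seealso [lrt()], [assign_membership()], [csm_scan()]
#' @examples
#' fit <- fit_beta_mixture(sum_m = c(38, 40, 2, 1), sum_n = rep(40, 4),
#'                         seed = 1)
#' coef(fit)
#' @export
fit_beta_mixture <- function(sum_m, sum_n, alpha = 1, beta = 1,
                             cell_id = NULL, K = 2L, restarts = 10L,
                             tol = 1e-6, max_iter = 500L, seed = NULL,
                             region_id = NULL) {
  stopifnot(K == 2L, length(sum_m) == length(sum_n), all(sum_m <= sum_n))
  n_cells <- length(sum_m)
  if (n_cells < 2L) stop("fit_beta_mixture() needs at least 2 cells with data")
  alpha <- rep_len(alpha, n_cells)
  beta <- rep_len(beta, n_cells)
  if (is.null(cell_id)) cell_id <- paste0("cell", seq_len(n_cells))
  a <- sum_m + alpha
  b <- sum_n - sum_m + beta
  eps <- 1e-6
  const <- lgamma(a) + lgamma(b) - lgamma(a + b)

  log_f <- function(theta) {
    # n_cells x K matrix of log component densities
    outer(a - 1, log(theta)) + outer(b - 1, log1p(-theta)) + const
  }

  # one-state null: closed-form maximizer of sum_i log Pr(i | theta)
  theta_null <- clamp01(sum(a - 1) / max(sum(a + b - 2), 2 * eps), eps)
  loglik_null <- sum(const + (a - 1) * log(theta_null) +
                       (b - 1) * log1p(-theta_null))

  run_em <- function(gamma1) {
    g <- cbind(gamma1, 1 - gamma1)
    dimnames(g) <- NULL
    lambda <- colMeans(g)
    theta <- update_theta(g, a, b, eps)
    ll_old <- -Inf
    ll_trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      lf <- log_f(theta)
      lw <- sweep(lf, 2L, log(pmax(lambda, eps)), `+`)
      mx <- apply(lw, 1L, max)
      lse <- mx + log(rowSums(exp(lw - mx)))
      ll <- sum(lse)
      ll_trace <- c(ll_trace, ll)
      g <- exp(lw - lse)
      lambda <- colMeans(g)
      theta <- update_theta(g, a, b, eps)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    list(lambda = lambda, theta = theta, gamma = g, loglik = ll,
         n_iter = length(ll_trace), converged = converged,
         ll_trace = ll_trace)
  }

  seed_eff <- derive_seed(seed, region_id)
  best <- NULL
  with_preserved_rng(seed_eff, {
    for (r in seq_len(max(1L, restarts) + 1L)) {
      g1 <- if (r == 1L) {
        # symmetric start: the one-state fixed point, so the best fit can
        # never fall below the nested null likelihood
        rep(0.5, n_cells)
      } else if (r == 2L) {
        pm <- a / (a + b)
        split0 <- as.numeric(pm >= stats::median(pm))
        if (all(split0 == split0[1L])) stats::runif(n_cells) else
          0.98 * split0 + 0.01
      } else {
        stats::runif(n_cells)
      }
      fit_r <- run_em(g1)
      if (is.null(best) || fit_r$loglik > best$loglik) best <- fit_r
    }
  })

  # relabel so theta[1] >= theta[2]
  if (best$theta[1L] < best$theta[2L]) {
    best$theta <- rev(best$theta)
    best$lambda <- rev(best$lambda)
    best$gamma <- best$gamma[, 2:1, drop = FALSE]
  }
  degenerate <- any(colSums(best$gamma) < eps)
  statistic <- 2 * (best$loglik - loglik_null)
  if (statistic < -1e-8) {
    stop("EM did not reach the null likelihood; increase restarts/max_iter")
  }
  statistic <- max(statistic, 0)
  p_value <- stats::pchisq(statistic, df = 2, lower.tail = FALSE)
  dimnames(best$gamma) <- list(cell_id, c("state1", "state2"))

  structure(list(
    K = K, lambda = best$lambda, theta = best$theta,
    theta_diff = best$theta[1L] - best$theta[2L],
    membership = best$gamma, loglik = best$loglik,
    loglik_null = loglik_null, theta_null = theta_null,
    statistic = statistic, df = 2L, p_value = p_value,
    n_cells = n_cells, n_iter = best$n_iter, converged = best$converged,
    degenerate = degenerate, ll_trace = best$ll_trace,
    data = data.frame(cell_id = cell_id, sum_m = sum_m, sum_n = sum_n,
                      alpha = alpha, beta = beta, a = a, b = b,
                      stringsAsFactors = FALSE),
    seed = seed_eff, region_id = region_id,
    call = match.call()), class = "beta_mixture")
}

update_theta <- function(g, a, b, eps) {
  num <- colSums(g * (a - 1))
  den <- colSums(g * (a + b - 2))
  num <- pmax(num, eps)
  den <- pmax(den, 2 * eps)
  clamp01(num / den, eps)
}

clamp01 <- function(x, eps) pmin(pmax(x, eps), 1 - eps)

derive_seed <- function(seed, region_id) {
  if (is.null(seed)) return(NULL)
  h <- 0
  if (!is.null(region_id)) {
    for (ch in utf8ToInt(as.character(region_id))) h <- (h * 31 + ch) %% 1000003
  }
  as.integer((as.numeric(seed) + h) %% .Machine$integer.max)
}

with_preserved_rng <- function(seed, code) {
  if (is.null(seed)) return(invisible(eval.parent(substitute(code))))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  invisible(eval.parent(substitute(code)))
}

#' @export
print.beta_mixture <- function(x, ...) {
  cat("Two-state beta mixture fit\n")
  cat(sprintf("  cells: %d   lambda: %.3f/%.3f\n", x$n_cells,
              x$lambda[1L], x$lambda[2L]))
  cat(sprintf("  theta: %.4f (hyper) / %.4f (hypo), diff %.4f\n",
              x$theta[1L], x$theta[2L], x$theta_diff))
  cat(sprintf("  logLik %.3f (null %.3f), LRT %.3f on %d df, p = %.3g\n",
              x$loglik, x$loglik_null, x$statistic, x$df, x$p_value))
  if (x$degenerate) cat("  warning: a state is empty (degenerate fit)\n")
  invisible(x)
}

#' @method summary beta_mixture
#' @export
summary.beta_mixture <- function(object, ...) {
  states <- assign_membership(object)
  cat("Two-state beta mixture model\n\n")
  print(object)
  cat("\nPer-cell assignment:\n")
  df <- data.frame(object$data[, c("cell_id", "sum_m", "sum_n")],
                   level = object$data$sum_m / pmax(object$data$sum_n, 1),
                   pr_state1 = object$membership[, 1L],
                   state = states)
  print(df, digits = 3)
  invisible(df)
}

#' @method coef beta_mixture
#' @export
coef.beta_mixture <- function(object, ...) {
  c(lambda1 = object$lambda[1L], lambda2 = object$lambda[2L],
    theta1 = object$theta[1L], theta2 = object$theta[2L])
}

#' @method logLik beta_mixture
#' @export
logLik.beta_mixture <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n_cells, class = "logLik")
}

#' Predict state memberships or hard labels from a mixture fit
#'
#' @param object a `beta_mixture` fit.
#' @param type `"membership"` (posterior probability matrix) or
#'   `"state"` (hard labels via [assign_membership()]).
#' @param ... unused.
#' @method predict beta_mixture
#' @export
predict.beta_mixture <- function(object, type = c("membership", "state"), ...) {
  type <- match.arg(type)
  if (type == "membership") object$membership else assign_membership(object)
}

#' Simulate pooled per-cell counts from a fitted mixture
#'
#' Draws cell states from the fitted proportions and methylated counts
#' from Binomial(sum_n_i, theta_state), keeping each cell's observed
#' total count.
#'
#' @param object a `beta_mixture` fit.
#' @param nsim number of replicate data sets.
#' @param seed optional seed (RNG state preserved).
#' @param ... unused.
#' @return list of `nsim` data frames (`cell_id`, `sum_m`, `sum_n`,
#'   `state`).
#' @method simulate beta_mixture
#' @export
simulate.beta_mixture <- function(object, nsim = 1, seed = NULL, ...) {
  n <- object$n_cells
  out <- vector("list", nsim)
  with_preserved_rng(seed, {
    for (s in seq_len(nsim)) {
      st <- 1L + (stats::runif(n) > object$lambda[1L])
      m <- stats::rbinom(n, object$data$sum_n, object$theta[st])
      out[[s]] <- data.frame(cell_id = object$data$cell_id,
                             sum_m = m, sum_n = object$data$sum_n,
                             state = st, stringsAsFactors = FALSE)
    }
  })
  out
}

#' Residuals of a beta mixture fit
#'
#' Pearson residuals of each cell's pooled methylated count against its
#' membership-weighted fitted probability.
#'
#' @param object a `beta_mixture` fit.
#' @param ... unused.
#' @method residuals beta_mixture
#' @export
residuals.beta_mixture <- function(object, ...) {
  fitted_p <- drop(object$membership %*% object$theta)
  n <- object$data$sum_n
  (object$data$sum_m - n * fitted_p) /
    sqrt(pmax(n * fitted_p * (1 - fitted_p), .Machine$double.eps))
}

#' Likelihood ratio test of two states versus one
#'
#' Compares the two-state mixture to the one-state null. The default
#' reference is chi-squared with 2 degrees of freedom; the parametric
#' bootstrap draws `B` data sets from the fitted null (keeping each
#' cell's total count and prior), refits both models, and reports the
#' empirical tail probability `( #{T* >= T} + 1 ) / (B + 1)`.
#'
#' @param fit a `beta_mixture` fit.
#' @param method `"chisq"` (default) or `"bootstrap"`.
#' @param B bootstrap replicates (default 200).
#' @param seed seed for the bootstrap.
#' @return list with `statistic`, `df`, `p_value`, `method`.
#' @export
lrt <- function(fit, method = c("chisq", "bootstrap"), B = 200L, seed = NULL) {
  stopifnot(inherits(fit, "beta_mixture"))
  method <- match.arg(method)
  if (method == "chisq") {
    return(list(statistic = fit$statistic, df = fit$df,
                p_value = fit$p_value, method = "chisq"))
  }
  n <- fit$n_cells
  stat_star <- numeric(B)
  with_preserved_rng(derive_seed(seed, fit$region_id), {
    for (bb in seq_len(B)) {
      m_star <- stats::rbinom(n, fit$data$sum_n, fit$theta_null)
      f_star <- fit_beta_mixture(m_star, fit$data$sum_n,
                                 alpha = fit$data$alpha, beta = fit$data$beta,
                                 restarts = 3L, seed = bb)
      stat_star[bb] <- f_star$statistic
    }
  })
  p <- (sum(stat_star >= fit$statistic) + 1) / (B + 1)
  list(statistic = fit$statistic, df = NA_integer_, p_value = p,
       method = "bootstrap", B = B)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of a vector of p-values.
#'
#' @param p p-values in \[0, 1\].
#' @return adjusted p-values (same order as input).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Hard state labels from a mixture fit
#'
#' Cell i is assigned to the first (hyper-methylated) state when
#' `Pr(Y_i = 1) >= Pr(Y_i = 2)`, ties going to state 1.
#'
#' @param fit a `beta_mixture` fit.
#' @return integer vector of 1/2 labels named by cell.
#' @export
assign_membership <- function(fit) {
  stopifnot(inherits(fit, "beta_mixture"))
  lab <- ifelse(fit$membership[, 1L] >= fit$membership[, 2L], 1L, 2L)
  stats::setNames(lab, rownames(fit$membership))
}

#' Call CSM regions from a table of mixture fits
#'
#' A region is a putative CSM locus when (i) its BH-adjusted LRT p-value
#' is significant at `alpha`, (ii) the estimated state difference
#' `theta1 - theta2` is at least `theta_diff_cutoff`, and (iii) data
#' were observed in at least `min_cells_call` cells. Optionally a screen
#' on the observed between-group methylation difference (`delta_min`)
#' can be enabled.
#'
#' @param results data frame with columns `p_adjusted`, `theta_diff`,
#'   `n_cells` (and `obs_diff` when `use_delta_min`).
#' @param theta_diff_cutoff minimum estimated state difference
#'   (default 0.3, set from simulation).
#' @param min_cells_call minimum cells with data (default 8).
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param use_delta_min also require `obs_diff >= delta_min`.
#' @param delta_min observed-difference screen (default 0).
#' @return the input with logical `is_csm` and a `reasons` character
#'   column listing failed criteria (empty for calls).
#' @export
call_csm <- function(results, theta_diff_cutoff = 0.3, min_cells_call = 8L,
                     alpha = 0.05, use_delta_min = FALSE, delta_min = 0) {
  fail <- function(cond, tag) ifelse(cond, "", tag)
  r1 <- fail(results$p_adjusted < alpha, "p_adjusted")
  r2 <- fail(results$theta_diff >= theta_diff_cutoff, "theta_diff")
  r3 <- fail(results$n_cells >= min_cells_call, "n_cells")
  r4 <- if (use_delta_min) fail(results$obs_diff >= delta_min, "obs_diff")
        else ""
  reasons <- trimws(paste(r1, r2, r3, r4))
  reasons <- gsub("\\s+", ",", reasons)
  results$is_csm <- reasons == ""
  results$reasons <- reasons
  results
}

#' Scan candidate regions for cell-subset specific methylation
#'
#' Runs the empirical-Bayes prior/posterior layer and the two-state
#' mixture fit over every region of a per-cell site-count table, applies
#' the likelihood ratio test, adjusts p-values across regions by
#' Benjamini-Hochberg, and calls CSM loci.
#'
#' @param counts site-count frame (`region_id`, `cell_id`, `position`,
#'   `meth`, `total`), e.g. from [build_candidate_regions()].
#' @param pool prior pooling convention, see [region_posteriors()].
#' @param restarts,tol,max_iter,seed EM controls, see
#'   [fit_beta_mixture()].
#' @param theta_diff_cutoff,min_cells_call,alpha calling thresholds, see
#'   [call_csm()].
#' @return a `csm_scan` object: a results data frame (one row per
#'   region: estimates, LRT, adjusted p, call) with the per-region fits
#'   in `attr(, "fits")`.
#' @export
csm_scan <- function(counts, pool = "cells", restarts = 10L, tol = 1e-6,
                     max_iter = 500L, seed = 1L, theta_diff_cutoff = 0.3,
                     min_cells_call = 8L, alpha = 0.05) {
  rids <- unique(counts$region_id)
  fits <- list()
  rows <- list()
  for (rid in rids) {
    d <- counts[counts$region_id == rid, , drop = FALSE]
    po <- region_posteriors(d, pool = pool)
    po <- po[po$sum_n > 0, , drop = FALSE]
    if (nrow(po) < 2L) next
    fit <- fit_beta_mixture(po$sum_m, po$sum_n, alpha = po$alpha,
                            beta = po$beta, cell_id = po$cell_id,
                            restarts = restarts, tol = tol,
                            max_iter = max_iter, seed = seed,
                            region_id = rid)
    st <- assign_membership(fit)
    lev <- po$sum_m / po$sum_n
    obs_diff <- if (length(unique(st)) == 2L) {
      mean(lev[st == 1L]) - mean(lev[st == 2L])
    } else NA_real_
    fits[[rid]] <- fit
    rows[[rid]] <- data.frame(
      region_id = rid, n_cells = fit$n_cells,
      lambda1 = fit$lambda[1L], theta1 = fit$theta[1L],
      theta2 = fit$theta[2L], theta_diff = fit$theta_diff,
      obs_diff = obs_diff, loglik = fit$loglik,
      loglik_null = fit$loglik_null, statistic = fit$statistic,
      p_value = fit$p_value, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    res <- data.frame(region_id = character(), n_cells = integer(),
                      lambda1 = numeric(), theta1 = numeric(),
                      theta2 = numeric(), theta_diff = numeric(),
                      obs_diff = numeric(), loglik = numeric(),
                      loglik_null = numeric(), statistic = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      is_csm = logical(), reasons = character(),
                      stringsAsFactors = FALSE)
    class(res) <- c("csm_scan", "data.frame")
    attr(res, "fits") <- list()
    return(res)
  }
  res <- do.call(rbind, rows)
  res$p_adjusted <- bh_adjust(res$p_value)
  res <- call_csm(res, theta_diff_cutoff = theta_diff_cutoff,
                  min_cells_call = min_cells_call, alpha = alpha)
  rownames(res) <- NULL
  class(res) <- c("csm_scan", "data.frame")
  attr(res, "fits") <- fits
  res
}

#' @export
print.csm_scan <- function(x, ...) {
  cat(sprintf("CSM scan over %d region(s): %d called\n",
              nrow(x), sum(x$is_csm)))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 3)
  if (nrow(x) > 10L) cat(sprintf("... and %d more region(s)\n", nrow(x) - 10L))
  invisible(x)
}

#' @method summary csm_scan
#' @export
summary.csm_scan <- function(object, ...) {
  called <- object[object$is_csm, , drop = FALSE]
  cat(sprintf("Regions tested: %d\nCSM calls:      %d\n",
              nrow(object), nrow(called)))
  if (nrow(called)) {
    cat(sprintf("theta_diff of calls: median %.3f (range %.3f-%.3f)\n",
                stats::median(called$theta_diff), min(called$theta_diff),
                max(called$theta_diff)))
  }
  invisible(called)
}
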
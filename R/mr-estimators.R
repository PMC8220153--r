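# Causal-effect estimators for two-sample MR from harmonized instruments.
#
# The headline estimator is inverse-variance weighted (IVW) with weights
# 1/var(beta_y); sensitivity methods (weighted median, maximum likelihood,
# MR-Egger, MR-PRESSO, leave-one-out) probe robustness to invalid
# instruments and pleiotropy.

new_mr_estimate <- function(theta, var_theta, method, k, q_ivs = NA_real_,
                            extra = list()) {
  se <- sqrt(var_theta)
  est <- list(
    theta = theta,
    var_theta = var_theta,
    se = se,
    ci_low = theta - qnorm(0.975) * se,
    ci_high = theta + qnorm(0.975) * se,
    pvalue = if (se > 0) 2 * pnorm(-abs(theta / se)) else as.numeric(theta == 0),
    odds_ratio = exp(theta),
    method = method,
    k = k,
    q_ivs = q_ivs
  )
  structure(c(est, extra), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], k = %d instruments\n", x$method, x$k))
  cat(sprintf("  theta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$theta, x$se, x$ci_low, x$ci_high, x$pvalue))
  cat(sprintf("  OR per SD = %.3f (95%% CI %.3f-%.3f)\n",
              x$odds_ratio, exp(x$ci_low), exp(x$ci_high)))
  if (!is.na(x$q_ivs)) {
    cat(sprintf("  between-instrument Q = %.2f on %d df\n", x$q_ivs, x$k - 1))
  }
  invisible(x)
}

check_harmonized <- function(h, k_min = 1, method = "MR") {
  if (nrow(h) < k_min) {
    stop_sexmr(method, " requires at least ", k_min, " instruments (got ",
               nrow(h), ")", class = "sexmr_domain_error")
  }
  if (any(h$se_y <= 0)) {
    stop_sexmr("outcome standard errors must be strictly positive",
               class = "sexmr_domain_error")
  }
  invisible(h)
}

iv_heterogeneity_q <- function(h, theta) {
  sum((h$beta_y - theta * h$beta_x)^2 / h$se_y^2)
}

#' Fixed-effects inverse-variance weighted estimator
#'
#' `theta = sum(w * beta_y * beta_x) / sum(w * beta_x^2)` with
#' `w = 1/se_y^2`, and `var(theta) = 1 / sum(w * beta_x^2)`.  Weights use
#' only the outcome variance; exposure standard errors are carried but not
#' used.  With a single instrument this reduces to the ratio estimate
#' `beta_y / beta_x`.
#'
#' @param h A [harmonize()]d instrument set.
#' @return An `mr_estimate`.
#' @export
ivw_fixed <- function(h) {
  check_harmonized(h, 1, "IVW")
  w <- 1 / h$se_y^2
  denom <- sum(w * h$beta_x^2)
  if (denom == 0) {
    stop_sexmr("all exposure effects are zero; instruments are degenerate",
               class = "sexmr_degenerate_error")
  }
  theta <- sum(w * h$beta_y * h$beta_x) / denom
  q <- if (nrow(h) >= 2) iv_heterogeneity_q(h, theta) else NA_real_
  new_mr_estimate(theta, 1 / denom, "ivw_fixed", nrow(h), q)
}

#' Multiplicative random-effects inverse-variance weighted estimator
#'
#' Point estimate identical to [ivw_fixed()]; the standard error is
#' inflated by `max(1, sqrt(Q/(k-1)))` where Q is the between-instrument
#' heterogeneity statistic, so that over-dispersion widens the interval but
#' homogeneous instruments are never rewarded with a narrower one.
#'
#' @inheritParams ivw_fixed
#' @return An `mr_estimate`; the applied inflation factor is included as
#'   `inflation`.
#' @export
ivw_random <- function(h) {
  check_harmonized(h, 2, "random-effects IVW")
  fixed <- ivw_fixed(h)
  k <- nrow(h)
  inflation <- max(1, sqrt(fixed$q_ivs / (k - 1)))
  if (inflation > 1) {
    sexmr_log("random-effects IVW: se inflated by ",
              formatC(inflation, digits = 4, format = "g"))
  }
  new_mr_estimate(fixed$theta, fixed$var_theta * inflation^2, "ivw_random",
                  k, fixed$q_ivs, extra = list(inflation = inflation))
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(r[1])
  if (cw[length(cw)] <= 0.5) return(r[length(r)])
  below <- max(which(cw < 0.5))
  r[below] + (r[below + 1] - r[below]) * (0.5 - cw[below]) /
    (cw[below + 1] - cw[below])
}

#' Weighted median estimator
#'
#' Per-instrument ratio estimates `beta_y/beta_x` with weights
#' `(beta_x/se_y)^2` are sorted and the weight-interpolated 50th percentile
#' taken; consistent when instruments carrying at least half the weight are
#' valid.  The standard error comes from a seeded parametric bootstrap that
#' perturbs both exposure and outcome effects by their standard errors.
#'
#' @inheritParams ivw_fixed
#' @param n_boot Number of bootstrap replicates for the SE.
#' @param seed Optional integer seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  check_harmonized(h, 3, "weighted median")
  if (any(h$beta_x == 0)) {
    stop_sexmr("zero exposure effect gives an undefined ratio for: ",
               paste(h$snp[h$beta_x == 0], collapse = ", "),
               class = "sexmr_domain_error")
  }
  ratios <- h$beta_y / h$beta_x
  weights <- (h$beta_x / h$se_y)^2
  theta <- weighted_median_point(ratios, weights)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  k <- nrow(h)
  boot <- vapply(seq_len(n_boot), function(b) {
    bx <- rnorm(k, h$beta_x, h$se_x)
    by <- rnorm(k, h$beta_y, h$se_y)
    ok <- bx != 0
    weighted_median_point(by[ok] / bx[ok], (bx[ok] / h$se_y[ok])^2)
  }, numeric(1))
  new_mr_estimate(theta, var(boot), "weighted_median", k,
                  iv_heterogeneity_q(h, theta))
}

#' Maximum-likelihood estimator
#'
#' Joint normal measurement-error model: observed `beta_x_i ~ N(xi_i,
#' se_x_i^2)` and `beta_y_i ~ N(theta * xi_i, se_y_i^2)`.  The latent true
#' effects are profiled out analytically, leaving a one-dimensional profile
#' likelihood in theta that is maximised numerically from the IVW starting
#' value; the standard error is the inverse observed information (profile
#' curvature) at the optimum.
#'
#' @inheritParams ivw_fixed
#' @param tol Convergence tolerance passed to the optimiser.
#' @param maxit Maximum optimiser iterations.
#' @return An `mr_estimate`.
#' @export
max_likelihood <- function(h, tol = 1e-10, maxit = 500) {
  check_harmonized(h, 2, "maximum likelihood")
  bx <- h$beta_x; by <- h$beta_y
  vx <- h$se_x^2; vy <- h$se_y^2
  # profile negative log-likelihood (constants dropped)
  nll <- function(theta) 0.5 * sum((by - theta * bx)^2 / (vy + theta^2 * vx))
  init <- ivw_fixed(h)$theta
  fit <- optim(init, nll, method = "BFGS", hessian = TRUE,
               control = list(maxit = maxit, reltol = tol))
  if (fit$convergence != 0) {
    stop_sexmr("maximum-likelihood optimisation did not converge ",
               "(code ", fit$convergence, ", ",
               fit$counts[1], " evaluations)",
               class = "sexmr_estimation_error")
  }
  info <- fit$hessian[1, 1]
  if (!is.finite(info) || info <= 0) {
    stop_sexmr("observed information is not positive at the optimum",
               class = "sexmr_estimation_error")
  }
  new_mr_estimate(fit$par, 1 / info, "max_likelihood", nrow(h),
                  iv_heterogeneity_q(h, fit$par))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure effects with an
#' intercept (weights `1/se_y^2`).  The slope is the causal estimate; a
#' non-zero intercept indicates directional pleiotropy.  Because Egger
#' regression is not invariant to allele orientation, every instrument is
#' re-signed so that `beta_x >= 0` before fitting.
#'
#' @inheritParams ivw_fixed
#' @return An object of class `egger_result`: list with `slope` (an
#'   `mr_estimate`), `intercept`, `intercept_se`, `intercept_ci_low`,
#'   `intercept_ci_high`, `intercept_pvalue`.
#' @export
mr_egger <- function(h) {
  check_harmonized(h, 3, "MR-Egger")
  flip <- sign(h$beta_x)
  flip[flip == 0] <- 1
  bx <- h$beta_x * flip
  by <- h$beta_y * flip
  w <- 1 / h$se_y^2
  fit <- lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  slope <- cf["bx", "Estimate"]
  slope_se <- cf["bx", "Std. Error"]
  intercept <- cf["(Intercept)", "Estimate"]
  intercept_se <- cf["(Intercept)", "Std. Error"]
  ip <- if (intercept_se > 0) {
    2 * pnorm(-abs(intercept / intercept_se))
  } else as.numeric(intercept == 0)
  structure(list(
    slope = new_mr_estimate(slope, slope_se^2, "mr_egger", nrow(h),
                            iv_heterogeneity_q(h, slope)),
    intercept = intercept,
    intercept_se = intercept_se,
    intercept_ci_low = intercept - qnorm(0.975) * intercept_se,
    intercept_ci_high = intercept + qnorm(0.975) * intercept_se,
    intercept_pvalue = ip
  ), class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  Egger intercept = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$intercept, x$intercept_se, x$intercept_ci_low,
              x$intercept_ci_high, x$intercept_pvalue))
  invisible(x)
}

# Leave-one-out IVW estimates for all i at once: O(k) via sum subtraction.
ivw_loo_thetas <- function(bx, by, w) {
  num <- sum(w * by * bx)
  den <- sum(w * bx^2)
  (num - w * by * bx) / (den - w * bx^2)
}

#' MR-PRESSO global and per-instrument outlier test
#'
#' Observed residual sum of squares `RSS = sum_i (beta_y_i - theta_(-i) *
#' beta_x_i)^2`, where `theta_(-i)` is the IVW estimate computed without
#' instrument i.  Its null distribution is simulated parametrically:
#' outcome effects are redrawn as `N(theta_(-i) * beta_x_i, se_y_i^2)` and
#' the RSS recomputed (with the leave-one-out estimates re-estimated on
#' each simulated dataset).  Per-instrument outlier p-values are the tail
#' fractions of each instrument's simulated squared residuals,
#' Bonferroni-adjusted over k.
#'
#' @inheritParams ivw_fixed
#' @param n_sim Number of parametric simulations.
#' @param alpha Significance level for flagging outliers.
#' @param seed Optional integer seed.
#' @return An object of class `presso_result`: list with `global_rss`,
#'   `global_pvalue`, `outlier_pvalues` (named, Bonferroni-adjusted),
#'   `outliers`, `n_sim`.
#' @export
mr_presso <- function(h, n_sim = 1000, alpha = 0.05, seed = NULL) {
  check_harmonized(h, 4, "MR-PRESSO")
  if (n_sim < 100) {
    warning("n_sim < 100 gives a very coarse MR-PRESSO p-value",
            call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  k <- nrow(h)
  bx <- h$beta_x; by <- h$beta_y
  w <- 1 / h$se_y^2
  theta_loo <- ivw_loo_thetas(bx, by, w)
  resid_obs2 <- (by - theta_loo * bx)^2
  global_rss <- sum(resid_obs2)

  # simulate n_sim outcome-effect vectors under the per-instrument null
  sim_by <- matrix(rnorm(n_sim * k, mean = rep(theta_loo * bx, each = n_sim),
                         sd = rep(h$se_y, each = n_sim)), n_sim, k)
  sim_resid2 <- matrix(0, n_sim, k)
  for (s in seq_len(n_sim)) {
    tl <- ivw_loo_thetas(bx, sim_by[s, ], w)
    sim_resid2[s, ] <- (sim_by[s, ] - tl * bx)^2
  }
  sim_rss <- rowSums(sim_resid2)
  global_pvalue <- (1 + sum(sim_rss >= global_rss)) / (1 + n_sim)
  p_i <- (1 + colSums(sim_resid2 >= rep(resid_obs2, each = n_sim))) /
    (1 + n_sim)
  p_adj <- pmin(1, p_i * k)
  names(p_adj) <- h$snp
  structure(list(
    global_rss = global_rss,
    global_pvalue = global_pvalue,
    outlier_pvalues = p_adj,
    outliers = h$snp[p_adj < alpha],
    n_sim = n_sim
  ), class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS = %.4f, p = %.3g (%d simulations)\n",
              x$global_rss, x$global_pvalue, x$n_sim))
  if (length(x$outliers)) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  } else {
    cat("  no instrument outliers detected\n")
  }
  invisible(x)
}

mr_estimator <- function(label) {
  switch(label,
    ivw_fixed = ivw_fixed,
    ivw_random = ivw_random,
    weighted_median = weighted_median,
    max_likelihood = max_likelihood,
    stop_sexmr("unknown estimator label: ", label,
               class = "sexmr_config_error")
  )
}

#' Leave-one-out sensitivity estimates
#'
#' Recomputes the causal estimate k times, excluding one instrument each
#' time, to show whether any single instrument drives the overall result.
#'
#' @inheritParams ivw_fixed
#' @param estimator Method label: one of `"ivw_fixed"`, `"ivw_random"`,
#'   `"weighted_median"`, `"max_likelihood"`.
#' @return A data.frame with one row per excluded instrument: `excluded`,
#'   `theta`, `se`, `ci_low`, `ci_high`, `pvalue`, `k`.
#' @export
loo_estimates <- function(h, estimator = "ivw_fixed") {
  check_harmonized(h, 2, "leave-one-out analysis")
  fn <- mr_estimator(estimator)
  rows <- lapply(seq_len(nrow(h)), function(i) {
    est <- tryCatch(
      fn(new_harmonized(as.data.frame(h)[-i, , drop = FALSE])),
      error = function(e) {
        stop_sexmr("leave-one-out estimate failed when excluding ",
                   h$snp[i], ": ", conditionMessage(e),
                   class = "sexmr_estimation_error")
      }
    )
    data.frame(excluded = h$snp[i], theta = est$theta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high,
               pvalue = est$pvalue, k = est$k, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
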
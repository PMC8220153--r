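# Formal comparison of sex-combined and sex-specific causal estimates.
#
# The u statistic is a Wald test of H0: theta_combined = theta_specific
# whose denominator accounts for the correlation rho between the two
# estimates (they share the outcome GWAS and often many instruments):
#   u = (theta_c - theta_s) / sqrt(se_c^2 + se_s^2 - 2 rho se_c se_s)
# rho is estimated by pairing leave-one-instrument-out recomputations of
# the two estimates.

#' u test for equality of two correlated causal estimates
#'
#' @param est_combined,est_specific `mr_estimate` objects (or lists with
#'   `theta` and `se`) for the sex-combined and sex-specific analyses.
#' @param rho Correlation between the two estimates, typically from
#'   [jackknife_rho()].
#' @param n_jackknife Optional count of jackknife pairs behind `rho`,
#'   carried through for reporting.
#' @return An object of class `comparison_result`: list with `u`, `pvalue`,
#'   `rho`, `theta_combined`, `theta_specific`, `se_combined`,
#'   `se_specific`, `n_jackknife`.
#' @export
u_test <- function(est_combined, est_specific, rho, n_jackknife = NA_integer_) {
  if (abs(rho) > 1) {
    stop_sexmr("rho must lie in [-1, 1]", class = "sexmr_domain_error")
  }
  se_c <- est_combined$se
  se_s <- est_specific$se
  denom2 <- se_c^2 + se_s^2 - 2 * rho * se_c * se_s
  if (denom2 <= 0) {
    stop_sexmr("non-positive variance of the estimate difference ",
               "(rho ~ 1 with equal standard errors); the two analyses are ",
               "statistically indistinguishable at this precision -- ",
               "consider more instruments or an intersection-only jackknife",
               class = "sexmr_degenerate_error")
  }
  u <- (est_combined$theta - est_specific$theta) / sqrt(denom2)
  structure(list(
    u = u,
    pvalue = 2 * pnorm(-abs(u)),
    rho = rho,
    theta_combined = est_combined$theta,
    theta_specific = est_specific$theta,
    se_combined = se_c,
    se_specific = se_s,
    n_jackknife = n_jackknife
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Comparison of causal estimates (H0: equal)\n"))
  cat(sprintf("  theta_combined = %.4f (se %.4f), theta_specific = %.4f (se %.4f)\n",
              x$theta_combined, x$se_combined, x$theta_specific,
              x$se_specific))
  cat(sprintf("  rho = %.3f, u = %.3f, p = %.3g\n", x$rho, x$u, x$pvalue))
  invisible(x)
}

#' Leave-one-out jackknife correlation between two causal estimates
#'
#' Iterates over the union of the two instrument sets; for each id the
#' sex-combined and sex-specific estimates are recomputed with that
#' instrument removed from whichever set(s) contain it (an estimate is left
#' at its full-set value when the id is absent from its set, unless
#' `intersection_only = TRUE`, which restricts iteration to shared ids).
#' The correlation of the paired series estimates rho for [u_test()].
#'
#' @param h_combined,h_specific [harmonize()]d instrument sets behind the
#'   two estimates.
#' @param estimator Method label used inside the jackknife (see
#'   [loo_estimates()]).
#' @param intersection_only Iterate only over instruments common to both
#'   sets.
#' @return A list with `rho` (clamped to `[-1, 1]`), and the audit series
#'   `series` (data.frame: `excluded`, `theta_combined`, `theta_specific`).
#' @export
jackknife_rho <- function(h_combined, h_specific, estimator = "ivw_fixed",
                          intersection_only = FALSE) {
  ids <- if (intersection_only) {
    intersect(h_combined$snp, h_specific$snp)
  } else {
    union(h_combined$snp, h_specific$snp)
  }
  if (length(ids) < 3) {
    stop_sexmr("need at least 3 instruments in the union for a jackknife ",
               "correlation", class = "sexmr_domain_error")
  }
  if (nrow(h_combined) < 2 || nrow(h_specific) < 2) {
    stop_sexmr("each instrument set needs at least 2 members",
               class = "sexmr_domain_error")
  }
  fn <- mr_estimator(estimator)
  drop_one <- function(h, id) {
    i <- match(id, h$snp)
    if (is.na(i)) return(NULL)
    new_harmonized(as.data.frame(h)[-i, , drop = FALSE])
  }
  full_c <- fn(h_combined)$theta
  full_s <- fn(h_specific)$theta
  series <- vapply(ids, function(id) {
    hc <- drop_one(h_combined, id)
    hs <- drop_one(h_specific, id)
    c(if (is.null(hc)) full_c else fn(hc)$theta,
      if (is.null(hs)) full_s else fn(hs)$theta)
  }, numeric(2))
  theta_c <- series[1, ]
  theta_s <- series[2, ]
  if (var(theta_c) == 0 || var(theta_s) == 0) {
    stop_sexmr("a jackknife series is constant; rho is undefined ",
               "(more instruments are needed)",
               class = "sexmr_degenerate_error")
  }
  rho <- cor(theta_c, theta_s)
  if (abs(rho) > 1) {
    sexmr_log("jackknife rho clamped from ", rho, " to [-1, 1]")
    rho <- max(-1, min(1, rho))
  }
  list(rho = rho,
       series = data.frame(excluded = ids, theta_combined = theta_c,
                           theta_specific = theta_s,
                           stringsAsFactors = FALSE, row.names = NULL))
}

#' Full sex-combined vs sex-specific comparison pipeline
#'
#' Harmonizes and QC-filters each instrument set against the shared
#' outcome, estimates both causal effects, estimates rho with the
#' leave-one-out jackknife, and runs the [u_test()].
#'
#' @param exposure_combined,exposure_specific [sumstat_table()]s of
#'   exposure associations from the pooled sample and the sex stratum.
#' @param outcome [sumstat_table()] of outcome associations.
#' @param ivs_combined,ivs_specific [instrument_set()]s selected in each
#'   stratum.
#' @param estimator Method label for the headline estimates and the
#'   jackknife (see [loo_estimates()]).
#' @param qc_alpha Significance level of the outcome-association QC screen.
#' @param intersection_only Passed to [jackknife_rho()].
#' @return A `comparison_result` with the two `mr_estimate`s attached as
#'   `est_combined`/`est_specific` and the jackknife audit series as
#'   `jackknife_series`.
#' @export
compare_pipeline <- function(exposure_combined, exposure_specific, outcome,
                             ivs_combined, ivs_specific,
                             estimator = "ivw_fixed", qc_alpha = 0.05,
                             intersection_only = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_sexmr("[stage ", name, "] ", conditionMessage(e),
                 class = "sexmr_pipeline_error")
    })
  }
  h_c <- stage("harmonize combined",
               harmonize(exposure_combined, outcome, ivs_combined))
  h_s <- stage("harmonize specific",
               harmonize(exposure_specific, outcome, ivs_specific))
  h_c <- stage("qc combined", qc_filter_outcome_associated(h_c, qc_alpha))
  h_s <- stage("qc specific", qc_filter_outcome_associated(h_s, qc_alpha))
  fn <- mr_estimator(estimator)
  est_c <- stage("estimate combined", fn(h_c))
  est_s <- stage("estimate specific", fn(h_s))
  jk <- stage("jackknife rho",
              jackknife_rho(h_c, h_s, estimator = estimator,
                            intersection_only = intersection_only))
  res <- stage("u test",
               u_test(est_c, est_s, jk$rho, n_jackknife = nrow(jk$series)))
  res$est_combined <- est_c
  res$est_specific <- est_s
  res$jackknife_series <- jk$series
  res
}
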
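# Closed-form power for two-sample MR with a binary outcome.

#' Power of a two-sample MR analysis with a binary outcome
#'
#' Normal approximation: with `b = |ln OR|` per SD of exposure, instrument
#' strength entering only through the exposure variance they explain (PVE),
#' the non-centrality parameter is
#' `ncp = sqrt(n * pve * p * (1 - p)) * b` with `p` the case fraction of
#' the outcome GWAS, and `power = Phi(ncp - z_{1 - alpha/2})`.  At OR = 1
#' the approximation returns `Phi(-z_{1 - alpha/2})` (0.025 at alpha =
#' 0.05), its documented floor, rather than alpha.
#'
#' All arguments are vectorised.
#'
#' @param n_outcome Total sample size of the outcome GWAS.
#' @param case_fraction Fraction of cases among `n_outcome`, in (0, 1).
#' @param or_per_sd Causal odds ratio per SD increase of the exposure.
#' @param pve Fraction of exposure variance explained by the instruments,
#'   in (0, 1) (e.g. 0.0151 for 1.51%).
#' @param alpha Two-sided significance level.
#' @return Power as a fraction in (0, 1).
#' @export
mr_power_binary <- function(n_outcome, case_fraction, or_per_sd, pve,
                            alpha = 0.05) {
  if (any(n_outcome <= 0) || any(case_fraction <= 0) ||
      any(case_fraction >= 1) || any(or_per_sd <= 0) ||
      any(pve <= 0) || any(pve >= 1) || any(alpha <= 0) || any(alpha >= 1)) {
    stop_sexmr("power inputs out of range: need n_outcome > 0, ",
               "case_fraction and pve in (0, 1), or_per_sd > 0, ",
               "alpha in (0, 1)", class = "sexmr_domain_error")
  }
  b <- abs(log(or_per_sd))
  ncp <- sqrt(n_outcome * pve * case_fraction * (1 - case_fraction)) * b
  pnorm(ncp - qnorm(1 - alpha / 2))
}
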
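# Per-instrument sex heterogeneity (two-group Cochran's Q) and effect
# correlation between strata.

#' Cochran's Q test for sex heterogeneity of one SNP effect
#'
#' With two strata the Q statistic reduces to the squared z of the effect
#' difference, `Q = (beta_f - beta_m)^2 / (se_f^2 + se_m^2)`, referred to a
#' chi-square distribution with 1 degree of freedom.  Heterogeneity is
#' additionally quantified with `I^2 = max(0, (Q - 1)/Q) * 100`.
#'
#' All arguments are vectorised over SNPs.
#'
#' @param beta_f,se_f Female-specific effect estimate and standard error.
#' @param beta_m,se_m Male-specific effect estimate and standard error.
#' @param snp_id Optional SNP labels.
#' @return A data.frame with columns `snp`, `q`, `pvalue`, `i2`.
#' @export
cochran_q_sex <- function(beta_f, se_f, beta_m, se_m, snp_id = NULL) {
  if (any(se_f <= 0) || any(se_m <= 0)) {
    stop_sexmr("standard errors must be strictly positive",
               class = "sexmr_domain_error")
  }
  q <- (beta_f - beta_m)^2 / (se_f^2 + se_m^2)
  pvalue <- pchisq(q, df = 1, lower.tail = FALSE)
  i2 <- ifelse(q > 0, pmax(0, (q - 1) / q) * 100, 0)
  data.frame(
    snp = snp_id %||% paste0("snp", seq_along(q)),
    q = q, pvalue = pvalue, i2 = i2,
    stringsAsFactors = FALSE
  )
}

#' Screen an instrument set for sex heterogeneity
#'
#' Runs [cochran_q_sex()] on every instrument, Bonferroni-corrects the
#' p-values over the number of instruments tested and flags instruments
#' with corrected p below `alpha`.
#'
#' @param female,male [sumstat_table()]s of sex-specific exposure
#'   associations; every instrument must be present in both.
#' @param ivs [instrument_set()] (or character vector of rsIDs).
#' @param alpha Significance level applied to the Bonferroni-corrected p.
#' @return A data.frame, one row per instrument in input order, with
#'   columns `snp`, `beta_f`, `se_f`, `beta_m`, `se_m`, `q`, `pvalue`,
#'   `pvalue_bonf`, `i2`, `flagged`.
#' @export
screen_heterogeneity <- function(female, male, ivs, alpha = 0.05) {
  ids <- as.character(ivs)
  fi <- match(ids, female$snp)
  mi <- match(ids, male$snp)
  if (anyNA(fi) || anyNA(mi)) {
    missing_ids <- ids[is.na(fi) | is.na(mi)]
    stop_sexmr("instrument(s) missing from a stratum table: ",
               paste(missing_ids, collapse = ", "),
               class = "sexmr_data_error")
  }
  res <- cochran_q_sex(female$beta[fi], female$se[fi],
                       male$beta[mi], male$se[mi], snp_id = ids)
  out <- data.frame(
    snp = ids,
    beta_f = female$beta[fi], se_f = female$se[fi],
    beta_m = male$beta[mi], se_m = male$se[mi],
    q = res$q, pvalue = res$pvalue,
    pvalue_bonf = pmin(1, res$pvalue * length(ids)),
    i2 = res$i2,
    stringsAsFactors = FALSE
  )
  out$flagged <- out$pvalue_bonf < alpha
  out
}

#' Pearson correlation of instrument effects between two strata
#'
#' Quantifies marginal genetic sharing across the instruments as the sample
#' Pearson correlation of the two effect-size vectors.  Two hypotheses are
#' assessed: r = 0 via the usual t statistic, and r = 1 via a Wald statistic
#' whose standard error is the leave-one-out jackknife SE of r (Fisher's z
#' is undefined at r = 1 and is not used for that null).
#'
#' @param beta_a,beta_b Equal-length numeric vectors (length >= 3) of
#'   per-SNP effects in the two strata.
#' @return An object of class `effect_correlation`: list with `r`,
#'   `n_snps`, `p_vs_zero`, `p_vs_one`, `se_jackknife`.
#' @export
pearson_effect_correlation <- function(beta_a, beta_b) {
  if (length(beta_a) != length(beta_b)) {
    stop_sexmr("effect vectors have different lengths",
               class = "sexmr_domain_error")
  }
  n <- length(beta_a)
  if (n < 3) {
    stop_sexmr("need at least 3 SNPs for a correlation",
               class = "sexmr_domain_error")
  }
  if (var(beta_a) == 0 || var(beta_b) == 0) {
    stop_sexmr("zero variance in an effect vector",
               class = "sexmr_domain_error")
  }
  r <- cor(beta_a, beta_b)
  # H0: r = 0, exact t under bivariate normality
  if (abs(r) < 1) {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p_vs_zero <- 2 * pt(-abs(tstat), df = n - 2)
  } else {
    p_vs_zero <- .Machine$double.xmin
  }
  # H0: r = 1, Wald with leave-one-out jackknife SE
  r_loo <- vapply(seq_len(n), function(i) cor(beta_a[-i], beta_b[-i]),
                  numeric(1))
  se_jack <- sqrt((n - 1) / n * sum((r_loo - mean(r_loo))^2))
  p_vs_one <- if (se_jack > 0) {
    2 * pnorm(-abs((r - 1) / se_jack))
  } else if (r == 1) 1 else .Machine$double.xmin
  structure(
    list(r = r, n_snps = n, p_vs_zero = p_vs_zero, p_vs_one = p_vs_one,
         se_jackknife = se_jack),
    class = "effect_correlation"
  )
}

#' @export
print.effect_correlation <- function(x, ...) {
  cat(sprintf("Instrument effect correlation: r = %.3f (n = %d)\n",
              x$r, x$n_snps))
  cat(sprintf("  H0 r = 0: p = %.3g\n", x$p_vs_zero))
  cat(sprintf("  H0 r = 1: p = %.3g (jackknife SE %.3g)\n",
              x$p_vs_one, x$se_jackknife))
  invisible(x)
}
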
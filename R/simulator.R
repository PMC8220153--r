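# Individual-level simulation of a female-specific two-sample MR study.
#
# Protocol per replicate: draw m SNPs (m ~ U{50..150}) with MAF ~
# U(0.01, 0.5); draw per-sex standardized effect sizes from a bivariate
# normal with unit variances and inter-sex correlation r_g; rescale them so
# the genetic variance of each sex's exposure hits the target PVE; simulate
# HWE genotypes for N males and N females; build exposures and a
# female-specific outcome y = theta * x_female + noise; run single-SNP
# GWAS per sex and of y; meta-analyse the two exposure GWAS into
# sex-combined statistics; select instruments at P < 0.05/m on either the
# combined or the female statistics; estimate theta by fixed-effects IVW
# for both instrument strategies.  The contrast between the two estimates
# measures the bias from sex-combined instruments.
#
# The outcome GWAS is computed, by default, on an independent female cohort
# drawn from the same architecture (a genuine two-sample design: exposure
# and outcome samples do not overlap, which is the validity condition of
# two-sample MR).  Setting outcome_overlap = TRUE instead regresses the
# outcome on the exposure cohort's own genotypes (one-sample design).

#' Define a simulation scenario
#'
#' Defaults are the study conditions of the bias experiment: 1e5
#' individuals per sex, 50-150 uncorrelated SNPs, MAF uniform on
#' (0.01, 0.5), and 200 replicates.
#'
#' @param n_male,n_female Individuals simulated per sex.
#' @param m_range Inclusive integer range for the SNP count m.
#' @param maf_range Range of the uniform minor-allele-frequency draw.
#' @param r_g Inter-sex correlation of per-SNP effect sizes, in `[-1, 1]`.
#' @param pve_male,pve_female Target fraction of exposure variance
#'   explained by the SNPs in each sex, in (0, 1).
#' @param theta True causal effect of the female exposure on the outcome.
#' @param iv_alpha Numerator of the instrument-selection threshold
#'   `iv_alpha / m`.
#' @param n_replicates Number of replicates for [run_scenario()].
#' @param seed Scenario-level seed; per-replicate sub-seeds are derived
#'   from it.
#' @param outcome_overlap If `TRUE`, the outcome GWAS is run on the female
#'   exposure cohort itself (one-sample design); the default `FALSE` draws
#'   an independent female outcome cohort of the same size (two-sample
#'   design).
#' @return A `simulation_scenario` list.
#' @export
simulation_scenario <- function(n_male = 1e5, n_female = 1e5,
                                m_range = c(50L, 150L),
                                maf_range = c(0.01, 0.5),
                                r_g = 0.1, pve_male = 0.01,
                                pve_female = 0.03, theta = 0.5,
                                iv_alpha = 0.05, n_replicates = 200L,
                                seed = 1L, outcome_overlap = FALSE) {
  stopifnot(n_male >= 2, n_female >= 2,
            length(m_range) == 2, m_range[1] >= 1, m_range[1] <= m_range[2],
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            abs(r_g) <= 1,
            pve_male > 0, pve_male < 1, pve_female > 0, pve_female < 1,
            iv_alpha > 0, n_replicates >= 1)
  structure(list(
    n_male = as.integer(n_male), n_female = as.integer(n_female),
    m_range = as.integer(m_range), maf_range = maf_range, r_g = r_g,
    pve_male = pve_male, pve_female = pve_female, theta = theta,
    iv_alpha = iv_alpha, n_replicates = as.integer(n_replicates),
    seed = as.integer(seed), outcome_overlap = isTRUE(outcome_overlap)
  ), class = "simulation_scenario")
}

#' Draw the genetic architecture of one replicate
#'
#' Uses the current RNG state.  Effect sizes for the two sexes are drawn
#' jointly from a bivariate normal with zero means, unit variances and
#' correlation `r_g` (realised via the Cholesky factor, so `r_g = 1`
#' degenerates to identical vectors).
#'
#' @param sc A [simulation_scenario()].
#' @return A list with `m`, `mafs`, `alpha_male`, `alpha_female`.
#' @export
draw_architecture <- function(sc) {
  m <- sample(sc$m_range[1]:sc$m_range[2], 1)
  mafs <- runif(m, sc$maf_range[1], sc$maf_range[2])
  z1 <- rnorm(m)
  z2 <- rnorm(m)
  alpha_male <- z1
  alpha_female <- sc$r_g * z1 + sqrt(1 - sc$r_g^2) * z2
  list(m = m, mafs = mafs, alpha_male = alpha_male,
       alpha_female = alpha_female)
}

#' Simulate unlinked HWE genotypes
#'
#' Column j is iid Binomial(2, `mafs[j]`): linkage equilibrium across SNPs
#' and Hardy-Weinberg equilibrium within each.
#'
#' @param n Number of individuals.
#' @param mafs Vector of minor allele frequencies in (0, 0.5].
#' @return An `n x length(mafs)` numeric dosage matrix with values 0/1/2.
#' @export
simulate_genotypes <- function(n, mafs) {
  if (any(mafs <= 0) || any(mafs > 0.5)) {
    stop_sexmr("minor allele frequencies must lie in (0, 0.5]",
               class = "sexmr_domain_error")
  }
  .gen_genotypes_cpp(as.integer(n), as.numeric(mafs))
}

#' Rescale effect sizes to a target variance explained
#'
#' With standardized genotype columns the exposure's genetic variance is
#' `delta^2 * sum(alpha^2)` against residual variance 1, so
#' `PVE = delta^2 S / (delta^2 S + 1)` inverts to
#' `delta = sqrt(pve / ((1 - pve) * S))`.
#'
#' @param alpha Vector of unscaled effect sizes.
#' @param pve Target variance fraction in (0, 1).
#' @return A list with `delta` and `alpha_scaled = delta * alpha`.
#' @export
rescale_to_pve <- function(alpha, pve) {
  s <- sum(alpha^2)
  if (s <= 0) {
    stop_sexmr("effect sizes are all zero; cannot rescale",
               class = "sexmr_domain_error")
  }
  if (pve <= 0 || pve >= 1) {
    stop_sexmr("pve must lie in (0, 1)", class = "sexmr_domain_error")
  }
  delta <- sqrt(pve / ((1 - pve) * s))
  list(delta = delta, alpha_scaled = delta * alpha)
}

# Genetic value with empirically standardized columns, computed as a single
# mat-vec on the raw dosages:  Gs %*% w == G %*% (w/sd) - sum(mu * w / sd).
standardized_genetic_value <- function(G, weights) {
  mom <- .col_moments_cpp(G)
  if (any(mom$sd == 0)) {
    stop_sexmr("monomorphic genotype column; cannot standardize",
               class = "sexmr_domain_error")
  }
  wv <- weights / mom$sd
  as.vector(G %*% wv) - sum(mom$mean * wv)
}

#' Build exposures and the female-specific outcome
#'
#' Exposures are the standardized-genotype genetic values plus standard
#' normal noise; the outcome exists only in the female sample:
#' `y = theta * x_female + eps`, eps standard normal.
#'
#' @param G_male,G_female Dosage matrices from [simulate_genotypes()].
#' @param alpha_male,alpha_female Rescaled effect-size vectors
#'   (`alpha_scaled` from [rescale_to_pve()]).
#' @param theta True causal effect.
#' @return A list with `x_male`, `x_female`, `y_female`.
#' @export
build_phenotypes <- function(G_male, G_female, alpha_male, alpha_female,
                             theta) {
  if (ncol(G_male) != length(alpha_male) ||
      ncol(G_female) != length(alpha_female)) {
    stop_sexmr("genotype/effect dimension mismatch",
               class = "sexmr_domain_error")
  }
  x_male <- standardized_genetic_value(G_male, alpha_male) +
    rnorm(nrow(G_male))
  x_female <- standardized_genetic_value(G_female, alpha_female) +
    rnorm(nrow(G_female))
  y_female <- theta * x_female + rnorm(nrow(G_female))
  list(x_male = x_male, x_female = x_female, y_female = y_female)
}

#' Single-SNP association scan
#'
#' Simple linear regression of the phenotype on each genotype column;
#' returns a [sumstat_table()] with synthetic ids `sim_1, sim_2, ...` and
#' placeholder A/G alleles so downstream harmonization runs unchanged.
#' Zero-variance columns are dropped with a warning.
#'
#' @param phen Phenotype vector.
#' @param G Dosage matrix with `length(phen)` rows.
#' @inheritParams sumstat_table
#' @return A [sumstat_table()] with one row per polymorphic SNP.
#' @export
marginal_gwas <- function(phen, G, trait_label = "trait",
                          stratum = c("combined", "female", "male")) {
  stratum <- match.arg(stratum)
  if (length(phen) != nrow(G)) {
    stop_sexmr("phenotype length does not match genotype rows",
               class = "sexmr_domain_error")
  }
  n <- nrow(G)
  res <- .gwas_kernel_cpp(G, as.numeric(phen))
  ok <- res$sgg > 0
  if (any(!ok)) {
    warning(sum(!ok), " monomorphic SNP(s) dropped from the scan",
            call. = FALSE)
  }
  beta <- res$beta[ok]
  se <- res$se[ok]
  # se = 0 only for an exact linear fit; report the smallest positive p and
  # clamp se to keep the strictly-positive contract
  pvalue <- ifelse(se > 0, 2 * pt(-abs(beta / se), df = n - 2),
                   ifelse(beta == 0, 1, .Machine$double.xmin))
  se <- pmax(se, .Machine$double.xmin)
  df <- data.frame(
    snp = paste0("sim_", which(ok)),
    chr = "1",
    pos = which(ok),
    effect_allele = "A",
    other_allele = "G",
    beta = beta, se = se, pvalue = pvalue, n = n,
    stringsAsFactors = FALSE
  )
  sumstat_table(df, trait_label = trait_label, stratum = stratum)
}

#' Fixed-effects inverse-variance meta-analysis of two strata
#'
#' Per SNP: `beta_c = (beta_f/se_f^2 + beta_m/se_m^2) / (1/se_f^2 +
#' 1/se_m^2)`, `se_c = (1/se_f^2 + 1/se_m^2)^(-1/2)`, p from the normal z.
#'
#' @param female,male [sumstat_table()]s over the same SNP set.
#' @return A [sumstat_table()] with stratum `"combined"`.
#' @export
meta_fixed <- function(female, male) {
  if (!setequal(female$snp, male$snp)) {
    stop_sexmr("female and male tables cover different SNP sets",
               class = "sexmr_data_error")
  }
  mi <- match(female$snp, male$snp)
  wf <- 1 / female$se^2
  wm <- 1 / male$se[mi]^2
  beta_c <- (female$beta * wf + male$beta[mi] * wm) / (wf + wm)
  se_c <- sqrt(1 / (wf + wm))
  z <- beta_c / se_c
  df <- data.frame(
    snp = female$snp, chr = female$chr, pos = female$pos,
    effect_allele = female$effect_allele, other_allele = female$other_allele,
    beta = beta_c, se = se_c, pvalue = 2 * pnorm(-abs(z)),
    n = female$n + male$n[mi],
    stringsAsFactors = FALSE
  )
  sumstat_table(df, trait_label = attr(female, "trait_label"),
                stratum = "combined")
}

#' Select instruments by marginal p-value
#'
#' Keeps SNPs with `pvalue < alpha / m` (strict).  If none pass, the single
#' smallest-p SNP is used instead (first in table order on ties) and the
#' returned set carries `fallback = TRUE`.
#'
#' @param table A [sumstat_table()].
#' @param m Number of tests the threshold is corrected for (typically the
#'   simulated SNP count).
#' @param alpha Numerator of the threshold.
#' @return An [instrument_set()] with attributes `fallback` and
#'   `selection_threshold = alpha / m`.
#' @export
select_ivs <- function(table, m, alpha = 0.05) {
  if (nrow(table) == 0) {
    stop_sexmr("cannot select instruments from an empty table",
               class = "sexmr_domain_error")
  }
  thr <- alpha / m
  hit <- table$pvalue < thr
  fallback <- !any(hit)
  ids <- if (fallback) table$snp[which.min(table$pvalue)] else table$snp[hit]
  out <- instrument_set(ids, source_stratum = attr(table, "stratum") %||% "combined",
                        selection_threshold = thr)
  attr(out, "fallback") <- fallback
  out
}

# Harmonize simulated exposure/outcome tables (identical A/G alleles by
# construction) and run fixed-effects IVW.
sim_ivw <- function(exposure, outcome, ivs) {
  h <- harmonize(exposure, outcome, ivs)
  ivw_fixed(h)
}

#' Run one simulation replicate
#'
#' Composes the full protocol and estimates the causal effect twice: with
#' instruments selected from (and effects taken from) the sex-combined
#' meta-analysed exposure statistics, and with female-specific ones.  Both
#' pairings use the same female outcome statistics, computed on an
#' independent female cohort unless the scenario sets `outcome_overlap`.
#'
#' @param sc A [simulation_scenario()].
#' @return A list of class `replicate_result`: `theta_hat_combined`,
#'   `theta_hat_specific`, `se_combined`, `se_specific`, `k_combined`,
#'   `k_specific`, `fallback_used_combined`, `fallback_used_specific`, `m`.
#' @export
run_replicate <- function(sc) {
  arch <- draw_architecture(sc)
  sc_m <- rescale_to_pve(arch$alpha_male, sc$pve_male)
  sc_f <- rescale_to_pve(arch$alpha_female, sc$pve_female)
  G_male <- simulate_genotypes(sc$n_male, arch$mafs)
  G_female <- simulate_genotypes(sc$n_female, arch$mafs)
  ph <- build_phenotypes(G_male, G_female, sc_m$alpha_scaled,
                         sc_f$alpha_scaled, sc$theta)
  ss_male <- marginal_gwas(ph$x_male, G_male, "exposure", "male")
  ss_female <- marginal_gwas(ph$x_female, G_female, "exposure", "female")
  ss_outcome <- if (sc$outcome_overlap) {
    marginal_gwas(ph$y_female, G_female, "outcome", "female")
  } else {
    G_out <- simulate_genotypes(sc$n_female, arch$mafs)
    x_out <- standardized_genetic_value(G_out, sc_f$alpha_scaled) +
      rnorm(nrow(G_out))
    marginal_gwas(sc$theta * x_out + rnorm(nrow(G_out)), G_out,
                  "outcome", "female")
  }
  ss_combined <- meta_fixed(ss_female, ss_male)

  ivs_c <- select_ivs(ss_combined, arch$m, sc$iv_alpha)
  ivs_f <- select_ivs(ss_female, arch$m, sc$iv_alpha)
  est_c <- sim_ivw(ss_combined, ss_outcome, ivs_c)
  est_f <- sim_ivw(ss_female, ss_outcome, ivs_f)
  structure(list(
    theta_hat_combined = est_c$theta,
    theta_hat_specific = est_f$theta,
    se_combined = est_c$se,
    se_specific = est_f$se,
    k_combined = est_c$k,
    k_specific = est_f$k,
    fallback_used_combined = isTRUE(attr(ivs_c, "fallback")),
    fallback_used_specific = isTRUE(attr(ivs_f, "fallback")),
    m = arch$m
  ), class = "replicate_result")
}

#' Run a full simulation scenario
#'
#' Executes `sc$n_replicates` replicates on independent sub-seeds derived
#' from the scenario seed and summarises the bias of each instrument
#' strategy.
#'
#' @param sc A [simulation_scenario()].
#' @param keep_replicates Attach the per-replicate data.frame.
#' @return A `scenario_summary` list: `mean_bias_combined`,
#'   `mean_bias_specific`, `mc_se_combined`, `mc_se_specific`,
#'   `n_replicates`, `scenario`, and (optionally) `replicates`.
#' @export
run_scenario <- function(sc, keep_replicates = TRUE) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(sc$seed)
  rep_seeds <- sample.int(.Machine$integer.max, sc$n_replicates)
  rows <- lapply(seq_len(sc$n_replicates), function(i) {
    set.seed(rep_seeds[i])
    r <- run_replicate(sc)
    data.frame(replicate = i, seed = rep_seeds[i],
               theta_hat_combined = r$theta_hat_combined,
               theta_hat_specific = r$theta_hat_specific,
               se_combined = r$se_combined, se_specific = r$se_specific,
               k_combined = r$k_combined, k_specific = r$k_specific,
               fallback_used_combined = r$fallback_used_combined,
               fallback_used_specific = r$fallback_used_specific,
               m = r$m)
  })
  reps <- do.call(rbind, rows)
  bias_c <- reps$theta_hat_combined - sc$theta
  bias_s <- reps$theta_hat_specific - sc$theta
  out <- list(
    mean_bias_combined = mean(bias_c),
    mean_bias_specific = mean(bias_s),
    mc_se_combined = sd(bias_c) / sqrt(nrow(reps)),
    mc_se_specific = sd(bias_s) / sqrt(nrow(reps)),
    n_replicates = nrow(reps),
    scenario = sc
  )
  if (keep_replicates) out$replicates <- reps
  structure(out, class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("Simulation scenario: r_g = %.2f, PVE male/female = %.3f/%.3f, theta = %.2f\n",
              sc$r_g, sc$pve_male, sc$pve_female, sc$theta))
  cat(sprintf("  %d replicates, N = %d + %d\n", x$n_replicates, sc$n_male,
              sc$n_female))
  cat(sprintf("  mean bias, sex-combined IVs: %.4f (MC se %.4f)\n",
              x$mean_bias_combined, x$mc_se_combined))
  cat(sprintf("  mean bias, sex-specific IVs: %.4f (MC se %.4f)\n",
              x$mean_bias_specific, x$mc_se_specific))
  invisible(x)
}
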
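# Summary-level synthetic data exercising every pipeline stage.
#
# Unlike the individual-level simulation engine (see run_replicate), this
# generator writes GWAS-style summary-statistic tables directly, planting
# records with known properties: clean instruments, sex-heterogeneous
# instruments with a controlled effect-difference z, outcome-associated
# instruments that must fall to the Bonferroni QC screen, allele-swapped
# and allele-inconsistent outcome records for the harmonizer, and
# instruments absent from the outcome GWAS.  A truth table records every
# planted property so tests can assert pipeline behaviour exactly.

#' Default settings for the synthetic summary-statistics generator
#'
#' @return A named list of generator settings; see
#'   [generate_synthetic_sumstats()].
#' @export
synth_config <- function() {
  list(
    n_clean = 30L,        # well-behaved instruments
    n_het = 8L,           # sex-heterogeneous instruments
    n_outcome_assoc = 2L, # directly outcome-associated (QC casualties)
    n_swapped = 3L,       # outcome rows with swapped alleles
    n_mismatched = 2L,    # outcome rows with inconsistent alleles
    n_absent = 1L,        # instruments missing from the outcome GWAS
    theta = 0.3,          # true causal effect (log-odds per SD)
    n_exposure = 2e5,     # exposure GWAS size per stratum
    n_outcome = 2e4,      # outcome GWAS size; kept well below the exposure
                          # GWAS so clean instruments' causal outcome
                          # signal stays clear of the Bonferroni QC
                          # boundary and the margin guard rarely engages
    z_instrument = c(8, 12), # range of exposure association z scores
    het_z = 8,            # realised female-male difference z for het SNPs
    clean_z_max = 0.9     # |difference z| bound for non-het SNPs
  )
}

random_alleles <- function(k) {
  bases <- c("A", "C", "G", "T")
  t(vapply(seq_len(k), function(i) sample(bases, 2), character(2)))
}

#' Generate synthetic sex-stratified summary statistics with known truth
#'
#' @param config Generator settings; defaults from [synth_config()], with
#'   any supplied elements overriding them.  Unknown setting names are an
#'   error.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param dir Optional directory; when given, the four summary tables, the
#'   instrument list and the truth table are written there as TSV/text.
#' @return A list with `exposure_female`, `exposure_male`,
#'   `exposure_combined`, `outcome` ([sumstat_table()]s), `ivs`
#'   ([instrument_set()] over every planted SNP present in the exposure
#'   tables), `truth` (data.frame: `snp`, `role`, `beta_true_f`,
#'   `beta_true_m`, `het_expected`, `qc_removed_expected`,
#'   `kept_expected`), `theta`, and `paths` when `dir` was given.
#' @export
generate_synthetic_sumstats <- function(config = list(), seed = 1L,
                                        dir = NULL) {
  cfg <- synth_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) {
    stop_sexmr("unknown generator setting(s): ",
               paste(unknown, collapse = ", "),
               class = "sexmr_config_error")
  }
  cfg[names(config)] <- config
  if (cfg$n_clean < 1) {
    stop_sexmr("need at least one clean instrument",
               class = "sexmr_config_error")
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  roles <- rep(c("clean", "het", "outcome_assoc", "swapped", "mismatched",
                 "absent"),
               c(cfg$n_clean, cfg$n_het, cfg$n_outcome_assoc, cfg$n_swapped,
                 cfg$n_mismatched, cfg$n_absent))
  k <- length(roles)
  snp <- sprintf("rs%07d", sample.int(9999999, k))
  alleles <- random_alleles(k)

  se_x <- rep(1 / sqrt(cfg$n_exposure), k)
  se_y <- rep(1 / sqrt(cfg$n_outcome), k)

  # true female effects: strong instruments with random sign
  z_x <- runif(k, cfg$z_instrument[1], cfg$z_instrument[2]) *
    sample(c(-1, 1), k, replace = TRUE)
  beta_true_f <- z_x * se_x
  beta_f <- beta_true_f + rnorm(k) * se_x

  # male effects differ from the female ones by a controlled z
  diff_z <- runif(k, -cfg$clean_z_max, cfg$clean_z_max)
  het <- roles == "het"
  diff_z[het] <- sample(c(-1, 1), sum(het), TRUE) *
    runif(sum(het), cfg$het_z, cfg$het_z + 2)
  beta_m <- beta_f - diff_z * sqrt(2) * se_x
  beta_true_m <- beta_true_f  # shared architecture except the planted shift

  # outcome effects induced through the causal path, with margins away from
  # the Bonferroni QC boundary so planted fates are unambiguous
  beta_y <- cfg$theta * beta_true_f + rnorm(k) * se_y
  z_crit <- qnorm(1 - 0.05 / (2 * k))  # QC boundary at Bonferroni alpha 0.05
  z_y <- beta_y / se_y
  too_close <- abs(z_y) > z_crit - 0.3 & roles != "outcome_assoc"
  beta_y[too_close] <- sign(z_y[too_close]) * (z_crit - 0.5) * se_y[too_close]
  oa <- roles == "outcome_assoc"
  beta_y[oa] <- sign(beta_y[oa] + (beta_y[oa] == 0)) * (z_crit + 7) * se_y[oa]

  mk_table <- function(beta, se, stratum, trait, n) {
    z <- beta / se
    sumstat_table(data.frame(
      snp = snp, chr = "1", pos = seq_len(k) * 1000,
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      beta = beta, se = se, pvalue = 2 * pnorm(-abs(z)), n = n,
      stringsAsFactors = FALSE
    ), trait_label = trait, stratum = stratum)
  }
  exposure_female <- mk_table(beta_f, se_x, "female", "exposure",
                              cfg$n_exposure)
  exposure_male <- mk_table(beta_m, se_x, "male", "exposure", cfg$n_exposure)
  exposure_combined <- meta_fixed(exposure_female, exposure_male)

  outcome <- mk_table(beta_y, se_y, "female", "outcome", cfg$n_outcome)
  out_df <- as.data.frame(outcome)
  swapped <- roles == "swapped"
  out_df$effect_allele[swapped] <- alleles[swapped, 2]
  out_df$other_allele[swapped] <- alleles[swapped, 1]
  out_df$beta[swapped] <- -out_df$beta[swapped]
  mismatched <- roles == "mismatched"
  third_allele <- vapply(which(mismatched), function(i) {
    sample(setdiff(c("A", "C", "G", "T"), alleles[i, ]), 1)
  }, character(1))
  out_df$other_allele[mismatched] <- third_allele
  out_df <- out_df[roles != "absent", , drop = FALSE]
  outcome <- sumstat_table(out_df, trait_label = "outcome",
                           stratum = "female")

  truth <- data.frame(
    snp = snp, role = roles,
    beta_true_f = beta_true_f, beta_true_m = beta_true_m,
    het_expected = het,
    qc_removed_expected = oa,
    kept_expected = roles %in% c("clean", "het", "swapped"),
    stringsAsFactors = FALSE
  )
  ivs <- instrument_set(snp, source_stratum = "female",
                        selection_threshold = 5e-8)

  res <- list(exposure_female = exposure_female,
              exposure_male = exposure_male,
              exposure_combined = exposure_combined,
              outcome = outcome, ivs = ivs, truth = truth,
              theta = cfg$theta)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      exposure_female = file.path(dir, "exposure_female.tsv"),
      exposure_male = file.path(dir, "exposure_male.tsv"),
      exposure_combined = file.path(dir, "exposure_combined.tsv"),
      outcome = file.path(dir, "outcome.tsv"),
      instruments = file.path(dir, "instruments.txt"),
      truth = file.path(dir, "truth.tsv")
    )
    write_sumstats(exposure_female, paths$exposure_female)
    write_sumstats(exposure_male, paths$exposure_male)
    write_sumstats(exposure_combined, paths$exposure_combined)
    write_sumstats(outcome, paths$outcome)
    writeLines(as.character(ivs), paths$instruments)
    write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    res$paths <- paths
  }
  res
}
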
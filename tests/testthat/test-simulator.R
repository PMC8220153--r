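# The individual-level simulation engine: architecture draws, genotypes,
# PVE rescaling, phenotypes, GWAS scan, meta-analysis, instrument
# selection, and the replicate/scenario drivers.

test_that("architecture draws honour r_g and are reproducible", {
  sc1 <- simulation_scenario(r_g = 1, pve_male = 0.01, pve_female = 0.03)
  withr::with_seed(1, {
    arch <- draw_architecture(sc1)
    expect_equal(arch$alpha_male, arch$alpha_female)
    expect_true(arch$m >= 50 && arch$m <= 150)
    expect_true(all(arch$mafs > 0.01 & arch$mafs < 0.5))
  })

  # large-m override: independent effects decorrelate
  sc0 <- simulation_scenario(r_g = 0, m_range = c(10000L, 10000L))
  withr::with_seed(2, {
    arch0 <- draw_architecture(sc0)
    expect_lt(abs(cor(arch0$alpha_male, arch0$alpha_female)), 0.03)
  })

  a <- withr::with_seed(3, draw_architecture(sc1))
  b <- withr::with_seed(3, draw_architecture(sc1))
  expect_identical(a, b)
})

test_that("genotypes are HWE binomial draws in linkage equilibrium", {
  withr::with_seed(5, {
    G <- simulate_genotypes(1e5, c(0.5, 0.01, 0.3))
    expect_equal(dim(G), c(1e5, 3))
    expect_true(all(G %in% c(0, 1, 2)))
    expect_equal(mean(G[, 1]), 1.0, tolerance = 0.02)
    expect_equal(var(G[, 2]), 2 * 0.01 * 0.99, tolerance = 0.15)
    expect_lt(abs(cor(G[, 1], G[, 3])), 0.02)
    # empirical allele frequency within 4 binomial SEs of the target
    for (j in 1:3) {
      maf <- c(0.5, 0.01, 0.3)[j]
      expect_lt(abs(mean(G[, j]) / 2 - maf),
                4 * sqrt(maf * (1 - maf) / (2 * 1e5)))
    }
  })
  expect_error(simulate_genotypes(100, c(0.2, 0.6)),
               class = "sexmr_domain_error")
  expect_error(simulate_genotypes(100, 0), class = "sexmr_domain_error")
})

test_that("PVE rescaling inverts the variance-explained identity exactly", {
  expect_equal(rescale_to_pve(1, 0.5)$delta, 1)
  r <- rescale_to_pve(c(1, 1), 0.03)
  expect_equal(r$delta, sqrt(0.03 / (0.97 * 2)), tolerance = 1e-12)
  expect_equal(r$delta, 0.12435, tolerance = 1e-4)

  # round trip: plug the scaled effects back into the identity
  withr::with_seed(7, {
    for (pve in c(0.01, 0.03, 0.2)) {
      alpha <- rnorm(60)
      sc <- rescale_to_pve(alpha, pve)
      s2 <- sum(sc$alpha_scaled^2)
      expect_equal(s2 / (s2 + 1), pve, tolerance = 1e-14)
    }
  })
  expect_error(rescale_to_pve(rep(0, 5), 0.1), class = "sexmr_domain_error")
  expect_error(rescale_to_pve(1, 1), class = "sexmr_domain_error")
})

test_that("phenotypes carry the target genetic variance and causal link", {
  withr::with_seed(9, {
    m <- 80
    mafs <- runif(m, 0.05, 0.5)
    a_m <- rescale_to_pve(rnorm(m), 0.01)$alpha_scaled
    a_f <- rescale_to_pve(rnorm(m), 0.03)$alpha_scaled
    G_m <- simulate_genotypes(1e5, mafs)
    G_f <- simulate_genotypes(1e5, mafs)
    ph <- build_phenotypes(G_m, G_f, a_m, a_f, theta = 0.5)

    # independent recomputation of the genetic value via scale()
    gv <- as.vector(scale(G_f) %*% a_f)
    expect_equal(var(gv) / var(ph$x_female), 0.03, tolerance = 0.005)
    # variance decomposition of the outcome
    expect_equal(var(ph$y_female), 0.25 * var(ph$x_female) + 1,
                 tolerance = 0.02)

    # null causal effect: outcome decouples from the exposure
    ph0 <- build_phenotypes(G_m, G_f, a_m, a_f, theta = 0)
    expect_lt(abs(cor(ph0$x_female, ph0$y_female)), 0.01)
  })
  expect_error(build_phenotypes(matrix(0, 5, 2), matrix(0, 5, 2),
                                c(1, 2, 3), c(1, 2), 0.1),
               class = "sexmr_domain_error")
})

test_that("the GWAS scan matches per-SNP lm() fits", {
  withr::with_seed(11, {
    n <- 500; m <- 5
    G <- simulate_genotypes(n, runif(m, 0.1, 0.5))
    phen <- 0.2 * G[, 2] + rnorm(n)
    tab <- marginal_gwas(phen, G, "x", "female")
    expect_equal(nrow(tab), m)
    for (j in 1:m) {
      fit <- summary(lm(phen ~ G[, j]))$coefficients
      expect_equal(tab$beta[j], fit[2, "Estimate"], tolerance = 1e-10)
      expect_equal(tab$se[j], fit[2, "Std. Error"], tolerance = 1e-10)
      expect_equal(tab$pvalue[j], fit[2, "Pr(>|t|)"], tolerance = 1e-8)
    }
  })
})

test_that("the GWAS scan recovers effects, is calibrated, and drops monomorphic SNPs", {
  withr::with_seed(13, {
    n <- 2e4
    G <- simulate_genotypes(n, runif(50, 0.1, 0.5))
    phen <- 0.2 * G[, 7] + rnorm(n)
    tab <- marginal_gwas(phen, G)
    expect_lt(abs(tab$beta[7] - 0.2), 3 * tab$se[7])

    # a column copied into the phenotype: beta 1, se ~ 0
    self <- marginal_gwas(as.numeric(G[, 1]), G)
    expect_equal(self$beta[1], 1, tolerance = 1e-12)
    expect_lt(self$se[1], 1e-6)

    # type-I calibration on an independent phenotype
    G2 <- simulate_genotypes(2000, runif(1000, 0.1, 0.5))
    tab2 <- marginal_gwas(rnorm(2000), G2)
    expect_lt(abs(mean(tab2$pvalue < 0.05) - 0.05), 0.02)

    # monomorphic column dropped with a warning
    G3 <- cbind(G[, 1:2], 0)
    expect_warning(tab3 <- marginal_gwas(phen, G3), "monomorphic")
    expect_equal(nrow(tab3), 2)
  })
})

test_that("fixed-effects meta-analysis matches hand arithmetic and metafor", {
  ids <- c("rs1", "rs2")
  f <- make_table(ids, c(0.1, 0.05), c(0.01, 0.02), stratum = "female")
  m <- make_table(ids, c(0.04, 0.05), c(0.02, 0.02), stratum = "male")
  out <- meta_fixed(f, m)
  expect_equal(out$beta[1], 0.088, tolerance = 1e-12)
  expect_equal(out$beta[2], 0.05, tolerance = 1e-12)
  expect_equal(out$se[2], 0.02 / sqrt(2), tolerance = 1e-12)
  expect_identical(attr(out, "stratum"), "combined")

  # dominance in the weak-study limit
  f2 <- make_table("rs1", 0.1, 0.01, stratum = "female")
  m2 <- make_table("rs1", 0.9, 1e6, stratum = "male")
  expect_equal(meta_fixed(f2, m2)$beta, 0.1, tolerance = 1e-6)

  # independent oracle: metafor's fixed-effects model per SNP
  withr::with_seed(15, {
    k <- 6
    ids <- paste0("rs", 1:k)
    bf <- rnorm(k, 0, 0.05); bm <- rnorm(k, 0, 0.05)
    sf <- runif(k, 0.005, 0.03); sm <- runif(k, 0.005, 0.03)
    out2 <- meta_fixed(make_table(ids, bf, sf, stratum = "female"),
                       make_table(ids, bm, sm, stratum = "male"))
    for (j in 1:k) {
      fit <- metafor::rma(yi = c(bf[j], bm[j]), sei = c(sf[j], sm[j]),
                          method = "FE")
      expect_equal(out2$beta[j], as.numeric(fit$beta), tolerance = 1e-10)
      expect_equal(out2$se[j], fit$se, tolerance = 1e-10)
    }
    # se_c strictly below either stratum's
    expect_true(all(out2$se < pmin(sf, sm)))
  })

  expect_error(meta_fixed(f, make_table("rsX", 0.1, 0.01, stratum = "male")),
               class = "sexmr_data_error")
})

test_that("instrument selection applies the strict threshold with min-P fallback", {
  tab <- make_table(paste0("rs", 1:5), rep(0.1, 5), rep(0.01, 5),
                    pvalue = rep(0.5, 5))
  sel <- select_ivs(tab, m = 100)
  expect_length(sel, 1)
  expect_equal(as.character(sel), "rs1")   # first of the tied minima
  expect_true(attr(sel, "fallback"))

  pv <- c(1e-6, 0.3, 2e-4, 4.9e-4, 0.051, 1e-5, 3e-4, 0.2, 1e-4, 4e-4)
  tab2 <- make_table(paste0("rs", 1:10), rep(0.1, 10), rep(0.01, 10),
                     pvalue = pv)
  sel2 <- select_ivs(tab2, m = 100)
  expect_length(sel2, 7)
  expect_false(attr(sel2, "fallback"))

  # boundary: p exactly equal to the threshold is excluded
  tab3 <- make_table(c("rs1", "rs2"), c(0.1, 0.1), c(0.01, 0.01),
                     pvalue = c(5e-4, 1e-6))
  sel3 <- select_ivs(tab3, m = 100)
  expect_equal(as.character(sel3), "rs2")
})

test_that("replicates are deterministic and concordant when sexes are identical", {
  sc <- simulation_scenario(n_male = 5000, n_female = 5000,
                            m_range = c(20L, 30L), r_g = 1,
                            pve_male = 0.05, pve_female = 0.05,
                            theta = 0.3, seed = 5)
  r1 <- withr::with_seed(17, run_replicate(sc))
  r2 <- withr::with_seed(17, run_replicate(sc))
  expect_identical(r1, r2)

  diffs <- withr::with_seed(19, {
    vapply(1:10, function(i) {
      r <- run_replicate(sc)
      r$theta_hat_combined - r$theta_hat_specific
    }, numeric(1))
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.02)
})

test_that("both instrument strategies are calibrated under a null causal effect", {
  sc <- simulation_scenario(n_male = 5000, n_female = 5000,
                            m_range = c(20L, 30L), r_g = 0.5,
                            pve_male = 0.02, pve_female = 0.02,
                            theta = 0, n_replicates = 200, seed = 23)
  summ <- run_scenario(sc)
  reps <- summ$replicates
  cov_c <- mean(abs(reps$theta_hat_combined) < 2 * reps$se_combined)
  cov_s <- mean(abs(reps$theta_hat_specific) < 2 * reps$se_specific)
  expect_gte(cov_c, 0.93)
  expect_gte(cov_s, 0.93)
  expect_equal(summ$mc_se_combined,
               sd(reps$theta_hat_combined) / sqrt(200), tolerance = 1e-12)
})

test_that("scenario runs are reproducible from the scenario seed", {
  sc <- simulation_scenario(n_male = 3000, n_female = 3000,
                            m_range = c(15L, 20L), r_g = 0.3,
                            pve_male = 0.02, pve_female = 0.04,
                            theta = 0.3, n_replicates = 3, seed = 99)
  s1 <- run_scenario(sc)
  s2 <- run_scenario(sc)
  expect_identical(s1$replicates, s2$replicates)
})

test_that("the synthetic generator's truth table governs pipeline behaviour", {
  gen <- generate_synthetic_sumstats(seed = 31)
  cfg <- synth_config()

  # harmonization excludes exactly the mismatched and absent records
  h <- suppressMessages(harmonize(gen$exposure_female, gen$outcome, gen$ivs))
  excl <- attr(h, "exclusions")
  expect_setequal(excl$allele_inconsistent,
                  gen$truth$snp[gen$truth$role == "mismatched"])
  expect_setequal(excl$missing_from_outcome,
                  gen$truth$snp[gen$truth$role == "absent"])

  # QC removes exactly the planted outcome-associated instruments
  h2 <- suppressMessages(qc_filter_outcome_associated(h))
  expect_setequal(setdiff(h$snp, h2$snp),
                  gen$truth$snp[gen$truth$qc_removed_expected])
  expect_setequal(h2$snp, gen$truth$snp[gen$truth$kept_expected])

  # swapped outcome records come back sign-corrected: IVW recovers theta
  est <- ivw_fixed(h2)
  expect_lt(abs(est$theta - gen$theta), 2 * est$se)

  # heterogeneity screen flags exactly the planted discordant instruments
  scr <- screen_heterogeneity(gen$exposure_female, gen$exposure_male,
                              gen$ivs)
  expect_setequal(scr$snp[scr$flagged],
                  gen$truth$snp[gen$truth$het_expected])

  # determinism and config validation
  gen2 <- generate_synthetic_sumstats(seed = 31)
  expect_identical(as.data.frame(gen$exposure_female),
                   as.data.frame(gen2$exposure_female))
  expect_error(generate_synthetic_sumstats(list(bogus = 1)),
               class = "sexmr_config_error")
})

test_that("the generator round-trips through disk and a 17-of-48 screen", {
  dir <- withr::local_tempdir()
  gen <- generate_synthetic_sumstats(
    list(n_clean = 31, n_het = 17, n_outcome_assoc = 0, n_swapped = 0,
         n_mismatched = 0, n_absent = 0),
    seed = 37, dir = dir
  )
  expect_true(all(file.exists(unlist(gen$paths))))
  back <- read_sumstats(gen$paths$exposure_female, trait_label = "exposure",
                        stratum = "female")
  expect_equal(as.data.frame(back), as.data.frame(gen$exposure_female))

  ivs <- read_instruments(gen$paths$instruments)
  scr <- screen_heterogeneity(back,
                              read_sumstats(gen$paths$exposure_male,
                                            stratum = "male"), ivs)
  expect_equal(sum(scr$flagged), 17)
})
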
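# sexmr

Sex-specific two-sample Mendelian randomization (MR) with instrument
heterogeneity diagnostics.

## Why

Two-sample MR estimates the causal effect of an exposure on an outcome
from GWAS summary statistics, using SNPs as instrumental variables.  When
the outcome is sex-specific (breast cancer, prostate cancer), instrument
effect sizes should come from the matching sex stratum — yet sex-combined
effects are commonly used, which silently assumes male and female SNP
effects are identical.  For anthropometric exposures they are not, at a
meaningful fraction of loci.  If the exposure's variance explained (PVE)
by the instruments differs between sexes, the sex-combined marginal
effects are systematically mis-scaled relative to the sex-specific effects
that generate the outcome signal, and the inverse-variance weighted (IVW)
estimate

θ̂ = Σᵢ var(â_iy)⁻¹ â_iy â_ix / Σᵢ var(â_iy)⁻¹ â_ix² ,  var(θ̂) = 1 / Σᵢ var(â_iy)⁻¹ â_ix²

is biased upward when the outcome sex's PVE exceeds the other sex's (and
downward when reversed).  `sexmr` is for epidemiologists and statistical
geneticists who want to diagnose, quantify and avoid that bias.

## What it does

* **I/O and QC** — read/write tab-separated GWAS summary statistics with
  header-dialect mapping; harmonize exposure and outcome records onto a
  shared effect allele (sign-flipping swapped alleles, excluding
  inconsistent ones); Bonferroni screen removing instruments directly
  associated with the outcome.
* **Sex-heterogeneity diagnostics** — per-instrument two-group Cochran's
  Q = (β̂_f − β̂_m)²/(se_f² + se_m²) with I², Bonferroni-corrected
  flagging, and the Pearson correlation of instrument effects between
  strata with tests against r = 0 and r = 1 (jackknife SE).
* **Estimators** — fixed- and multiplicative random-effects IVW,
  weighted median (bootstrap SE), profile maximum likelihood, MR-Egger,
  an MR-PRESSO-style global/outlier test, leave-one-out.
* **Formal comparison** — the u statistic
  u = (θ̂_comb − θ̂_spec)/√(se²_comb + se²_spec − 2ρ se_comb se_spec)
  with ρ estimated by a leave-one-instrument-out jackknife over the union
  of the two instrument sets.
* **Power** — closed-form binary-outcome MR power
  Φ(√(N·PVE·p(1−p))·|ln OR| − z_{1−α/2}).
* **Simulation engine** — the full individual-level experiment
  quantifying sex-combined-instrument bias (HWE genotypes, bivariate
  per-sex effects with correlation r_g, PVE rescaling, per-sex GWAS,
  fixed-effects meta-analysis, P < 0.05/m selection, IVW), plus a
  summary-level synthetic-data generator with a planted truth record.

## Worked example

```r
library(sexmr)

# Is this waist-circumference instrument sex-heterogeneous?
cochran_q_sex(beta_f = -0.014, se_f = 0.009,
              beta_m = 0.052, se_m = 0.010, snp_id = "rs17472426")
#>          snp       q      pvalue       i2
#> 1 rs17472426 24.0663 9.30751e-07 95.84481

# Power of an MR analysis on a 228,951-sample case-control outcome GWAS
mr_power_binary(228951, case_fraction = 122977/228951,
                or_per_sd = 0.845, pve = 0.0151)   # 0.999

# End-to-end on synthetic summary statistics with known truth
gen <- generate_synthetic_sumstats(seed = 42)
h <- harmonize(gen$exposure_female, gen$outcome, gen$ivs)
h <- qc_filter_outcome_associated(h)
ivw_fixed(h)
#> MR estimate [ivw_fixed], k = 41 instruments
#>   theta = 0.2901 (se 0.0494), 95% CI [0.1933, 0.3869], p = 4.32e-09
#>   OR per SD = 1.337 (95% CI 1.213-1.472)
#>   between-instrument Q = 37.85 on 40 df

compare_pipeline(gen$exposure_combined, gen$exposure_female, gen$outcome,
                 gen$ivs, gen$ivs)
#> Comparison of causal estimates (H0: equal)
#>   theta_combined = 0.2787 (se 0.0488), theta_specific = 0.2901 (se 0.0494)
#>   rho = 0.958, u = -0.803, p = 0.422
```

The generator planted a true causal effect of 0.3; IVW recovers 0.290
(0.194–0.387) after harmonization dropped 3 defective records and QC
removed the 2 planted outcome-associated instruments.  Here female and
combined instruments share one architecture, so the u test correctly
finds no discrepancy (p = 0.42).

Simulating the bias from sex-combined instruments (reduced scale shown;
the full study conditions are the defaults):

```r
sc <- simulation_scenario(n_male = 2e4, n_female = 2e4, r_g = 0.1,
                          pve_male = 0.01, pve_female = 0.03,
                          theta = 0.5, n_replicates = 20, seed = 1)
run_scenario(sc)
```

Config-driven commands (`cmd_het`, `cmd_mr`, `cmd_compare`,
`cmd_simulate`, `cmd_power`, `cmd_synth`) wrap these stages with YAML
configs and TSV outputs; `inst/cli/sexmr.R` is a thin Rscript dispatcher
over them.

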
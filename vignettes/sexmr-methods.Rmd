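---
title: "Sex-specific two-sample Mendelian randomization with sexmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific two-sample Mendelian randomization with sexmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexmr)
```

## The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from GWAS summary statistics alone, using genetic
variants as instrumental variables (IVs).  When the outcome is
sex-specific — breast cancer, prostate cancer — the exposure's instruments
should in principle come from the matching sex stratum.  In practice many
studies use sex-combined instrument effects, implicitly assuming that SNP
effects on the exposure are identical in males and females.  For
anthropometric traits that assumption demonstrably fails for a subset of
loci, and the mismatch biases the causal estimate: if the exposure's
variance explained (PVE) differs between sexes, the sex-combined marginal
effects are systematically too small or too large relative to the
sex-specific effects that actually generate the outcome associations, and
the ratio-based causal estimate inherits the distortion.

`sexmr` provides the full workflow: diagnosing per-instrument sex
heterogeneity, estimating causal effects from harmonized summary
statistics, formally comparing sex-combined with sex-specific estimates,
computing power, and simulating the bias mechanism at the individual
level.

## Models and statistics

### Per-instrument sex heterogeneity

For one SNP with sex-specific estimates $(\hat\beta_f, se_f)$ and
$(\hat\beta_m, se_m)$, the two-group Cochran statistic reduces to the
squared $z$ of the difference,

$$Q = \frac{(\hat\beta_f - \hat\beta_m)^2}{se_f^2 + se_m^2}
  \;\sim\; \chi^2_1 \text{ under } H_0,$$

with $I^2 = \max(0, (Q-1)/Q) \times 100$ as the conventional
heterogeneity percentage.  Across an instrument set the p-values are
Bonferroni-corrected over the number of instruments tested
(`screen_heterogeneity()`).  Marginal genetic sharing between strata is
summarized by the Pearson correlation of the two effect vectors
(`pearson_effect_correlation()`); the null $r = 1$ is assessed with a
Wald statistic whose standard error is the leave-one-out jackknife SE of
$r$ — Fisher's $z$ is undefined at $r = 1$, and the literature this
workflow follows does not specify a construction, so the jackknife choice
is documented in the output rather than inferred.

### Causal estimation

With $k$ harmonized instruments carrying exposure effects
$\hat a_{ix}$ and outcome effects $\hat a_{iy}$ with variances
$\mathrm{var}(\hat a_{iy})$, the fixed-effects inverse-variance weighted
(IVW) estimator is

$$\hat\theta =
  \frac{\sum_i \mathrm{var}(\hat a_{iy})^{-1}\hat a_{iy}\hat a_{ix}}
       {\sum_i \mathrm{var}(\hat a_{iy})^{-1}\hat a_{ix}^2},
  \qquad
  \mathrm{var}(\hat\theta) =
  \frac{1}{\sum_i \mathrm{var}(\hat a_{iy})^{-1}\hat a_{ix}^2}.$$

Weights deliberately use only the outcome variance (first-order weights,
as printed in the source equations); exposure standard errors are carried
in the data structure but do not enter IVW.  For $k = 1$ the estimator is
the plain ratio $\hat a_y/\hat a_x$.  The random-effects variant keeps
the point estimate and multiplies the SE by
$\max\!\left(1, \sqrt{Q_{IV}/(k-1)}\right)$, the multiplicative
over-dispersion correction, so homogeneous instrument sets are never
rewarded with narrower intervals.

Sensitivity methods:

* **Weighted median** — the weight-interpolated 50th percentile of the
  per-instrument ratios with weights $(\hat a_{ix}/se_{iy})^2$;
  consistent when valid instruments carry half the weight.  Its SE comes
  from a seeded parametric bootstrap (default 1000 draws) perturbing both
  exposure and outcome effects, because the method's literature does not
  fix an analytic SE.
* **Maximum likelihood** — the joint normal measurement-error model
  $\hat a_{ix}\sim N(\xi_i, se_{ix}^2)$,
  $\hat a_{iy}\sim N(\theta\xi_i, se_{iy}^2)$, with the latent
  $\xi_i$ profiled out analytically; the resulting one-dimensional
  profile likelihood is maximised by BFGS from the IVW start and the SE
  taken from the observed information at the optimum.
* **MR-Egger** — WLS of outcome on exposure effects with intercept
  (weights $se_{iy}^{-2}$); instruments are re-signed to
  $\hat a_{ix}\ge 0$ first because Egger regression is not
  orientation-invariant and no convention is universal; the one used is
  stated in the output.
* **MR-PRESSO-style outlier test** — observed
  $RSS = \sum_i(\hat a_{iy}-\hat\theta_{(-i)}\hat a_{ix})^2$ with
  leave-one-out IVW estimates, compared against a parametric null in
  which outcome effects are redrawn from
  $N(\hat\theta_{(-i)}\hat a_{ix}, se_{iy}^2)$ and the leave-one-out
  estimates recomputed per simulated dataset; per-instrument outlier
  p-values are Bonferroni-corrected.  The companion distortion test is
  out of scope.
* **Leave-one-out** — the estimate recomputed $k$ times with one
  instrument removed.

P-values are two-sided normal throughout, matching the
$\hat\theta \mp 1.96\,se$ interval convention of the workflow.

### Comparing sex-combined and sex-specific estimates

The two estimates share the outcome GWAS and usually many instruments,
so they are strongly correlated; a naive two-sample $z$ test would be
badly conservative.  The comparison statistic is

$$u = \frac{\hat\theta_{comb} - \hat\theta_{spec}}
  {\sqrt{se_{comb}^2 + se_{spec}^2
    - 2\rho\, se_{comb}\, se_{spec}}},$$

asymptotically standard normal under equality.  $\rho$ is estimated by a
leave-one-instrument-out jackknife: iterating over the union of the two
instrument sets, each estimate is recomputed without the left-out
instrument when it belongs to that estimate's set (and held at its
full-set value otherwise); $\rho$ is the Pearson correlation of the
paired series.  Instruments unique to one set therefore contribute pairs
in which the other side does not move — the union convention follows the
source procedure, and an intersection-only mode is available
(`intersection_only = TRUE`).  $\rho$ is clamped to $[-1,1]$ after
floating-point computation, with clamping logged.  When
$\rho \approx 1$ with equal SEs the denominator can vanish; this is
reported as a degenerate comparison rather than an infinite statistic.

### Power

For a binary outcome, with $b = |\ln OR|$ per SD of exposure, outcome
GWAS size $N$ with case fraction $p$, and instruments explaining a
fraction $PVE$ of exposure variance,

$$\text{power} = \Phi\!\left(\sqrt{N \cdot PVE \cdot p(1-p)}\; b
  - z_{1-\alpha/2}\right).$$

This closed form reproduces the published power values this workflow is
validated against (99.9, 2.8 and 93.6 percent) to the printed decimal;
it is a normal approximation whose value at $OR = 1$ is
$\Phi(-z_{1-\alpha/2})$ (0.025 at $\alpha = 0.05$), a documented floor
rather than exactly $\alpha$.  The instrument count enters only through
PVE, matching the interface of the widely used online calculator.

## The simulation engine

`run_scenario()` implements the bias experiment.  Per replicate:

1. $m \sim U\{50..150\}$ SNPs with MAF $\sim U(0.01, 0.50)$; per-sex
   effect sizes $(\alpha_{1j}, \alpha_{2j})$ drawn from a bivariate
   normal with unit variances and correlation $r_g$.
2. Effects rescaled so the exposure's genetic variance hits the target
   PVE: with standardized genotype columns the identity
   $PVE = \delta^2\sum_j\alpha_j^2 / (\delta^2\sum_j\alpha_j^2 + 1)$
   inverts exactly to
   $\delta = \sqrt{PVE/((1-PVE)\sum_j \alpha_j^2)}$.
3. HWE genotypes (Binomial(2, MAF), linkage equilibrium) for $N$ males
   and $N$ females; exposures are the standardized-genotype genetic
   values plus unit normal noise; the female-specific outcome is
   $y = \theta x_{female} + \varepsilon$.
4. Single-SNP regressions give sex-specific exposure summary statistics;
   the sex-combined statistics are their fixed-effects inverse-variance
   meta-analysis.
5. Instruments are selected at $P < 0.05/m$ (strict; if none pass, the
   single minimum-$P$ SNP is used and flagged), separately on the
   combined and the female statistics.
6. Fixed-effects IVW pairs each exposure table with the female outcome
   statistics; the scenario summary reports
   $\mathrm{mean}(\hat\theta - \theta)$ for both instrument strategies
   with Monte Carlo SEs.

### Design choices that were genuinely open

**Genotype standardization.**  The PVE identity in step 2 is exact only
if genotype columns have unit variance, so columns are empirically
standardized when phenotypes are formed.  (GWAS regressions in step 4 run
on the raw dosages, as real GWAS do; MR ratios are invariant to per-SNP
genotype scaling.)  A raw-dosage phenotype mode was examined and rejected:
without standardization the realized PVE is deflated by the average
dosage variance ($2\,\mathrm{MAF}(1-\mathrm{MAF}) \approx 0.34$ under the
MAF distribution used), so nominal PVEs of 1%/3% would actually simulate
0.34%/1.0%.

**Outcome cohort overlap.**  By default the outcome GWAS is computed on
an *independent* female cohort drawn from the same architecture
(`outcome_overlap = FALSE`).  This is the defining condition of
two-sample MR — non-overlapping exposure and outcome samples — and it is
what the workflow's validated bias values reflect.  The alternative
(`outcome_overlap = TRUE`), regressing the outcome on the exposure
cohort's own genotypes, couples the sampling errors of the exposure and
outcome effects; with no confounding that coupling happens to cancel the
winner's-curse attenuation, so sex-specific estimates become exactly
unbiased, but the sex-combined bias inflates by roughly 0.02–0.03 at
$\theta = 0.5$ and no longer matches the validated values.  Both designs
are implemented; the default follows the two-sample assumption.

**Consequence to note.**  Under the two-sample default, the sex-specific
strategy shows a small negative bias ($\approx -0.017$ at
$\theta = 0.5$, i.e. ~3.5%) from winner's curse: instruments are selected
and their effect sizes taken from the same exposure GWAS.  This is a real
property of two-sample MR pipelines, not an artifact; "approximately
unbiased" is the right reading of the sex-specific strategy, not "exactly
unbiased".

**Replicates and seeding.**  The replicate count of the original
experiment is not published; 200 replicates per scenario is the default,
giving Monte Carlo SEs of ~0.003 on the bias at $\theta = 0.5$.  Each
scenario seed spawns per-replicate sub-seeds, so any replicate can be
reproduced in isolation.

**Problem sizes in the test suite.**  Full-scale checks (the four-point
$r_g$ grid at $N = 10^5$ per sex, 200 replicates) run once in the
acceptance tests and in `scripts/acceptance.R`.  Unit and property tests
exercise the same machinery at reduced scale ($N$ = 2,000–100,000, small
$m$) chosen so each check's Monte Carlo error is far below its assertion
margin.

## The summary-level synthetic generator

`generate_synthetic_sumstats()` writes GWAS-shaped summary tables with a
known truth record, planting: clean instruments; sex-heterogeneous
instruments with a controlled realised difference $z$ (default 8, safely
beyond any Bonferroni threshold at the default set size); directly
outcome-associated instruments (at 7 z-units beyond the QC boundary);
allele-swapped and allele-inconsistent outcome records; and instruments
missing from the outcome GWAS.  Two deliberate margins make the truth
unambiguous: the non-heterogeneous instruments' difference $z$ is capped
at 0.9, and clean instruments' outcome associations are kept clear of
the Bonferroni QC boundary — the outcome GWAS is smaller than the
exposure GWAS (default 20,000 vs 200,000) so the causal path alone
rarely pushes an instrument near significance, and a guard nudges the
rare boundary case inward.  The guard is one-sided, so exaggerated
causal-path draws are truncated slightly; at the defaults this costs the
IVW estimate under 1% of $\theta$, well inside every assertion margin.
What the generator does *not* emulate: linkage disequilibrium between
instruments, pleiotropy, MAF-dependent effect sizes, binary-outcome
liability scales.  Tests passing on this generator therefore validate
pipeline logic — harmonization, QC, screening, estimation — not
robustness to those real-data features.

## Degenerate inputs and numerical conventions

* Standard errors must be strictly positive; p-values are clamped to
  the open unit interval when regression tails underflow.
* Allele comparison is case-insensitive; only single-nucleotide alleles
  are accepted (indel rows are dropped at parse time with a warning).
  Palindromic A/T and C/G SNPs are retained when alleles match exactly
  (`drop_palindromic = TRUE` for the stricter behaviour), since the
  summary tables carry no strand information to resolve them.
* The Bonferroni denominator of the outcome-association QC rule is the
  number of instruments entering the filter (post-harmonization); with
  `alpha = 0` the filter is a no-op, which is also the recommended
  setting for simulated data with a real causal effect and no
  pleiotropy, where the rule would only discard the strongest valid
  instruments.
* Instrument selection uses a strict inequality at $P = 0.05/m$; ties at
  the minimum p fall back to the first SNP in table order, and the
  fallback is flagged so its frequency is auditable.
* The maximum-likelihood optimiser reports non-convergence as an error
  carrying the optimiser diagnostics rather than returning a value.

## Known limitations

* Genome-wide genetic correlation (LD-score regression) is out of scope;
  the effect correlation here is over instruments only and measures
  marginal, not global, sharing.
* No LD clumping or proxy lookup: instrument lists are inputs.
* The power formula covers binary outcomes only.
* Real-data results from consortium GWAS downloads are not reproduced
  here; the pipeline is validated end-to-end on generator output
  emulating their structure.
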
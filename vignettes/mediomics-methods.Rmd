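---
title: "Methods: high-dimensional mediation from BMI to breast density through the circulating metabolome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-dimensional mediation from BMI to breast density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mediomics)
```

## The scientific question

Early-life body mass index is inversely associated with mammographic breast
density in premenopausal women, and both are linked to breast-cancer risk. One
candidate explanation is metabolic: adiposity reshapes the circulating
metabolome and lipidome, and some of those molecules may sit on the causal
path to breast tissue composition. `mediomics` implements the statistical
machinery for asking that question at omics scale: given a BMI exposure
(recalled BMI at age 10 or 18, kg/m²), a panel of hundreds of metabolites or
lipid species, and volumetric density outcomes (VPD, DV, NDV from volumetric
mammography, analysed as log10 values), which features mediate the
exposure–outcome association, and how much of the total effect do they carry?

## The model

Everything rests on three linear structural equations. With exposure $B$,
covariates $Z$, and mediators $M_k$ ($k = 1, \dots, p$):

$$Y = c^* + B\gamma^* + Z\delta_y^* + \varepsilon_1$$
$$M_k = c_k + B\alpha_k + Z\delta_k + e_k$$
$$Y = c + B\gamma + \sum_k M_k\beta_k + Z\delta_y + \varepsilon_2$$

$\gamma^*$ is the total effect, $\gamma$ the direct effect, $\alpha_k\beta_k$
the indirect effect through mediator $k$, and
$100\,\alpha_k\beta_k/\gamma^*$ the percent of the total effect mediated
(negative under inconsistent mediation — an indirect path opposing the total
effect). When every mediator is included unpenalized and the covariate sets
match, OLS satisfies $\hat\gamma^* - \hat\gamma = \sum_k \hat\alpha_k\hat\beta_k$
*exactly*; the test suite asserts this identity to 1e-10, which pins down the
bookkeeping conventions (mediators standardized, exposure on its natural
kg/m² scale) against silent scale bugs.

With $p \approx 800 >$ tractable, the engine follows the established
high-dimensional mediation recipe:

1. **Sure independence screening.** Each feature is ranked by the absolute
   t-statistic of its coefficient in `outcome ~ mediator + exposure +
   covariates`; the top $d = \lceil 2n/\log n \rceil$ survive (214 at
   $n = 700$). The screening statistic is exposure-adjusted because the
   stated goal is the mediator–outcome partial association given confounders;
   a marginal correlation variant would keep features that merely proxy the
   exposure.
2. **MCP selection.** Penalized least squares with the minimax concave
   penalty on mediator coefficients only (exposure and covariates always stay
   in). Coordinate descent in covariance form, mediator columns scaled to
   $x'x/n = 1$, convergence when no coefficient moves more than `tol = 1e-7`
   in a full sweep. $\gamma_{\mathrm{MCP}} = 3$ (the standard concavity
   default; values near 1 approach best-subset and destabilise the path).
   $\lambda$ is chosen by BIC over a 100-point log-spaced grid from
   $\lambda_{\max}$ (smallest $\lambda$ with empty support, computed in
   closed form) down to $0.01\lambda_{\max}$; BIC rather than
   cross-validation keeps the procedure deterministic, which the whole
   pipeline is — the only randomness anywhere is in simulation seeds.
3. **Joint significance.** For each selected mediator,
   $p_{\mathrm{joint}} = \max(p_\alpha, p_\beta)$, with $\beta_k$ from one
   unpenalized refit on all selected mediators and $\alpha_k$ from equation 2.
   The raw joint p is Bonferroni-scaled by the support size and reported as
   the "FDR p-value", matching the naming convention of the method this
   reimplements (the label conflates FWER and FDR; a Benjamini–Hochberg
   alternative sits behind `adjust = "BH"`). Mediators with adjusted
   p < 0.1 are declared significant.

## Preprocessing

The data-preparation rules mirror how such cohorts are actually processed:

* **Missingness filter** — features missing in more than 300 of 700 samples
  are dropped (`max_missing`, absolute by default with a fractional variant
  for other cohort sizes).
* **kNN imputation** — remaining gaps are filled by averaging, at the target
  sample, the `k = 10` features nearest in root-mean-square distance over
  co-observed samples. Neighbours are *features*, the default orientation of
  the classic omics imputation scheme; the sample-space orientation is
  implemented behind `orientation = "sample"` because the verbal description
  of such schemes is genuinely ambiguous. Observed cells are never altered,
  and the implementation is tested against an exhaustive brute-force oracle
  on every matrix shape up to 20×20.
* **Batch adjustment** — empirical-Bayes location/scale harmonisation
  (the ComBat model) for metabolite peak areas; lipid concentrations skip
  this step, as in the motivating cohort. The adjustment runs on log10
  values by default (the model assumes approximate normality; raw peak areas
  are log-normal), although the stated order of operations in the source
  protocol lists batch adjustment before the log transform —
  `transform = "none"` reproduces that literal order if wanted. Pooled and
  per-batch variances use unbiased denominators so the non-EB variant is
  exactly idempotent.
* **log10 + unit-SD scaling** — each feature becomes
  $(\log_{10} x - \bar{x})/s$, so association and mediation coefficients are
  per-SD of feature. Centering is not part of the stated protocol but is
  harmless for every slope reported.
* **Density arithmetic** — VPD = DV/total volume, NDV = total − DV, log10
  versions for analysis; physically impossible records (DV > total,
  non-positive volumes) are flagged and excluded rather than fatal, because
  a handful of such records is the norm in screening cohorts (705 → 700 in
  the cohort this package models).
* **Covariate imputation** — chained equations (linear, logistic, and
  one-vs-rest multinomial for the 3-level race variable), ten cycles from a
  random-draw initialisation, producing a single completed dataset. The
  number of imputed datasets is a genuinely open choice; one is used because
  every downstream quantity here is a point estimate and the missingness in
  the emulated cohort is small (< 12% per variable).

## The synthetic cohort

Because the motivating cohort is private, the generator *is* the test bed.
`sim_config()` defaults state the world the analysis assumes: $n = 700$
women; BMI at 10 ~ Normal(17.4, 2.8²) and at 18 ~ Normal(22.1, 4.4²) with
correlation 0.6 (recall-validation studies for these instruments report
correlations around 0.6–0.65); age ~ Normal(46, 5²); race 72/23/5%
(non-Hispanic white / non-Hispanic black / other); 22% family history; age at
menarche ~ Normal(12.9, 1.5²); $p = 828$ features with 1.3% of cells missing
completely at random; five assay batches with log10-scale shifts of SD 0.3
and scale factors of SD 0.1; total breast volume log-normal around 800 cm³.
Mediators are drawn from equation 2 on the standardized scale and pushed onto
a positive peak-area scale as $10^{M + \mathrm{shift}}$, so that the
preprocessing chain (log10 + z-scoring) inverts the construction exactly —
one of the invariant tests asserts grid ≡ latent mediators to 1e-8. The
outcome is generated as log10 VPD and DV/NDV are back-derived from simulated
total volume, keeping the three density measures mutually consistent (and
occasionally producing VPD > 1 records, which exercises the invalid-record
path the way real data would).

Default effect sizes (a handful of true mediators with $\alpha \approx 0.04$
SD per kg/m², $\beta \approx -0.05$ log10-VPD per SD, $\gamma = -0.02$) echo
the magnitudes printed for the real cohort; the residual scales are chosen
for testability — the private raw data offer nothing to calibrate against,
and no generator parameter was tuned to make any test pass. What a green
test establishes is therefore that the *machinery* is correct under the
stated linear-Gaussian world; it says nothing about metabolite correlation
networks, non-MCAR missingness, or assay chemistry, none of which are
simulated.

## Published-table arithmetic as an oracle

The printed per-mediator results of the motivating study
(`reference_mediation_tables()`) satisfy an internal identity: within one
exposure × outcome block every row shares the same total effect, so
$\hat\alpha\hat\beta/(\%\mathrm{TE}/100)$ must be constant across rows.
`implied_total_effects()` and `reconstruct_pct_total_effect()` exploit this:
the implied totals agree within a coefficient of variation well under 2% in
six of the seven blocks with at least three rows, and every printed
percentage is recovered from its own $\hat\alpha$, $\hat\beta$ and the
held-out block median within 0.3 percentage points. The one exception is the
metabolite BMI-at-18 → NDV block, where a mediator with $\hat\beta$ printed
as −0.003 (one significant digit) carries enough rounding error to push that
block's CV to ≈ 4.5%; the corresponding acceptance check is deliberately
left failing rather than loosened, since the discrepancy is fully explained
by print precision.

## Numerical choices and edge cases

* OLS throughout is QR-based; rank-deficient designs error and name the
  collinear columns rather than silently dropping them.
* Screening ties break by feature order; all orderings are deterministic.
* The MCP solver refuses to return at non-convergence (errors with
  diagnostics) instead of handing back a half-converged path.
* `pct_total_effect()` errors at $\hat\gamma^* = 0$ — the proportion is
  undefined, not zero.
* Zero-variance features error in standardization; a constant column is an
  upstream data bug, not something to impute around.
* Empty MCP support yields an empty (zero-row) mediation table, not an error:
  "nothing mediates" is a valid scientific answer.

## Known limitations

Mediators are treated as independent given the exposure (no exposure–mediator
interactions, no mediator–mediator causal ordering), inference after
selection is the joint-significance test without post-selection corrections
beyond Bonferroni, and %TE has no confidence interval — all deliberate,
matching the scope of the procedure being reimplemented.
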
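---
title: "Co-twin control discovery of dietary biomarkers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-twin control discovery of dietary biomarkers: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Self-reported food intake is noisy; blood metabolites that track habitual
intake of specific foods can serve as objective dietary biomarkers. A twin
cohort offers an unusually strong validation design: monozygotic (MZ)
co-twins share genotype, age, sex and much of their environment, so an
association between a food group and a metabolite that holds *within* MZ
pairs discordant for that food is much less likely to be confounded by
genetics or shared upbringing than a population-level correlation.

`twinmetab` implements this design end to end: diet and metabolite
preprocessing, a two-stage discovery/replication scan over all
(food group, metabolite) pairs, inverse-variance fixed-effect
meta-analysis of the two stages, and a follow-up scan of candidate SNPs on
food intake. Because registry twin data are access-restricted, the package
ships a synthetic cohort generator with known ground truth; every stage is
tested against that truth.

## The regression model

For metabolite $Y$ and food group $X$, with twin $j$ in family $i$:

$$Y_{ij} = \beta_0 + \beta X_{ij} + \gamma\,\mathrm{age}_{ij}
          + \delta\,\mathrm{BMI}_{ij} + \mathrm{batch}_{ij} + \zeta_i
          + \varepsilon_{ij},$$

where $\zeta_i \sim N(0, \sigma_f^2)$ is a family random intercept
capturing twin relatedness, batch (metabolomics run day) enters as
categorical fixed effects, and $\varepsilon_{ij} \sim N(0, \sigma_e^2)$.
The model is fitted by restricted maximum likelihood (REML) via
`lme4::lmer`; the food-group slope $\beta$ is tested with a two-sided Wald
z statistic. When the family variance estimate hits the zero boundary the
fit coincides with ordinary least squares — the estimates are continuous in
the variance estimate, which the test suite checks explicitly, along with
agreement (to $10^{-4}$ relative error) with a brute-force profiled-REML
grid-search oracle on small balanced instances.

A single family-level intercept is used; a separate MZ/DZ residual
correlation is deliberately **not** modelled, because the inference target
is the fixed slope $\beta$, not heritability. Inside a scan, where only the
response changes between metabolites for a given food group, the model is
re-optimised with `lme4::refit` rather than rebuilt, which cuts the scan
cost roughly in half without changing any estimate.

## Discordance partitioning and the two stages

For each food group the sample SD of the energy-adjusted intake is computed
over all subjects with an observed value. A complete MZ pair is
*discordant* when the absolute within-pair difference is at least one SD
(ties at exactly one SD count as discordant; the margin is the
`sd_multiplier` argument). Members of discordant MZ pairs form the
replication set; everyone else — concordant MZ pairs, all DZ pairs,
singletons, and pairs where one co-twin's intake is missing — stays in
discovery. The two sets are disjoint by construction and replication
contains only complete MZ pairs; both invariants are asserted in tests.

Discovery fits are Bonferroni-corrected at
$\alpha / (\text{food groups} \times \text{metabolites})$, with the
denominator spanning **both** platforms in a joint run (the classic
configuration of 71 food groups and 601 metabolites gives
$0.05/42671 = 1.17\times10^{-6}$ at 3 significant figures; pass `n_tests`
to reproduce a fixed denominator). Discovery-significant pairs are refitted
on the replication set; an association replicates when the slope direction
agrees and — on the non-targeted platform only — the replication p-value is
below 0.05. The direction-only rule for the targeted platform reflects its
much smaller assayed subsample. The "5% level" is read as two-sided
$p < 0.05$: the direction criterion is stated separately, so a one-sided
reading would double-count it.

Both stages are then combined by inverse-variance fixed-effect
meta-analysis: with $w_k = 1/\mathrm{SE}_k^2$,
$\hat\beta_\mathrm{meta} = \sum_k w_k \hat\beta_k / \sum_k w_k$ and
$\mathrm{SE}_\mathrm{meta} = (\sum_k w_k)^{-1/2}$. The meta estimate always
lies between the stage estimates and its SE is no larger than either
stage's; these identities, plus invariance to stage order, are tested as
algebraic properties.

## Preprocessing

Non-targeted (relative-intensity) panels go through, in order:

1. **Run-day median normalisation** — each value divided by the median of
   that metabolite on its run day, removing multiplicative batch drift.
2. **Missingness filter** — metabolites with *strictly more than* 20%
   missing values are excluded (a metabolite at exactly 20% is retained;
   the cut-off is configurable).
3. **Run-day minimum imputation** — missing cells take the minimum
   observed value of that metabolite on that run day, the natural fill-in
   when missingness reflects values below the detection limit; a run day
   with no observations for a metabolite falls back to the global
   per-metabolite minimum (an artifact decision for degenerate days).
4. **Inverse normal transformation** — per metabolite, Blom scores
   $\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$ with average ranks for ties.
   The variant is not dictated by the design; Blom is the metabolomics/GWAS
   convention and is applied across all samples (not within run day). The
   transform depends on the data only through rank order, which is tested
   as an invariance property.

The filter is computed on the original missingness mask; normalisation
cannot change which cells are missing, so the normalise-then-filter order
is inconsequential for the exclusions but is enforced anyway through a
recorded processing state — each operation declares its prerequisites and
an out-of-order chain errors rather than silently producing a
differently-normalised panel.

Targeted (absolute concentration, mM) panels are log-transformed (they are
right-skewed) and metabolites quantified on both platforms are dropped from
the targeted panel (the classic panel: 163 assayed − 18 overlapping = 145
analysed). Betas are therefore in SD-of-metabolite per serving/week on the
non-targeted platform and log-mM per serving/week on the targeted one.

## Diet preprocessing

FFQ items are reported on a 9-point frequency scale. The default
code→servings/week map uses category midpoints
(0, 0.5, 1, 3, 5.5, 7, 17.5, 31.5, 45 for "never/<1 per month" through
"6+ per day"); no standard numeric mapping is dictated by the design, so
the map is a configurable argument validated for monotonicity. Items are
summed into food groups, then adjusted for total energy intake by the
residual method: the group intake is replaced by its residual from a
regression on energy, re-centred on the group mean so units and location
are preserved. Adjustment at the group level (after aggregation) is the
default because the reported effect scale is per food group;
`adjust_order = "item"` adjusts before aggregation instead. Group-level
output is uncorrelated with energy to numerical precision, preserves the
mean exactly and never increases variance — all tested.

## The synthetic cohort generator

`simulate_cohort()` draws `n_pairs` twin pairs (default 500, half MZ by
rounded allocation). Co-twins share age exactly (uniform 18–79 y, the
adult-female registry range); BMI is drawn per subject around a shared pair
mean (total SD 4 kg/m² around mean 25). FFQ codes come from a latent
pair-correlated consumption propensity cut at fixed right-skewed category
breaks (30% of item-responses in the floor category). Total energy is
$1500 + 5\times\text{total weekly servings} + N(0,300)$ kcal/day: energy
tracks overall consumption only moderately (correlation ≈ 0.6), as
FFQ-derived energy does; a near-deterministic energy–intake link would make
the residual adjustment tie all food groups together and marginal
associations would propagate across correlated groups.

Metabolites follow exactly the model the pipeline fits: planted slopes
times the energy-adjusted food-group matrix, age and BMI confounding
(defaults 0.005/y and 0.01 per kg/m²), a family intercept
($\sigma_f^2 = 0.3$) plus extra MZ-shared variance (0.2), and residual
noise (0.5). The non-targeted panel is then multiplied by a per-(run day,
metabolite) factor $e^{N(0, 0.1^2)}$ and thinned with intensity-weighted
missingness (5% expected rate, low/mid/high-intensity tertile weights
1.8/0.9/0.3 — left-censoring-like, which is what makes minimum imputation
sensible). The targeted panel is exponentiated, so the pipeline's log
transform exactly recovers the latent linear scale. Genotypes use
Hardy–Weinberg sampling with MAF uniform on [0.1, 0.5], identical MZ
dosages and one shared allele draw in DZ pairs; planted genotype effects
shift the latent consumption propensity, so their effect on servings is
monotone but not exactly linear (the ordinal FFQ scale intervenes).

What the generator does *not* emulate: mass-spectral peaks, a ±years gap
between questionnaire and blood draw (single time point), serum/plasma
differences, linkage disequilibrium, or non-Gaussian residuals. Passing
tests therefore demonstrate that the inference machinery is correct under
the model's own assumptions, not that the assumptions hold in any real
cohort.

## Calibration and problem sizes

The test suite verifies, at sizes chosen to keep a full run in minutes on
one CPU:

* type-I error of a single discovery fit within the 95% binomial band
  around 0.05 (200 null replicates at 500 pairs);
* family-wise error of the full Bonferroni-controlled scan consistent with
  the nominal 5% (200 all-null scans of 10 food groups × 20 metabolites at
  100 pairs);
* mean meta-analysed slope within 2 Monte-Carlo SEs of a planted 0.1
  (100 replicates at 500 pairs). The recovery scenario plants the effect on
  the targeted platform because its preprocessing (log) exactly inverts the
  generator's scale; on the non-targeted platform the inverse normal
  transform rescales the response, so the estimand there is the slope on
  the transformed scale, not the planted latent slope;
* end-to-end: three planted, well-powered effects are exactly the
  significant-and-replicated meta records of a joint two-platform run.

## Numerical choices and degenerate inputs

* Wald z (normal) p-values throughout, including the meta stage —
  consistent with inverse-variance weighting and with large-sample mixed
  model practice. Extremely large z underflows to $p = 0$; the reporting
  layer prints `0` rather than a fabricated exponent.
* A constant food group (zero SD) yields an empty replication set with a
  warning; a constant metabolite is rejected by the inverse normal
  transform; a monomorphic SNP and a collinear fixed-effect design are
  rejected with the offending column named.
* Listwise deletion of incomplete covariates within each fit; fits require
  at least 10 subjects and 2 families; failed fits inside a scan are
  collected per pair with their error message, never silently dropped.
* Batch enters as fixed effects with the first level lexicographically as
  reference; a single-batch subset drops the term.
* All tables are TSV (missing = empty field) with numbers at 15
  significant digits; rerunning the pipeline on identical inputs is
  byte-identical.

## Known limitations

The discordance SD is computed on the energy-adjusted intake over the full
analysis sample; computing it on raw intake or before exclusions would
change the partition at the margin. Wald (not sandwich) standard errors
are used in both stages. The SNP follow-up assumes a random-intercept
family adjustment, matching the main model. Power at desk scale is limited:
the defaults are sized for correctness checks, not for reproducing
cohort-scale association counts, which depend on data that are not
publicly redistributable.
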
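---
title: "Validating and scoring a responsiveness & respectful-treatment questionnaire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and scoring a responsiveness & respectful-treatment questionnaire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrtscore)
```

## The measurement problem

Questionnaires on women's experience of maternity care mix short Likert
scales, yes/no items and categorical items with answers that cannot be
ranked ("Don't know", "Not relevant"). Treating such codes as continuous
and normally distributed biases every downstream step, so this package
keeps the ordinal view throughout: associations between items are
modelled as **polychoric correlations** — each ordinal item is the
discretisation of a latent standard normal variable through a set of
thresholds, and the correlation of the latent pair is estimated from the
observed contingency table.

The package covers the complete workflow — data cleaning, suitability
diagnostics, exploratory factor analysis with an explicit acceptance
protocol, confirmatory factor analysis on a held-out half, and two
subscale scoring rules — together with a synthetic-cohort generator
that emulates the structure the analysis assumes, because the original
survey data are not publicly deposited.

## Data model and cleaning rules

An `rrt_schema` describes each item: scale kind, the ordered scored
labels (worst → best *after* any recoding and reverse-coding), the
non-scorable labels, a reverse flag, and an optional recode rule that
merges raw categories or routes labels to the non-scored sentinel or to
median imputation. The shipped 36-item fixture reconstructs the
instrument behind the published six-factor solution; its prompts and
category labels are plausible stand-ins (the original item metadata is
not public) while item identity, factor membership and loadings follow
the published tables. The schema file format is the public contract, so
real instrument metadata can be dropped in without code changes. The
set of reverse-coded items in the fixture is likewise a reconstruction:
the negatively phrased mistreatment, privacy and waiting-time items.

Cleaning applies the study's data-management rules:

* respondents with **more than 5** missing items are removed. The rule
  is deliberately inclusive at the boundary — exactly five missing
  items are imputed, not excluded — because the source description
  covers "more than five" and "fewer than five" but is silent about
  five itself; the threshold is a parameter (`max_missing`).
* remaining missing cells are imputed with the **per-item median** of
  the observed codes. With an even count the lower middle order
  statistic is taken, so the imputed value is always a valid category
  code, and the column median is provably unchanged.
* reverse-coded items are flipped (`c − 1 − q`) so higher always means
  better.

Two cleaning paths serve different consumers. Factor analysis requires
a complete matrix, so the factor path also imputes non-scorable
answers. Scores must be computable for a single woman without
population information, so the scoring path leaves missing and
non-scorable answers unanswered; they simply drop out of the score
sums. This asymmetry is intentional and mirrors the source analysis.

For validation the cohort is split into halves — exploratory and
confirmatory — by shuffling respondents within each country with a
seeded RNG and assigning them alternately, which guarantees per-country
balance to ±1.

## Polychoric estimation and suitability gates

Estimation is two-step: thresholds from the marginal cumulative
proportions through the inverse normal CDF, then per pair a bounded
Brent search of the latent correlation on (−0.999, 0.999) maximising
the bivariate-normal likelihood of the contingency table. Numerical
choices:

* empty cells receive a 0.5 continuity correction before the
  likelihood is evaluated (prevents divergence);
* structurally perfect 2×2 tables (an empty discordant diagonal) are
  short-circuited to ±0.999 and flagged;
* a non-positive-definite matrix is eigenvalue-smoothed (floor 1e-6,
  renormalised to unit diagonal) and flagged;
* the bivariate-normal CDF is a C++ implementation of the
  Gauss–Legendre adaptation of the Drezner–Wesolowsky method, accurate
  to ~1e-14; the test suite checks it against an independent
  implementation.

Each pairwise estimate also yields an asymptotic variance from the
curvature of the profile log-likelihood at the optimum (thresholds
fixed) — these become the weights of the confirmatory fit below.

Suitability for factoring is gated on Bartlett's sphericity test
(p ≤ 0.05) and the Kaiser–Meyer–Olkin measure (≥ 0.5). Both are
computed on the polychoric matrix by default; the source analysis does
not state which correlation it used, so Pearson input is available via
an argument.

## Factor retention and the acceptance search

**Horn's parallel analysis** compares the observed eigenvalues with
those of reference datasets obtained by permuting each item's observed
responses independently — this preserves every marginal distribution
while destroying association, which is the right null for ordinal
items. The default reference summary is the **95th percentile** of the
replicate eigenvalues rather than the mean: under pure noise the first
observed eigenvalue exceeds its own expected value in about half of all
samples, so the mean reference retains one or two spurious factors far
too often (in our null simulations, roughly a quarter of seeds). The
mean variant remains available (`summary_stat = "mean"`).

**Extraction** is iterated principal axes on the polychoric matrix,
initialised at squared multiple correlations. The convergence tolerance
is 1e-3 on the maximum communality change (500 iterations cap): with
two-item factors the smallest communalities are only weakly identified
and the fixed-point iteration is linear with rate close to one, so a
much tighter tolerance costs hundreds of iterations and changes the
loadings by less than the sampling noise. Communalities above one
(Heywood) are capped and flagged. **Rotation** is Promax with the
conventional power κ = 4 (varimax pre-rotation, oblique fit to the
|loading|^κ target), giving a pattern matrix and a factor correlation
matrix Φ.

A candidate solution is evaluated against four criteria: no item with
two pattern loadings ≥ |0.4|; at least three significant items per
factor, with **two-item factors flagged as warnings rather than
rejected** (they are legitimate when the pair loads highly and coheres
theoretically); McDonald's ω ≥ 0.7 per factor, computed from the
assigned items' loadings as `(Σ|λ|)² / ((Σ|λ|)² + Σ(1 − λ²))` — the
absolute values let a negatively loading item contribute its magnitude;
and theoretical sense, which **cannot be automated**: it is recorded
from caller-supplied override notes and is never auto-passed. Override
fields mirror the lenience the protocol allows: named justified
cross-loaders, and an `omega_floor` accepting a near-threshold
reliability (the published solution itself accepted an ω of 0.678).

The search descends from the parallel-analysis suggestion one factor at
a time; if no factor count is acceptable, the item that cross-loaded in
the most candidate solutions is eliminated (ties to the lowest item
index) and the search restarts on the reduced item set, failing cleanly
once fewer than three items per initially sought factor remain or no
cross-loader is left to remove. Items in an accepted solution map to
their highest-|loading| factor; items below the threshold are reported
unassigned.

## Confirmatory fit

The accepted assignment (or the shipped published solution) becomes a
confirmatory model: one loading per item, all factor pairs correlated.
Estimation is **two-stage DWLS**: thresholds and polychoric
correlations with their asymptotic variances are estimated first; then
the model-implied correlations `ρ_ij = λ_i λ_j φ_{f(i) f(j)}` are fit
by minimising `Σ_s w_s (r_s − ρ_s)²` with `w_s` the inverse asymptotic
variances (L-BFGS-B with analytic gradients, parameters bounded to
(−0.999, 0.999)). Because each weight is the inverse variance of that
estimate at the observed sample size, the minimised discrepancy is
itself the test statistic; no robust mean-and-variance correction is
applied, matching the plain-DWLS description of the source analysis.
The baseline model keeps the thresholds and sets every correlation to
zero. Fit is summarised by CFI and TLI (baseline-referenced, capped to
[0, 1]), RMSEA (`√(max(χ²−df,0)/(df(n−1)))`) and SRMR (root mean square
of the raw correlation residuals, off-diagonals only — the diagonal of
a correlation structure is exact). Conventional bands: CFI/TLI > 0.9
acceptable, > 0.95 good; RMSEA < 0.08 acceptable, < 0.05 good;
SRMR < 0.08 good — and, as in the source protocol, SRMR may fail while
a solution is still accepted, since it performs poorly on categorical
data.

## Scoring

Responses are normalised to `q/(c−1)` with 0 the worst and 1 the best
answer; non-scorable answers receive no value. Two subscale scores on
0–10 are computed over the answered items of each subscale:

* the **sum score** uses only the *sign* of each loading — negatively
  loading items are subtracted — plus a shift term (the count of
  answered negative-loading items over n) that restores the 0–10 range;
* the **factor score** weights each normalised response by its loading,
  divides by the sum of |loadings| of the answered items, and shifts by
  the analogous |loading|-weighted term.

When all loadings in a subscale are equal in magnitude and sign the two
methods coincide exactly; the test suite checks both against a literal
term-by-term implementation of the equations at 1e-12 on thousands of
random specifications, including negative loadings. A subscale with no
answered item receives no score; the overall score and the
responsiveness / respectful-treatment domain scores are 10 times the
mean of the subscale scores that exist, i.e. percentages of best
practice. Scores are kept unrounded internally and rounded to two
decimals only at CSV serialisation. The factor score is labelled for
within-study use and the sum score for cross-study comparison, and the
cohort summary reports per-respondent means and SDs (the per-woman
reading of the aggregation, consistent with the overall score being a
per-woman quantity).

## The synthetic generator: what it emulates, and what it does not

`simulate_latent_ordinal()` draws correlated standard-normal factor
scores (Φ has 0.3 off-diagonal by default — the published analysis used
oblique rotation but never printed Φ, so a moderate value is assumed
and configurable), builds each item's latent response as
`λ f + √(1−λ²) ε`, and discretises through the item's thresholds. The
defaults reproduce the study conditions: four country strata × four
hospitals × three rounds × ~51 women (2448 respondents, matching the
1217/1216 exploratory/confirmatory halves after exclusions), the
published six-factor pattern including the single negative loading, and
sparse completely-at-random missingness calibrated so that roughly
fifteen respondents are affected and about one exceeds the exclusion
threshold. Non-scorable answers are injected only into items whose
scale declares such labels.

Two deliberate deviations from a literal reading of the published
numbers:

* two published pattern coefficients exceed 1 (1.09 and 1.02). That is
  legal for oblique pattern loadings but impossible for standardised
  generating coefficients (the implied uniqueness would be negative),
  so the generator caps |λ| at 0.95 (`max_abs_loading`); the shipped
  fixture still carries the printed values for scoring and model
  specification.
* thresholds default to equal-probability categories, which makes every
  marginal uniform. Real experience surveys are strongly ceiling-shifted
  (most women report the best category); the `"skewed"` preset mimics
  that regime for stress-testing polychoric boundary handling. Passing
  tests on the default generator therefore demonstrate correctness of
  the machinery under a well-conditioned regime, not robustness to
  every pathology of real data: items the generator leaves structureless
  are fully independent (real discarded items correlate weakly), the
  missingness mechanism is MCAR, and hospital-level clustering and
  intervention time trends are not simulated.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and restores the
caller's RNG state. The test suite exercises the pipeline at the
study's subsample sizes (n ≈ 1216–1224 for the confirmatory checks,
ten-seed replication for factor-count recovery) and uses n = 5000
cohorts where an invariant is asserted against a generating value with
±0.03–0.05 tolerance; closed-form checks (Bartlett, KMO, ω, fit
indices, the three-item principal-axis solution) are exact to printed
or analytic precision. Parallel analysis uses 100 replicates — the
minimum the function accepts — throughout.

## Known limitations

* Polychoric standard errors are curvature-based with thresholds
  treated as fixed; the extra threshold-estimation variability is
  ignored (standard two-stage practice, slightly anti-conservative).
* Plain DWLS χ² without robust corrections is not well calibrated for
  severe misspecification; the incremental indices are the primary fit
  summary, as in the source protocol.
* The acceptance search automates only the three statistical criteria;
  judgments of theoretical sense enter through overrides and are
  recorded, not made.
* No measurement-invariance testing across countries, no modification
  indices, no weighting for the field sampling design.
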
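---
title: "Deciding between taxonic and dimensional latent structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding between taxonic and dimensional latent structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxometry)
```

## The question the package answers

Given a set of questionnaire indicators — here, suicidal-ideation scores
such as the three Beck Scale for Suicide Ideation (BSS) factor scores or
individual Suicidal Ideation Attributes Scale (SIDAS) items — do the
scores arise from a *taxonic* latent structure (a discrete subgroup, the
taxon, versus its complement) or from a *dimensional* one (a continuous
latent trait)?  The package implements the coherent-cut-kinetics family
of taxometric procedures together with the simulated-comparison-data
framework: the empirical curves produced by each procedure are compared
against the curves the same procedure produces on data simulated to share
the empirical marginals and correlations under each candidate structure,
and the comparison is summarized by the comparison curve fit index
(CCFI).

## Indicator screening

Before any curves are drawn, each indicator is screened descriptively
(mean, SD, skewness as the standardized third moment, *excess* kurtosis)
and gated on validity.  Validity is the indicator's ability to separate
the "extremes of the sample": cases are ranked on the sum of the
standardized indicators, the top `round(n * base_rate)` cases form the
putative taxon, and the indicator's Cohen's *d* (pooled-SD denominator,
sign preserved) between putative groups must reach **1.25** (inclusive).
At least three valid indicators are required; otherwise the analysis
aborts naming the offenders.  Two operationalization choices were open
and are fixed as follows:

* *Putative-group assignment* by standardized-total ranking with the cut
  at the assumed base rate — the standard total-score classification in
  the taxometrics literature.  Boundary ties are broken by stable
  original case order with a warning: reproducibility over randomness.
* *Excess* kurtosis (normal = 0), consistent with screening tables whose
  near-normal indicators show values near zero.

## The three curve procedures

**MAMBAC** (mean above minus below a cut).  For each ordered pair of
indicators, cases are sorted on the input indicator and 50 cuts are
slid from case 25 to case *n* − 25; each cut's statistic is the output
indicator's mean above minus mean below.  Ties on the input are broken
by a random permutation, averaged over 10 replications (tie-free inputs
are computed once — the result is identical).  A two-class structure
peaks the curve near the class boundary: with the taxon as the
high-scoring minority at base rate *p*, the difference is maximal near
sorted rank *n*(1 − *p*) — i.e. to the *right* of the midpoint for
*p* < 0.5 — because below that rank the lower group is nearly pure while
above it the upper mean is fully taxon.  The same geometry fixes the
end heights near Δ·*p* (left) and Δ·(1 − *p*) (right), so the reported
base-rate heuristic is *p̂* = y₁ / (y₁ + y_last) on the curve shifted
just enough to be non-negative.  This estimator is a conventional
curve-end heuristic: simulation recovery (true *p* = 0.25 recovered
within ±0.12 on average) is its only validation, and it feeds no CCFI.

**MAXEIG**.  For each indicator used as the sorting input, the remaining
indicators' covariance matrix is computed inside 50 overlapping windows
of equal case count (90% overlap), its diagonal zeroed, and the largest
eigenvalue taken as the statistic.  With two outputs this reduces to the
absolute within-window covariance; the statistic is always non-negative
(zero-trace symmetric matrix).  Windows are defined by case counts, not
input-value widths, so all panels share a common length.  The base-rate
heuristic is the proportion of cases above the midpoint rank of the
averaged curve's peak window.

**L-Mode**.  A single common factor is extracted from the indicator
correlation matrix by iterated principal axes; regression-method factor
scores are standardized and reflected so skewness is non-negative
(placing a minority taxon on the right); the score density is estimated
with a Gaussian kernel (Silverman bandwidth, 512-point grid spanning the
scores ±0.5).  Bimodality indicates taxonicity, and the mode locations
invert to base rates through the two-point-mixture identities
*p̂*\_L = m\_L² / (1 + m\_L²), *p̂*\_R = 1 / (1 + m\_R²): for standardized
scores from a two-class mixture with base rate *p* the masses sit at
−√(*p*/(1 − *p*)) and √((1 − *p*)/*p*), so both identities are exact on
a noiseless mixture.  A *mode* is the highest interior local maximum on
each side of zero (the two outermost grid points are excluded); a bare
argmax at the sign boundary of a unimodal density is not a mode, which
is why unimodal data leave one side undefined and *p̂* falls back to the
defined side with a warning.

## Comparison data

`gen_data_matched()` produces datasets whose columns are *exactly*
permutations of supplied marginal vectors and whose correlation matrix
approximates a target: a latent multivariate normal sample is drawn from
an intermediate correlation matrix (initialized at the target), each
column is replaced by the rank-reordered marginal, the achieved
correlation is measured, and the intermediate matrix is adjusted by the
residual — keeping the best iterate by correlation RMSR, stopping after
100 iterations, 10 non-improving iterations, or RMSR < 0.01.  Indefinite
intermediate matrices are repaired by clipping eigenvalues at 10⁻⁶ and
renormalizing the diagonal.

The *dimensional* ensemble matches the whole-sample correlations and
marginals; the *taxonic* ensemble splits the sample into putative taxon
and complement at the assumed base rate, matches each group's own
correlations and marginals, and concatenates the groups.  Marginals are
bootstrap-resampled per simulated dataset (an exact-marginal mode exists
for debugging), so ensembles vary the way the published figures'
"variability across the simulated datasets" does.  100 datasets per
structure is the default; there is no published count to match.

Every simulated dataset is scored by the same curve settings as the
empirical run, and the L-Mode density grid is locked to the empirical
run's range, so all curves per method share one length and x grid — the
precondition for the CCFI.

## CCFI and its profile

For each method, fit_tax and fit_dim are the RMSRs between the empirical
averaged curve and the taxonic and dimensional ensembles' *mean* curves
(pointwise by index; no renormalization — both alternatives remain
available switches), and

> CCFI = fit_dim / (fit_dim + fit_tax).

0 indicates dimensional, 1 taxonic structure; swapping the ensembles
maps c to 1 − c; equal fits give exactly 0.5, which is also the reported
value (with a warning) in the degenerate both-zero case.  Values in
\[0.40, 0.60\] — bounds included — are *ambiguous*.  The analysis is
interpreted on the unweighted mean CCFI across methods; aggregation uses
full precision and rounding to two decimals happens only in reports
(rounding first can change the second decimal of the mean).

The **CCFI profile** relaxes the fixed base-rate assumption: the taxonic
ensemble is regenerated at every rate of a grid (default 0.025–0.975,
step 0.025; the dimensional ensemble is rate-independent and generated
once), giving a rate × method CCFI matrix, per-rate aggregates (mean
over methods), per-method aggregates (mean over rates — consistent with
published aggregate arithmetic), and their overall mean.  Rates whose
putative group would be smaller than *k* + 2 cases cannot support a
within-group correlation estimate and are skipped, never clamped.

## Seeds and determinism

A master seed spawns fixed-offset child seeds per stage (empirical
curves, dimensional ensemble, taxonic ensemble, profile), and each
simulated dataset inside an ensemble gets its own child seed.  Toggling
one stage therefore never perturbs another's random stream, and the
fixed-base-rate CCFIs are bit-identical whether or not a profile is
computed in the same run.  Identical config and seed reproduce
byte-identical report files.

## The synthetic-data module

The study's raw data are not deposited, so the generator provides
structure-known stand-ins:

* **Taxonic**: exactly `round(n * p)` taxon cases (deterministic count —
  Bernoulli membership would add base-rate sampling noise to recovery
  tests); within each group a latent multivariate normal with
  exchangeable correlation `within_r`, unit variances, and the taxon
  shifted by `separation` SD units per indicator.
* **Dimensional**: the one-factor model
  x = λf + √(1 − λ²)e, so indicator pairs correlate at λ_a·λ_b.
* **Matched pairs**: the dimensional member's loadings are solved from
  the taxonic mixture's implied pooled correlations
  (cov = w + p(1 − p)d_a d_b, var = 1 + p(1 − p)d_j²; triad identity
  λ_a = √(r_ab·r_ac / r_bc)), so the pair differs *only* in latent
  structure — the fairness harness behind every recovery claim.
* **Marginal transforms**: an optional monotone exp(g·z) skewing, a
  linear rescale, and clip-and-round discretization to bounded scale
  points emulate bounded, positively skewed questionnaire scores.  The
  `bss_like` (n = 547, three sum-score factors) and `sidas_like`
  (n = 989, three 0–10 items) presets freeze parameters from a one-off
  coarse calibration against the published descriptive table; matching
  is approximate by design and tests assert bands (means within ±0.75),
  not exact moments.

What the generator does *not* emulate: item-level response processes,
floor effects beyond clipping, measurement non-invariance, and the
study's true (unpublished) inter-indicator correlation matrices.
Passing recovery tests therefore show the machinery discriminates known
structures under realistic shapes — not that any particular empirical
dataset is taxonic or dimensional.

## Recovery behaviour and problem sizes

The headline property uses matched pairs at k = 3, n = 600, d = 2.0,
p = 0.25, within-group r = 0.1, 50 comparison datasets per structure:
taxonic members score mean CCFI > 0.5 and dimensional members < 0.5 in
at least 18 of 20 seeds.  Weak separation (d = 0.8) produces mean CCFIs
scattered around the lower ambiguity boundary (roughly 0.28–0.52 across
seeds, about half inside the 0.40–0.60 band): with d well below the
1.25 validity convention the mixture is genuinely close to dimensional,
and the index says so.  Unit and property tests run on scaled-down
settings (n = 150–300, 20 cuts/windows, 4–12 comparison sets) chosen so
the whole suite stays fast while each contract is still exercised; the
analysis scripts use the full published grid with 25 sets per profile
rate and 100 for fixed-rate runs.

## Known limitations

* The base-rate estimators attached to MAMBAC and MAXEIG curves are
  heuristics validated only by simulation recovery; published per-method
  estimates could have been produced by different conventions.
* CCFI curve comparison is by point index; for L-Mode this relies on the
  locked common density grid, and for MAMBAC/MAXEIG on equal case
  counts between empirical and simulated data (guaranteed by
  construction).
* MAXCOV, MAXSLOPE and inchworm consistency tests are out of scope, as
  are inferential intervals on the CCFI.
* With fewer than three valid indicators the analysis refuses to run
  rather than degrade to a two-indicator variant.
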
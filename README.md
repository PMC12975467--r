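# taxometry

Taxometric analysis of psychological indicators with simulated
comparison data.

## The problem

Is suicidal ideation (or any construct measured by a handful of
questionnaire indicators) a *category* — a discrete latent subgroup, a
**taxon**, versus its complement — or a *continuum*?  The answer shapes
screening cutoffs, diagnostic conventions and how risk models should be
built.  Taxometric procedures (Meehl's coherent cut kinetics) answer it
from the data themselves: indicators sampled from a two-class mixture
leave characteristic fingerprints — peaked covariance along an ordering
indicator, bimodal factor scores — that a continuous one-factor
structure does not.

`taxometry` is aimed at researchers in clinical psychology and
psychiatric epidemiology who have an n × k matrix of indicator scores
(e.g. the three Beck Scale for Suicide Ideation factor scores, or
individual Suicidal Ideation Attributes Scale items) and want a
reproducible, scriptable answer.

## What it computes

Three non-redundant curve procedures, each run on the empirical data and
on populations of simulated **comparison data** that reproduce the
empirical marginals (exactly, by rank reordering of bootstrap-resampled
values) and correlations (iteratively, to RMSR ≤ ~0.01–0.05) under each
candidate structure:

* **MAMBAC** — mean above minus below a moving cut, per ordered
  indicator pair;
* **MAXEIG** — largest eigenvalue of the zero-diagonal covariance matrix
  of the remaining indicators inside overlapping windows along each
  input indicator;
* **L-Mode** — kernel density of one-factor scores, with mode locations
  `m_L`, `m_R` inverted to base-rate estimates via
  `p̂_L = m_L²/(1+m_L²)`, `p̂_R = 1/(1+m_R²)`.

For each method the fit of the empirical curve to each ensemble's mean
curve (root-mean-square residual) is combined into the **comparison
curve fit index**

    CCFI = fit_dim / (fit_dim + fit_tax),   CCFI ∈ [0, 1]

with 0 → dimensional, 1 → taxonic, and [0.40, 0.60] ambiguous; the
analysis is interpreted on the unweighted mean CCFI across methods.
Around this core the package provides indicator screening with the
Cohen's *d* ≥ 1.25 validity gate, **CCFI profiles** over assumed taxon
base rates (0.025–0.975), sensitivity re-analysis (log transform,
screening filter, base-rate variants), a structure-known synthetic-data
generator with matched taxonic/dimensional pairs, and deterministic
seeded reports.

## Worked example

```r
library(taxometry)

# a 989-case synthetic dataset shaped like three 0-10 ideation items,
# generated from a two-group mixture (base rate 0.25)
sim <- simulate_taxonic(preset_spec("sidas_like", seed = 1))

res <- run_full_analysis(run_config(sim$matrix, n_sets = 50, seed = 1))
print(res)
#> Taxometric analysis: 989 cases, 3 valid indicator(s) [ind1, ind2, ind3]
#>  method ccfi
#>  mambac 0.91
#>  maxeig 0.76
#>   lmode 0.87
#> mean CCFI = 0.85 (taxonic)
#> base-rate estimates: mambac = 0.27, maxeig = 0.25, lmode = 0.30; mean = 0.27
```

Every per-method CCFI exceeds 0.60, so the mean CCFI of 0.85 classifies
the dataset as taxonic — correctly, since it was generated from a
two-group mixture — and the per-method base-rate estimates bracket the
generating base rate of 0.25.  Adding `out_dir = "results/demo"` writes
`report.json`, `validity.csv` and one `curves_<method>.csv` per method;
`profile = TRUE` adds the base-rate profile.

The `analysis/` directory holds the numbered workflow scripts
(simulate → validity screening → fixed-base-rate analysis → CCFI
profiles → sensitivity) that drive the package over the synthetic study
datasets and leave their tables under `results/`.

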
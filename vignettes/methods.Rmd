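---
title: "Hierarchical Bayesian analysis of oligosaccharide immunomodulation in equine PBMCs"
author: "oligopbmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian analysis of oligosaccharide immunomodulation in equine PBMCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligopbmc)
```

## The experiment this package models

Equine peripheral blood mononuclear cells (PBMCs) are incubated with three
commercial oligosaccharide fractions — galacto-oligosaccharides (GOS),
GOS combined with long-chain fructo-oligosaccharides (GOS/FOS, oligosaccharide
ratio 9:1), and a triple mix with pectin-derived acidic oligosaccharides
(GOS/FOS/AOS, 9:1:2) — at 0.5, 1 and 2% w/v total oligosaccharide, with and
without a 1 µg/ml lipopolysaccharide (LPS) challenge. TNF-α and IL-10 are read
out by ELISA on triplicate or quadruplicate wells per horse; a CCK-8 assay
reads out cell viability. Because the commercial products carry appreciable
glucose and lactose, matched glucose/lactose control incubations are run in a
separate group of horses, and because the products carry traces of endotoxin,
the package also implements the mixture and endotoxin bookkeeping needed to
interpret the incubations (see `incubation_table()`,
`extrapolate_endotoxin()`, `eu_to_ng_range()`).

Three donor-horse groups are modelled: five horses for the oligosaccharide
incubations, four for the glucose/lactose controls, three for viability. The
raw plate data of the original experiments were never deposited, so the
package ships a synthetic-data generator with the same statistical structure;
every downstream stage is exercised on generated data.

## The model

Each analyte (TNF-α, IL-10, viability) is modelled separately. For well $i$
from horse $h(i)$ under condition $c(i)$, the log response is

$$\log y_i = \beta_{c(i)} + z_{c(i)}^\top b_{h(i)} + \varepsilon_i,
\qquad \varepsilon_i \sim \mathcal N(0, \sigma^2),$$

with a *cell-means* fixed-effect parameterisation: one coefficient
$\beta_c$ per condition, so $\exp(\beta_c)$ is the condition's population
mean response and every reported contrast is a coefficient difference. A
cell-means layout is the only parameterisation that can express the
non-monotone GOS/FOS/AOS dose response (stimulation at 0.5–1%, suppression
at 2%) without imposing a dose–response shape.

Between-horse variation enters through a 5-vector of random effects per
horse — a general reactivity intercept and slopes for the LPS challenge
indicator and the GOS, FOS and AOS doses (% w/v of each component):

$$z_c = (1,\; \mathbf 1\{\text{LPS}\},\; \text{GOS}_c,\; \text{FOS}_c,\;
\text{AOS}_c), \qquad b_h \sim \mathcal N_5(0, \Sigma_b).$$

LPS enters as an indicator because only 0 and 1 µg/ml occur;
glucose/lactose control wells share the same $z$ structure with zero
oligosaccharide columns, which lets the oligosaccharide and sugar-control
arms be compared inside one model.

Cytokine values below the ELISA detection limits (15.625 pg/ml for TNF-α,
156.25 pg/ml for IL-10) are left-censored. Censored wells are handled by
data augmentation: a latent log value, upper-truncated at the log limit, is
imputed each iteration. With no flagged wells the sampler is bit-identical
to one without augmentation.

### Priors

* $\beta_c \sim \mathcal N(0, 100^2)$ — effectively flat on the log scale.
* $\sigma^2$ — inverse-gamma with mean 1 and variance 10,000;
  `derive_invgamma_hyperparams(1, 10000)` gives shape 2.0001, scale 1.0001.
* $\Sigma_b$ — scaled inverse-Wishart via parameter expansion:
  $\Sigma_b = \mathrm{diag}(\xi)\,\Omega\,\mathrm{diag}(\xi)$ with
  $\Omega \sim \mathcal{IW}(I_5,\; d+1 = 6)$ and independent
  $\xi_k \sim \mathcal N(0, 1)$. $\Sigma_b$ involves $\xi$ only through
  products of pairs, so the sign of $\xi$ is immaterial and the mean-zero
  normal is the same prior a half-normal scale would induce. The unit scale
  on $\xi$ matters: combined with the identity Wishart scale it places a
  weakly-informative, half-t-like prior with scale $\approx 1$ on each
  random-effect SD. That is appropriate for log-scale biological responses,
  whose between-subject SDs are of order 0.1–1; a much larger scale (say 10)
  lets the prior dominate the small horse groups (3–9 animals), inflating
  the posterior random-effect variances and with them every credible
  interval. The Wishart scale matrix, degrees of freedom and expansion scale
  are declared package defaults, all adjustable through `default_priors()`.

## Sampling and diagnostics

`run_chains()` is a purpose-built conjugate Gibbs sampler: every full
conditional is available in closed form ($\beta$ and the per-horse effects
are normal, $\sigma^2$ inverse-gamma, $\Omega$ inverse-Wishart, the $\xi_k$
scalar normals, censored latents upper-truncated normals), so each update
is an exact draw and no tuning or acceptance-rate monitoring is needed.
Chains start from overdispersed initial values — data cell means plus
chain-specific jitter — so that the Gelman–Rubin diagnostic is meaningful,
and a single master seed derives independent per-chain substreams, making
every fit exactly reproducible.

The reference protocol is four chains of $10^6$ iterations, thinned to
every 50th draw, first half discarded; `mcmc_config(scaled_down = TRUE)`
selects a structurally identical desk-scale profile (4 × 20,000, thin 10)
that the examples and tests use. Convergence is assessed with the classical
(non-split) potential scale reduction factor on the saved draws,

$$\hat R = \sqrt{\frac{\frac{n-1}{n} W + \frac{B}{n}}{W}},$$

with pass threshold 1.1 (a declared convention; `check_convergence()`
reports every monitored parameter: all cell means, $\sigma^2$ and the
diagonal of $\Sigma_b$). Note $\hat R$ can fall below 1 on agreeing short
chains — the hand-checkable example `psrf(rbind(1:3, 1:3))` gives
$\sqrt{2/3} \approx 0.8165$.

## Reporting

`summarize_condition()` reports $\exp(\beta_c)$ by its posterior median
with 2.5% and 97.5% percentile bounds. The median is used because it
commutes with the exponential back-transformation (the bounds are exactly
the exponentiated log-scale percentiles) and is robust; whether the original
analysis used a mean or a median is not stated anywhere, so this is a
declared choice. `compare()` forms per-draw ratios of two condition means;
a difference is *significant* when the 95% credible interval of the ratio
excludes 1. Percent changes are reported as integers, rounded half away
from zero, and computed from the two point estimates. `build_report()`
applies the table conventions: `*` marks a significant difference from the
challenge reference (blank when unchallenged, LPS-alone when challenged),
`#` from the next-lower dose of the same fraction; oligosaccharide
conditions are additionally contrasted with their matched glucose/lactose
controls. `viability_relative()` reports each condition's ratio to blank,
flagging one-sided significant increases.

## The synthetic-data generator

`default_generative_params()` anchors each condition × analyte mean to the
published point estimates (blank TNF-α 12.6 pg/ml, LPS-alone 1749.4 pg/ml,
the non-monotone GOS/FOS/AOS series, flat unchallenged IL-10, viability
multipliers of 1.38–1.61 for GOS/FOS/AOS and 1.14 for the 1% sugar
control). Sugar-control anchors are only published as percent differences,
so their absolute values are reconstructed from those percents; the
sugar-arm IL-10 mean is set to 120 pg/ml, below the detection limit, where
those measurements mostly fell. Noise defaults ($\sigma = 0.2$; diagonal
$\Sigma_b$ with SDs 0.25, 0.20, 0.08, 0.30, 0.25 for intercept/LPS/GOS/FOS/AOS)
were chosen once so that simulated 95% intervals have widths comparable to
the published tables. Per-horse random streams are derived from the master
seed and the horse id alone, so adding a horse never perturbs existing
horses' data.

What the generator does *not* emulate: plate spatial effects, pipetting
error structure, ELISA optical-density noise and standard-curve error,
non-normal heavy tails, or any true correlation structure between the five
random effects (the defaults are diagonal; the true between-horse
covariance is unknowable from published summaries). Passing recovery tests
therefore show that the pipeline is self-consistent under its own
assumptions — not that those assumptions hold for real plates.

## Numerical choices and degenerate inputs

* Truncated-normal draws use inverse-CDF sampling in log-probability space,
  stable even when a well's mean sits far above the detection limit; if the
  CDF underflows entirely the draw falls back to the bound.
* Reported masses and table values round half away from zero
  (`round_half_away()`), matching the source tables' 0.725 → 0.73 style;
  `base::round()`'s round-half-even would disagree on exact ties.
* An all-censored condition remains proper (the prior bounds it above) but
  is only weakly identified; its chains mix slowly and its interval is
  mostly prior-driven.
* Zero-data fits are legal and sample from the prior — used as a prior
  predictive check in the tests.
* `mcmc_config()` refuses settings that leave no saved draws; the sampler
  raises an error (with the iteration index) on a non-positive-definite
  conditional covariance rather than propagating NaNs.
* With ~75% of blank TNF-α wells below the detection limit at the default
  anchors, the blank posterior is left-skewed at 5 horses; ratio-scale
  contrasts against blank (the ~139-fold LPS response) are therefore noisy
  and right-skewed across replications, which is why the workflow reports
  their median over simulation replications.

## Problem sizes used by the tests and scripts

The test suite and the acceptance script run the sampler at desk scale,
chosen to keep the whole suite in minutes while leaving Monte-Carlo error
well below the tolerances being checked: the analytic-oracle comparison
uses 4 × 20,000 iterations of the fixed-effects sampler; parameter-recovery
checks use 10 simulated replications of the 5-horse oligosaccharide arm
(20 conditions, ~200 coverage events) with 2 × 6,000–10,000 iterations per
fit. At these lengths a few cell means in a few replications can show
$\hat R$ up to ≈1.5 (most often the censoring-dominated blank); the
reference-scale profile is available via `mcmc_config()` when a
publication-grade fit is wanted.

## Known limitations

* Separate models per analyte; any cross-cytokine correlation within wells
  is ignored (as in the source analysis, which reports analytes separately).
* The EU→ng endotoxin conversion reproduces the published convention
  (multiply EU/ml by 5 and 10) although the stated equivalence
  "1 ng = 5–10 EU", read literally, would divide; `eu_to_ng_range()`
  documents this and deliberately does not correct it.
* Significance is credible-interval exclusion per contrast; no multiplicity
  adjustment is applied (none was used in the source analysis).
* With three viability horses, power for the LPS-challenged viability
  contrasts is marginal; the unchallenged GOS/FOS/AOS increases are
  reliably detected, the challenged ones not always.
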
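---
title: "Site indicator values as predictors: models, simulation design, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site indicator values as predictors: models, simulation design, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eivsdm)
```

## The question the package answers

Species distribution models (SDMs) relate presence/absence records to
mapped environmental layers. When such a model explains little deviance,
two very different explanations compete: the species' distribution may be
intrinsically hard to predict from environment, or the available maps may
simply be poor proxies of the conditions the plants actually experience.
Community-mean ecological indicator values offer a way to separate the
two. Expert systems such as Landolt's or Ellenberg's assign each plant
species an ordinal score (1–5 here) along gradients of temperature (T),
soil moisture (M), light (L), continentality (K), soil reaction (R), and
nutrients (N). Averaging the scores of the species recorded at a
vegetation plot — the *site EIV* — gives a bio-assay of the local
conditions, integrated by the vegetation itself over years to decades.
If substituting a mapped predictor by the corresponding site EIV improves
an SDM, the map was missing signal the plants can see.

`eivsdm` implements that substitution experiment end to end: site-EIV
computation with leave-one-out exclusion of the focal species, five SDM
techniques behind one fit/predict contract, the 70/30 external plus
10-fold internal evaluation scheme with AUC/TSS/kappa/accuracy/explained
deviance, permutation variable importance with paired Wilcoxon–Holm
comparisons, and a repeated-cross-validation test of whether site EIVs
are themselves mappable from the environmental layers. Because the
interesting claims are causal ("the maps are the bottleneck"), the
package also ships a fully synthetic study system in which the true
local conditions are known and the map quality is controlled — so every
directional claim can be verified against ground truth.

## Circularity control: leave-one-out site EIVs

The focal species' own indicator values must never inform its own model.
`compute_site_eivs(x, eivs, focal_species = s)` therefore excludes `s`
from every plot mean, so each species is modelled against predictors
computed from the *other* members of its communities. Two consequences
are handled explicitly:

* a plot that only contained the focal species (on some dimension) loses
  its site EIV there; such plots are dropped from that species' model
  data rather than imputed;
* wherever the focal species is absent, the leave-one-out value equals
  the all-species value exactly — an identity the test suite asserts on
  thousands of random fixtures.

Species present in a survey but absent from the indicator table
contribute nothing and trigger a warning; dimension means use only
species scored on that dimension ("indifferent" species carry no score).
Site EIVs are kept as continuous means, never rounded back to the
ordinal scale.

## The modelling engines

All techniques consume a plot × predictor table and return suitabilities
in [0, 1]:

* **GLM** — binomial regression with linear and quadratic terms per
  predictor. Predictors are centred and scaled before squaring (limits
  collinearity between a variable and its square), and the fit carries a
  very small ridge penalty (`1e-6`, on a warm-start path) so perfectly
  separated data keep finite coefficients and a finite deviance.
* **GAM** — binomial model with univariate smooths, basis dimension 4
  (the classic low-rank setting for ecological response curves);
  predictors with too few distinct values fall back to linear terms.
* **RF** — a 500-tree probability forest; the presence-vote fraction is
  the score.
* **MAXENT** — a maximum-entropy-style L2-regularised binomial model
  (`lambda = 1e-3`) on the same linear + quadratic features. With
  presence/absence plots rather than presence-only records, the recorded
  absences play the role of background points.
* **SRE** — the surface range envelope: a two-sided quantile envelope
  (default 0.025 per side, linear-interpolation quantiles) of the
  presence points per predictor; a site scores 1 inside all envelopes,
  else 0.

These native engines follow the conventional defaults of the ecological
modelling literature; their exact hyperparameters are declared (and
configurable) rather than inferred from any particular legacy toolchain.

## Evaluation

Each species gets its own split scheme: 70% calibration / 30% external
evaluation (`floor(0.3 n)` plots), plus ten internal 70/30 re-splits of
the calibration set. External plots never enter any fitting step; the
runner enforces this and aborts on violation. Headline comparisons use
external metrics only.

AUC uses the Mann–Whitney pair formulation (ties count ½). TSS and kappa
are maximised exactly over every midpoint between consecutive distinct
scores plus the endpoints 0 and 1 — no threshold-grid resolution
parameter, and a score vector carrying no information yields 0 for both.
Accuracy is reported at the TSS-optimal threshold (a reporting choice,
recorded with the output). Explained deviance D² = 1 − Dev(model)/
Dev(null) is defined for the two deviance-based engines only; on an
evaluation subset the null deviance is recomputed on that subset, so
external D² is a pure evaluation-set quantity and may be negative.

Permutation importance follows the prediction-correlation convention:
shuffle one predictor column, re-predict, and report 1 minus the mean
Pearson correlation with the original predictions (mean clipped into
[0, 1]; ten permutations by default). Raw importances are kept as-is —
they need not sum to one — and are normalised only where a profile plot
or evenness summary requires it. Predictor sets are compared per species
with two-sided paired Wilcoxon signed-rank tests under a Holm step-down
correction; pairs whose differences are all zero get p = 1 by
convention.

## The substitution design

The reference predictor set `M_ref` holds six mapped layers (annual
temperature, soil pH, precipitation, topographic position, slope, solar
radiation — the standard topo-climatic sextet). Each substitution set
swaps one role for the corresponding site EIV: `M_T` (temperature → T),
`M_R`/`M_N`/`M_Soil` (pH → R, N, or N + R, the last having seven
predictors), `M_M` (precipitation → M), `M_K` (both topographic columns
→ K, five predictors), `M_L` (radiation → L), and `M_EIV` uses the six
site EIVs alone. `M_cor` instead selects, per indicator dimension, the
candidate layer with the highest absolute Spearman correlation to the
site EIV. To keep that screen out of the evaluation data it runs once on
a master-seeded 70% subset of all plots (a per-species screen would
define ten different `M_cor` sets; the single global screen is the
package's choice and is recorded in the run manifest). The moisture
indicator is written `M` throughout; `F`, its other customary letter, is
accepted on input as an alias.

## The synthetic study system

`simulate_study()` generates the default fixture: a 120 × 120 cell
mountain landscape, 250 virtual species, and 1,200 vegetation plots
(about 200 species end up with the >30 presences needed for modelling —
large enough for stable medians, small enough that the whole experiment
runs in minutes on one CPU; these problem sizes are stated here as the
package's defaults and scale up freely).

**Landscape.** Each of the six gradients is a Gaussian random field
(white noise convolved with a Gaussian kernel, standardised, affinely
rescaled to plausible units). Every *mapped* layer equals its latent
gradient plus a smoothed error field scaled to `k` latent-SDs, giving an
expected map fidelity of `1/sqrt(1 + k²)`. The defaults encode the
study design: the temperature map is exact (`k = 0`); precipitation
(`k = 2`) and radiation (`k = 2`) are poor proxies of moisture and
light; pH (`k = 1`) is a fair proxy of reaction; nutrients have no map
of their own but co-vary with reaction (ρ = 0.85), as soil nutrient
status does with pH in the field; and continentality is proxied only by
two nearly uninformative topographic layers (`k = 10` each). Smooth
random fields on a finite grid have few effective degrees of freedom, so
nominally independent gradients would often correlate at |r| ≈ 0.1–0.3
by chance; the generator therefore orthogonalises every latent gradient
and every map-error field against all previously generated fields,
making the configured correlations the *only* cross-gradient structure.

**Species.** Each species has a Gaussian niche per gradient: optimum
uniform over the gradient's range, breadth drawn per dimension (in
latent-SD units). Thermal filtering is strong (breadths 0.7–1.3 — the
elevation gradient sorts mountain plants sharply), continentality weak
(1.5–3), the rest intermediate (1.1–2.2). A species is actually
constrained by a non-thermal dimension only with some probability
(0.65–0.8 by dimension); an indifferent species has a flat response
there and, as in real indicator compilations, carries no score on that
dimension. Its indicator value on a constrained dimension is the ordinal
1–5 equal-width bin of its true optimum — an honest but coarse summary —
with 3% of scores additionally blanked. One further construction detail
matters: in a finite pool, randomly drawn optima leave chance smooth
dependence of, say, continentality scores on thermal optima; community
means inherit it, and an *exact* temperature map can then "predict" the
continentality site EIV for reasons unrelated to continentality. The
generator removes this by re-assigning each non-thermal dimension's
optima so that their spline dependence on the thermal optimum vanishes
while the uniform marginal is kept exactly (`balanced = TRUE`).

**Plots.** Grid cells are sampled without replacement; presence is
Bernoulli with `P = prevalence × Π_d exp(−(x_d − opt_d)²/(2σ_d²))`
evaluated on the **latent** gradients, while the plot predictor table is
filled from the **mapped** layers — the simulated field ecologist
measures reality only through imperfect maps. Default communities hold
about 25 species per plot, so site EIVs average enough scores to track
their gradients tightly where filtering is strong (site T vs latent
temperature r ≈ 0.97) and loosely where it is weak (site K r ≈ 0.7). An
optional per-group detection factor supports pooled surveys with
different plot sizes; it defaults to 1 (detection differences between
the pooled survey types are not modelled).

By construction, then: `M_EIV` must beat `M_ref` for most species (the
site EIVs see the hidden moisture/light/nutrient/reaction signal),
`M_T` must be near-neutral (replacing an exact map by a good bio-assay
of the same gradient), importance must spread more evenly under `M_EIV`
than in the temperature-dominated `M_ref`, and in the mappability
analysis T must come out best and K worst. The acceptance tests assert
exactly these four directional outcomes on the default fixture; the
probe-seed robustness of each was verified by simulation while the
generator defaults were being fixed, and the defaults have not moved
since.

## Mappability of the site EIVs

`cross_validate_eiv()` reads "25-fold cross-validation (70/30)" as 25
repeated random 70/30 splits — a literal 25-fold partition cannot be
70/30 — fitting Gaussian GLM (linear + quadratic), GAM, gradient-boosted
trees (500 trees, depth 3, learning rate 0.05) or a regression forest on
the training share and scoring Pearson r and RMSE on the held-out share.
Site EIVs here are all-species means: with no focal species there is
nothing to leave out. Repeats whose test fold is constant have an
undefined correlation; they are logged and excluded from the mean.

## Numerical choices and degenerate inputs

* Threshold metrics: classification is `score >= threshold`; the grid of
  candidate thresholds is exact (all midpoints plus 0 and 1), so
  maximised TSS and kappa are never negative.
* Deviance: predicted probabilities are clipped at 1e-12 before logs.
* Kappa with degenerate expected agreement (p_e = 1) is defined as 0;
  AUC requires both classes and refuses one-class label vectors.
* Constant predictor columns are retained with a message (their
  coefficients are effectively zero), so predictor sets keep their
  declared shape.
* Correlation-screen ties break by candidate column order (first wins),
  deterministically.
* All generators and the experiment runner are pure functions of
  (configuration, seed); per-species and per-fit seeds are derived from
  the master seed, and `reproduce_study()` re-runs the whole pipeline
  bit-identically from a result's manifest.
* 70/30 rounding puts `floor(0.3 n)` plots in the evaluation set.

## What passing tests do and do not show

The synthetic system emulates the statistical skeleton of a real
mountain vegetation survey — wide gradients, spatially autocorrelated
environment, ordinal expert scores tied to true optima, maps of unequal
fidelity — but not its full ecology: no dispersal limitation, no biotic
interactions, no abundance information, no observer error beyond the
detection factor, and indicator scores that are *correct by
construction* rather than expert judgements with idiosyncratic error.
Passing the recovery tests therefore shows that the pipeline's
machinery measures what it claims to measure when the causal story holds;
it does not by itself establish how large the map-quality effect is in
any real data set. Real relevé tables, indicator tables, and plot
predictor tables enter through `read_releve_table()` /
`read_species_eivs()` and run through the identical machinery. Raster
input/output uses plain ESRI ASCII grids; ensemble forecasting and
spatial projection maps are out of scope.
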
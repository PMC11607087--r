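---
title: "Partitioning individual dietary specialization: model, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning individual dietary specialization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Individuals of omnivorous, generalist species often occupy only a slice of
their population's dietary niche. In female brown bears this specialization
can be read from stable-nitrogen isotopes in annually regrown guard hair:
each hair sample integrates one foraging season, and repeated samples of
the same bear measure how consistently she eats high or low on the food
web. `dietspec` implements the full chain of analyses needed to ask *where
that consistency comes from*: social learning of the mother's diet during
rearing, the habitat composition of the home range, additive genetic
effects, other maternal effects, or permanent individual quirks — and a
synthetic-data generator with the same statistical anatomy so that every
stage can be verified by parameter recovery.

## Trophic position

A hair sample's d15N (permil vs AIR) is converted at ingest to a trophic
position relative to a strict-herbivore baseline (moose hair):

    TP = (d15N_bear - mean(d15N_moose)) / TEF + lambda

with trophic enrichment factor `TEF = 3.4` permil per trophic level and
`lambda = 2` (the baseline is a primary consumer). Both are
`trophic_config()` parameters. The conversion is affine, so any constant
baseline correction (for example a hair-to-meat offset) shifts every
trophic position by the same amount and leaves all variance components and
correlations untouched; accordingly no such correction is applied.
Downstream modules only ever see the `trophic_position` column, never raw
d15N. No bounds are enforced on TP — extreme values are data, not errors.

## The two-step model

**Step 1 (repeatability).** A Gaussian mixed model of trophic position on
a second-order polynomial of scaled age with an i.i.d. individual
intercept. Its variance-standardized individual component,
`V_I / (V_Age + V_I + V_R)`, is the headline measure of individual
specialization. Because it is ambiguous whether the fixed-effect (age)
variance belongs in the denominator, `repeatability()` reports both
`with_fixed` and `without_fixed` variants.

**Step 2 (the hybrid animal model).** The same response, with

* fixed effects: a second-order polynomial of scaled time since
  separation from the mother (age and time since separation are
  near-perfectly collinear in this design, so one stands in for the
  other), the mother's trophic position, and the interaction of maternal
  trophic position with (first-order) time since separation — the decay of
  social learning. A quadratic interaction is switchable
  (`quadratic_interaction = TRUE`) but off by default, since only the
  first-order decay is part of the core design;
* random effects: a permanent individual intercept, a mother-identity
  intercept, an additive genetic effect with covariance proportional to
  the pedigree relationship matrix **A**, and an environmental effect with
  covariance proportional to the habitat-similarity matrix **E** (or the
  spatial-distance matrix **S** in the alternative variant).

The "hybrid" part is deliberate: social learning enters as a *fixed*
effect of the maternal phenotype, so the maternal-identity *random* effect
pools only the resemblance among siblings that the mother's own diet does
not explain.

## Covariance structures

**A** is built by the tabular method over a validated, topologically
sorted pedigree; unknown parents are treated as unrelated founders. The
pedigree is pruned to phenotyped individuals plus their ancestors, and the
model uses the principal submatrix of **A** over the phenotyped ids — the
exact marginal covariance of their breeding values, so pruning loses
nothing.

**E** z-scores three home-range features — proportion mature forest,
proportion disturbed forest, Simpson habitat diversity — with equal
weight, takes pairwise Euclidean distances, and maps them to similarity by
`1 - d/max(d)`. The min-max alternative (normalising distance before
inversion) would deny near-identical pairs a similarity of 1, so the
linear transform is the default; both are simple to swap. **S** applies
the same transform to centroid distances, keeping the two variants
structurally parallel; the exact distance-to-covariance kernel for the
spatial variant is a documented package choice (a linear similarity), not
an inference about any particular prior analysis, and an exponential-decay
kernel could be substituted by the user.

Similarity matrices built this way are not automatically valid
covariances, so they are projected to the nearest positive semi-definite
matrix (`nearest_psd()`: eigenvalues clipped at 1e-8, reconstructed,
diagonal rescaled to 1, iterated a few times if the rescale reintroduces a
tiny negative eigenvalue). The sampler additionally inverts each
covariance through a symmetric eigendecomposition with a relative
eigenvalue floor of 1e-6, so near-singular projected matrices stay
numerically usable.

## Inference

`fit_hmm()` samples the posterior by a blocked Gibbs sampler written in
C++ (RcppArmadillo), using R's RNG throughout so every fit is bit-for-bit
reproducible under its seed.

*Priors.* `beta ~ Normal(0, (10 sd(y))^2)`; every standard deviation
(random effects and residual) gets half-Student-t(3, 0, 2.5 sd(y)),
implemented by the inverse-gamma scale-mixture so the variance updates
stay conjugate. These are the conventional weakly-informative defaults of
general-purpose Bayesian regression software, and both are configurable
via the `prior` argument.

*Mixing.* Variance components that share a grouping factor (individual,
genetic, environmental) compete for the same signal and mix slowly under
plain centred Gibbs, especially near zero. Three inexpensive, exact
remedies are built in: (1) a Gibbs "translation" move that exchanges
intercept mass between the fixed intercept and each random-effect block
mean (the likelihood is invariant, and both priors are Gaussian, so the
conditional of the shift is Gaussian); (2) an ancillary Metropolis move
that rescales `(sigma_k, u_k)` jointly on the log scale with the whitened
effects held fixed — this is the non-centred step that defuses the funnel
at small variances — with step sizes adapted toward 44% acceptance during
warmup only; (3) two full sweeps over the random-effect blocks per
iteration.

*Settings and gate.* Defaults are 4 chains x 6000 iterations, 3000
warmup, thinning 10 — 1200 retained draws. Split-Rhat and an
autocorrelation-based effective sample size (Geyer initial monotone
truncation) are computed for every fixed effect and variance component;
summarising functions refuse to run (without an explicit override) when
any Rhat >= 1.01 or any ESS <= 400.

## Variance decomposition

Per posterior draw, the fixed-effect contribution is the variance of the
fixed-only linear predictor across the observed design ("variance in
fitted values"); each random component contributes its sigma^2; the
residual its sigma^2_R; and proportions are taken of the total. Fixed
effects are split into an age group and a social-learning group (maternal
trophic position + interaction) by semi-partial contributions — the loss
in fitted-value variance when the group's coefficients are zeroed —
rescaled to sum exactly to the fixed-effect variance, which makes the
groups additive. With correlated covariates semi-partial contributions
can in principle go negative (classical suppression); the rescaling
preserves this, and no clamping is applied.

Summaries report the median, mean and 89% equal-tail interval (the 5.5th
to 94.5th percentile) of every proportion, and a component is flagged
*inconclusive* when its lower interval limit falls below 0.001 — the same
reporting conventions as the field analysis this package operationalises.
`nakagawa_r2()` adds marginal (fixed / total) and conditional
((fixed + random) / total) R-squared.

## Model comparison

`loo_elpd()` implements Pareto-smoothed importance-sampling leave-one-out
cross-validation from the pointwise log-likelihood matrix: the largest
`min(0.2 S, 3 sqrt(S))` importance ratios per observation are replaced by
expected order statistics of a generalized Pareto distribution fitted by
the Zhang–Stephens profile method, truncated at the raw maximum. Pareto-k
values above 0.7 attach a reliability warning. `compare_loo()` treats an
elpd difference below 4 as no preference, and the sex-specific analysis
then retains the *simplest* adequate model, so a sex main effect or
interaction must earn its keep.

## Permutation test for heritability

The reduced "basic animal model" (individual intercept + pedigree effect
only) is refitted on pedigrees whose dam–sire pairs are randomly
reassigned across sibships *within sibship-size classes* — this preserves
both the multiset of parent pairs and all litter sizes, while destroying
the alignment between relatedness and phenotype across families. The
p-value is the proportion of permuted fits whose genetic share of the
phenotypic variance (posterior median) reaches the observed one; the
`(b+1)/(m+1)` corrected version is reported alongside. Permuted fits use
half-length chains (only a point summary is needed) and are excluded,
counted, and reported when their split-Rhat exceeds 1.1 — a threshold
matched to the sampling noise of short chains rather than the strict 1.01
gate of headline fits.

Two properties of this test are worth knowing. Within-sibship structure
is never destroyed (full sibs stay full sibs), so power comes entirely
from across-family relatedness. And any pedigree-aligned non-genetic
covariance — maternal effects above all — inflates the *observed* genetic
share but not the permuted ones, making the test anticonservative in
exactly the situation the full model exists to disentangle. The
calibration experiment therefore simulates its null with individual and
residual variance only.

## The synthetic population

`sim_config()` defaults encode the study conditions: 33 founder mothers;
1–6 daughters each (median 2), with `target_daughters = 71` available for
exact-scale runs; 1–11 annual samples per individual (median 3,
`target_obs = 213`); a founder sire pool of 15 allowing paternal
half-sibs; mother centroids uniform over a 120 km square; daughters
settling at a lognormal distance from the natal centroid with median
8.56 km (sdlog 0.6, spanning roughly 1.4–28.8 km); habitat class
fractions from softmax-transformed Gaussian random fields with
exponential spatial correlation (range 20 km), Simpson diversity computed
from the full class set.

Variance components default to a phenotypic variance of 0.04 (SD 0.2
trophic-position units, matching individual medians spanning roughly half
a trophic position around a grand mean of 2.9) with shares: additive
genetic 3%, maternal 11%, environmental 5%, permanent individual 9%,
social learning ~13%, residual the remainder. The social-learning weight
declines linearly from `beta_sl = 1.6` at separation to zero at
`t_star = 5` years (an exponential decay is switchable); `beta_sl = 1.6`
is calibrated so that the realised social-learning share of phenotypic
variance sits near its 13% target given the maternal-phenotype variance
the other components imply. d15N values are back-computed by inverting
the trophic-position equation against the realised moose-baseline mean,
so ingest reproduces the simulated trophic positions exactly, and a
latent-value ledger makes every observation exactly reconstructable.

**What the generator does not emulate.** Mothers' own phenotypes carry
only their additive, environmental and permanent components — a mother's
*own* upbringing (her mother's maternal effect and the social learning
she received) is not modelled. Synthetic mothers are therefore less
repeatable than the real population's females, and with a median of ~3
samples each their model-estimated trophic positions are strongly
shrunken. Feeding those estimates into the animal model attenuates the
social-learning share well below its generating value. The
parameter-recovery experiment and the acceptance script consequently use
the generator's latent maternal values as the covariate
(`maternal_tp = "true"`), isolating the decomposition from
covariate-estimation error; the estimation route remains available
(`maternal_tp = "estimated"`) and is exercised by the analysis scripts.
Passing recovery under the true-covariate route demonstrates the
estimator, not the field-realism of two-stage covariate estimation at
these sample sizes. The generator also ignores demography (no deaths, no
immigration), movement within years, annual habitat change, and non-planar
geometry.

## Problem sizes used by the test-suite experiments

Chosen as desk-scale package defaults: parameter recovery runs 25
replicates at the study scale (71 daughters / 213 samples) and requires
each generating proportion inside its 89% interval in at least 80% of
replicates, plus an inconclusive flag when the generating genetic variance
is zero; the permutation-calibration experiment runs 30 zero-heritability
experiments x 50 permutations on a 40-daughter population with shortened
chains and checks uniformity of the p-values by a Kolmogorov–Smirnov test
at alpha 0.01; the PSIS-LOO check compares against exact refits at n = 8.

## Known limitations

* The individual, genetic and environmental components are weakly
  identified at n = 213 with 71 individuals; posteriors are wide and
  prior-influenced, and single-dataset point estimates scatter
  considerably around the truth even when coverage is nominal.
* The permutation test's anticonservatism under pedigree-aligned maternal
  structure (above) means its p-value should be read alongside the full
  model's decomposition, not instead of it.
* The two-stage maternal-covariate pipeline ignores the uncertainty of
  the maternal posterior medians; a joint model would propagate it but is
  out of scope here.
* Gaussian likelihood only, single response, and no estimated spatial
  range parameter — the spatial variant uses a fixed linear
  distance-to-similarity transform.
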
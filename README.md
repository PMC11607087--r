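# dietspec

Sources of individual dietary specialization from stable-isotope trophic
positions.

Long-lived omnivores — Scandinavian female brown bears are the motivating
system — differ consistently from one another in how high on the food web
they feed. Repeated stable-nitrogen-isotope (δ15N) measurements of
annually regrown hair turn that consistency into a quantitative trait:
the trophic position. `dietspec` is for behavioural and evolutionary
ecologists who want to ask *why* individuals specialize: does a daughter
eat like her mother because she learned from her during rearing, because
she settled in a similar home range, because she shares her genes, or
because of maternal effects beyond any of these? The package provides the
complete analysis chain — trophic-position conversion, pedigree and
habitat-similarity machinery, a Bayesian "animal model" sampler, variance
decomposition, model comparison, a permutation test for heritability — and
a synthetic multigenerational data generator with the same statistical
anatomy, so that every stage is verifiable by parameter recovery without
access to restricted field data.

## The model

Each hair sample converts to a trophic position against a
strict-herbivore baseline (moose hair):

    TP = (δ15N_bear − mean δ15N_moose) / 3.4 + 2

(3.4 ‰ per trophic level; the baseline feeds at level 2). Step one fits
the *basic* model — TP on a quadratic of scaled age with an individual
intercept — whose intraclass correlation `V_I / (V_Age + V_I + V_R)`
measures individual specialization. Step two partitions it with the
hybrid animal model

    TP_it = β0 + f(time since separation) + w(t)·TP_mother
            + a_i + m_i + u_i + p_i + ε_it

where `w(t)` carries the decaying fixed effect of the mother's phenotype
(social learning), `a ~ N(0, σ²_A A)` with **A** the pedigree additive
relationship matrix, `u ~ N(0, σ²_E E)` with **E** a habitat-similarity
matrix (or a spatial-distance variant **S**), `m` a mother-identity
intercept, and `p` a permanent individual intercept. Posterior draws from
a blocked Gibbs sampler (half-t priors on SDs; 4 chains × 6000
iterations, warmup 3000, thin 10 → 1200 draws; convergence gated at
Rhat < 1.01, ESS > 400) yield per-draw variance proportions
`V_Age, V_SL, V_I, V_E, V_A, V_M, V_R` of the phenotypic total,
summarised with 89% equal-tail intervals; components whose lower limit
falls below 0.1% are flagged inconclusive. PSIS-LOO compares the
sex-specific and paternal models; a pedigree-permutation test (dam–sire
pairs reshuffled across sibships) locates the observed genetic share in
its null distribution.

## Worked example

Simulate a population at the study's scale — 33 mothers, 71 daughters,
213 annual samples, philopatric settlement, habitat fields, variance
shares of 3% genetic / 11% maternal / 5% environment / 9% individual and
a decaying social-learning effect — then run the full pipeline and
compare with the generating truth:

```r
library(dietspec)

cfg <- sim_config(target_daughters = 71, target_obs = 213)
dat <- simulate_dataset(cfg, seed = 11)

est <- analyse_synthetic(dat, settings = mcmc_settings(seed = 11),
                         maternal_tp = "true")
est$decomp
#> posterior variance decomposition (proportions of V_P):
#>     component median  mean ci_low ci_high inconclusive
#>         V_Age  0.005 0.008  0.000   0.023         TRUE
#>          V_SL  0.092 0.096  0.028   0.183        FALSE
#>  V_individual  0.124 0.128  0.004   0.274        FALSE
#>      V_mother  0.034 0.050  0.001   0.150         TRUE
#>      V_animal  0.047 0.077  0.001   0.246         TRUE
#>         V_env  0.066 0.119  0.001   0.406         TRUE
#>    V_residual  0.531 0.522  0.338   0.667        FALSE

round(dat$true$proportions, 3)
#> social_learning          animal          mother             env
#>           0.140           0.030           0.109           0.049
#>      individual        residual
#>           0.089           0.583
```

Every generating proportion lies inside its 89% interval; the genetic
component (truth 3%) is correctly flagged inconclusive — the estimator
reports that n = 213 cannot distinguish so small an additive signal from
zero, which is itself the scientifically important output. The basic
model's repeatability for the same dataset prints as

```r
est$repeatability$summary
#>       component median  mean ci_low ci_high
#> 1    with_fixed  0.365 0.366  0.234   0.497
#> 2 without_fixed  0.369 0.369  0.236   0.500
```

## The analysis workflow

The `analysis/` directory holds the narrative pipeline, each script a
thin driver over package functions, writing its tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generate the synthetic study population (four CSV input tables + latent truth) |
| `02_trophic.R`  | δ15N → trophic position against the moose baseline |
| `03_matrices.R` | pedigree **A**, habitat **E**, spatial **S**; dispersal summaries |
| `04_fit_models.R` | maternal-TP population model; basic + animal model; spatial/reduced/sensitivity variants |
| `05_social_learning.R` | windowed mother–offspring correlations; sex-specific and paternal analyses |
| `06_permutation_power.R` | permutation null for the genetic component |
| `07_recovery.R` | quick parameter-recovery check |

Run them in order from the repository root
(`Rscript analysis/01_simulate.R`, ...).

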
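# braintraits

Bayesian dissection of which lifestyle traits uniquely explain gray-matter
volume variation in the 36 regions of the social brain atlas.

Population imaging cohorts pair structural MRI with rich questionnaire
data: dozens of binary lifestyle indicators covering social life,
personality and demographic standing. The scientific question this package
addresses is *attribution*: for a given brain region, which of 40
competing traits carries a unique association with its gray-matter volume,
in women and in men — not which traits correlate in isolation. It is aimed
at researchers analyzing region-level volumetric phenotypes against many
correlated binary predictors, and at methodologists who want a fully
synthetic, ground-truth-equipped testbed for that analysis.

## The model

For region *j* with participants grouped by sex *g*:

    y_j = beta0[g] + x_1 * beta_1[g] + ... + x_40 * beta_40[g]
          + z(age) * beta_age[g] + eps_j

    beta_i[g] ~ Normal(mu_i, tau_i^2)   mu_i ~ Normal(0, 1)
    tau_i ~ HalfCauchy(1)               sigma ~ HalfCauchy(5)
    eps_j ~ Normal(0, sigma)

with y_j the standardized, deconfounded (head size, BMI) region volume and
x_i the median-split binary traits. Each trait's male and female
coefficients are partially pooled through a shared location/dispersion
prior. Inference is MCMC — a blocked Gibbs sampler drawing the entire
84-coefficient vector jointly from its exact Gaussian conditional, with
the half-Cauchy scales handled by their inverse-gamma mixture — run as
4 chains of 5000 draws, the first 4000 discarded, convergence required at
split R-hat < 1.02. Downstream summaries include 95% highest-density
intervals, per-region dominant traits (largest |posterior mean|),
draw-wise female−male contrasts and bias counts, joint age-trait posterior
clouds, posterior predictive R² (500 candidate models), a partial-volume
reanalysis isolating each region's unique variance, and split-sample
replication. The methods vignette
(`vignettes/methods.Rmd`) documents every modeling choice and limitation.

## Worked example

```r
library(braintraits)

atlas  <- load_atlas()          # 36 regions, MNI coordinates, 4 networks
traits <- load_trait_table()    # 40 binary indicators, sex-wise prevalences

# a synthetic cohort with known ground truth (ages 40-69, 52.4% female,
# planted trait effects of 0.03-0.08 per region)
sim    <- simulate_cohort(n = 2000, seed = 1)
vol    <- simulate_region_volumes(sim, sim$truth, atlas, seed = 1)
vol    <- residualize_confounds(vol, cbind(head_size = sim$cohort$head_size,
                                           bmi = sim$cohort$bmi))
design <- build_design(sim$cohort, traits)

fit <- fit_region(vol$values[, "vmPFC"], design, model_config(seed = 1),
                  region_id = "vmPFC")
check_convergence(fit)
#> Max split R-hat 1.0126 (threshold 1.020): PASS
#>       age      beta intercept        mu     sigma       tau
#>    1.0002    1.0064    1.0006    1.0022    0.9999    1.0126

summ <- summarize_fit(fit)
fem  <- summ[summ$sex == "female", ]
head(fem[order(-abs(fem$posterior_mean)), 
         c("trait_id", "posterior_mean", "hpdi_low", "hpdi_high")], 3)
#>                trait_id posterior_mean hpdi_low hpdi_high
#> 58      fed_up_feelings         -0.160 -0.28047   -0.0479
#> 76 walking_standing_job          0.150 -0.00165    0.2829
#> 56         irritability          0.132 -0.01437    0.2825

posterior_predictive_r2(fit, vol$values[, "vmPFC"], design)[c("r2_total",
                                                              "r2_male",
                                                              "r2_female")]
#> $r2_total  0.0504...   $r2_male  0.0557...   $r2_female  0.0443...
```

Reading the output: the maximum split R-hat (1.013, driven by the
dispersion scales `tau`) certifies mixing under the default protocol. Each
trait row gives the marginal association of that trait with vmPFC volume
for women, conditional on the other 39 traits and age, with its 95% HPDI —
at n = 2000 the intervals are ~0.28 wide, so the top-ranked traits here
are sampling noise around the small planted effects (the generator's true
dominant trait for this seed, `breastfed_as_infant`, carries only ~0.07);
the interval widths are the honest statement of that uncertainty. The
posterior predictive R² puts the variance explained by all traits plus age
at ~5% in-sample. The same calls scale unchanged to the full
36-region × n = 10,000 analysis via `run_pipeline()`, and
`partial_residualize()` feeds the identical machinery the region-unique
volume residuals.

A thin command-line wrapper over these functions ships in
`inst/cli/braintraits.R` (subcommands `simulate` and `run`).

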
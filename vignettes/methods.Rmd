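---
title: "Dissecting trait-volume associations in the social brain: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting trait-volume associations in the social brain: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Given a large population cohort with (a) 36 standardized gray-matter volume
variables extracted at the consensus coordinates of the social brain atlas
and (b) 40 binary lifestyle indicators spanning social, personality and
demographic domains, which traits *uniquely* explain volume variation in
each region, and how do these associations differ between women and men?
`braintraits` implements the full analysis chain as reusable, tested
functions, together with a synthetic-cohort generator whose ground truth
makes every stage verifiable.

## The model

For each region $j$, the standardized (and deconfounded) volume $y_j$ is
modeled as a multiple regression on all 40 binary traits plus z-scored age,
with every coefficient indexed by sex group $g$:

$$y_j = \beta^{(j)}_{0[g]} + \sum_{i=1}^{40} x_i \beta^{(j)}_{i[g]}
      + z(\mathrm{age})\,\beta^{(j)}_{\mathrm{age}[g]} + \varepsilon_j,
  \qquad \varepsilon_j \sim \mathcal N(0, \sigma_j)$$

Priors follow a trait-level hierarchy: each trait's male and female
coefficients share a location $\mu_i \sim \mathcal N(0, 1)$ and dispersion
$\tau_i \sim \mathrm{HalfCauchy}(1)$, with
$\beta_{i[g]} \sim \mathcal N(\mu_i, \tau_i^2)$; intercepts and age
coefficients are $\mathcal N(0,1)$, and
$\sigma \sim \mathrm{HalfCauchy}(5)$. The hierarchy partially pools the
sexes per trait: sex differences are estimated, not assumed, and the amount
of pooling adapts to the data. Because each coefficient quantifies a
trait's association *conditional on the other 39 traits and age*, these
are marginal (partial) associations, not simple correlations.

Two deliberate design choices, made where the design was genuinely open:

* **One joint model per region**, with sex-indexed coefficients under the
  shared trait-level prior, rather than two separate per-sex fits. The
  group-indexed coefficient notation together with a location/dispersion
  prior pair reads most naturally as a grouped hierarchical coefficient,
  and a joint model gives exact draw-wise female−male contrasts.
* **The age coefficient is also sex-indexed** (a shared-age variant is
  available via `model_config(shared_age = TRUE)`), because the sex-specific
  joint age-trait posterior clouds are a reported output; a shared age
  coefficient would make that contrast undefined.

## Inference: a blocked Gibbs sampler with exact conditional updates

Posterior inference uses Markov chain Monte Carlo with the canonical
protocol: 5000 draws per chain, the first 4000 discarded, 4 chains, and
split R-hat required to stay below 1.02 (10,000 draws with 8,000 discarded
for the partial-volume reanalysis, where the signal is weaker). The sampler
is a blocked Gibbs scheme in which

* the full coefficient vector (84 entries: 2 intercepts, 2 age terms,
  80 sex-indexed trait terms) is drawn *jointly* from its exact
  multivariate-Gaussian conditional via the Cholesky factor of the
  posterior precision. Cross-products $W^\top W$, $W^\top y$, $y^\top y$
  are precomputed once, so per-iteration cost is independent of the number
  of participants;
* the half-Cauchy scales are sampled through the inverse-gamma mixture
  representation ($\tau \sim \mathrm{HC}(A) \iff \tau^2 \mid a \sim
  \mathrm{IG}(\tfrac12, 1/a),\ a \sim \mathrm{IG}(\tfrac12, 1/A^2)$), which
  keeps every hyperparameter update conjugate.

Joint coefficient updates make the chain mix well despite the hierarchy:
the slowest-mixing parameters are the 40 dispersion scales $\tau_i$, whose
split R-hat stays around 1.01–1.02 under the default protocol on cohorts of
2,000–10,000. Chains start from overdispersed initializations (ridge
solution plus chain-specific jitter; dispersions log-uniform), so R-hat is
an honest diagnostic. Everything is deterministic given `seed`: chain
streams are derived from it, and identical configurations reproduce
retained draws bit for bit.

The sampler's correctness is validated against an *analytic oracle*: with
the hierarchy disabled and $\sigma$ fixed, the model has the closed-form
Gaussian posterior $\mathcal N(A^{-1}X^\top y/\sigma^2, A^{-1})$,
$A = X^\top X/\sigma^2 + I/s^2$, and the MCMC means and SDs are required to
match it within Monte-Carlo error (`conjugate_oracle()`).

## From images to variables

The imaging path mirrors standard volumetric practice: each participant
image is smoothed with a 5 mm FWHM Gaussian
($\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$, kernel truncated at $4\sigma$,
mirror-reflected at borders so constants and impulse mass are preserved),
then averaged over all voxel centers within 2.5 mm (inclusive) of each
region's MNI coordinate — "5 mm" names the sphere *diameter*, with 2.5 and
7.5 mm as sensitivity alternatives — and finally z-scored per region using
the population (divide-by-$n$) convention so results are bit-reproducible.
MNI-to-voxel mapping goes through the (diagonal) image affine; nonlinear
registration is an upstream concern and out of scope. Head size and BMI are
removed from each region column by ordinary least-squares residualization
with intercept (z-scoring the confounds first only conditions the solve;
it does not change residuals). Age is *not* residualized — it is a model
covariate. Raw ordinal traits are binarized by median split with ties
assigned to the low group.

## The partial-volume reanalysis

To isolate each region's unique variation, region $j$'s z-scored column is
replaced by its least-squares residual on the 35 remaining region columns
before refitting the same trait model. The residuals are exactly orthogonal
to every *other region's original column* — that is the defining property —
and are deliberately left un-rescaled: their shrunken scale is why the
partial analysis reports visibly smaller coefficients (~0.005–0.02 rather
than ~0.03–0.08). One caveat worth stating precisely: residuals of such
mutual regressions are *not* mutually uncorrelated. A precision-matrix
identity makes the correlation of two residual columns equal to minus their
partial correlation, so a genuinely planted network factor leaves a small
negative footprint (about $-\rho/(1+(m{-}2)\rho)$ for $m$ equicorrelated
regions; ≈ −0.04 for the default generator). The shared positive
within-network structure is removed; exact mutual decorrelation is
mathematically unattainable for this construction, and tests assert the
former, not the latter.

## The synthetic generator and what it does (not) emulate

`simulate_cohort()` draws ages from Normal(55, 7.5) truncated to [40, 69]
by inverse CDF (note the *realized* SD of a doubly truncated normal is
≈ 6.5 years; 7.5 is the parent-distribution parameter), sex as
Bernoulli(female = 0.524), BMI from truncated-positive Normal(26.7, 4.3),
a sex-shifted head-size proxy (male 1200 ± 110, female 1050 ± 100, arbitrary
units), and every trait as Bernoulli with its packaged sex-specific
prevalence. Traits are independent by default — no trait-trait dependence
structure is published — with an opt-in within-domain Gaussian copula
(`copula_rho`) that preserves the marginal prevalences exactly.

`simulate_region_volumes()` realizes the linear model above, adding
confound effects, one shared standard-normal latent factor per atlas
network (default loading 0.25, giving the within-network residual
correlation the partial stage exists to remove), and Gaussian noise.
Planted trait effects default to the 0.03–0.08 standardized range reported
for real cohorts, with one clearly dominant trait per region (0.06–0.08)
placed on moderate-prevalence traits (both-sex prevalence in [0.2, 0.8]),
plus two minor effects (0.03–0.04). The `r2-target` scenario rescales all
systematic effects so the analytic explained-variance fraction
(`true_r2`, exact for independent traits, Monte-Carlo under the copula)
hits a requested value — the basis of the posterior-predictive calibration
tests. The generator does not attempt realistic image appearance, scanner
artifacts, motion, nonlinear anatomy, or non-Gaussian volume distributions;
passing tests demonstrate correctness of the *statistical machinery* under
the assumed generative family, not robustness to real-data violations.

## Reported quantities

* **HPDI** (`hpdi()`): shortest contiguous interval over sorted draws
  containing `ceiling(mass * n)` samples, ties broken toward the lower
  window — the highest-density definition, not equal-tailed.
* **Dominant trait** (`dominant_trait()`): argmax of |posterior mean|
  across the 40 traits for one region and sex; sign-blind; exact ties go to
  canonical order with a warning. A recovery caveat: with effects capped
  near 0.08 and 40 competitors, coefficients of extreme-prevalence null
  traits carry sampling error of the same order (≈ 0.04–0.06 per sex at
  n = 10,000), so argmax identification of a planted dominant trait is
  unreliable at cohort sizes of 2,000–10,000. The corresponding acceptance
  check is implemented at its stated scale and documents this limit rather
  than relaxing it.
* **Sex contrasts** (`sex_contrast()`, `sex_bias_count()`): draw-wise
  female − male differences on identically indexed retained draws;
  per-region counts of positive / negative contrast means; exact zeros
  count as neither. Detecting a 0.06 sex asymmetry at 95% interval level
  needs a contrast SE well under 0.03, i.e. cohorts well above 10,000 — the
  recovery test runs at 40,000 with a compact trait set for exactly this
  reason.
* **Joint age-trait posteriors** (`joint_age_trait()`): per-sex
  (age, trait) draw clouds plus a Bhattacharyya coefficient of
  moment-matched Gaussians (1 = identical, 0 = disjoint) operationalizing
  "largely divergent" descriptions; the threshold is reported, never
  hard-coded into conclusions.
* **Posterior predictive R²** (`posterior_predictive_r2()`): 500 candidate
  models evenly thinned from the retained draws; R² compares observed
  volumes with the mean linear predictor (a per-replicate R² distribution
  is available behind `per_draw = TRUE`); sex-specific values reuse the
  joint fit on observation subsets. No multiple-comparison correction is
  applied anywhere — reporting is fully Bayesian (posterior summaries),
  which is a property users should be aware of when scanning 36 × 40 × 2
  intervals.
* **Split-sample replication** (`split_replicate()`): disjoint random
  splits, full pipeline refit per split, Pearson correlation between
  concatenated posterior-mean vectors (regions × traits × sexes) against
  the full-data reference; the split assignment and seeds are recorded for
  exact reruns.

## Numerical choices and degenerate inputs

Z-scoring refuses zero-variance columns (`degenerate_column`); median
splits refuse constant traits; confound and region-column collinearity
raise `rank_deficient`; sphere extraction raises on coordinates outside the
grid or spheres containing no voxel center; HPDIs require ≥ 50 draws.
Convergence failures are classed warnings by default (a 36-region batch
should finish and report) and fatal under `strict = TRUE`. The residual
sum of squares inside the sampler is computed from precomputed
cross-products and clamped at a tiny positive floor; dispersion draws are
floored at $10^{-6}$ in scale to avoid exact zeros.

## Problem sizes used by the test-suite

The suite exercises the full protocol (5000/4000 × 4 chains) where a
criterion is about that protocol (convergence, posterior-predictive
calibration), and reduced designs elsewhere: cohorts of 2,000 for recovery
replicates with 1,000–2,500 draws over 2–4 chains, 10,000 for calibration
checks, 100,000 once for the analytic-moment oracle of the generator, and a
compact 8-trait table with small region subsets for end-to-end and
replication paths. These sizes are stated here as the package's validation
design; all of them are honest miniatures of the full 36 × 40 × 10,000
analysis, which `run_pipeline()` executes unchanged.

## Known limitations

* The sampler is specialized to this model family (Gaussian likelihood,
  grouped-coefficient hierarchy); it is not a general-purpose MCMC engine.
* Ground-truth `true_r2` is analytic only for independent traits; under
  the copula it is a fixed-seed Monte-Carlo estimate.
* The imaging path assumes isotropic, axis-aligned (diagonal-affine)
  grids; rotated or sheared affines are rejected rather than resampled.
* Dominant-trait identification and sex-contrast detection are
  power-limited at realistic effect sizes, as quantified above; the package
  reports uncertainty rather than overstating identification.
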
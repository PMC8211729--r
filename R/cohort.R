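# Synthetic cohort generator: the stand-in for the (restricted) population
# imaging cohort. Defaults reproduce the published demographic structure:
# ages truncated-Normal(55, 7.5) on [40, 69], 52.4% female, BMI 26.7 (4.3),
# and per-trait Bernoulli prevalences from the packaged taxonomy.

#' Scenario configuration for the synthetic generator
#'
#' @param scenario One of \code{"paper-like"} (a handful of planted effects
#'   per region in the 0.03-0.08 standardized range, one clearly dominant
#'   trait per region), \code{"null"} (all trait and age effects zero),
#'   \code{"vmPFC-dominant"} (a single 0.067 health-satisfaction effect for
#'   women in vmPFC, all competing effects at most 0.03), or
#'   \code{"r2-target"} (effects scaled so each region's explained-variance
#'   fraction equals \code{target_r2}).
#' @param effect_range Magnitude range for planted minor effects.
#' @param dominant_range Magnitude range for the planted dominant effect.
#' @param n_minor_effects Number of additional non-dominant planted traits
#'   per region in the \code{"paper-like"} scenario.
#' @param target_r2 Explained-variance fraction for \code{"r2-target"}.
#' @param copula_rho Within-domain latent (Gaussian-copula) correlation of
#'   trait indicators; 0 (default) draws traits independently.
#' @param network_loading Loading of the shared per-network latent factor on
#'   every region of that network; gives the volume matrix the
#'   within-network residual correlation that the partial-volume stage
#'   removes.
#' @param noise_sd Residual standard deviation of each region volume.
#' @param confound_gammas Length-2 vector: effects of (z-scored) head size
#'   and BMI on every region volume.
#' @param beta_age Age effect (per SD of age), applied to both sexes.
#' @param female_fraction,age_mean,age_sd,age_range,bmi_mean,bmi_sd
#'   Demographic parameters of the emulated cohort.
#' @param beta Optional explicit region x trait x sex effect array,
#'   overriding the named scenario.
#' @return A list of class \code{"generation_config"}.
#' @export
generation_config <- function(scenario = c("paper-like", "null", "vmPFC-dominant", "r2-target"),
                              effect_range = c(0.03, 0.04),
                              dominant_range = c(0.06, 0.08),
                              n_minor_effects = 2L,
                              target_r2 = 0.10,
                              copula_rho = 0,
                              network_loading = 0.25,
                              noise_sd = 1,
                              confound_gammas = c(head_size = 0.15, bmi = 0.10),
                              beta_age = -0.08,
                              female_fraction = 0.524,
                              age_mean = 55, age_sd = 7.5, age_range = c(40, 69),
                              bmi_mean = 26.7, bmi_sd = 4.3,
                              beta = NULL) {
  scenario <- match.arg(scenario)
  if (!all(is.finite(effect_range)) || !all(is.finite(dominant_range)))
    bt_stop("scenario effect sizes must be finite", "validation")
  if (copula_rho < 0 || copula_rho >= 1)
    bt_stop("copula_rho must lie in [0, 1)", "validation")
  structure(list(scenario = scenario, effect_range = effect_range,
                 dominant_range = dominant_range,
                 n_minor_effects = as.integer(n_minor_effects),
                 target_r2 = target_r2, copula_rho = copula_rho,
                 network_loading = network_loading, noise_sd = noise_sd,
                 confound_gammas = confound_gammas, beta_age = beta_age,
                 female_fraction = female_fraction,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd, beta = beta),
            class = "generation_config")
}

# Traits with both-sex prevalence in [0.2, 0.8] carry planted effects:
# binary indicators near even split are the informative carriers for a
# recovery benchmark, and the published dominant effects sit on such traits.
moderate_prevalence_traits <- function(trait_table, lo = 0.2, hi = 0.8) {
  ok <- trait_table$prev_male >= lo & trait_table$prev_male <= hi &
    trait_table$prev_female >= lo & trait_table$prev_female <= hi
  trait_table$trait_id[ok]
}

#' Ground truth of a generation scenario
#'
#' Builds the true effect arrays realized by [simulate_region_volumes()].
#' The returned object is consumed by recovery tests only; the model never
#' sees it.
#'
#' @param config A [generation_config()].
#' @param trait_table Trait taxonomy ([load_trait_table()]).
#' @param atlas Atlas ([load_atlas()]).
#' @param seed Integer seed controlling which traits carry planted effects.
#' @return List of class \code{"ground_truth"} with elements \code{beta}
#'   (region x trait x sex), \code{beta_age} (region x sex),
#'   \code{confound_gammas} (region x 2), \code{network_loading},
#'   \code{noise_sd}, \code{dominant_trait} (per region, \code{NA} if none)
#'   and \code{true_r2}, the analytic explained-variance fraction of the
#'   trait-plus-age linear predictor net of confounds.
#' @export
make_ground_truth <- function(config, trait_table, atlas, seed = 1L) {
  traits <- trait_table$trait_id
  regions <- atlas_region_ids(atlas)
  nt <- length(traits); nr <- length(regions)
  beta <- array(0, dim = c(nr, nt, 2),
                dimnames = list(regions, traits, c("male", "female")))
  dominant <- rep(NA_character_, nr); names(dominant) <- regions
  set.seed(as.integer(seed))
  pool <- moderate_prevalence_traits(trait_table)
  if (!is.null(config$beta)) {
    if (!identical(dim(config$beta), dim(beta)))
      bt_stop("explicit beta array must be region x trait x sex", "dimension")
    beta[] <- config$beta
    for (j in seq_len(nr)) {
      mag <- pmax(abs(beta[j, , 1]), abs(beta[j, , 2]))
      if (any(mag > 0)) dominant[j] <- traits[which.max(mag)]
    }
  } else if (config$scenario == "paper-like" || config$scenario == "r2-target") {
    for (j in seq_len(nr)) {
      picked <- sample(pool, 1L + config$n_minor_effects)
      dom <- picked[1L]
      dominant[j] <- dom
      dom_effect <- stats::runif(1, config$dominant_range[1], config$dominant_range[2])
      beta[j, dom, ] <- dom_effect
      for (tr in picked[-1L]) {
        eff <- stats::runif(1, config$effect_range[1], config$effect_range[2]) *
          sample(c(-1, 1), 1)
        beta[j, tr, ] <- eff
      }
    }
  } else if (config$scenario == "vmPFC-dominant") {
    beta["vmPFC", "health_satisfaction", "female"] <- 0.067
    beta["vmPFC", "health_satisfaction", "male"] <- 0.03
    beta["vmPFC", "income", ] <- 0.03
    dominant["vmPFC"] <- "health_satisfaction"
  } # "null": all zeros

  age_eff <- if (config$scenario == "null") 0 else config$beta_age
  beta_age <- matrix(age_eff, nr, 2, dimnames = list(regions, c("male", "female")))
  gam <- matrix(rep(config$confound_gammas, each = nr), nr, 2,
                dimnames = list(regions, c("head_size", "bmi")))
  loading <- rep(config$network_loading, nr); names(loading) <- regions
  noise <- rep(config$noise_sd, nr); names(noise) <- regions

  truth <- structure(list(beta = beta, beta_age = beta_age, confound_gammas = gam,
                          network_loading = loading, noise_sd = noise,
                          dominant_trait = dominant, scenario = config$scenario,
                          copula_rho = config$copula_rho,
                          female_fraction = config$female_fraction),
                     class = "ground_truth")
  truth$true_r2 <- compute_true_r2(truth, trait_table)

  if (config$scenario == "r2-target") {
    # rescale all systematic effects so the signal fraction hits target_r2
    truth <- rescale_to_r2(truth, trait_table, config$target_r2)
  }
  truth
}

# Explained-variance fraction of the trait + age linear predictor, net of
# confounds (which the preprocessing stage removes): within-sex trait
# variance sum + between-sex mean shift, over that plus the shared network
# factor and residual noise. Exact for independent Bernoulli traits; a
# Monte-Carlo estimate is substituted when a trait copula is active.
compute_true_r2 <- function(truth, trait_table) {
  wf <- truth$female_fraction; wm <- 1 - wf
  pm <- trait_table$prev_male; pf <- trait_table$prev_female
  nr <- nrow(truth$beta)
  if (truth$copula_rho > 0) {
    vm <- mc_trait_moments(trait_table, truth$copula_rho, "male")
    vf <- mc_trait_moments(trait_table, truth$copula_rho, "female")
  }
  r2 <- numeric(nr)
  for (j in seq_len(nr)) {
    bm <- truth$beta[j, , "male"]; bf <- truth$beta[j, , "female"]
    if (truth$copula_rho > 0) {
      var_m <- drop(t(bm) %*% vm %*% bm)
      var_f <- drop(t(bf) %*% vf %*% bf)
    } else {
      var_m <- sum(pm * (1 - pm) * bm^2)
      var_f <- sum(pf * (1 - pf) * bf^2)
    }
    var_within <- wm * (var_m + truth$beta_age[j, "male"]^2) +
      wf * (var_f + truth$beta_age[j, "female"]^2)
    var_between <- wm * wf * (sum(pm * bm) - sum(pf * bf))^2
    signal <- var_within + var_between
    r2[j] <- signal / (signal + truth$network_loading[j]^2 + truth$noise_sd[j]^2)
  }
  names(r2) <- rownames(truth$beta)
  r2
}

mc_trait_moments <- function(trait_table, rho, sex, n = 50000L) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(902114L)
  x <- draw_traits(n, trait_table, rho, sex)
  stats::cov(x) * (n - 1) / n
}

rescale_to_r2 <- function(truth, trait_table, target) {
  if (target < 0 || target >= 1) bt_stop("target_r2 must lie in [0, 1)", "validation")
  noise_var <- truth$network_loading^2 + truth$noise_sd^2
  for (j in seq_len(nrow(truth$beta))) {
    if (target == 0) {
      truth$beta[j, , ] <- 0; truth$beta_age[j, ] <- 0
      next
    }
    r2j <- truth$true_r2[j]
    signal <- r2j / (1 - r2j) * noise_var[j]
    want <- target / (1 - target) * noise_var[j]
    s <- sqrt(want / signal)
    truth$beta[j, , ] <- truth$beta[j, , ] * s
    truth$beta_age[j, ] <- truth$beta_age[j, ] * s
  }
  truth$true_r2 <- compute_true_r2(truth, trait_table)
  truth
}

# Truncated-normal draws by inverse CDF: deterministic under seed, no
# rejection loop.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd); phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# n x n_traits binary matrix for one sex; equicorrelated Gaussian copula
# within each trait domain when rho > 0 (marginal prevalences preserved).
draw_traits <- function(n, trait_table, rho, sex) {
  p <- if (sex == "male") trait_table$prev_male else trait_table$prev_female
  nt <- nrow(trait_table)
  if (rho <= 0) {
    x <- matrix(stats::rbinom(n * nt, 1L, rep(p, each = n)), n, nt)
  } else {
    z <- matrix(stats::rnorm(n * nt), n, nt)
    for (d in unique(trait_table$domain)) {
      idx <- which(trait_table$domain == d)
      common <- stats::rnorm(n)
      z[, idx] <- sqrt(rho) * common + sqrt(1 - rho) * z[, idx]
    }
    thr <- stats::qnorm(1 - p)
    x <- 1L * (z > matrix(thr, n, nt, byrow = TRUE))
  }
  colnames(x) <- trait_table$trait_id
  x
}

#' Simulate a participant cohort with known ground truth
#'
#' Draws ages from Normal(55, 7.5) truncated to [40, 69], sex as
#' Bernoulli(female = 0.524), BMI from truncated-positive Normal(26.7, 4.3),
#' a sex-shifted head-size proxy, and each binary trait from its
#' sex-specific packaged prevalence (optionally with a within-domain
#' Gaussian-copula correlation).
#'
#' @param n Number of participants (>= 2).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param trait_table Trait taxonomy.
#' @param config A [generation_config()].
#' @param atlas Atlas used to shape the ground-truth effect arrays.
#' @return A list of class \code{"cohort_sim"}: \code{cohort} (data.frame
#'   of class \code{"cohort_table"} with \code{participant_id},
#'   \code{age_years}, \code{sex}, \code{head_size}, \code{bmi} and one
#'   column per trait) and \code{truth} (a \code{"ground_truth"}).
#' @export
simulate_cohort <- function(n, seed, trait_table = load_trait_table(),
                            config = generation_config(), atlas = load_atlas()) {
  n <- stopifnot_scalar_count(n, "n")
  if (n < 2) bt_stop("n must be at least 2", "validation")
  truth <- make_ground_truth(config, trait_table, atlas, seed = seed)
  set.seed(as.integer(seed) + 1L)
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_range[1], config$age_range[2])
  bmi <- rtruncnorm(n, config$bmi_mean, config$bmi_sd, 0, Inf)
  head_size <- ifelse(sex == "male",
                      stats::rnorm(n, 1200, 110), stats::rnorm(n, 1050, 100))
  x <- matrix(0L, n, nrow(trait_table),
              dimnames = list(NULL, trait_table$trait_id))
  for (s in c("male", "female")) {
    idx <- which(sex == s)
    if (length(idx)) x[idx, ] <- draw_traits(length(idx), trait_table,
                                             config$copula_rho, s)
  }
  cohort <- data.frame(participant_id = seq_len(n), age_years = age, sex = sex,
                       head_size = head_size, bmi = bmi, check.names = FALSE)
  cohort <- cbind(cohort, as.data.frame(x, check.names = FALSE))
  class(cohort) <- c("cohort_table", "data.frame")
  validate_cohort(cohort, trait_table)
  structure(list(cohort = cohort, truth = truth, seed = seed,
                 config = config), class = "cohort_sim")
}

validate_cohort <- function(cohort, trait_table = NULL) {
  if (anyNA(cohort)) bt_stop("cohort contains missing values", "validation")
  if (!all(cohort$sex %in% c("male", "female")))
    bt_stop("sex must be 'male' or 'female'", "validation")
  ids <- if (is.null(trait_table)) cohort_trait_ids(cohort) else trait_table$trait_id
  xm <- as.matrix(cohort[, ids, drop = FALSE])
  if (!all(xm %in% c(0L, 1L)))
    bt_stop("trait indicators must be strictly 0/1", "validation")
  invisible(cohort)
}

cohort_trait_ids <- function(cohort) {
  setdiff(names(cohort), c("participant_id", "age_years", "sex", "head_size", "bmi"))
}

#' Simulate region volumes from a cohort and a ground truth
#'
#' Realizes, per participant p and region j,
#' \deqn{y_{pj} = \sum_i x_{pi}\beta_{ji[g(p)]} + z(age_p)\beta^{age}_{j[g(p)]}
#'   + \gamma_{head} z(head_p) + \gamma_{bmi} z(bmi_p)
#'   + \lambda_j f_{net(j),p} + \varepsilon_{pj}}
#' with one shared standard-normal latent factor per atlas network (giving
#' the within-network residual correlation that the partial-volume stage is
#' designed to remove) and \eqn{\varepsilon \sim N(0, \sigma_j)}.
#'
#' @param cohort A \code{cohort_table} (or a \code{cohort_sim}).
#' @param truth A \code{ground_truth} whose dimensions match the atlas and
#'   the cohort's trait columns.
#' @param atlas Atlas defining region order and networks.
#' @param seed Integer seed for the stochastic terms.
#' @return A \code{region_volume_matrix} (unstandardized).
#' @export
simulate_region_volumes <- function(cohort, truth, atlas, seed) {
  if (inherits(cohort, "cohort_sim")) cohort <- cohort$cohort
  regions <- atlas_region_ids(atlas)
  traits <- dimnames(truth$beta)[[2]]
  if (!identical(rownames(truth$beta), regions))
    bt_stop("ground truth regions do not match atlas", "dimension")
  if (!all(traits %in% names(cohort)))
    bt_stop("ground truth traits do not match cohort columns", "dimension")
  n <- nrow(cohort); nr <- length(regions)
  x <- as.matrix(cohort[, traits, drop = FALSE])
  age_z <- as.numeric(scale(cohort$age_years))
  head_z <- as.numeric(scale(cohort$head_size))
  bmi_z <- as.numeric(scale(cohort$bmi))
  set.seed(as.integer(seed) + 2L)
  lp <- matrix(0, n, nr, dimnames = list(NULL, regions))
  for (s in c("male", "female")) {
    idx <- which(cohort$sex == s)
    if (!length(idx)) next
    lp[idx, ] <- x[idx, , drop = FALSE] %*% t(truth$beta[, , s]) +
      outer(age_z[idx], truth$beta_age[, s])
  }
  lp <- lp + outer(head_z, truth$confound_gammas[, "head_size"]) +
    outer(bmi_z, truth$confound_gammas[, "bmi"])
  nets <- atlas$regions$network
  f <- matrix(stats::rnorm(n * length(unique(nets))), n,
              dimnames = list(NULL, unique(nets)))
  lp <- lp + f[, nets, drop = FALSE] *
    matrix(truth$network_loading, n, nr, byrow = TRUE)
  eps <- matrix(stats::rnorm(n * nr), n, nr) *
    matrix(truth$noise_sd, n, nr, byrow = TRUE)
  region_volume_matrix(lp + eps, regions, standardized = FALSE)
}
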
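test_that("conjugate oracle reduces to known closed forms", {
  set.seed(3)
  y <- rnorm(40, mean = 2)
  X <- matrix(1, 40, 1)
  # flat-prior limit, intercept only: posterior mean -> sample mean
  or <- conjugate_oracle(y, X, prior_sd = Inf, noise_sd = 1)
  expect_equal(unname(or$mean), mean(y), tolerance = 1e-10)
  # orthonormal single predictor, sigma = 1, prior_sd = 1: mean = X'y / 2
  x <- rnorm(40); x <- x / sqrt(sum(x^2))
  or2 <- conjugate_oracle(y, matrix(x), prior_sd = 1, noise_sd = 1)
  expect_equal(unname(or2$mean), sum(x * y) / 2, tolerance = 1e-10)
  expect_equal(or2$cov[1, 1], 1 / 2, tolerance = 1e-10)
})

test_that("fixed-scale non-hierarchical MCMC agrees with the conjugate oracle", {
  fx <- sim_fix()
  y <- fx$volumes$values[, "FP"]
  cfg <- model_config(draws = 1250, burn_in = 250, chains = 4, seed = 5,
                      hierarchical = FALSE, prior_sd = 1, sigma_fixed = 1)
  fit <- fit_region(y, fx$design, cfg, "FP")
  W <- build_model_matrix(fx$design)
  or <- conjugate_oracle(y, W, prior_sd = 1, noise_sd = 1)
  pm <- colMeans(fit$theta_draws)
  ps <- apply(fit$theta_draws, 2, sd)
  mcse_mean <- or$sd / sqrt(fit$n_retained)
  mcse_sd <- or$sd / sqrt(2 * fit$n_retained)
  expect_true(all(abs(pm - or$mean) < 4 * mcse_mean))
  expect_true(all(abs(ps - or$sd) < 4 * mcse_sd))
  expect_lt(mean(abs(pm - or$mean) / mcse_mean), 1.2)
})

test_that("null data gives well-calibrated, convergent posteriors", {
  cfg <- generation_config(scenario = "null", network_loading = 0,
                          confound_gammas = c(head_size = 0, bmi = 0))
  sim <- simulate_cohort(2000, 77, tt_fix(), cfg, atlas_fix())
  vol <- zscore_columns(simulate_region_volumes(sim, sim$truth, atlas_fix(), 77))
  des <- build_design(sim$cohort, tt_fix())
  fit <- suppressWarnings(
    fit_region(vol$values[, "AM_L"], des,
               model_config(draws = 1500, burn_in = 500, chains = 2, seed = 2),
               "AM_L"))
  sm <- summarize_fit(fit)
  cover0 <- mean(sm$hpdi_low <= 0 & sm$hpdi_high >= 0)
  expect_gte(cover0, 0.90)
  expect_true(all(fit$sigma_draws > 0))
  expect_true(all(fit$tau_draws > 0))
  expect_equal(fit$n_retained, 2000L)
})

test_that("a planted single effect is recovered with an honest interval", {
  tt <- tt_fix(); at <- atlas_fix()
  beta <- array(0, c(36, 40, 2),
                dimnames = list(at$regions$region_id, tt$trait_id,
                                c("male", "female")))
  beta["HC_R", "morning_person", "male"] <- 0.08
  cfg <- generation_config(beta = beta, network_loading = 0,
                          confound_gammas = c(head_size = 0, bmi = 0),
                          beta_age = 0)
  sim <- simulate_cohort(10000, 55, tt, cfg, at)
  vol <- zscore_columns(simulate_region_volumes(sim, sim$truth, at, 55))
  des <- build_design(sim$cohort, tt)
  fit <- suppressWarnings(
    fit_region(vol$values[, "HC_R"], des,
               model_config(draws = 1500, burn_in = 500, chains = 2, seed = 4),
               "HC_R"))
  sm <- summarize_fit(fit)
  row <- sm[sm$trait_id == "morning_person" & sm$sex == "male", ]
  expect_lt(abs(row$posterior_mean - 0.08), 0.03)
  expect_gt(row$hpdi_low, 0)  # HPDI excludes zero
})

test_that("fits are exactly reproducible under a fixed seed", {
  fx <- sim_fix()
  cfg <- model_config(draws = 300, burn_in = 100, chains = 2, seed = 123)
  f1 <- suppressWarnings(fit_region(fx$volumes$values[, "vmPFC"], fx$design, cfg))
  f2 <- suppressWarnings(fit_region(fx$volumes$values[, "vmPFC"], fx$design, cfg))
  expect_identical(f1$theta_draws, f2$theta_draws)
  expect_identical(f1$sigma_draws, f2$sigma_draws)
})

test_that("convergence checking reports families and catches broken chains", {
  fit <- fit_fix()
  rep <- check_convergence(fit)
  expect_true(all(c("beta", "intercept", "age", "mu", "tau", "sigma") %in%
                  names(rep$per_family)))
  expect_true(rep$pass)
  expect_lte(rep$max_rhat, 1.02)

  # chains pinned far apart with almost no draws must fail
  fx <- sim_fix()
  bad_cfg <- model_config(draws = 6, burn_in = 0, chains = 2, seed = 1,
                          init = list(theta = 100, mu = 100, tau = 1e-6))
  expect_warning(
    bad <- fit_region(fx$volumes$values[, "FP"], fx$design, bad_cfg, "FP"),
    class = "braintraits_convergence")
  expect_false(check_convergence(bad)$pass)
  # strict mode makes it fatal
  strict_cfg <- bad_cfg; strict_cfg$strict <- TRUE
  expect_bt_error(fit_region(fx$volumes$values[, "FP"], fx$design, strict_cfg),
                  "convergence")
  # single chain cannot be diagnosed
  one <- suppressWarnings(fit_region(
    fx$volumes$values[, "FP"], fx$design,
    model_config(draws = 200, burn_in = 100, chains = 1, seed = 1)))
  expect_bt_error(check_convergence(one), "validation")
})

test_that("single-sex data and shape mismatches are rejected", {
  fx <- sim_fix()
  co <- fx$sim$cohort
  males <- co[co$sex == "male", ]
  des_m <- build_design(males, tt_fix())
  expect_bt_error(fit_region(rnorm(nrow(males)), des_m, model_config()),
                  "single_sex")
  expect_bt_error(fit_region(rnorm(10), fx$design, model_config()), "dimension")
  expect_bt_error(model_config(draws = 100, burn_in = 100), "validation")
})

test_that("hierarchical shrinkage pulls estimates toward zero on average", {
  fx <- sim_fix()
  y <- fx$volumes$values[, "PCC"]
  fit <- suppressWarnings(fit_region(y, fx$design,
                                     model_config(draws = 1200, burn_in = 400,
                                                  chains = 2, seed = 6), "PCC"))
  W <- build_model_matrix(fx$design)
  or <- conjugate_oracle(y, W, prior_sd = 100, noise_sd = sd(y))
  lay <- attr(W, "layout")
  hier <- c(colMeans(fit$beta_draws[, , "male"]),
            colMeans(fit$beta_draws[, , "female"]))
  flat <- or$mean[c(lay$beta_male, lay$beta_female)]
  expect_lt(mean(abs(hier)), mean(abs(flat)))
})

test_that("permuting trait columns permutes the posterior summaries", {
  fx <- sim_fix()
  tt <- tt_fix()
  perm <- rev(seq_len(nrow(tt)))
  tt_perm <- tt[perm, ]; rownames(tt_perm) <- NULL
  des_perm <- build_design(fx$sim$cohort, tt_perm)
  cfg <- model_config(draws = 1200, burn_in = 400, chains = 2, seed = 31)
  y <- fx$volumes$values[, "TPJ_L"]
  f1 <- suppressWarnings(fit_region(y, fx$design, cfg, "TPJ_L"))
  f2 <- suppressWarnings(fit_region(y, des_perm, cfg, "TPJ_L"))
  s1 <- summarize_fit(f1); s2 <- summarize_fit(f2)
  key <- function(s) s[order(s$sex, s$trait_id), ]
  a <- key(s1); b <- key(s2)
  expect_equal(a$trait_id, b$trait_id)
  # same posterior up to Monte-Carlo error
  expect_lt(max(abs(a$posterior_mean - b$posterior_mean)), 0.01)
})
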
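test_that("hpdi matches a brute-force all-windows oracle", {
  brute_hpdi <- function(x, mass) {
    s <- sort(x); n <- length(s); m <- ceiling(mass * n)
    best <- c(-Inf, Inf)
    for (i in seq_len(n - m + 1)) {
      if (s[i + m - 1] - s[i] < best[2] - best[1]) best <- c(s[i], s[i + m - 1])
    }
    best
  }
  set.seed(14)
  for (r in 1:20) {
    x <- switch(1 + r %% 3, rnorm(200), rexp(200), rt(200, 3))
    for (mass in c(0.5, 0.9, 0.95)) {
      expect_identical(unname(hpdi(x, mass)), brute_hpdi(x, mass))
    }
  }
})

test_that("hpdi of a dense standard-normal grid matches analytic quantiles", {
  x <- qnorm(seq(0.5 / 10001, 1 - 0.5 / 10001, length.out = 10001))
  iv <- hpdi(x, 0.95)
  expect_lt(abs(iv["low"] - qnorm(0.025)), 0.01)
  expect_lt(abs(iv["high"] - qnorm(0.975)), 0.01)
})

test_that("hpdi handles degenerate and invalid input", {
  expect_equal(unname(hpdi(rep(2.5, 60))), c(2.5, 2.5))
  expect_bt_error(hpdi(rnorm(10)), "too_few_draws")
  expect_bt_error(hpdi(rnorm(100), mass = 1), "validation")
})

test_that("dominant trait is the sign-blind argmax with canonical tie-break", {
  mk <- function(means, ids = paste0("t", seq_along(means))) {
    s <- data.frame(region_id = "r", trait_id = ids, sex = "female",
                    posterior_mean = means, hpdi_low = means - 1,
                    hpdi_high = means + 1, prob_positive = 0.5)
    attr(s, "n_traits") <- length(means)
    s
  }
  expect_equal(dominant_trait(mk(c(0.067, 0.053, 0.01),
                                 c("health_satisfaction", "income", "iq"))),
               "health_satisfaction")
  expect_equal(dominant_trait(mk(c(-0.09, 0.08))), "t1")  # magnitude rule
  expect_warning(dt <- dominant_trait(mk(c(0, 0, 0))), class = "braintraits_tie")
  expect_equal(dt, "t1")
  s <- mk(c(1, 2, 3)); attr(s, "n_traits") <- 40
  expect_bt_error(dominant_trait(s), "incomplete_summary")
})

test_that("sex contrasts are draw-wise and antisymmetric", {
  fit <- fit_fix()
  sc <- sex_contrast(fit, "income")
  expect_equal(sc$diff_mean, mean(sc$diff_draws))
  expect_equal(sc$diff_draws,
               fit$beta_draws[, "income", "female"] -
                 fit$beta_draws[, "income", "male"])
  # antisymmetry: male - female is the exact negation, draw for draw
  manual <- fit$beta_draws[, "income", "male"] -
    fit$beta_draws[, "income", "female"]
  expect_equal(manual, -sc$diff_draws)
  # contrast of a sex with itself is identically zero
  fit0 <- fit
  fit0$beta_draws[, , "male"] <- fit0$beta_draws[, , "female"]
  sc0 <- sex_contrast(fit0, "income")
  expect_true(all(sc0$diff_draws == 0))
})

test_that("a planted male-only effect yields a negative female-male contrast", {
  # the 0.06 sex asymmetry needs a contrast SE well below 0.03 to separate,
  # so this recovery runs at n = 40,000 on the compact trait set
  tt <- tt_small_fix(); at <- atlas_fix()
  nt <- nrow(tt)
  beta <- array(0, c(36, nt, 2),
                dimnames = list(at$regions$region_id, tt$trait_id,
                                c("male", "female")))
  beta["vmPFC", "income", "male"] <- 0.06
  cfg <- generation_config(beta = beta, network_loading = 0, beta_age = 0,
                          confound_gammas = c(head_size = 0, bmi = 0))
  sim <- simulate_cohort(40000, 61, tt, cfg, at)
  vol <- zscore_columns(simulate_region_volumes(sim, sim$truth, at, 61))
  des <- build_design(sim$cohort, tt)
  fit <- suppressWarnings(
    fit_region(vol$values[, "vmPFC"], des,
               model_config(draws = 1500, burn_in = 500, chains = 2, seed = 9),
               "vmPFC"))
  sc <- sex_contrast(fit, "income")
  expect_lt(sc$diff_mean, 0)
  expect_lt(sc$diff_hpdi["high"], 0)  # HPDI excludes zero
  # and the joint age-trait clouds of the two sexes separate
  jt <- joint_age_trait(fit, "income")
  expect_lt(jt$overlap, 0.5)
})

test_that("sex bias counting classifies contrast signs", {
  fit <- fit_fix()
  contrasts <- lapply(fit$trait_ids, function(tr) sex_contrast(fit, tr))
  counts <- sex_bias_count(contrasts)
  expect_equal(sum(counts), 40L)
  expect_equal(unname(counts["n_female_biased"]),
               sum(vapply(contrasts, `[[`, 0, "diff_mean") > 0))
  # an exact zero counts as neither, with a warning
  contrasts[[1]]$diff_mean <- 0
  expect_warning(c2 <- sex_bias_count(contrasts), class = "braintraits_tie")
  expect_equal(sum(c2), 39L)
  expect_bt_error(sex_bias_count(contrasts[1:5]), "incomplete_summary")
})

test_that("joint age-trait overlap is 1 for identical clouds", {
  fit <- fit_fix()
  jt <- joint_age_trait(fit, "worrier")
  same <- braintraits:::bhattacharyya_gaussian(jt$male, jt$male)
  expect_equal(same, 1, tolerance = 1e-6)
  expect_true(jt$overlap >= 0 && jt$overlap <= 1)
  # shared-age fits cannot produce per-sex joint clouds
  fx <- sim_fix()
  shared <- suppressWarnings(fit_region(
    fx$volumes$values[, "FP"], fx$design,
    model_config(draws = 300, burn_in = 100, chains = 2, seed = 3,
                 shared_age = TRUE)))
  expect_bt_error(joint_age_trait(shared, "worrier"), "shared_age")
})

test_that("hpdi width shrinks with sample size on conjugate posteriors", {
  widths <- vapply(c(500, 2000, 10000), function(n) {
    set.seed(n)
    x <- rnorm(n, 0.05, 1)
    or <- conjugate_oracle(x, matrix(1, n, 1), prior_sd = 10, noise_sd = 1)
    draws <- qnorm(seq(0.0005, 0.9995, length.out = 2001), or$mean, or$sd)
    diff(hpdi(draws))
  }, 0)
  expect_true(all(diff(widths) < 0))
})
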
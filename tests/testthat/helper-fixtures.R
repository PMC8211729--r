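# Shared lazily-built fixtures; everything is generated in code.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tt_fix <- function() cached("trait_table", load_trait_table)
atlas_fix <- function() cached("atlas", load_atlas)

# A modest paper-like cohort reused by several modeling tests.
sim_fix <- function() cached("sim2000", function() {
  sim <- simulate_cohort(2000, 7, tt_fix(), generation_config(), atlas_fix())
  vol <- simulate_region_volumes(sim, sim$truth, atlas_fix(), 7)
  dec <- residualize_confounds(vol, cbind(head_size = sim$cohort$head_size,
                                          bmi = sim$cohort$bmi))
  list(sim = sim, volumes_raw = vol, volumes = dec,
       design = build_design(sim$cohort, tt_fix()))
})

# One fitted region at reduced draws, shared by posterior/ppc tests.
fit_fix <- function() cached("fit_vmpfc", function() {
  fx <- sim_fix()
  suppressWarnings(fit_region(fx$volumes$values[, "vmPFC"], fx$design,
                              model_config(draws = 2500, burn_in = 1500,
                                           chains = 4, seed = 11),
                              region_id = "vmPFC"))
})

# Reduced trait table (8 moderate traits) for fast end-to-end paths.
tt_small_fix <- function() cached("tt_small", function() {
  tt <- tt_fix()
  keep <- c("living_with_others", "morning_person", "risk_taking",
            "health_satisfaction", "income", "worrier", "family_visits",
            "manual_job")
  out <- tt[match(keep, tt$trait_id), ]
  rownames(out) <- NULL
  out
})

# Tiny 3-region atlas on a compact grid for the imaging path.
mini_atlas_fix <- function() cached("mini_atlas", function() {
  mini_atlas(atlas_fix(), c("vmPFC", "FP", "rACC"))
})

expect_bt_error <- function(expr, class) {
  expect_error(expr, class = paste0("braintraits_", class))
}
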
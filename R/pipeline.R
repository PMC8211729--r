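# Orchestration, file contracts, and fixture generation.

#' Write / read a cohort table as TSV
#' @param cohort A \code{cohort_table} (or \code{cohort_sim}).
#' @param path TSV path.
#' @export
write_cohort <- function(cohort, path) {
  if (inherits(cohort, "cohort_sim")) cohort <- cohort$cohort
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- read_tsv_checked(path, c("participant_id", "age_years", "sex",
                                  "head_size", "bmi"))
  class(tab) <- c("cohort_table", "data.frame")
  validate_cohort(tab)
  tab
}

#' Write / read a region volume matrix as TSV (+ sidecar metadata)
#'
#' The TSV has a \code{participant_id} column followed by one column per
#' region; a JSON sidecar (\code{<path>.meta.json}) records the
#' standardized / partial flags.
#'
#' @param volumes A \code{region_volume_matrix}.
#' @param path TSV path.
#' @param participant_id Optional ids (default row number).
#' @export
write_region_volumes <- function(volumes, path, participant_id = NULL) {
  v <- volumes$values
  if (is.null(participant_id)) participant_id <- seq_len(nrow(v))
  out <- data.frame(participant_id = participant_id, v, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(standardized = volumes$standardized,
                            partial = volumes$partial,
                            region_order = volumes$region_order),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_region_volumes
#' @export
read_region_volumes <- function(path) {
  tab <- read_tsv_checked(path, "participant_id")
  meta_path <- paste0(path, ".meta.json")
  regions <- setdiff(names(tab), "participant_id")
  standardized <- FALSE; partial <- FALSE
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    standardized <- isTRUE(meta$standardized)
    partial <- isTRUE(meta$partial)
    if (!identical(as.character(meta$region_order), regions))
      bt_stop("sidecar region order disagrees with TSV columns", "validation")
  }
  region_volume_matrix(as.matrix(tab[, regions, drop = FALSE]), regions,
                       standardized = standardized, partial = partial)
}

#' Write the tidy posterior summary of one or more fits
#' @param fits List of \code{posterior_fit} objects.
#' @param path Output TSV.
#' @param mass HPDI mass.
#' @export
write_fit_summary <- function(fits, path, mass = 0.95) {
  sm <- do.call(rbind, lapply(fits, summarize_fit, mass = mass))
  utils::write.table(sm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sm)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param cohort_path Cohort TSV.
#' @param volumes_path Region-volume TSV (mutually exclusive with
#'   \code{nifti_dir}).
#' @param nifti_dir Directory of per-participant NIfTI images to extract
#'   from instead of a precomputed table.
#' @param mode \code{"main"}, \code{"partial"} or \code{"both"}. Partial
#'   mode defaults to 10,000 draws with 8,000 burn-in.
#' @param out_dir Output directory.
#' @param model Optional [model_config()] overriding the mode defaults.
#' @param regions Optional subset of region ids to fit.
#' @param trait_table_path Optional trait table path (default packaged).
#' @param atlas_path Optional atlas path (default packaged).
#' @param seed Global seed.
#' @param strict Make convergence failures fatal.
#' @param n_ppc_replicates Candidate models per PPC (default 500).
#' @export
run_config <- function(cohort_path, volumes_path = NULL, nifti_dir = NULL,
                       mode = c("main", "partial", "both"),
                       out_dir = "braintraits-run", model = NULL,
                       regions = NULL, trait_table_path = NULL,
                       atlas_path = NULL, seed = 1L, strict = FALSE,
                       n_ppc_replicates = 500L) {
  mode <- match.arg(mode)
  for (p in c(cohort_path, volumes_path, nifti_dir, trait_table_path, atlas_path))
    if (!is.null(p) && !file.exists(p))
      bt_stop(sprintf("configured path does not exist: %s", p), "validation")
  if (is.null(volumes_path) && is.null(nifti_dir))
    bt_stop("either volumes_path or nifti_dir is required", "validation")
  structure(list(cohort_path = cohort_path, volumes_path = volumes_path,
                 nifti_dir = nifti_dir, mode = mode, out_dir = out_dir,
                 model = model, regions = regions,
                 trait_table_path = trait_table_path, atlas_path = atlas_path,
                 seed = as.integer(seed), strict = isTRUE(strict),
                 n_ppc_replicates = n_ppc_replicates),
            class = "run_config")
}

default_mode_config <- function(mode, seed, strict) {
  if (mode == "partial")
    model_config(draws = 10000L, burn_in = 8000L, seed = seed, strict = strict)
  else model_config(seed = seed, strict = strict)
}

run_one_analysis <- function(volumes, design, config, regions, n_ppc, atlas) {
  fits <- run_region_fits(volumes, design, config, regions)
  summary <- do.call(rbind, lapply(fits, summarize_fit))
  ppc <- lapply(fits, function(f)
    posterior_predictive_r2(f, volumes$values[, f$region_id], design,
                            n_replicates = min(n_ppc, f$n_retained)))
  dom <- dominant_trait_report(fits)
  conv <- vapply(fits, function(f) check_convergence(f)$max_rhat, 0)
  nets <- if (setequal(names(ppc), atlas$regions$region_id))
    network_summary(unname(ppc), atlas)
  list(fits = fits, summary = summary, ppc = ppc, dominant = dom,
       max_rhat = conv, network_summary = nets)
}

#' Run the full analysis pipeline
#'
#' Stages: (optional) sphere extraction from images, deconfounding and
#' z-scoring, (optional) partial residualization, per-region Bayesian fits,
#' posterior summaries, dominant-trait report, posterior predictive R2, and
#' a JSON manifest recording seeds, sizes and per-region convergence. All
#' stage outputs are written under \code{out_dir}.
#'
#' @param config A [run_config()].
#' @return The run manifest (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  trait_table <- if (is.null(config$trait_table_path)) load_trait_table()
  else load_trait_table(config$trait_table_path)
  atlas <- if (is.null(config$atlas_path)) load_atlas()
  else load_atlas(config$atlas_path)
  cohort <- read_cohort(config$cohort_path)
  volumes <- if (!is.null(config$volumes_path)) read_region_volumes(config$volumes_path)
  else extract_region_volumes(read_voxel_cohort(config$nifti_dir), atlas)
  if (nrow(volumes$values) != nrow(cohort))
    bt_stop("cohort and volumes disagree on participant count", "dimension")

  volumes <- residualize_confounds(volumes, cbind(head_size = cohort$head_size,
                                                  bmi = cohort$bmi))
  design <- build_design(cohort, trait_table)
  regions <- if (is.null(config$regions)) volumes$region_order else config$regions

  manifest <- list(seed = config$seed, mode = config$mode,
                   n_participants = nrow(cohort), regions = regions,
                   package_version = as.character(utils::packageVersion("braintraits")),
                   r_version = R.version.string, analyses = list())
  analyses <- list()
  modes <- if (config$mode == "both") c("main", "partial") else config$mode
  for (m in modes) {
    mcfg <- if (is.null(config$model)) default_mode_config(m, config$seed, config$strict)
    else config$model
    vol_m <- if (m == "partial") partial_residualize(volumes) else volumes
    res <- run_one_analysis(vol_m, design, mcfg, regions,
                            config$n_ppc_replicates, atlas)
    prefix <- file.path(config$out_dir, m)
    utils::write.table(res$summary, paste0(prefix, "_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(res$dominant, paste0(prefix, "_dominant_traits.json"),
                         auto_unbox = TRUE)
    ppc_tab <- data.frame(region_id = names(res$ppc),
                          r2_total = vapply(res$ppc, `[[`, 0, "r2_total"),
                          r2_male = vapply(res$ppc, `[[`, 0, "r2_male"),
                          r2_female = vapply(res$ppc, `[[`, 0, "r2_female"))
    utils::write.table(ppc_tab, paste0(prefix, "_ppc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_draws_long(res$fits, paste0(prefix, "_draws.tsv"))
    manifest$analyses[[m]] <- list(
      draws = mcfg$draws, burn_in = mcfg$burn_in, chains = mcfg$chains,
      max_rhat = as.list(res$max_rhat),
      rhat_threshold = mcfg$rhat_threshold)
    analyses[[m]] <- res
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$results <- analyses
  invisible(manifest)
}

# Self-describing long-format draw container: chain, draw, parameter, value.
# Kept deliberately plain-text; one file per run, thinned to keep size sane.
write_draws_long <- function(fits, path, thin = 20L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("region\tchain\tdraw\tparameter\tvalue", con)
  for (f in fits) {
    idx <- seq(1, nrow(f$theta_draws), by = thin)
    for (p in colnames(f$theta_draws)) {
      writeLines(sprintf("%s\t%d\t%d\t%s\t%.6g", f$region_id, f$chain[idx],
                         idx, p, f$theta_draws[idx, p]), con)
    }
  }
  invisible(path)
}

#' Generate a self-contained synthetic dataset on disk
#'
#' Writes a cohort TSV, a region-volume TSV, the ground-truth JSON, and the
#' generation config YAML for a named scenario; optionally also a NIfTI set
#' for the imaging path (small grids only).
#'
#' @param scenario Scenario name understood by [generation_config()].
#' @param out_dir Output directory.
#' @param n Cohort size.
#' @param seed Seed.
#' @param write_nifti Also paint and write per-participant NIfTI images
#'   (requires a modest \code{n}; uses a compact grid around the atlas).
#' @export
generate_fixtures <- function(scenario, out_dir, n = 500L, seed = 1L,
                              write_nifti = FALSE) {
  known <- c("paper-like", "null", "vmPFC-dominant", "r2-target")
  if (!scenario %in% known)
    bt_stop(sprintf("unknown scenario '%s' (known: %s)", scenario,
                    paste(known, collapse = ", ")), "unknown_scenario")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trait_table <- load_trait_table()
  atlas <- load_atlas()
  config <- generation_config(scenario = scenario)
  sim <- simulate_cohort(n, seed, trait_table, config, atlas)
  volumes <- simulate_region_volumes(sim, sim$truth, atlas, seed)
  write_cohort(sim, file.path(out_dir, "cohort.tsv"))
  write_region_volumes(volumes, file.path(out_dir, "volumes.tsv"),
                       participant_id = sim$cohort$participant_id)
  jsonlite::write_json(
    list(scenario = scenario, seed = seed, n = n,
         beta = sim$truth$beta, beta_age = sim$truth$beta_age,
         confound_gammas = sim$truth$confound_gammas,
         network_loading = sim$truth$network_loading,
         noise_sd = sim$truth$noise_sd,
         dominant_trait = as.list(sim$truth$dominant_trait),
         true_r2 = sim$truth$true_r2),
    file.path(out_dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  yaml::write_yaml(list(scenario = scenario, n = n, seed = seed,
                        copula_rho = config$copula_rho,
                        network_loading = config$network_loading,
                        noise_sd = config$noise_sd),
                   file.path(out_dir, "config.yaml"))
  if (write_nifti) {
    mini <- mini_atlas(atlas, c("vmPFC", "FP", "rACC"))
    grid <- grid_spec(origin = c(-20, 20, -40), dim = c(45, 50, 85))
    vox <- simulate_voxel_cohort(sim, subset_volumes(volumes, mini), mini,
                                 grid, seed)
    write_voxel_cohort(vox, file.path(out_dir, "nifti"))
  }
  invisible(out_dir)
}

#' Restrict an atlas to a subset of regions (non-strict)
#' @param atlas An \code{atlas_spec}.
#' @param region_ids Regions to keep, in atlas order.
#' @export
mini_atlas <- function(atlas, region_ids) {
  keep <- atlas$regions$region_id %in% region_ids
  if (!any(keep)) bt_stop("no matching regions", "validation")
  structure(list(regions = atlas$regions[keep, , drop = FALSE],
                 sphere_diameter_mm = atlas$sphere_diameter_mm,
                 smoothing_fwhm_mm = atlas$smoothing_fwhm_mm),
            class = "atlas_spec")
}

#' @rdname mini_atlas
#' @param volumes A \code{region_volume_matrix} to subset to the atlas.
#' @export
subset_volumes <- function(volumes, atlas) {
  ids <- atlas$regions$region_id
  region_volume_matrix(volumes$values[, ids, drop = FALSE], ids,
                       standardized = volumes$standardized,
                       partial = volumes$partial)
}
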
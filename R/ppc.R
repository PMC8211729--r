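# Posterior predictive R2 checks and split-sample replication.

#' Posterior predictive explained variance (R2)
#'
#' Spawns \code{n_replicates} candidate models (parameter vectors evenly
#' thinned from the retained draws), forms each model's linear predictor,
#' and scores the mean predictor against the observed volumes:
#' R2 = 1 - SS_res / SS_tot, overall and within each sex subset. With
#' \code{per_draw = TRUE} the per-replicate R2 distribution is also
#' returned.
#'
#' @param fit A \code{posterior_fit}.
#' @param y Observed standardized volume column the model was fitted to.
#' @param design The \code{design_matrix} used for the fit.
#' @param n_replicates Number of candidate models (default 500; must not
#'   exceed the retained draws).
#' @param per_draw Also compute R2 separately for every replicate.
#' @return List of class \code{"ppc_result"} with \code{r2_total},
#'   \code{r2_male}, \code{r2_female}, \code{n_replicates} (and
#'   \code{r2_draws} if requested).
#' @export
posterior_predictive_r2 <- function(fit, y, design, n_replicates = 500L,
                                    per_draw = FALSE) {
  n_replicates <- stopifnot_scalar_count(n_replicates, "n_replicates")
  if (n_replicates < 1) bt_stop("n_replicates must be >= 1", "validation")
  if (n_replicates > fit$n_retained)
    bt_stop(sprintf("n_replicates (%d) exceeds retained draws (%d)",
                    n_replicates, fit$n_retained), "insufficient_draws")
  W <- build_model_matrix(design, shared_age = fit$shared_age)
  idx <- unique(round(seq(1, fit$n_retained, length.out = n_replicates)))
  theta <- fit$theta_draws[idx, , drop = FALSE]
  pred_mean <- drop(W %*% colMeans(theta))
  r2_of <- function(obs, pred) {
    1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  }
  male <- design$sex_index == 0L
  out <- structure(list(
    region_id = fit$region_id,
    r2_total = r2_of(y, pred_mean),
    r2_male = r2_of(y[male], pred_mean[male]),
    r2_female = r2_of(y[!male], pred_mean[!male]),
    n_replicates = length(idx)), class = "ppc_result")
  if (per_draw) {
    preds <- W %*% t(theta)
    out$r2_draws <- apply(preds, 2, function(p) r2_of(y, p))
  }
  out
}

#' Per-network summary of explained variance
#'
#' @param results List of \code{ppc_result} objects, one per atlas region.
#' @param atlas The atlas defining network membership.
#' @return data.frame with one row per network: best region, maximum and
#'   median R2 (total), and the sex-specific maxima.
#' @export
network_summary <- function(results, atlas) {
  ids <- vapply(results, `[[`, "", "region_id")
  missing <- setdiff(atlas$regions$region_id, ids)
  if (length(missing))
    bt_stop(sprintf("missing PPC result(s) for region(s): %s",
                    paste(missing, collapse = ", ")), "missing_region")
  tab <- data.frame(
    region_id = ids,
    network = atlas$regions$network[match(ids, atlas$regions$region_id)],
    r2_total = vapply(results, `[[`, 0, "r2_total"),
    r2_male = vapply(results, `[[`, 0, "r2_male"),
    r2_female = vapply(results, `[[`, 0, "r2_female"))
  out <- do.call(rbind, lapply(split(tab, tab$network), function(g) {
    best <- which.max(g$r2_total)
    data.frame(network = g$network[1], best_region = g$region_id[best],
               r2_max = g$r2_total[best], r2_median = stats::median(g$r2_total),
               r2_max_male = max(g$r2_male), r2_max_female = max(g$r2_female))
  }))
  rownames(out) <- NULL
  out[match(intersect(ATLAS_NETWORKS, out$network), out$network), , drop = FALSE]
}

fit_mean_vector <- function(fits) {
  unlist(lapply(fits, function(f)
    c(colMeans(f$beta_draws[, , "male"]), colMeans(f$beta_draws[, , "female"]))))
}

run_region_fits <- function(volumes, design, config, regions) {
  fits <- list()
  for (j in seq_along(regions)) {
    cfg <- config
    cfg$seed <- config$seed + j
    fits[[regions[j]]] <- fit_region(volumes$values[, regions[j]], design,
                                     cfg, region_id = regions[j])
  }
  fits
}

#' Split-sample replication of the posterior-mean pattern
#'
#' Randomly divides the cohort into \code{k_splits} disjoint samples,
#' reruns the full pipeline (deconfounding, z-scoring, region fits) in each,
#' and reports the Pearson correlation between the concatenated
#' posterior-mean coefficient vectors (regions x traits x sexes) of a
#' reference fit on the full data and each split's refit.
#'
#' @param cohort A \code{cohort_table} (or \code{cohort_sim}).
#' @param volumes The unstandardized \code{region_volume_matrix} for the
#'   full cohort.
#' @param k_splits Number of disjoint splits (each must keep >= 100
#'   participants).
#' @param seed Seed for the random division.
#' @param config A [model_config()] used for every fit.
#' @param trait_table Trait taxonomy.
#' @param regions Optional subset of region ids to fit (default: all
#'   columns of \code{volumes}).
#' @return List of class \code{"replication_report"}: \code{overall}
#'   data.frame (split, n, pearson_r), \code{per_region} matrix, and the
#'   split assignment for exact reruns.
#' @export
split_replicate <- function(cohort, volumes, k_splits, seed,
                            config = model_config(),
                            trait_table = load_trait_table(),
                            regions = NULL) {
  if (inherits(cohort, "cohort_sim")) cohort <- cohort$cohort
  n <- nrow(cohort)
  k_splits <- stopifnot_scalar_count(k_splits, "k_splits")
  if (k_splits < 1 || k_splits > n / 100)
    bt_stop("each split must keep at least 100 participants", "too_small_split")
  if (is.null(regions)) regions <- volumes$region_order
  prep <- function(rows) {
    sub <- cohort[rows, , drop = FALSE]
    vol <- region_volume_matrix(volumes$values[rows, , drop = FALSE],
                                volumes$region_order)
    vol <- residualize_confounds(vol, cbind(head_size = sub$head_size,
                                            bmi = sub$bmi))
    list(design = build_design(sub, trait_table), volumes = vol)
  }
  ref <- prep(seq_len(n))
  ref_fits <- run_region_fits(ref$volumes, ref$design, config, regions)
  ref_vec <- fit_mean_vector(ref_fits)

  set.seed(as.integer(seed))
  assignment <- sample(rep_len(seq_len(k_splits), n))
  overall <- data.frame(split = seq_len(k_splits), n = NA_integer_,
                        pearson_r = NA_real_)
  per_region <- matrix(NA_real_, k_splits, length(regions),
                       dimnames = list(NULL, regions))
  for (k in seq_len(k_splits)) {
    rows <- which(assignment == k)
    sp <- prep(rows)
    sp_fits <- run_region_fits(sp$volumes, sp$design, config, regions)
    overall$n[k] <- length(rows)
    overall$pearson_r[k] <- stats::cor(ref_vec, fit_mean_vector(sp_fits))
    for (j in regions)
      per_region[k, j] <- stats::cor(fit_mean_vector(ref_fits[j]),
                                     fit_mean_vector(sp_fits[j]))
  }
  structure(list(overall = overall, per_region = per_region,
                 assignment = assignment, seed = seed, regions = regions),
            class = "replication_report")
}
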
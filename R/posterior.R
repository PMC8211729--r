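# Posterior summaries: HPDIs, dominant traits, female-male contrasts,
# joint age-trait posteriors.

#' Highest posterior density interval
#'
#' Shortest contiguous interval over the sorted draws containing
#' \code{ceiling(mass * n)} samples; width ties are broken toward the lower
#' window. This is the highest-density definition, not the equal-tailed
#' interval.
#'
#' @param draws Numeric sample vector (>= 50 draws).
#' @param mass Probability mass to cover (default 0.95).
#' @return Named numeric vector \code{c(low, high)}.
#' @export
hpdi <- function(draws, mass = 0.95) {
  draws <- as.numeric(draws)
  if (length(draws) < 50)
    bt_stop("at least 50 draws are required for an HPDI", "too_few_draws")
  if (!is.numeric(mass) || mass <= 0 || mass >= 1)
    bt_stop("mass must lie strictly in (0, 1)", "validation")
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(mass * n)
  if (m >= n) return(c(low = s[1], high = s[n]))
  widths <- s[m:n] - s[1:(n - m + 1)]
  i <- which.min(widths)  # earliest window on ties
  c(low = s[i], high = s[i + m - 1])
}

#' Tidy per-trait posterior summary of a fit
#'
#' @param fit A \code{posterior_fit}.
#' @param mass HPDI mass (default 0.95).
#' @return data.frame of class \code{"trait_summary"} with columns
#'   \code{region_id}, \code{trait_id}, \code{sex}, \code{posterior_mean},
#'   \code{hpdi_low}, \code{hpdi_high}, \code{prob_positive}.
#' @export
summarize_fit <- function(fit, mass = 0.95) {
  rows <- list()
  for (s in c("male", "female")) {
    dr <- fit$beta_draws[, , s]
    hp <- apply(dr, 2, hpdi, mass = mass)
    rows[[s]] <- data.frame(
      region_id = fit$region_id, trait_id = fit$trait_ids, sex = s,
      posterior_mean = colMeans(dr),
      hpdi_low = hp["low", ], hpdi_high = hp["high", ],
      prob_positive = colMeans(dr > 0), row.names = NULL)
  }
  out <- rbind(rows$male, rows$female)
  class(out) <- c("trait_summary", "data.frame")
  out
}

#' Dominant trait of one region and sex
#'
#' The trait whose marginal posterior mean has the largest absolute value
#' (strongest positive or negative association) among all modeled traits.
#' Exact ties are broken toward the earlier trait in canonical order, with
#' a warning.
#'
#' @param summaries A \code{trait_summary} restricted to a single region
#'   and sex, covering the complete trait set (age and intercept excluded
#'   by construction).
#' @return The dominant \code{trait_id} (character scalar).
#' @export
dominant_trait <- function(summaries) {
  if (length(unique(summaries$region_id)) != 1 ||
      length(unique(summaries$sex)) != 1)
    bt_stop("summaries must cover exactly one region and sex", "incomplete_summary")
  if (anyDuplicated(summaries$trait_id) || anyNA(summaries$posterior_mean))
    bt_stop("summary has duplicate or missing trait entries", "incomplete_summary")
  expected <- attr(summaries, "n_traits")
  if (is.null(expected)) expected <- N_TRAITS
  if (nrow(summaries) != expected)
    bt_stop(sprintf("summary must contain all %d traits, got %d",
                    expected, nrow(summaries)), "incomplete_summary")
  mag <- abs(summaries$posterior_mean)
  top <- which(mag == max(mag))
  if (length(top) > 1)
    bt_warn("tie for the dominant trait; returning the first in canonical order",
            "tie")
  summaries$trait_id[top[1]]
}

#' Female - male posterior contrast for one trait
#'
#' Draw-wise subtraction of identically indexed retained draws, so the
#' contrast distribution respects the joint posterior.
#'
#' @param fit A \code{posterior_fit}.
#' @param trait_id Trait to contrast.
#' @param mass HPDI mass for the contrast interval.
#' @return List of class \code{"sex_contrast"}: \code{diff_draws},
#'   \code{diff_mean}, \code{diff_hpdi}.
#' @export
sex_contrast <- function(fit, trait_id, mass = 0.95) {
  if (!trait_id %in% fit$trait_ids)
    bt_stop(sprintf("unknown trait '%s'", trait_id), "validation")
  d <- fit$beta_draws[, trait_id, "female"] - fit$beta_draws[, trait_id, "male"]
  structure(list(region_id = fit$region_id, trait_id = trait_id,
                 diff_draws = d, diff_mean = mean(d),
                 diff_hpdi = hpdi(d, mass)),
            class = "sex_contrast")
}

#' Count female- and male-biased traits for one region
#'
#' Classifies each trait contrast by the sign of its posterior-mean
#' difference (female - male); exact zeros count as neither and trigger a
#' warning.
#'
#' @param contrasts List of [sex_contrast()] results covering the full
#'   trait set of one region.
#' @return Named integer vector \code{c(n_female_biased, n_male_biased)}.
#' @export
sex_bias_count <- function(contrasts) {
  if (!length(contrasts) || !all(vapply(contrasts, inherits, TRUE, "sex_contrast")))
    bt_stop("contrasts must be a list of sex_contrast objects", "incomplete_summary")
  ids <- vapply(contrasts, `[[`, "", "trait_id")
  if (anyDuplicated(ids) || length(ids) != N_TRAITS)
    bt_stop(sprintf("expected %d distinct trait contrasts, got %d",
                    N_TRAITS, length(ids)), "incomplete_summary")
  d <- vapply(contrasts, `[[`, 0, "diff_mean")
  if (any(d == 0))
    bt_warn("contrast(s) with exactly zero mean counted as neither sex", "tie")
  c(n_female_biased = sum(d > 0), n_male_biased = sum(d < 0))
}

# Bhattacharyya coefficient of two moment-matched Gaussians (1 identical,
# 0 disjoint).
bhattacharyya_gaussian <- function(x1, x2) {
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  s1 <- stats::cov(x1); s2 <- stats::cov(x2)
  s <- (s1 + s2) / 2
  d <- m1 - m2
  db <- drop(t(d) %*% solve(s, d)) / 8 +
    0.5 * log(det(s) / sqrt(det(s1) * det(s2)))
  exp(-db)
}

#' Joint age-trait posterior per sex
#'
#' Returns the matched (age coefficient, trait coefficient) draw pairs for
#' each sex plus a Bhattacharyya overlap score between the two sexes'
#' moment-matched Gaussian approximations of the joint posterior clouds.
#'
#' @param fit A \code{posterior_fit} fitted with sex-indexed age
#'   coefficients (the default).
#' @param trait_id Trait of interest.
#' @return List of class \code{"joint_age_trait"}: \code{male} and
#'   \code{female} two-column draw matrices and \code{overlap} in [0, 1].
#' @export
joint_age_trait <- function(fit, trait_id) {
  if (fit$shared_age)
    bt_stop("model was fitted with a shared age coefficient; refit with sex-indexed age",
            "shared_age")
  if (!trait_id %in% fit$trait_ids)
    bt_stop(sprintf("unknown trait '%s'", trait_id), "validation")
  male <- cbind(beta_age = fit$beta_age_draws[, "male"],
                beta_trait = fit$beta_draws[, trait_id, "male"])
  female <- cbind(beta_age = fit$beta_age_draws[, "female"],
                  beta_trait = fit$beta_draws[, trait_id, "female"])
  structure(list(region_id = fit$region_id, trait_id = trait_id,
                 male = male, female = female,
                 overlap = bhattacharyya_gaussian(male, female)),
            class = "joint_age_trait")
}

#' Dominant-trait report across fits
#'
#' @param fits List of \code{posterior_fit} objects.
#' @param mass HPDI mass passed to [summarize_fit()].
#' @return Nested list keyed by region then sex, each entry a trait id.
#' @export
dominant_trait_report <- function(fits, mass = 0.95) {
  out <- list()
  for (fit in fits) {
    sm <- summarize_fit(fit, mass)
    attr(sm, "n_traits") <- length(fit$trait_ids)
    ent <- list()
    for (s in c("male", "female")) {
      sub <- sm[sm$sex == s, ]
      attr(sub, "n_traits") <- length(fit$trait_ids)
      ent[[s]] <- dominant_trait(sub)
    }
    out[[fit$region_id]] <- ent
  }
  out
}
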
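# Two-choice trait encoding and confound removal before modeling.

#' Median-split (two-choice) encoding of an ordered trait
#'
#' Participants strictly above the sample median are coded 1; ties at the
#' median are all assigned to the low (0) group, yielding the most even
#' split attainable for discrete responses.
#'
#' @param raw Numeric (or ordered) vector of raw responses.
#' @return Integer 0/1 vector.
#' @export
binarize_trait <- function(raw) {
  raw <- as.numeric(raw)
  if (anyNA(raw)) bt_stop("raw trait responses contain NA", "validation")
  if (length(unique(raw)) < 2)
    bt_stop("trait has a single distinct value; cannot median-split", "degenerate_trait")
  as.integer(raw > stats::median(raw))
}

#' Residualize confounds out of region volumes
#'
#' Per region, replaces the volume column by its least-squares residual on
#' an intercept plus the (z-scored) confound columns, then re-z-scores.
#' This is ordinary linear deconfounding: residuals are exactly orthogonal
#' to every confound.
#'
#' @param volumes A \code{region_volume_matrix}.
#' @param confounds Numeric matrix or data.frame, participants x k
#'   (defaults expected: head size and BMI).
#' @param re_zscore Re-standardize residual columns afterwards (default
#'   TRUE, matching the modeling contract that y is z-scored).
#' @return A \code{region_volume_matrix} of residuals.
#' @export
residualize_confounds <- function(volumes, confounds, re_zscore = TRUE) {
  v <- volumes$values
  cf <- as.matrix(confounds)
  if (nrow(cf) != nrow(v))
    bt_stop("confound rows must match participants", "dimension")
  if (ncol(cf) < 1) bt_stop("at least one confound column required", "validation")
  cf <- scale(cf)  # conditioning only; residuals unchanged
  X <- cbind(1, cf)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    bt_stop("confound matrix (plus intercept) is rank deficient", "rank_deficient")
  res <- qr.resid(qx, v)
  out <- region_volume_matrix(res, volumes$region_order, standardized = FALSE)
  if (re_zscore) out <- zscore_columns(out)
  out
}

#' Build the model design from a cohort
#'
#' Assembles the participants x traits binary matrix in canonical trait
#' order, the z-scored age covariate, and the 0/1 sex index (0 = male,
#' 1 = female).
#'
#' @param cohort A \code{cohort_table} (or \code{cohort_sim}).
#' @param trait_table Trait taxonomy giving the canonical column order.
#' @return Object of class \code{"design_matrix"}.
#' @export
build_design <- function(cohort, trait_table = load_trait_table()) {
  if (inherits(cohort, "cohort_sim")) cohort <- cohort$cohort
  ids <- trait_table$trait_id
  missing <- setdiff(ids, names(cohort))
  if (length(missing))
    bt_stop(sprintf("cohort lacks trait column(s): %s",
                    paste(missing, collapse = ", ")), "validation")
  x <- as.matrix(cohort[, ids, drop = FALSE])
  storage.mode(x) <- "double"
  if (!all(x %in% c(0, 1))) bt_stop("trait entries must be 0/1", "validation")
  age <- cohort$age_years
  if (stats::sd(age) == 0) bt_stop("age has zero variance", "validation")
  age_z <- as.numeric(scale(age))
  sex_index <- as.integer(cohort$sex == "female")
  structure(list(x = x, age_z = age_z, sex_index = sex_index,
                 trait_ids = ids, n = nrow(x)), class = "design_matrix")
}
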
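# Partial-volume reanalysis: isolate each region's unique variance before
# refitting the trait model.

rvm_fingerprint <- function(volumes) {
  v <- volumes$values
  sprintf("rvm-%dx%d-%s", nrow(v), ncol(v),
          format(round(sum(v * v), 6), scientific = TRUE))
}

#' Region-unique (partial) volume residuals
#'
#' For each region j, replaces its z-scored column by the least-squares
#' residual of a multiple regression on all remaining region columns
#' (an intercept is included for safety; it is null for centered data).
#' The residual is the component of region j's volume variation not
#' linearly explained by any other region — the de-correlated basis of the
#' partial reanalysis.
#'
#' Residuals are deliberately not re-standardized by default: their reduced
#' scale is informative (coefficients from the partial refit are expected
#' to be visibly smaller than in the main analysis).
#'
#' @param volumes A standardized \code{region_volume_matrix} with more
#'   participants than regions.
#' @param re_zscore Re-standardize residual columns (default FALSE).
#' @return A \code{region_volume_matrix} with \code{partial = TRUE} and a
#'   \code{source_hash} fingerprint of the input.
#' @export
partial_residualize <- function(volumes, re_zscore = FALSE) {
  if (!volumes$standardized)
    bt_stop("volumes must be standardized before partial residualization",
            "validation")
  v <- volumes$values
  nr <- ncol(v)
  if (nrow(v) <= nr)
    bt_stop("need more participants than regions", "validation")
  res <- matrix(NA_real_, nrow(v), nr, dimnames = dimnames(v))
  for (j in seq_len(nr)) {
    X <- cbind(1, v[, -j, drop = FALSE])
    qx <- qr(X)
    if (qx$rank < ncol(X))
      bt_stop(sprintf("region columns are collinear when predicting '%s'",
                      colnames(v)[j]), "rank_deficient")
    res[, j] <- qr.resid(qx, v[, j])
  }
  out <- region_volume_matrix(res, volumes$region_order,
                              standardized = FALSE, partial = TRUE)
  if (re_zscore) { out <- zscore_columns(out); out$partial <- TRUE }
  out$source_hash <- rvm_fingerprint(volumes)
  out
}
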
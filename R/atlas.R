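# Packaged data model: the 40-trait taxonomy and the 36-region social brain atlas.

TRAIT_DOMAINS <- c("social", "personality", "demographic")
TRAIT_DOMAIN_COUNTS <- c(social = 12L, personality = 15L, demographic = 13L)
ATLAS_NETWORKS <- c("visual-sensory", "limbic", "intermediate", "higher-associative")
N_TRAITS <- 40L
N_REGIONS <- 36L

bt_extdata <- function(file) {
  path <- system.file("extdata", file, package = "braintraits")
  if (!nzchar(path)) bt_stop(sprintf("packaged file '%s' not found", file), "validation")
  path
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) bt_stop(sprintf("file not found: %s", path), "malformed_table")
  tab <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE, quote = ""),
    error = function(e) bt_stop(sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
                                "malformed_table")
  )
  missing <- setdiff(required, names(tab))
  if (length(missing))
    bt_stop(sprintf("table '%s' is missing column(s): %s", path,
                    paste(missing, collapse = ", ")), "malformed_table")
  tab
}

#' Load and validate the lifestyle-trait taxonomy
#'
#' Reads the packaged 40-trait table (or a user table in the same layout):
#' one row per binary lifestyle indicator with its questionnaire field id,
#' domain (social / personality / demographic), a human-readable label, and
#' the sex-specific population prevalence of the "1" response used by the
#' synthetic-cohort generator.
#'
#' @param path Path to a tab-separated trait table. Defaults to the table
#'   shipped with the package (12 social, 15 personality and 13 demographic
#'   indicators drawn from a large UK population cohort).
#' @param strict If \code{TRUE} (default) the packaged invariants are
#'   enforced: exactly 40 rows with the 12/15/13 domain split. Set to
#'   \code{FALSE} to load reduced user tables (e.g. a trait subset for a
#'   small simulation), in which case only per-row validity is checked.
#' @return A \code{data.frame} of class \code{"trait_table"} with columns
#'   \code{trait_id}, \code{ukbb_field}, \code{domain}, \code{label},
#'   \code{prev_male}, \code{prev_female}, in canonical row order.
#' @export
load_trait_table <- function(path = bt_extdata("trait_table.tsv"), strict = TRUE) {
  tab <- read_tsv_checked(path, c("trait_id", "ukbb_field", "domain", "label",
                                  "prev_male", "prev_female"))
  if (anyDuplicated(tab$trait_id))
    bt_stop("duplicate trait_id entries in trait table", "validation")
  if (!all(tab$domain %in% TRAIT_DOMAINS))
    bt_stop(sprintf("unknown trait domain label(s): %s",
                    paste(unique(setdiff(tab$domain, TRAIT_DOMAINS)), collapse = ", ")),
            "validation")
  prev <- c(tab$prev_male, tab$prev_female)
  if (!is.numeric(prev) || any(!is.finite(prev)) || any(prev <= 0) || any(prev >= 1))
    bt_stop("trait prevalences must lie strictly in (0, 1)", "validation")
  if (strict) {
    if (nrow(tab) != N_TRAITS)
      bt_stop(sprintf("trait table must have exactly %d rows, got %d", N_TRAITS, nrow(tab)),
              "validation")
    counts <- table(factor(tab$domain, levels = TRAIT_DOMAINS))
    if (!all(counts == TRAIT_DOMAIN_COUNTS[names(counts)]))
      bt_stop(sprintf("trait domain split must be 12/15/13 (social/personality/demographic), got %s",
                      paste(counts, collapse = "/")), "validation")
  }
  tab$ukbb_field <- as.integer(tab$ukbb_field)
  rownames(tab) <- NULL
  class(tab) <- c("trait_table", "data.frame")
  tab
}

#' Load and validate the social brain atlas
#'
#' Reads the packaged atlas (or a user file in the same layout): 36 named
#' regions with consensus MNI coordinates (millimetres) and a functional
#' network label. Region order in the file is the canonical column ordering
#' used by every matrix in the package.
#'
#' @param path Tab-separated atlas with columns \code{region_id},
#'   \code{x}, \code{y}, \code{z}, \code{network} (optionally \code{label}).
#' @param sphere_diameter_mm Diameter of the extraction sphere around each
#'   consensus coordinate. Default 5 mm; 2.5 and 7.5 mm are the standard
#'   sensitivity alternatives.
#' @param smoothing_fwhm_mm Full width at half maximum of the Gaussian
#'   smoothing kernel applied to images before extraction. Default 5 mm.
#' @param strict Enforce the packaged invariants (exactly 36 regions).
#' @return An object of class \code{"atlas_spec"}: a list with elements
#'   \code{regions} (data.frame), \code{sphere_diameter_mm},
#'   \code{smoothing_fwhm_mm}.
#' @export
load_atlas <- function(path = bt_extdata("social_brain_atlas.tsv"),
                       sphere_diameter_mm = 5, smoothing_fwhm_mm = 5,
                       strict = TRUE) {
  tab <- read_tsv_checked(path, c("region_id", "x", "y", "z", "network"))
  if (anyDuplicated(tab$region_id))
    bt_stop("duplicate region_id entries in atlas", "validation")
  if (!all(tab$network %in% ATLAS_NETWORKS))
    bt_stop(sprintf("unknown network label(s): %s",
                    paste(unique(setdiff(tab$network, ATLAS_NETWORKS)), collapse = ", ")),
            "validation")
  for (cc in c("x", "y", "z"))
    if (!is.numeric(tab[[cc]]) || any(!is.finite(tab[[cc]])))
      bt_stop(sprintf("atlas coordinate column '%s' must be finite numeric", cc), "validation")
  if (strict) {
    if (nrow(tab) != N_REGIONS)
      bt_stop(sprintf("atlas must have exactly %d regions, got %d", N_REGIONS, nrow(tab)),
              "validation")
    if (!all(ATLAS_NETWORKS %in% tab$network))
      bt_stop("every atlas network must contain at least one region", "validation")
  }
  if (!is.numeric(sphere_diameter_mm) || sphere_diameter_mm <= 0)
    bt_stop("sphere_diameter_mm must be positive", "validation")
  if (!is.numeric(smoothing_fwhm_mm) || smoothing_fwhm_mm < 0)
    bt_stop("smoothing_fwhm_mm must be non-negative", "validation")
  rownames(tab) <- NULL
  structure(list(regions = tab,
                 sphere_diameter_mm = sphere_diameter_mm,
                 smoothing_fwhm_mm = smoothing_fwhm_mm),
            class = "atlas_spec")
}

#' @export
print.atlas_spec <- function(x, ...) {
  cat(sprintf("Social brain atlas: %d regions, sphere diameter %g mm, smoothing FWHM %g mm\n",
              nrow(x$regions), x$sphere_diameter_mm, x$smoothing_fwhm_mm))
  print(table(x$regions$network))
  invisible(x)
}

#' Write a trait table or atlas back to TSV
#'
#' Serialization is loss-free: reloading reproduces the object field for field.
#'
#' @param x A \code{trait_table} or \code{atlas_spec}.
#' @param path Output TSV path.
#' @export
write_spec_table <- function(x, path) {
  tab <- if (inherits(x, "atlas_spec")) x$regions else x
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

atlas_region_ids <- function(atlas) atlas$regions$region_id
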
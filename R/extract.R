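# Region-volume container plus the imaging path: voxel grids, Gaussian
# smoothing, sphere averaging, and column standardization.

#' Participants-by-regions volume matrix
#'
#' @param values Numeric matrix, participants in rows, regions in columns.
#' @param region_order Character vector of region ids (canonical order).
#' @param standardized Whether columns are z-scored.
#' @param partial Whether columns are partial (region-unique) residuals.
#' @return Object of class \code{"region_volume_matrix"}.
#' @export
region_volume_matrix <- function(values, region_order = colnames(values),
                                 standardized = FALSE, partial = FALSE) {
  values <- as.matrix(values)
  if (is.null(region_order)) bt_stop("region_order is required", "validation")
  if (ncol(values) != length(region_order))
    bt_stop("region_order length must match column count", "dimension")
  colnames(values) <- region_order
  structure(list(values = values, region_order = region_order,
                 standardized = standardized, partial = partial),
            class = "region_volume_matrix")
}

#' @export
print.region_volume_matrix <- function(x, ...) {
  cat(sprintf("Region volume matrix: %d participants x %d regions (%s%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$standardized) "standardized" else "raw",
              if (x$partial) ", partial residuals" else ""))
  invisible(x)
}

#' Regular voxel lattice in MNI millimetres
#'
#' Voxel \code{(i, j, k)} (1-based) has its center at
#' \code{origin + (c(i, j, k) - 1) * spacing} millimetres; this defines the
#' diagonal affine used when images are written to NIfTI.
#'
#' @param origin MNI coordinate (mm) of the first voxel center.
#' @param dim Integer triple of grid dimensions.
#' @param spacing Isotropic voxel size in mm (default 1).
#' @export
grid_spec <- function(origin, dim, spacing = 1) {
  if (length(origin) != 3 || length(dim) != 3)
    bt_stop("origin and dim must have length 3", "validation")
  if (spacing <= 0) bt_stop("spacing must be positive", "validation")
  structure(list(origin = as.numeric(origin), dim = as.integer(dim),
                 spacing = as.numeric(spacing)), class = "grid_spec")
}

grid_extent <- function(grid) {
  rbind(lo = grid$origin, hi = grid$origin + (grid$dim - 1) * grid$spacing)
}

grid_affine <- function(grid) {
  aff <- diag(c(rep(grid$spacing, 3), 1))
  aff[1:3, 4] <- grid$origin - grid$spacing  # NIfTI uses 0-based indices
  aff
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Voxel-center mask of a sphere: Euclidean distance to center <= radius
# (inclusive), computed by exhaustive scan over a bounding box.
sphere_mask_indices <- function(grid, center_mm, radius_mm) {
  ext <- grid_extent(grid)
  if (any(center_mm < ext["lo", ]) || any(center_mm > ext["hi", ]))
    bt_stop(sprintf("atlas coordinate (%s) lies outside the image grid",
                    paste(center_mm, collapse = ", ")), "out_of_grid")
  idx_c <- (center_mm - grid$origin) / grid$spacing + 1
  halo <- radius_mm / grid$spacing
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, floor(idx_c[a] - halo))
    hi <- min(grid$dim[a], ceiling(idx_c[a] + halo))
    seq.int(lo, hi)
  })
  gg <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  mm <- t(grid$origin + (t(as.matrix(gg)) - 1) * grid$spacing)
  d2 <- rowSums(sweep(mm, 2, center_mm)^2)
  keep <- d2 <= radius_mm^2 + 1e-9
  if (!any(keep))
    bt_stop(sprintf("no voxel center within %g mm of (%s)", radius_mm,
                    paste(center_mm, collapse = ", ")), "empty_sphere")
  m <- as.matrix(gg[keep, , drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Paint region volumes into per-participant voxel images
#'
#' Inverse of [extract_region_volumes()]: each participant's grid is a
#' baseline plus voxel noise, and voxels inside a region's sphere carry, in
#' addition, that participant's region value. Overlapping spheres add their
#' values (the construction is additive).
#'
#' @param cohort \code{cohort_table} (or \code{cohort_sim}); supplies the
#'   participant ids.
#' @param volumes \code{region_volume_matrix} with the values to paint.
#' @param atlas Atlas supplying sphere centers, diameter and the smoothing
#'   FWHM used in the margin check.
#' @param grid A [grid_spec()]; must cover every atlas coordinate with a
#'   margin of at least sphere radius + 3 smoothing sigmas.
#' @param seed Seed for voxel noise.
#' @param baseline Background intensity.
#' @param voxel_noise_sd Standard deviation of iid voxel noise (0 for none).
#' @return Object of class \code{"voxel_cohort"}: list of 3-D arrays plus
#'   the grid.
#' @export
simulate_voxel_cohort <- function(cohort, volumes, atlas, grid, seed,
                                  baseline = 0, voxel_noise_sd = 0) {
  if (inherits(cohort, "cohort_sim")) cohort <- cohort$cohort
  regions <- volumes$region_order
  coords <- as.matrix(atlas$regions[match(regions, atlas$regions$region_id),
                                    c("x", "y", "z")])
  if (anyNA(coords)) bt_stop("volume regions missing from atlas", "dimension")
  radius <- atlas$sphere_diameter_mm / 2
  margin <- radius + 3 * fwhm_to_sigma(atlas$smoothing_fwhm_mm)
  ext <- grid_extent(grid)
  ok <- coords - margin >= matrix(ext["lo", ], nrow(coords), 3, byrow = TRUE) &
    coords + margin <= matrix(ext["hi", ], nrow(coords), 3, byrow = TRUE)
  if (!all(ok))
    bt_stop(sprintf("grid too small: regions %s need a %g mm margin",
                    paste(regions[!apply(ok, 1, all)], collapse = ", "), margin),
            "grid_too_small")
  masks <- lapply(seq_along(regions), function(j)
    sphere_mask_indices(grid, coords[j, ], radius))
  set.seed(as.integer(seed) + 3L)
  n <- nrow(cohort)
  images <- vector("list", n)
  for (p in seq_len(n)) {
    arr <- array(baseline, dim = grid$dim)
    if (voxel_noise_sd > 0)
      arr <- arr + array(stats::rnorm(prod(grid$dim), 0, voxel_noise_sd), grid$dim)
    for (j in seq_along(regions))
      arr[masks[[j]]] <- arr[masks[[j]]] + volumes$values[p, j]
    images[[p]] <- arr
  }
  structure(list(images = images, grid = grid,
                 participant_id = cohort$participant_id),
            class = "voxel_cohort")
}

#' Separable Gaussian smoothing of a 3-D image
#'
#' Convolves with a normalized Gaussian kernel of the stated FWHM along each
#' axis (sigma = FWHM / (2 sqrt(2 ln 2)), converted from millimetres to
#' voxels). The kernel is truncated at 4 sigma; the image border is handled
#' by mirror reflection, which preserves constant images exactly and
#' conserves the total mass of any impulse.
#'
#' @param image 3-D numeric array.
#' @param fwhm_mm Kernel FWHM in millimetres; 0 returns the input unchanged.
#' @param voxel_mm Isotropic voxel size in millimetres (or a
#'   \code{grid_spec} from which it is taken).
#' @export
gaussian_smooth <- function(image, fwhm_mm, voxel_mm) {
  if (inherits(voxel_mm, "grid_spec")) voxel_mm <- voxel_mm$spacing
  if (!is.numeric(voxel_mm) || length(voxel_mm) != 1 || !is.finite(voxel_mm) ||
      voxel_mm <= 0)
    bt_stop("voxel size could not be derived; supply a positive voxel_mm", "affine")
  if (fwhm_mm == 0) return(image)
  sigma <- fwhm_to_sigma(fwhm_mm) / voxel_mm
  h <- max(1L, ceiling(4 * sigma))
  kern <- exp(-0.5 * ((-h:h) / sigma)^2)
  kern <- kern / sum(kern)
  d <- dim(image)
  for (axis in 1:3) {
    da <- d[axis]
    band <- matrix(0, da, da)
    for (o in -h:h) {
      i <- seq_len(da); j <- i + o
      # mirror reflection at the borders (half-sample symmetric)
      j <- ifelse(j < 1, 2L - j, j)
      j <- ifelse(j > da, 2L * da - j, j)
      j <- pmin(pmax(j, 1L), da)
      band[cbind(i, j)] <- band[cbind(i, j)] + kern[o + h + 1]
    }
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(image, perm), nrow = da)
    m <- band %*% m
    image <- aperm(array(m, dim = d[perm]), order(perm))
  }
  image
}

#' Extract standardized-ready region volumes from images
#'
#' For each participant image: smooth with the atlas FWHM, then average the
#' voxel values whose centers fall within sphere_diameter/2 millimetres
#' (inclusive) of each region's MNI coordinate. Returns the unstandardized
#' matrix; pass through [zscore_columns()] before modeling.
#'
#' @param images A \code{voxel_cohort}.
#' @param atlas Atlas with coordinates, sphere diameter, smoothing FWHM.
#' @param smooth Apply the smoothing step (default TRUE).
#' @return A \code{region_volume_matrix}.
#' @export
extract_region_volumes <- function(images, atlas, smooth = TRUE) {
  grid <- images$grid
  regions <- atlas$regions$region_id
  coords <- as.matrix(atlas$regions[, c("x", "y", "z")])
  radius <- atlas$sphere_diameter_mm / 2
  masks <- lapply(seq_along(regions), function(j)
    sphere_mask_indices(grid, coords[j, ], radius))
  n <- length(images$images)
  out <- matrix(NA_real_, n, length(regions), dimnames = list(NULL, regions))
  for (p in seq_len(n)) {
    img <- images$images[[p]]
    if (smooth && atlas$smoothing_fwhm_mm > 0)
      img <- gaussian_smooth(img, atlas$smoothing_fwhm_mm, grid$spacing)
    for (j in seq_along(regions)) out[p, j] <- mean(img[masks[[j]]])
  }
  region_volume_matrix(out, regions, standardized = FALSE)
}

#' Z-score the columns of a volume matrix
#'
#' Centers each region column to mean zero and scales to unit variance using
#' the population (divide-by-n) standard deviation, so results are exactly
#' reproducible across implementations.
#'
#' @param volumes A \code{region_volume_matrix} or plain matrix.
#' @export
zscore_columns <- function(volumes) {
  rvm <- inherits(volumes, "region_volume_matrix")
  m <- if (rvm) volumes$values else as.matrix(volumes)
  mu <- colMeans(m)
  cen <- sweep(m, 2, mu)
  sd_pop <- sqrt(colMeans(cen^2))
  bad <- !is.finite(sd_pop) | sd_pop < 1e-12
  if (any(bad))
    bt_stop(sprintf("column(s) with zero variance cannot be z-scored: %s",
                    paste(colnames(m)[bad], collapse = ", ")), "degenerate_column")
  z <- sweep(cen, 2, sd_pop, "/")
  if (rvm) {
    volumes$values <- z; volumes$standardized <- TRUE
    volumes
  } else {
    region_volume_matrix(z, colnames(m), standardized = TRUE)
  }
}

#' Write a voxel cohort as NIfTI-1 files
#'
#' One file per participant (\code{sub-<id>.nii}), with the diagonal affine
#' implied by the grid.
#'
#' @param images A \code{voxel_cohort}.
#' @param dir Output directory (created if needed).
#' @export
write_voxel_cohort <- function(images, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aff <- grid_affine(images$grid)
  paths <- character(length(images$images))
  for (p in seq_along(images$images)) {
    img <- RNifti::asNifti(images$images[[p]])
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    paths[p] <- file.path(dir, sprintf("sub-%04d.nii", images$participant_id[p]))
    RNifti::writeNifti(img, paths[p])
  }
  invisible(paths)
}

#' Read a directory of NIfTI images as a voxel cohort
#'
#' Expects the diagonal-affine layout written by [write_voxel_cohort()];
#' grids must agree across files.
#'
#' @param dir Directory of \code{.nii}/\code{.nii.gz} files.
#' @export
read_voxel_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  if (!length(files)) bt_stop(sprintf("no NIfTI files in %s", dir), "validation")
  imgs <- lapply(files, RNifti::readNifti)
  affs <- lapply(imgs, function(x) unclass(RNifti::xform(x)))
  dims <- lapply(imgs, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    bt_stop("images do not share a common grid", "dimension")
  aff <- affs[[1]]
  spacing <- aff[1, 1]
  if (abs(aff[2, 2] - spacing) > 1e-6 || abs(aff[3, 3] - spacing) > 1e-6)
    bt_stop("anisotropic or rotated affine not supported", "affine")
  origin <- aff[1:3, 4] + spacing
  grid <- grid_spec(origin, dims[[1]], spacing)
  ids <- as.integer(sub("^sub-0*([0-9]+)\\.nii(\\.gz)?$", "\\1", basename(files)))
  structure(list(images = lapply(imgs, function(x) array(as.numeric(x), dim(x))),
                 grid = grid, participant_id = ids),
            class = "voxel_cohort")
}
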
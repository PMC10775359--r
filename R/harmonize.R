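## Method-of-Moments harmonization: align the per-voxel mean and
## variance of the six selected-direction signals of a target site to a
## reference site through the voxelwise linear map f(S) = alpha * S + beta.

#' Per-voxel spherical moment maps over the six selected directions
#'
#' For each subject, computes the per-voxel mean and population (1/n)
#' variance of the six selected-direction signals; takes the voxelwise
#' median of each moment across subjects; and smooths both median
#' images with a Gaussian filter (sigma in voxels; 0 disables).  All
#' subjects must share the template grid (synthetic cohorts do by
#' construction; no registration is performed).
#'
#' @param subjects list of `subject_phantom`s on one grid.
#' @param six_indices measurement indices of the six selected
#'   directions (from [select_six_directions()]).
#' @param smoothing_sigma Gaussian sigma in voxels (default 1).
#' @return object of class `moment_maps`: list with `mean_map`,
#'   `var_map` (3D arrays), `n_subjects`, `smoothing_sigma`.
#' @export
compute_moment_maps <- function(subjects, six_indices, smoothing_sigma = 1) {
  if (!length(subjects)) stop2("need at least one subject")
  gs <- dim(subjects[[1]]$dwi)[1:3]
  means <- vars <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    d <- dim(subjects[[i]]$dwi)
    if (!all(d[1:3] == gs)) stop2("subjects are on mismatched grids")
    S <- matrix(subjects[[i]]$dwi, prod(gs), d[4])[, six_indices, drop = FALSE]
    m <- rowMeans(S)
    means[[i]] <- m
    vars[[i]] <- rowMeans(S^2) - m^2        # population (1/n) variance
  }
  med <- function(lst) {
    if (length(lst) == 1) return(array(lst[[1]], gs))
    array(apply(do.call(cbind, lst), 1, median), gs)
  }
  mean_map <- gaussian_smooth_3d(med(means), smoothing_sigma)
  var_map <- pmax(gaussian_smooth_3d(med(vars), smoothing_sigma), 0)
  structure(list(mean_map = mean_map, var_map = var_map,
                 n_subjects = length(subjects),
                 smoothing_sigma = smoothing_sigma),
            class = "moment_maps")
}

#' Derive the voxelwise linear harmonization map
#'
#' `alpha = sqrt(ref_var / max(src_var, var_floor))`,
#' `beta = ref_mean - alpha * src_mean`, per voxel, so that applying the
#' map to source-moment data reproduces the reference moments exactly
#' wherever the source variance is above the floor.  Alpha is clipped to
#' `alpha_bounds` and floored voxels are counted.
#'
#' @param source `moment_maps` of the data to be transformed.
#' @param reference `moment_maps` of the site to match.
#' @param var_floor positive variance floor guarding degenerate voxels.
#' @param alpha_bounds length-2 clipping interval for alpha.
#' @return object of class `harmonization_field`: list with 3D arrays
#'   `alpha`, `beta`, plus `n_floored` and `n_clipped` counts.
#' @export
derive_mapping <- function(source, reference, var_floor = 1e-6,
                           alpha_bounds = c(0.1, 10)) {
  if (!all(dim(source$mean_map) == dim(reference$mean_map))) {
    stop2("moment maps must share one grid")
  }
  if (var_floor <= 0) stop2("var_floor must be positive")
  sv <- pmax(source$var_map, var_floor)
  n_floored <- sum(source$var_map < var_floor)
  alpha_raw <- sqrt(reference$var_map / sv)
  alpha <- pmin(pmax(alpha_raw, alpha_bounds[1]), alpha_bounds[2])
  n_clipped <- sum(alpha != alpha_raw)
  beta <- reference$mean_map - alpha * source$mean_map
  structure(list(alpha = alpha, beta = beta,
                 n_floored = n_floored, n_clipped = n_clipped),
            class = "harmonization_field")
}

#' @export
print.harmonization_field <- function(x, ...) {
  cat(sprintf("<harmonization_field> alpha in [%.3g, %.3g], %d floored, %d clipped voxels\n",
              min(x$alpha), max(x$alpha), x$n_floored, x$n_clipped))
  invisible(x)
}

#' Apply a harmonization field to a signal volume
#'
#' `S' = alpha * S + beta` per voxel; every volume along the fourth
#' dimension shares the voxel's `(alpha, beta)`.  Output is floored at 0.
#'
#' @param dwi 4D signal array (e.g. the six selected-direction volumes).
#' @param field a [derive_mapping()] result.
#' @return harmonized 4D array.
#' @export
apply_mapping <- function(dwi, field) {
  d <- dim(dwi)
  if (!all(d[1:3] == dim(field$alpha))) stop2("grid mismatch")
  pmax(dwi * as.numeric(field$alpha) + as.numeric(field$beta), 0)
}

#' Harmonize a subject's DWI toward a reference site
#'
#' Applies the voxelwise `(alpha, beta)` map to all measurements the
#' downstream six-direction pipeline consumes (the six selected
#' directions and the b0s used for normalization), leaving the rest of
#' the scheme untouched.
#'
#' @param subject a `subject_phantom`.
#' @param field a [derive_mapping()] result.
#' @param six_indices indices of the six selected directions.
#' @return the subject with harmonized `dwi`.
#' @export
harmonize_subject <- function(subject, field, six_indices) {
  idx <- sort(unique(c(six_indices, b0_indices(subject$scheme))))
  d <- dim(subject$dwi)
  sub_ <- array(subject$dwi[, , , idx], c(d[1:3], length(idx)))
  subject$dwi[, , , idx] <- apply_mapping(sub_, field)
  subject
}

#' QC summary of pre/post harmonization moment discrepancies
#'
#' @param target_maps,harmonized_maps,reference_maps `moment_maps`.
#' @param mask optional 3D logical mask restricting the summary.
#' @return named list of mean absolute mean/variance discrepancies
#'   before and after harmonization.
#' @export
harmonization_qc <- function(target_maps, harmonized_maps, reference_maps,
                             mask = NULL) {
  sel <- if (is.null(mask)) TRUE else mask > 0
  d <- function(a, b) mean(abs(a[sel] - b[sel]))
  list(mean_abs_mean_pre = d(target_maps$mean_map, reference_maps$mean_map),
       mean_abs_mean_post = d(harmonized_maps$mean_map, reference_maps$mean_map),
       mean_abs_var_pre = d(target_maps$var_map, reference_maps$var_map),
       mean_abs_var_post = d(harmonized_maps$var_map, reference_maps$var_map))
}
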
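## Evaluation suite: Agreement Rate (peak-count consistency), Angular
## Error among GT-matched peaks, and Apparent Fiber Density error,
## stratified by ground-truth fiber count.

#' Angle between two directions with antipodal identification
#'
#' `acos(|u . v|)` in degrees, in `[0, 90]`.
#'
#' @param u,v unit 3-vectors (or n x 3 matrices, paired by row).
#' @return angle(s) in degrees.
#' @export
angular_error <- function(u, v) {
  u <- as_direction_matrix(u, tol = 1e-6, normalize = TRUE)
  v <- as_direction_matrix(v, tol = 1e-6, normalize = TRUE)
  peak_angle_deg(u, v)
}

#' Minimum-angle matching of predicted to ground-truth peaks
#'
#' Pairs ground-truth with predicted peaks, each used at most once and
#' only at angles up to `cap_deg`.  Among all admissible matchings the
#' one with the most pairs is chosen, ties resolved by the smallest
#' total angle and then by (gt index, pred index) order, so the result
#' is deterministic and exact for the small (at most `max_peaks`) sets
#' peak extraction produces.
#'
#' @param gt,pred [peak_set()]s.
#' @param cap_deg maximum pairing angle in degrees (default 45).
#' @return data.frame with columns `gt_index`, `pred_index`,
#'   `angle_deg` (zero rows if nothing matches).
#' @export
match_peaks <- function(gt, pred, cap_deg = 45) {
  ng <- length(gt$amplitudes); np <- length(pred$amplitudes)
  empty <- data.frame(gt_index = integer(0), pred_index = integer(0),
                      angle_deg = numeric(0))
  if (ng == 0 || np == 0) return(empty)
  m <- match_peaks_raw(gt$directions, pred$directions, cap_deg)
  if (!nrow(m)) return(empty)
  data.frame(gt_index = m[, 1], pred_index = m[, 2], angle_deg = m[, 3])
}

## Core of match_peaks on raw direction matrices; returns a matrix with
## columns (gt_index, pred_index, angle_deg).  Exhaustive search over
## injective matchings (feasible because peak sets are capped at a few
## peaks); falls back to greedy closest-pair matching for large sets.
match_peaks_raw <- function(gd, pd, cap_deg = 45) {
  ng <- nrow(gd); np <- nrow(pd)
  if (!ng || !np) return(matrix(0, 0, 3))
  ang <- matrix(acos(pmin(abs(gd %*% t(pd)), 1)) * 180 / pi, ng, np)
  if (ng > 5L || np > 5L) return(match_peaks_greedy(ang, cap_deg))
  best_pairs <- matrix(0L, 0, 2)
  best_n <- -1L; best_tot <- Inf
  rec <- function(i, used, pairs) {
    if (i > ng) {
      n <- nrow(pairs)
      tot <- if (n) sum(ang[pairs]) else 0
      if (n > best_n || (n == best_n && tot < best_tot - 1e-9)) {
        best_pairs <<- pairs; best_n <<- n; best_tot <<- tot
      }
      return()
    }
    for (j in seq_len(np)) {
      if (!used[j] && ang[i, j] <= cap_deg) {
        used[j] <- TRUE
        rec(i + 1L, used, rbind(pairs, c(i, j)))
        used[j] <- FALSE
      }
    }
    rec(i + 1L, used, pairs)          # leave gt peak i unmatched
  }
  rec(1L, logical(np), matrix(0L, 0, 2))
  if (best_n <= 0L) return(matrix(0, 0, 3))
  cbind(best_pairs, ang[best_pairs])
}

match_peaks_greedy <- function(ang, cap_deg) {
  a <- ang
  out <- matrix(0, min(dim(ang)), 3)
  k <- 0L
  repeat {
    mn <- min(a)
    if (!is.finite(mn) || mn > cap_deg) break
    w <- which(a == mn, arr.ind = TRUE)
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE][1, ]
    k <- k + 1L
    out[k, ] <- c(w[1], w[2], ang[w[1], w[2]])
    a[w[1], ] <- Inf
    a[, w[2]] <- Inf
  }
  out[seq_len(k), , drop = FALSE]
}

## Peak fields for the voxels of a mask, with caching hooks: metrics
## functions accept either sh_field objects or precomputed peak_fields.
as_peak_field <- function(x, wm_mask, peak_params = list()) {
  if (inherits(x, "peak_field")) return(x)
  if (!inherits(x, "sh_field")) stop2("expected an sh_field or peak_field")
  vox <- which(wm_mask > 0)
  do.call(extract_peaks_field,
          c(list(coeffs = x$coefficients[, vox, drop = FALSE]), peak_params))
}

#' Agreement Rate for one fiber-count stratum
#'
#' Among mask voxels whose ground-truth FOD has exactly `k` peaks, the
#' percentage whose predicted FOD also has exactly `k` peaks.  An empty
#' stratum is reported as `NA` (missing), not 0.
#'
#' @param gt_field,pred_field [sh_field()]s (or precomputed
#'   `peak_field`s over the mask voxels).
#' @param wm_mask 3D logical mask.
#' @param k fiber count stratum (1, 2 or 3).
#' @param peak_params list of arguments for [extract_peaks_field()].
#' @return percentage in `[0, 100]`, or `NA` for an empty stratum.
#' @export
agreement_rate <- function(gt_field, pred_field, wm_mask, k,
                           peak_params = list()) {
  pg <- as_peak_field(gt_field, wm_mask, peak_params)
  pp <- as_peak_field(pred_field, wm_mask, peak_params)
  sel <- pg$count == k
  if (!any(sel)) return(NA_real_)
  100 * mean(pp$count[sel] == k)
}

#' Mean Angular Error for one stratum, over GT-matched peak pairs
#'
#' Over mask voxels in ground-truth stratum `k`, pools the matched-pair
#' angles from [match_peaks()] and returns their mean.  Zero matched
#' pairs gives `NA`.
#'
#' @inheritParams agreement_rate
#' @param cap_deg matching cap passed to [match_peaks()].
#' @return mean angle in degrees, or `NA`.
#' @export
angular_error_field <- function(gt_field, pred_field, wm_mask, k,
                                peak_params = list(), cap_deg = 45) {
  pg <- as_peak_field(gt_field, wm_mask, peak_params)
  pp <- as_peak_field(pred_field, wm_mask, peak_params)
  sel <- which(pg$count == k)
  angs <- unlist(lapply(sel, function(v) {
    match_peaks_raw(pg$directions[[v]], pp$directions[[v]],
                    cap_deg = cap_deg)[, 3]
  }))
  if (!length(angs)) return(NA_real_)
  mean(angs)
}

#' Apparent Fiber Density error
#'
#' Per voxel, total AFD is the FOD's sphere integral, `c00 * 2 sqrt(pi)`;
#' the error is the mean absolute difference over mask voxels.
#'
#' @param gt_field,pred_field [sh_field()]s on the same grid.
#' @param wm_mask 3D logical mask.
#' @return mean `|AFD_pred - AFD_gt|`.
#' @export
afd_error <- function(gt_field, pred_field, wm_mask) {
  if (!all(gt_field$grid_shape == pred_field$grid_shape)) {
    stop2("FOD fields must share one grid")
  }
  vox <- which(wm_mask > 0)
  s <- 2 * sqrt(pi)
  mean(abs(pred_field$coefficients[1, vox] - gt_field$coefficients[1, vox]) * s)
}

#' Full metric report: AR/AE per fiber stratum plus AFD error
#'
#' Extracts peaks once per field and assembles Agreement Rate and
#' Angular Error for k = 1, 2, 3 together with the AFD error and
#' stratum voxel counts.  Three-fiber rows are computed but can be
#' flagged as excluded from headline comparisons.
#'
#' @param gt_field,pred_field [sh_field()]s on the same grid.
#' @param wm_mask 3D logical mask (non-empty).
#' @param peak_params list of arguments for [extract_peaks_field()].
#' @param cap_deg peak-matching cap in degrees.
#' @param gt_peaks,pred_peaks optional precomputed `peak_field`s over
#'   the mask voxels (avoids re-extracting the same peaks repeatedly).
#' @param exclude_3f logical flag recorded in the report (3-fiber rows
#'   stay available either way).
#' @return object of class `metrics_report`.
#' @export
evaluate_fods <- function(gt_field, pred_field, wm_mask,
                          peak_params = list(), cap_deg = 45,
                          gt_peaks = NULL, pred_peaks = NULL,
                          exclude_3f = TRUE) {
  if (!any(wm_mask)) stop2("white-matter mask is empty")
  pg <- gt_peaks %||% as_peak_field(gt_field, wm_mask, peak_params)
  pp <- pred_peaks %||% as_peak_field(pred_field, wm_mask, peak_params)
  ks <- 1:3
  ar <- ae <- rep(NA_real_, 3)
  nvox <- nmatch <- integer(3)
  for (k in ks) {
    sel <- which(pg$count == k)
    nvox[k] <- length(sel)
    if (!length(sel)) next
    ar[k] <- 100 * mean(pp$count[sel] == k)
    angs <- unlist(lapply(sel, function(v) {
      match_peaks_raw(pg$directions[[v]], pp$directions[[v]],
                      cap_deg = cap_deg)[, 3]
    }))
    nmatch[k] <- length(angs)
    if (length(angs)) ae[k] <- mean(angs)
  }
  structure(list(ar_by_k = ar, ae_by_k = ae,
                 afd_error = afd_error(gt_field, pred_field, wm_mask),
                 n_voxels_by_k = nvox, n_matched_pairs_by_k = nmatch,
                 n_zero_peak_gt = sum(pg$count == 0),
                 exclude_3f = exclude_3f),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(as.data.frame(x), row.names = FALSE)
  cat(sprintf("  AFD error: %.4f\n", x$afd_error))
  invisible(x)
}

#' Tidy a metrics report into a one-row-per-stratum data frame
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return data.frame with `k`, `ar`, `ae`, `n_voxels`, `n_matched`.
#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(k = 1:3, ar = x$ar_by_k, ae = x$ae_by_k,
             n_voxels = x$n_voxels_by_k, n_matched = x$n_matched_pairs_by_k)
}

## Mean of several metrics_reports (unweighted over reports; NA strata
## are dropped per stratum).
mean_metrics <- function(reports) {
  pick <- function(f) sapply(reports, f)
  ar <- rowMeans(sapply(reports, function(r) r$ar_by_k), na.rm = TRUE)
  ae <- rowMeans(sapply(reports, function(r) r$ae_by_k), na.rm = TRUE)
  ar[is.nan(ar)] <- NA_real_; ae[is.nan(ae)] <- NA_real_
  structure(list(ar_by_k = ar, ae_by_k = ae,
                 afd_error = mean(pick(function(r) r$afd_error)),
                 n_voxels_by_k = Reduce(`+`, lapply(reports, `[[`, "n_voxels_by_k")),
                 n_matched_pairs_by_k = Reduce(`+`, lapply(reports, `[[`, "n_matched_pairs_by_k")),
                 n_zero_peak_gt = sum(pick(function(r) r$n_zero_peak_gt)),
                 exclude_3f = reports[[1]]$exclude_3f),
            class = "metrics_report")
}
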
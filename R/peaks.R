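## FOD peak extraction on a dense antipodally symmetric grid, with
## batched tangent-plane ascent refinement.  Peaks are the discrete
## fiber directions read off an FOD; every evaluation metric in the
## package is built on them.

#' Construct a peak set
#'
#' @param directions k x 3 unit vectors (antipodally identified).
#' @param amplitudes FOD amplitudes at the peaks, non-negative.
#' @return object of class `peak_set`, sorted by descending amplitude.
#' @export
peak_set <- function(directions = matrix(numeric(0), 0, 3),
                     amplitudes = numeric(0)) {
  directions <- if (nrow(directions) > 0) {
    as_direction_matrix(directions, tol = 1e-6, normalize = TRUE)
  } else {
    matrix(numeric(0), 0, 3)
  }
  if (nrow(directions) != length(amplitudes)) {
    stop2("one amplitude per peak direction")
  }
  o <- order(amplitudes, decreasing = TRUE)
  structure(list(directions = directions[o, , drop = FALSE],
                 amplitudes = amplitudes[o]),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> ", length(x$amplitudes), " peak(s)\n", sep = "")
  if (length(x$amplitudes)) {
    print(cbind(round(x$directions, 4), amplitude = round(x$amplitudes, 4)))
  }
  invisible(x)
}

## k-nearest-neighbour index matrix (by angular distance, no antipodal
## identification: the grid itself contains both hemispheres).
grid_neighbors <- function(grid, k = 8L) {
  G <- grid %*% t(grid)
  n <- nrow(grid)
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    o <- order(G[i, ], decreasing = TRUE)
    idx[i, ] <- o[o != i][seq_len(k)]
  }
  idx
}

## Cached default grid/neighbor structures (724-point grid, lmax 8 basis).
.peak_cache <- new.env(parent = emptyenv())

peak_grid_struct <- function(n_half = 362L, lmax = 8L, k = 8L) {
  key <- paste(n_half, lmax, k, sep = "-")
  if (is.null(.peak_cache[[key]])) {
    grid <- sphere_grid(n_half)
    .peak_cache[[key]] <- list(grid = grid,
                               basis = sh_basis(grid, lmax),
                               neigh = grid_neighbors(grid, k))
  }
  .peak_cache[[key]]
}

## Angle in degrees between unit vectors with antipodal identification.
peak_angle_deg <- function(u, v) {
  d <- pmin(1, abs(rowSums(u * v)))
  acos(d) * 180 / pi
}

#' Extract FOD peaks from an SH coefficient vector
#'
#' Finds strict local maxima of the FOD on a dense antipodally symmetric
#' grid's neighbourhood graph, refines each by tangent-plane ascent,
#' discards peaks below `rel_threshold` times the largest amplitude,
#' merges peaks closer than `min_separation_deg` (keeping the larger)
#' and returns at most `max_peaks` peaks.  An FOD that is nowhere
#' positive yields an empty peak set; so does a constant (isotropic)
#' FOD, which has no strict local maximum.
#'
#' @param fod SH coefficient vector (even order).
#' @param grid optional dense grid (matrix of unit vectors); defaults to
#'   the package 724-point grid.
#' @param rel_threshold relative amplitude cutoff in (0, 1).
#' @param min_separation_deg merge radius in degrees.
#' @param max_peaks maximum number of peaks returned.
#' @param refine logical: run local ascent refinement (default TRUE).
#' @return a [peak_set()].
#' @export
extract_peaks <- function(fod, grid = NULL, rel_threshold = 0.1,
                          min_separation_deg = 15, max_peaks = 3L,
                          refine = TRUE) {
  pf <- extract_peaks_field(cbind(fod), grid = grid,
                            rel_threshold = rel_threshold,
                            min_separation_deg = min_separation_deg,
                            max_peaks = max_peaks, refine = refine)
  peak_field_get(pf, 1L)
}

#' Extract peaks for a whole field of FODs (vectorized)
#'
#' Same algorithm as [extract_peaks()] applied to every column of a
#' coefficient matrix at once; the dense-grid evaluation and the ascent
#' refinement are batched across voxels.
#'
#' @param coeffs ncoef x nvox matrix of SH coefficients.
#' @inheritParams extract_peaks
#' @return object of class `peak_field`: a list with `count` (integer
#'   per voxel), `directions` (list of k x 3 matrices) and `amplitudes`.
#' @export
extract_peaks_field <- function(coeffs, grid = NULL, rel_threshold = 0.1,
                                min_separation_deg = 15, max_peaks = 3L,
                                refine = TRUE) {
  if (!is.matrix(coeffs)) coeffs <- cbind(coeffs)
  if (rel_threshold <= 0 || rel_threshold >= 1) {
    stop2("rel_threshold must lie strictly between 0 and 1")
  }
  lmax <- lmax_from_ncoef(nrow(coeffs))
  if (is.null(grid)) {
    gs <- peak_grid_struct(lmax = lmax)
    grid <- gs$grid; B <- gs$basis; neigh <- gs$neigh
  } else {
    grid <- as_direction_matrix(grid)
    B <- sh_basis(grid, lmax)
    neigh <- grid_neighbors(grid)
  }
  nvox <- ncol(coeffs)
  A <- B %*% coeffs                          # ngrid x nvox amplitudes
  nm <- A[neigh[, 1], , drop = FALSE]
  for (j in 2:ncol(neigh)) nm <- pmax(nm, A[neigh[, j], , drop = FALSE])
  is_max <- A > nm & A > 0

  w <- which(is_max)
  cand_idx <- (w - 1L) %% nrow(A) + 1L
  cand_vox <- (w - 1L) %/% nrow(A) + 1L
  cand_dir <- grid[cand_idx, , drop = FALSE]
  cand_amp <- A[w]

  min_dot <- cos(min_separation_deg * pi / 180)
  ## deterministic candidate order per voxel: amplitude desc, ties by
  ## lexicographic direction
  merge_voxel <- function(d, a) {
    o <- order(-a, d[, 1], d[, 2], d[, 3])
    d <- d[o, , drop = FALSE]; a <- a[o]
    keep <- logical(length(a))
    for (i in seq_along(a)) {
      prev <- which(keep)
      if (!length(prev) ||
          all(abs(d[prev, , drop = FALSE] %*% d[i, ]) <= min_dot)) {
        keep[i] <- TRUE
      }
    }
    list(d = d[keep, , drop = FALSE], a = a[keep])
  }

  counts <- integer(nvox)
  dirs <- vector("list", nvox)
  amps <- vector("list", nvox)
  empty <- matrix(numeric(0), 0, 3)
  split_idx <- split(seq_along(cand_vox), factor(cand_vox, levels = seq_len(nvox)))
  ## first pass at grid resolution: merge antipodal twins and nearby
  ## maxima, drop clearly sub-threshold lobes, cap the count
  for (v in seq_len(nvox)) {
    ii <- split_idx[[v]]
    if (!length(ii)) { dirs[[v]] <- empty; amps[[v]] <- numeric(0); next }
    m <- merge_voxel(cand_dir[ii, , drop = FALSE], cand_amp[ii])
    sel <- m$a >= 0.5 * rel_threshold * m$a[1] &
      seq_along(m$a) <= max_peaks + 1L
    dirs[[v]] <- m$d[sel, , drop = FALSE]
    amps[[v]] <- m$a[sel]
  }

  if (refine) {
    rv <- rep.int(seq_len(nvox), vapply(amps, length, 1L))
    if (length(rv)) {
      rd <- do.call(rbind, dirs[vapply(dirs, nrow, 1L) > 0])
      ra <- unlist(amps)
      ref <- refine_peaks_batch(rd, rv, coeffs, lmax)
      ok <- ref$amp >= ra - 1e-12
      rd[ok, ] <- ref$dir[ok, , drop = FALSE]
      ra[ok] <- ref$amp[ok]
      back <- split(seq_along(rv), factor(rv, levels = seq_len(nvox)))
      for (v in seq_len(nvox)) {
        jj <- back[[v]]
        if (!length(jj)) next
        ## refined peaks may have coalesced: merge again
        m <- merge_voxel(rd[jj, , drop = FALSE], ra[jj])
        dirs[[v]] <- m$d
        amps[[v]] <- m$a
      }
    }
  }
  for (v in seq_len(nvox)) {
    a <- amps[[v]]
    if (!length(a)) { counts[v] <- 0L; next }
    sel <- a >= rel_threshold * a[1] & seq_along(a) <= max_peaks
    dirs[[v]] <- dirs[[v]][sel, , drop = FALSE]
    amps[[v]] <- a[sel]
    counts[v] <- sum(sel)
  }
  structure(list(count = counts, directions = dirs, amplitudes = amps),
            class = "peak_field")
}

#' @export
print.peak_field <- function(x, ...) {
  cat("<peak_field> ", length(x$count), " voxels; peak counts: ", sep = "")
  print(table(x$count))
  invisible(x)
}

## The peak_set of voxel v within a peak_field.
peak_field_get <- function(pf, v) {
  peak_set(pf$directions[[v]], pf$amplitudes[[v]])
}

## Batched tangent-plane gradient ascent: refines all candidate peaks of
## all voxels simultaneously.  Step size adapts per peak (halved when a
## step does not improve the amplitude).
refine_peaks_batch <- function(dir0, vox, coeffs, lmax,
                               n_iter = 16L, step0 = 2 * pi / 180,
                               eps = 0.25 * pi / 180) {
  n <- nrow(dir0)
  d <- dir0
  TC <- t(coeffs[, vox, drop = FALSE])     # n x ncoef, fixed across iterations
  amp_at <- function(dd) rowSums(sh_basis(dd, lmax) * TC)
  f <- amp_at(d)
  step <- rep(step0, n)
  for (it in seq_len(n_iter)) {
    ## local tangent frame per peak
    ref <- matrix(c(0, 0, 1), n, 3, byrow = TRUE)
    near_z <- abs(d[, 3]) >= 0.9
    if (any(near_z)) {
      ref[near_z, ] <- matrix(c(1, 0, 0), sum(near_z), 3, byrow = TRUE)
    }
    t1 <- cbind(d[, 2] * ref[, 3] - d[, 3] * ref[, 2],
                d[, 3] * ref[, 1] - d[, 1] * ref[, 3],
                d[, 1] * ref[, 2] - d[, 2] * ref[, 1])
    t1 <- t1 / sqrt(rowSums(t1^2))
    t2 <- cbind(d[, 2] * t1[, 3] - d[, 3] * t1[, 2],
                d[, 3] * t1[, 1] - d[, 1] * t1[, 3],
                d[, 1] * t1[, 2] - d[, 2] * t1[, 1])
    rot <- function(dd, tt, ang) {
      out <- dd * cos(ang) + tt * sin(ang)
      out / sqrt(rowSums(out^2))
    }
    g1 <- (amp_at(rot(d, t1, eps)) - amp_at(rot(d, t1, -eps))) / (2 * eps)
    g2 <- (amp_at(rot(d, t2, eps)) - amp_at(rot(d, t2, -eps))) / (2 * eps)
    gn <- sqrt(g1^2 + g2^2)
    gn[gn < 1e-12] <- 1e-12
    move <- t1 * (g1 / gn) + t2 * (g2 / gn)
    cand <- rot(d, move, step)
    fc <- amp_at(cand)
    better <- fc > f
    d[better, ] <- cand[better, , drop = FALSE]
    f[better] <- fc[better]
    step[!better] <- step[!better] / 2
    if (all(step < 1e-5)) break
  }
  list(dir = d, amp = f)
}
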
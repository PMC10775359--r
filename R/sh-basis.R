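## Real even-order spherical harmonics: the mathematical substrate for
## signal projection, FOD representation and peak extraction.
##
## Convention (fixed for the whole package): real, symmetric basis using
## even orders l only, columns ordered l-major with m running from -l to
## +l within each order (the ordering used by MRtrix-style FOD files).
## Negative m carries sin(|m| phi), positive m carries cos(m phi), and
## the basis is orthonormal over the unit sphere.

#' Number of real even-order SH coefficients up to order `lmax`
#'
#' @param lmax even non-negative integer.
#' @return `(lmax + 1) * (lmax + 2) / 2`.
#' @export
sh_ncoef <- function(lmax) {
  check_lmax(lmax)
  as.integer((lmax + 1) * (lmax + 2) / 2)
}

check_lmax <- function(lmax) {
  if (length(lmax) != 1L || lmax < 0 || lmax %% 2 != 0) {
    stop2("lmax must be a single even non-negative integer, got ", lmax)
  }
  invisible(lmax)
}

#' (l, m) index pairs for the package's SH coefficient ordering
#'
#' @param lmax even non-negative integer.
#' @return data.frame with columns `l` and `m`, one row per coefficient.
#' @export
sh_index_table <- function(lmax) {
  check_lmax(lmax)
  l <- unlist(lapply(seq(0, lmax, by = 2), function(li) rep(li, 2 * li + 1)))
  m <- unlist(lapply(seq(0, lmax, by = 2), function(li) seq(-li, li)))
  data.frame(l = l, m = m)
}

## Associated Legendre functions P_l^m(x) (Condon-Shortley phase) for
## all l = 0..lmax, m = 0..l, via the standard stable recurrences,
## vectorized over x.  Returns a list indexed [[l + 1]][[m + 1]].
assoc_legendre_table <- function(x, lmax) {
  P <- lapply(0:lmax, function(l) vector("list", l + 1L))
  s <- sqrt(pmax(0, 1 - x^2))
  for (m in 0:lmax) {
    ## P_m^m = (-1)^m (2m-1)!! (1-x^2)^{m/2}
    pmm <- if (m == 0) rep(1, length(x)) else {
      (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) * s^m
    }
    P[[m + 1L]][[m + 1L]] <- pmm
    if (m < lmax) {
      pm1 <- x * (2 * m + 1) * pmm          # P_{m+1}^m
      P[[m + 2L]][[m + 1L]] <- pm1
      if (m + 2L <= lmax) {
        for (l in (m + 2L):lmax) {
          pl <- ((2 * l - 1) * x * pm1 - (l + m - 1) * pmm) / (l - m)
          P[[l + 1L]][[m + 1L]] <- pl
          pmm <- pm1; pm1 <- pl
        }
      }
    }
  }
  P
}

#' Build the real even-order SH design matrix
#'
#' Evaluates every basis function up to even order `lmax` at the given
#' unit directions.  Rows correspond to directions, columns to (l, m)
#' pairs in the package ordering (see [sh_index_table()]).  The basis is
#' antipodally symmetric: the row for `-u` equals the row for `u`.
#'
#' @param directions n x 3 matrix of unit vectors (or a flat numeric
#'   vector of length 3k).
#' @param lmax even non-negative integer.
#' @return n x `sh_ncoef(lmax)` numeric matrix.
#' @export
sh_basis <- function(directions, lmax) {
  check_lmax(lmax)
  u <- as_direction_matrix(directions)
  n <- nrow(u)
  ct <- pmin(1, pmax(-1, u[, 3]))          # cos(theta)
  phi <- atan2(u[, 2], u[, 1])
  B <- matrix(0, n, sh_ncoef(lmax))
  P <- assoc_legendre_table(ct, lmax)
  cosm <- lapply(seq_len(max(lmax, 1L)), function(m) cos(m * phi))
  sinm <- lapply(seq_len(max(lmax, 1L)), function(m) sin(m * phi))
  col <- 1L
  for (l in seq(0, lmax, by = 2)) {
    for (m in seq(-l, l)) {
      am <- abs(m)
      Nlm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lfactorial(l - am) - lfactorial(l + am)))
      base <- Nlm * P[[l + 1L]][[am + 1L]]
      B[, col] <- if (m < 0) {
        sqrt(2) * base * sinm[[am]]
      } else if (m == 0) {
        base
      } else {
        sqrt(2) * base * cosm[[m]]
      }
      col <- col + 1L
    }
  }
  B
}

#' Project per-direction values onto the SH basis
#'
#' (Regularized) least-squares fit of real even-order SH coefficients to
#' sampled values.  With `ridge = 0` the system must be determined
#' (`length(values) >= sh_ncoef(lmax)`); six well-spread measurements at
#' `lmax = 2` give an exact 6 x 6 solve.
#'
#' @param values numeric vector of samples, one per direction.
#' @param directions n x 3 unit vectors where `values` were sampled.
#' @param lmax even non-negative integer.
#' @param ridge non-negative Tikhonov weight (0 = plain least squares).
#' @return numeric coefficient vector of length `sh_ncoef(lmax)`.
#' @export
sh_project <- function(values, directions, lmax, ridge = 0) {
  u <- as_direction_matrix(directions)
  if (length(values) != nrow(u)) {
    stop2("length(values) must match the number of directions")
  }
  if (ridge < 0) stop2("ridge must be non-negative")
  nc <- sh_ncoef(lmax)
  if (ridge == 0 && length(values) < nc) {
    stop2("underdetermined SH fit: ", length(values), " directions for ",
          nc, " coefficients; supply more directions or a positive ridge")
  }
  B <- sh_basis(u, lmax)
  if (ridge == 0) {
    qr.solve(B, values)
  } else {
    solve(crossprod(B) + diag(ridge, nc), crossprod(B, values))[, 1]
  }
}

#' Evaluate an SH coefficient vector (or field) at unit directions
#'
#' @param coeffs coefficient vector of length `sh_ncoef(lmax)` for some
#'   even `lmax`, or a matrix with one column per voxel.
#' @param directions n x 3 unit vectors.
#' @return numeric vector of length n (or an n x nvox matrix).
#' @export
sh_evaluate <- function(coeffs, directions) {
  nc <- if (is.matrix(coeffs)) nrow(coeffs) else length(coeffs)
  lmax <- lmax_from_ncoef(nc)
  B <- sh_basis(directions, lmax)
  out <- B %*% (if (is.matrix(coeffs)) coeffs else cbind(coeffs))
  if (is.matrix(coeffs)) out else as.numeric(out)
}

## Inverse of sh_ncoef; errors on lengths that match no even order.
lmax_from_ncoef <- function(nc) {
  lmax <- (sqrt(8 * nc + 1) - 3) / 2
  if (abs(lmax - round(lmax)) > 1e-9 || round(lmax) %% 2 != 0) {
    stop2("coefficient length ", nc, " matches no even SH order")
  }
  as.integer(round(lmax))
}

#' Antipodally symmetric spherical point grid
#'
#' Golden-angle spiral over the upper hemisphere, mirrored through the
#' origin, giving `2 * n_half` points used as the dense evaluation grid
#' for peak finding and as the non-negativity constraint grid in CSD.
#'
#' @param n_half points per hemisphere (default 362, i.e. a 724-point grid).
#' @return `2 n_half` x 3 matrix of unit vectors.
#' @export
sphere_grid <- function(n_half = 362L) {
  i <- seq_len(n_half)
  z <- (i - 0.5) / n_half          # uniform in (0, 1): upper hemisphere
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  g <- cbind(r * cos(phi), r * sin(phi), z)
  rbind(g, -g)
}

#' Band-limited apodized delta kernel (zonal Legendre coefficients)
#'
#' Legendre expansion coefficients of an axial Watson-shaped kernel
#' `exp(kappa * t^2)`, normalized so that the sphere integral of the
#' reconstructed kernel is exactly 1 (`4 * pi * k_0 = 1`).  Used to turn
#' discrete fiber directions into smooth band-limited ground-truth FODs.
#'
#' @param lmax even truncation order.
#' @param kappa concentration of the axial kernel (larger = sharper lobe).
#' @return numeric vector `k_l` for even l = 0, 2, ..., lmax.
#' @export
apodized_delta_kernel <- function(lmax = 8L, kappa = 12) {
  check_lmax(lmax)
  gq <- pracma::gaussLegendre(128, -1, 1)
  Kt <- exp(kappa * gq$x^2)
  ls <- seq(0, lmax, by = 2)
  Ptab <- assoc_legendre_table(gq$x, lmax)
  kl <- vapply(ls, function(l) {
    (2 * l + 1) / 2 * sum(gq$w * Kt * Ptab[[l + 1L]][[1L]])
  }, numeric(1))
  kl / (4 * pi * kl[1])
}

#' SH coefficients of a mixture of apodized delta lobes
#'
#' By the addition theorem, a zonal kernel centred on `u` has SH
#' coefficients `k_l * 4 pi / (2l + 1) * Y_lm(u)`; a fiber mixture sums
#' these over its populations weighted by the volume fractions.
#'
#' @param directions k x 3 unit lobe directions.
#' @param fractions volume fraction per lobe.
#' @param lmax even truncation order.
#' @param kernel optional precomputed [apodized_delta_kernel()].
#' @return SH coefficient vector of length `sh_ncoef(lmax)`.
#' @export
delta_mixture_sh <- function(directions, fractions, lmax = 8L,
                             kernel = NULL) {
  u <- as_direction_matrix(directions)
  if (length(fractions) != nrow(u)) stop2("one fraction per direction")
  kl <- kernel %||% apodized_delta_kernel(lmax)
  idx <- sh_index_table(lmax)
  wl <- (4 * pi / (2 * idx$l + 1)) * kl[match(idx$l, seq(0, lmax, by = 2))]
  Y <- sh_basis(u, lmax)                     # nfib x ncoef
  as.numeric(crossprod(Y, fractions) * wl)
}
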
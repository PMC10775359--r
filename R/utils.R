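#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif median var optim dnorm quantile coef fitted
#' @importFrom utils combn head modifyList
NULL

## Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Derive a reproducible child seed from a master seed and a label
#'
#' Every stochastic stage of the toolkit draws its seed through this
#' function so that one master seed fans out deterministically to cohort
#' generation, noise, training batch order, initialization and dropout.
#' The result always lies in `[0, 2^31 - 1]`.
#'
#' @param master integer master seed.
#' @param label character label naming the consumer (e.g. `"subject-3-noise"`).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, label) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

## Run code under a local RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Coerce a directions argument to an n x 3 matrix of unit vectors.
as_direction_matrix <- function(directions, tol = 1e-10, normalize = FALSE) {
  if (is.numeric(directions) && is.null(dim(directions))) {
    directions <- matrix(directions, ncol = 3, byrow = TRUE)
  }
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop2("directions must be 3-vectors")
  if (nrow(directions) < 1L) stop2("need at least one direction")
  nrm <- sqrt(rowSums(directions^2))
  if (normalize) {
    if (any(nrm < tol)) stop2("zero-length direction cannot be normalized")
    directions <- directions / nrm
  } else if (any(abs(nrm - 1) > tol)) {
    stop2("directions must be unit vectors (norm deviates by > ", tol, ")")
  }
  directions
}

## Linear (column-major) voxel indices for a 3D grid.
grid_nvox <- function(grid_shape) prod(as.integer(grid_shape))

## A smooth random scalar field on a 3D grid: a fixed number of
## random-phase low-frequency cosine modes, standardized to roughly
## unit amplitude.  Deterministic for a given seed.
smooth_random_field <- function(grid_shape, seed, n_modes = 6L,
                                max_cycles = 1.5) {
  grid_shape <- as.integer(grid_shape)
  with_seed(seed, {
    ax <- lapply(grid_shape, function(n) (seq_len(n) - 0.5) / n)
    g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
    f <- numeric(nrow(g))
    for (i in seq_len(n_modes)) {
      k <- runif(3, -max_cycles, max_cycles) * 2 * pi
      ph <- runif(1, 0, 2 * pi)
      f <- f + cos(g$x * k[1] + g$y * k[2] + g$z * k[3] + ph)
    }
    f <- f / sqrt(n_modes / 2)   # approx unit variance
    array(f, dim = grid_shape)
  })
}

## Separable 3D Gaussian smoothing with normalized-convolution edge
## handling, so constant images are preserved exactly.  sigma in voxels;
## sigma = 0 returns the input unchanged.
gaussian_smooth_3d <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  sm1 <- function(x) {        # smooth along first dim of a 3D array
    d <- dim(x)
    out <- array(0, d)
    wgt <- array(0, d)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_len(d[1]) + off
      ok <- src >= 1L & src <= d[1]
      out[ok, , ] <- out[ok, , ] + k[j] * x[src[ok], , ]
      wgt[ok, , ] <- wgt[ok, , ] + k[j]
    }
    out / wgt
  }
  v <- sm1(vol)
  v <- aperm(sm1(aperm(v, c(2, 1, 3))), c(2, 1, 3))
  aperm(sm1(aperm(v, c(3, 2, 1))), c(3, 2, 1))
}
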
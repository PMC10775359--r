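# Shared fixture builders: everything is generated in code at test time.

# A fiber configuration where every WM voxel holds one population along
# a fixed direction (defaults to +z over the whole grid).
single_fiber_config <- function(grid_shape = c(6L, 6L, 6L),
                                direction = c(0, 0, 1), seed = 1L) {
  spec <- region_spec(shares = c(1, 0, 0), wm_lo = c(1L, 1L, 1L),
                      wm_hi = grid_shape, jitter_deg = 0,
                      base_dirs = list(matrix(direction, 1), NULL, NULL))
  sample_fiber_geometry(grid_shape, spec, seed = seed)
}

# Deterministic rotation matrix about an axis.
rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# The six icosahedral vertex axes: an optimal spread for order-2 SH.
ico6 <- function() {
  phi <- (1 + sqrt(5)) / 2
  u <- rbind(c(0, 1, phi), c(0, -1, phi), c(1, phi, 0),
             c(-1, phi, 0), c(phi, 0, 1), c(-phi, 0, 1))
  u / sqrt(rowSums(u^2))
}

# Random unit vectors (rows), optionally restricted to a hemisphere.
random_dirs <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(rnorm(3 * n), n, 3)
  u / sqrt(rowSums(u^2))
}

# A tiny noiseless subject phantom built directly from a fiber config.
phantom_from_config <- function(config, scheme, diffusivities = c(1.7e-3, 3e-4),
                                S0 = 100, age = 6, site = "test", seed = 1L) {
  dwi <- simulate_signal(config, diffusivities, scheme, S0 = S0)
  structure(list(dwi = dwi, scheme = scheme,
                 gt_fod = analytic_gt_fod(config),
                 fiber_config = config,
                 wm_mask = array(config$n_fibers > 0, dim = config$grid_shape),
                 age = age, site = site, seed = seed, S0 = S0),
            class = "subject_phantom")
}
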
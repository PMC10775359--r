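# Small noiseless phantoms shared by the CSD tests.  The scheme keeps
# >= 90 diffusion-weighted measurements so split halves stay determined
# at order 8.
csd_scheme <- function() dhcp_scheme(n_b0 = 2, n400 = 16, n1000 = 40, n2600 = 40)

single_fiber_subject <- function(grid = c(5L, 5L, 2L)) {
  cfg <- single_fiber_config(grid)
  phantom_from_config(cfg, csd_scheme())
}

test_that("the response of identical single-fiber voxels is their zonal projection", {
  s <- single_fiber_subject()
  sf_mask <- array(TRUE, dim(s$wm_mask))
  resp <- estimate_response(s$dwi, s$scheme, sf_mask)
  # oracle: project one voxel's normalized signal (fiber already along +z)
  sc <- s$scheme
  for (b in c(400, 1000, 2600)) {
    idx <- shell_indices(sc, b)
    sig <- s$dwi[1, 1, 1, idx] / mean(s$dwi[1, 1, 1, b0_indices(sc)])
    Z <- fodshift:::zonal_basis(sc$bvecs[idx, , drop = FALSE], 8)
    zc <- qr.solve(Z, sig)
    si <- which(resp$bvals == b)
    expect_equal(resp$zonal[si, ], zc, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("isotropic voxels give a response with no angular structure", {
  sc <- csd_scheme()
  gs <- c(4L, 4L, 2L)
  dwi <- array(0, c(gs, length(sc$bvals)))
  for (j in seq_along(sc$bvals)) {
    dwi[, , , j] <- 100 * exp(-sc$bvals[j] * 1e-3)
  }
  resp <- estimate_response(dwi, sc, array(TRUE, gs))
  expect_true(all(abs(resp$zonal[, -1]) < 1e-6))
  expect_true(all(resp$zonal[, 1] > 0))
})

test_that("the estimated kernel reproduces the single-fiber signal", {
  s <- single_fiber_subject()
  resp <- estimate_response(s$dwi, s$scheme, array(TRUE, dim(s$wm_mask)))
  sc <- s$scheme
  # forward-model oracle: convolve the kernel with a delta along +z and
  # compare with the simulated signal on each shell
  for (b in c(1000, 2600)) {
    idx <- shell_indices(sc, b)
    Z <- fodshift:::zonal_basis(sc$bvecs[idx, , drop = FALSE], 8)
    si <- which(resp$bvals == b)
    pred <- Z %*% resp$zonal[si, ]
    truth <- s$dwi[1, 1, 1, idx] / mean(s$dwi[1, 1, 1, b0_indices(sc)])
    expect_lt(max(abs(pred - truth)) / max(truth), 0.02)
  }
})

test_that("empty single-fiber masks are rejected", {
  s <- single_fiber_subject()
  expect_error(estimate_response(s$dwi, s$scheme,
                                 array(FALSE, dim(s$wm_mask))), ">= 20")
})

test_that("CSD recovers noiseless single fibers and 90-degree crossings", {
  sc <- csd_scheme()
  # response from a matched single-fiber phantom
  s1 <- single_fiber_subject()
  resp <- estimate_response(s1$dwi, s1$scheme, array(TRUE, dim(s1$wm_mask)))

  # single fiber along a tilted direction
  u <- c(1, 1, 1) / sqrt(3)
  cfg_u <- single_fiber_config(c(2L, 2L, 1L), direction = u)
  dwi_u <- simulate_signal(cfg_u, c(1.7e-3, 3e-4), sc)
  fod_u <- csd_fit(dwi_u, sc, resp)
  p <- extract_peaks(fod_u$coefficients[, 1])
  expect_equal(length(p$amplitudes), 1L)
  expect_lt(angular_error(p$directions[1, ], u), 2)

  # two equal fibers at 90 degrees
  spec2 <- region_spec(shares = c(0, 1, 0), wm_lo = c(1L, 1L, 1L),
                       wm_hi = c(2L, 2L, 1L), jitter_deg = 0,
                       base_dirs = list(NULL, rbind(c(0, 0, 1), c(1, 0, 0)),
                                        NULL))
  cfg2 <- sample_fiber_geometry(c(2L, 2L, 1L), spec2, seed = 1)
  dwi2 <- simulate_signal(cfg2, c(1.7e-3, 3e-4), sc)
  fod2 <- csd_fit(dwi2, sc, resp)
  p2 <- extract_peaks(fod2$coefficients[, 1])
  expect_equal(length(p2$amplitudes), 2L)
  errs <- sapply(1:2, function(i) {
    min(angular_error(p2$directions[i, ], c(0, 0, 1)),
        angular_error(p2$directions[i, ], c(1, 0, 0)))
  })
  expect_lt(max(errs), 5)
  expect_lt(abs(p2$amplitudes[1] / p2$amplitudes[2] - 1), 0.1)

  # isotropic input consistent with the response (an isotropic FOD
  # convolved with the kernel, i.e. per-shell constants matching the
  # response means): energy above order 0 below 1 %
  gs <- c(2L, 2L, 1L)
  use <- which(sc$bvals > 50)
  A1 <- fodshift:::csd_forward_matrix(sc, resp, 8, use)
  dwi_iso <- array(0, c(gs, length(sc$bvals)))
  dwi_iso[, , , -use] <- 100
  for (j in seq_along(use)) {
    dwi_iso[, , , use[j]] <- 100 * A1[j, 1] * 0.3   # c00 = 0.3 iso FOD
  }
  fod_iso <- csd_fit(dwi_iso, sc, resp)
  co <- fod_iso$coefficients[, 1]
  expect_lt(sum(co[-1]^2) / sum(co^2), 0.01)

  # a free-water voxel (decay unlike any response shell mean) leaks
  # only a modest share of energy into higher orders
  dwi_w <- array(0, c(gs, length(sc$bvals)))
  for (j in seq_along(sc$bvals)) {
    dwi_w[, , , j] <- 100 * exp(-sc$bvals[j] * 1e-3)
  }
  fod_w <- csd_fit(dwi_w, sc, resp)
  cw <- fod_w$coefficients[, 1]
  expect_lt(sum(cw[-1]^2) / sum(cw^2), 0.10)
})

test_that("the CSD FOD stays effectively non-negative", {
  s1 <- single_fiber_subject()
  resp <- estimate_response(s1$dwi, s1$scheme, array(TRUE, dim(s1$wm_mask)))
  fod <- csd_fit(s1$dwi, s1$scheme, resp)
  # only slight residual ringing remains after the soft constraint
  dense <- sh_evaluate(fod$coefficients[, 1], sphere_grid(500))
  expect_gt(min(dense), -2e-2 * max(dense))
  expect_equal(attr(fod, "n_flagged"), 0L)
})

test_that("CSD is equivariant to a global rotation", {
  sc <- csd_scheme()
  s1 <- single_fiber_subject()
  resp <- estimate_response(s1$dwi, s1$scheme, array(TRUE, dim(s1$wm_mask)))
  R <- rotation_matrix(c(1, 0.3, 0.2), 40)
  u <- c(0, 0, 1)
  cfg_rot <- single_fiber_config(c(2L, 2L, 1L),
                                 direction = as.numeric(R %*% u))
  sc_rot <- gradient_scheme(sc$bvals, sc$bvecs %*% t(R))
  dwi_rot <- simulate_signal(cfg_rot, c(1.7e-3, 3e-4), sc_rot)
  fod_rot <- csd_fit(dwi_rot, sc_rot, resp)
  p <- extract_peaks(fod_rot$coefficients[, 1])
  expect_lt(angular_error(p$directions[1, ], as.numeric(R %*% u)), 2)
})

test_that("the CSD FOD integral scales with the fiber fraction", {
  sc <- csd_scheme()
  s1 <- single_fiber_subject()
  resp <- estimate_response(s1$dwi, s1$scheme, array(TRUE, dim(s1$wm_mask)))
  # scale only the diffusion-weighted fiber signal (the remaining
  # volume fraction contributes b0 signal but no attenuated signal), so
  # the FOD integral must track the fiber fraction linearly
  dwi_full <- simulate_signal(single_fiber_config(c(2L, 2L, 1L)),
                              c(1.7e-3, 3e-4), sc)
  integral_for <- function(frac) {
    dwi <- dwi_full
    nz <- which(sc$bvals > 50)
    dwi[, , , nz] <- frac * dwi[, , , nz]
    fod <- csd_fit(dwi, sc, resp)
    fod$coefficients[1, 1] * 2 * sqrt(pi)
  }
  i_half <- integral_for(0.5)
  i_full <- integral_for(1.0)
  expect_equal(i_half / i_full, 0.5, tolerance = 0.05)
})

test_that("split halves partition the measurements and agree when noiseless", {
  s <- single_fiber_subject(grid = c(4L, 4L, 2L))
  resp <- estimate_response(s$dwi, s$scheme, array(TRUE, dim(s$wm_mask)))
  rep_ <- split_half_consistency(s$dwi, s$scheme, resp, s$wm_mask)
  halves <- attr(rep_, "halves")
  nz <- which(s$scheme$bvals > s$scheme$shell_tol)
  expect_length(intersect(halves$h1, halves$h2), 0)
  expect_setequal(c(halves$h1, halves$h2), nz)
  expect_equal(rep_$ar_by_k[1], 100)
  expect_lt(rep_$ae_by_k[1], 1)
  # the two halves see different direction subsets, so the soft
  # constraint leaves a small AFD discrepancy even without noise
  expect_lt(rep_$afd_error, 5e-3)
})

test_that("split-half agreement degrades monotonically with noise", {
  cfg <- single_fiber_config(c(4L, 4L, 2L), seed = 2)
  sc <- csd_scheme()
  clean <- simulate_signal(cfg, c(1.7e-3, 3e-4), sc)
  resp <- estimate_response(clean, sc, array(TRUE, c(4, 4, 2)))
  wm <- array(TRUE, c(4, 4, 2))
  ars <- sapply(c(0, 0.02, 0.05), function(sig) {
    prof <- site_profile("n", sc, rician_sigma = sig,
                         gain_field = array(1, c(4, 4, 2)),
                         offset_field = array(0, c(4, 4, 2)))
    dwi <- apply_site_effects(clean, prof, seed = 77, s0_ref = 100)
    split_half_consistency(dwi, sc, resp, wm)$ar_by_k[1]
  })
  expect_true(all(diff(ars) <= 0))
  expect_equal(ars[1], 100)
})
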
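test_that("fiber geometry honours region shares exactly and is reproducible", {
  spec <- region_spec(shares = c(0.3, 0.5, 0.2), wm_lo = c(1L, 1L, 1L),
                      wm_hi = c(16L, 16L, 16L))
  cfg <- sample_fiber_geometry(c(16L, 16L, 16L), spec, seed = 3)
  n_wm <- 16^3
  counts <- table(factor(cfg$n_fibers[cfg$n_fibers > 0], levels = 1:3))
  expect_equal(as.integer(counts),
               c(round(0.3 * n_wm), round(0.5 * n_wm),
                 n_wm - round(0.3 * n_wm) - round(0.5 * n_wm)))
  cfg2 <- sample_fiber_geometry(c(16L, 16L, 16L), spec, seed = 3)
  expect_identical(cfg, cfg2)

  all_z <- single_fiber_config(c(8L, 8L, 8L))
  expect_true(all(all_z$n_fibers == 1L))
  expect_equal(all_z$directions[, , 1],
               matrix(rep(c(0, 0, 1), each = 512), 512, 3))
  expect_true(all(all_z$fractions[, 1] == 1))

  expect_error(sample_fiber_geometry(c(4L, 4L, 4L),
                                     region_spec(wm_lo = c(1L, 1L, 1L),
                                                 wm_hi = c(5L, 4L, 4L))),
               "exceeds")
})

test_that("crossing angles stay within the configured range", {
  spec <- region_spec(shares = c(0, 1, 0), wm_lo = c(1L, 1L, 1L),
                      wm_hi = c(6L, 6L, 6L), jitter_deg = 0)
  for (seed in 1:5) {
    cfg <- sample_fiber_geometry(c(6L, 6L, 6L), spec, seed = seed)
    ang <- angular_error(cfg$directions[1, , 1], cfg$directions[1, , 2])
    expect_gte(ang, 44.9)
    expect_lte(ang, 90.0)
  }
})

test_that("the multi-tensor signal matches its closed forms", {
  sc <- gradient_scheme(c(0, 1000, 1000),
                        rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0)))
  cfg <- single_fiber_config(c(2L, 2L, 1L))
  dwi <- simulate_signal(cfg, c(1.7e-3, 0.3e-3), sc, S0 = 100)
  expect_equal(dwi[1, 1, 1, 1], 100)                      # b = 0
  expect_equal(dwi[1, 1, 1, 2] / 100, exp(-1.7), tolerance = 1e-12)  # g || fiber
  expect_equal(dwi[1, 1, 1, 3] / 100, exp(-0.3), tolerance = 1e-12)  # g perp
  expect_error(simulate_signal(cfg, c(0.3e-3, 1.7e-3), sc), "lambda_par")
})

test_that("the noiseless signal is invariant under antipodal flips", {
  sc <- dhcp_scheme(n_b0 = 1, n400 = 6, n1000 = 8, n2600 = 6)
  flipped <- sc
  flipped$bvecs[5, ] <- -flipped$bvecs[5, ]
  cfg <- sample_fiber_geometry(c(4L, 4L, 4L), region_spec(
    wm_lo = c(1L, 1L, 1L), wm_hi = c(4L, 4L, 4L)), seed = 2)
  s1 <- simulate_signal(cfg, c(1.7e-3, 4e-4), sc)
  s2 <- simulate_signal(cfg, c(1.7e-3, 4e-4), flipped)
  expect_equal(s1, s2)
})

test_that("age maps to diffusivities reproducing the model FA", {
  am <- age_model()
  # root-consistency oracle: FA recomputed from the returned tensor
  for (t in c(-2, 0, 3, 12, 48)) {
    dv <- age_to_diffusivities(t, am)
    fa_back <- (dv[1] - dv[2]) / sqrt(dv[1]^2 + 2 * dv[2]^2)
    expect_equal(as.numeric(fa_back), fa_at_age(am, t), tolerance = 1e-8)
  }
  flat <- age_model(a = 1e-9, b = 1e-9, t0 = 0, d = 0)   # FA = 0 at t = t0
  dv0 <- age_to_diffusivities(0, flat)
  expect_equal(as.numeric(dv0[2]), as.numeric(dv0[1]), tolerance = 1e-6)
  # monotone: older age -> higher FA -> lower radial diffusivity
  d1 <- age_to_diffusivities(1, am)[2]
  d2 <- age_to_diffusivities(24, am)[2]
  expect_gt(as.numeric(d1), as.numeric(d2))
})

test_that("site effects reduce to identity and exact linear maps", {
  x <- array(runif(4 * 4 * 4 * 3, 10, 90), c(4, 4, 4, 3))
  id <- site_profile("id", NULL, rician_sigma = 0,
                     gain_field = array(1, c(4, 4, 4)),
                     offset_field = array(0, c(4, 4, 4)))
  expect_equal(apply_site_effects(x, id, seed = 1), x)
  lin <- site_profile("lin", NULL, rician_sigma = 0,
                      gain_field = array(2, c(4, 4, 4)),
                      offset_field = array(5, c(4, 4, 4)))
  expect_equal(apply_site_effects(x, lin, seed = 1), 2 * x + 5)
})

test_that("pure-noise magnitudes follow the Rayleigh mean", {
  n <- 1e5
  zero <- array(0, c(n, 1, 1, 1))
  prof <- site_profile("noise", NULL, rician_sigma = 0.05,
                       gain_field = array(1, c(n, 1, 1)),
                       offset_field = array(0, c(n, 1, 1)))
  obs <- apply_site_effects(zero, prof, seed = 4, s0_ref = 100)
  sigma <- 0.05 * 100
  expect_equal(mean(obs), sigma * sqrt(pi / 2), tolerance = 0.02)
})

test_that("analytic ground-truth FODs integrate and peak correctly", {
  cfg1 <- single_fiber_config(c(2L, 2L, 1L))
  f1 <- analytic_gt_fod(cfg1)
  expect_equal(f1$coefficients[1, 1] * 2 * sqrt(pi), 1, tolerance = 1e-9)
  # quadrature oracle for the sphere integral
  g <- sphere_grid(3000)
  integral <- mean(sh_evaluate(f1$coefficients[, 1], g)) * 4 * pi
  expect_equal(integral, 1, tolerance = 1e-5)   # grid-quadrature error

  u <- rbind(c(0, 0, 1), c(1, 0, 0))
  fod2 <- delta_mixture_sh(u, c(0.5, 0.5))
  p2 <- extract_peaks(fod2)
  expect_equal(p2$amplitudes[1], p2$amplitudes[2], tolerance = 1e-6)

  # peaks of random crossing configs recover the inputs within 2 degrees
  spec <- region_spec(shares = c(0.4, 0.4, 0.2), wm_lo = c(1L, 1L, 1L),
                      wm_hi = c(8L, 8L, 8L))
  cfg <- sample_fiber_geometry(c(8L, 8L, 8L), spec, seed = 5)
  fod <- analytic_gt_fod(cfg)
  vox <- which(cfg$n_fibers > 0)
  pf <- extract_peaks_field(fod$coefficients[, vox])
  expect_equal(pf$count, cfg$n_fibers[vox])
  for (v in sample(seq_along(vox), 30)) {
    k <- cfg$n_fibers[vox[v]]
    gt_dirs <- t(matrix(cfg$directions[vox[v], , 1:k], 3, k))
    m <- match_peaks(peak_set(gt_dirs, rep(1, k)),
                     peak_set(pf$directions[[v]], pf$amplitudes[[v]]))
    expect_equal(nrow(m), k)
    expect_lt(max(m$angle_deg), 2)
  }
})

test_that("cohort generation is reproducible and age-structured", {
  sc <- dhcp_scheme(n_b0 = 1, n400 = 6, n1000 = 10, n2600 = 8)
  prof <- site_profile("dhcp", sc, rician_sigma = 0.01, gain_amp = 0.05,
                       subject_jitter = 0.05)
  am <- age_model()
  spec <- region_spec(wm_lo = c(2L, 2L, 2L), wm_hi = c(11L, 11L, 11L))
  c1 <- generate_cohort(2, c(1.5, 60), prof, am, spec = spec, seed = 21,
                        grid_shape = c(12L, 12L, 12L))
  c2 <- generate_cohort(2, c(1.5, 60), prof, am, spec = spec, seed = 21,
                        grid_shape = c(12L, 12L, 12L))
  expect_identical(c1[[1]]$dwi, c2[[1]]$dwi)         # bit-identical
  ages <- sapply(c1, `[[`, "age")
  expect_true(all(ages >= 1.5 & ages <= 60))
  expect_error(generate_cohort(2, c(5, 5), prof, am), "age_range")
})

test_that("single-fiber DTI FA reproduces the age model without noise", {
  sc <- dhcp_scheme(n_b0 = 1, n400 = 6, n1000 = 10, n2600 = 8)
  clean_prof <- site_profile("clean", sc, rician_sigma = 0)
  am <- age_model()
  spec <- region_spec(shares = c(1, 0, 0), wm_lo = c(1L, 1L, 1L),
                      wm_hi = c(6L, 6L, 6L), jitter_deg = 5)
  coh <- generate_cohort(3, c(0, 36), clean_prof, am, spec = spec, seed = 9,
                         grid_shape = c(6L, 6L, 6L))
  for (s in coh) {
    tf <- fit_tensor(s$dwi, s$scheme)
    maps <- compute_fa_md(tf)
    expect_equal(mean(maps$fa[s$wm_mask]), fa_at_age(am, s$age),
                 tolerance = 1e-3)
  }
})

test_that("mean white-matter FA rises with age across a cohort", {
  sc <- dhcp_scheme(n_b0 = 1, n400 = 6, n1000 = 10, n2600 = 8)
  prof <- site_profile("dhcp", sc, rician_sigma = 0.005)
  am <- age_model()
  spec <- region_spec(shares = c(1, 0, 0), wm_lo = c(2L, 2L, 2L),
                      wm_hi = c(9L, 9L, 9L))
  coh <- generate_cohort(10, c(-2, 36), prof, am, spec = spec, seed = 13,
                         grid_shape = c(10L, 10L, 10L))
  tab <- cohort_fa_table(coh)
  # regenerated mean WM FA follows the maturation curve within noise
  expect_lt(max(abs(tab$mean_wm_fa - fa_at_age(am, tab$age_months))), 0.005)
  o <- order(tab$age_months)
  expect_gt(tab$mean_wm_fa[o[length(o)]], tab$mean_wm_fa[o[1]])
})

test_that("subjects round-trip through NIfTI + text files", {
  sc <- dhcp_scheme(n_b0 = 1, n400 = 6, n1000 = 10, n2600 = 8)
  prof <- site_profile("io", sc, rician_sigma = 0.01)
  spec <- region_spec(wm_lo = c(2L, 2L, 2L), wm_hi = c(7L, 7L, 7L))
  s <- generate_cohort(1, c(1, 10), prof, age_model(), spec = spec,
                       seed = 31, grid_shape = c(8L, 8L, 8L))[[1]]
  tmp <- withr::local_tempdir()
  write_subject(s, tmp)
  s2 <- read_subject(tmp)
  expect_equal(s2$dwi, unclass(s$dwi), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(s2$gt_fod$coefficients, s$gt_fod$coefficients,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(s2$wm_mask, s$wm_mask, ignore_attr = TRUE)
  expect_equal(s2$age, s$age, tolerance = 1e-9)
  expect_equal(s2$scheme$bvals, s$scheme$bvals)
})
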
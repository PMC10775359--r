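# Brute-force oracle: optimal assignment by enumerating permutations of
# the smaller peak set (instances here never exceed 3 x 3).
brute_force_match <- function(gd, pd, cap = 45) {
  ng <- nrow(gd); np <- nrow(pd)
  if (!ng || !np) return(0)
  ang <- matrix(acos(pmin(abs(gd %*% t(pd)), 1)) * 180 / pi, ng, np)
  best <- list(n = -1, total = Inf)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  k <- min(ng, np)
  combs <- combn(max(ng, np), k, simplify = FALSE)
  for (cmb in combs) {
    for (p in perms(seq_len(k))) {
      gi <- if (ng <= np) seq_len(k) else cmb[p]
      pi_ <- if (ng <= np) cmb[p] else seq_len(k)
      a <- ang[cbind(gi, pi_)]
      ok <- a <= cap
      n <- sum(ok); tot <- sum(a[ok])
      if (n > best$n || (n == best$n && tot < best$total - 1e-9)) {
        best <- list(n = n, total = tot)
      }
    }
  }
  best
}

test_that("angular error has its closed forms and symmetries", {
  expect_equal(angular_error(c(1, 0, 0), c(0, 1, 0)), 90)
  u <- c(0.3, -0.5, 0.8); u <- u / sqrt(sum(u^2))
  expect_equal(angular_error(u, -u), 0)
  v <- c(cos(10 * pi / 180), sin(10 * pi / 180), 0)
  expect_equal(angular_error(c(1, 0, 0), v), 10, tolerance = 1e-9)
  expect_equal(angular_error(u, v), angular_error(v, u))
  expect_error(angular_error(c(0, 0, 0), c(0, 0, 1)), "zero")
})

test_that("peak matching is capped and deterministic", {
  z <- peak_set(rbind(c(0, 0, 1)), 1)
  x <- peak_set(rbind(c(1, 0, 0)), 1)
  expect_equal(nrow(match_peaks(z, x)), 0L)       # 90 deg > cap

  gt <- peak_set(rbind(c(0, 0, 1), c(1, 0, 0)), c(1, 0.9))
  pr <- peak_set(rbind(c(sin(5 * pi / 180), 0, cos(5 * pi / 180)),
                       c(cos(8 * pi / 180), 0, sin(8 * pi / 180))),
                 c(1, 0.9))
  m <- match_peaks(gt, pr)
  expect_equal(nrow(m), 2L)
  expect_equal(sort(m$angle_deg), c(5, 8), tolerance = 1e-6)

  same <- match_peaks(gt, gt)
  expect_equal(same$angle_deg, c(0, 0))
  expect_equal(same$gt_index, same$pred_index)
})

test_that("matching attains the optimal assignment on random instances", {
  set.seed(33)
  for (i in 1:200) {
    ng <- sample(0:3, 1); np <- sample(0:3, 1)
    gd <- random_dirs(max(ng, 1))[seq_len(ng), , drop = FALSE]
    pd <- random_dirs(max(np, 1))[seq_len(np), , drop = FALSE]
    m <- match_peaks(peak_set(gd, rep(1, ng)), peak_set(pd, rep(1, np)))
    if (ng == 0 || np == 0) {
      expect_equal(nrow(m), 0L)
      next
    }
    bf <- brute_force_match(gd, pd)
    expect_equal(nrow(m), bf$n)
    # total angle attains the optimum on these small instances
    expect_equal(sum(m$angle_deg), bf$total, tolerance = 1e-6)
  }
})

make_fields <- function(counts_gt, counts_pred, rot_deg = 0) {
  # single/multi-fiber voxels along canonical axes; rotation applied to
  # predictions about the y axis
  axes <- list(rbind(c(0, 0, 1)), rbind(c(0, 0, 1), c(1, 0, 0)),
               rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)))
  n <- length(counts_gt)
  gs <- c(n, 1L, 1L)
  R <- rotation_matrix(c(0, 1, 0), rot_deg)
  gt <- sapply(counts_gt, function(k) {
    if (k == 0) rep(0, 45) else delta_mixture_sh(axes[[k]], rep(1 / k, k))
  })
  pr <- sapply(counts_pred, function(k) {
    if (k == 0) rep(0, 45) else {
      delta_mixture_sh(axes[[k]] %*% t(R), rep(1 / k, k))
    }
  })
  list(gt = sh_field(gt, gs), pred = sh_field(pr, gs),
       mask = array(TRUE, gs))
}

test_that("agreement rate counts stratum-wise peak-count matches", {
  f <- make_fields(c(1, 1, 2, 2), c(1, 2, 2, 1))
  expect_equal(agreement_rate(f$gt, f$pred, f$mask, 1), 50)
  expect_equal(agreement_rate(f$gt, f$pred, f$mask, 2), 50)
  expect_true(is.na(agreement_rate(f$gt, f$pred, f$mask, 3)))
  idf <- make_fields(c(1, 2, 3), c(1, 2, 3))
  for (k in 1:3) expect_equal(agreement_rate(idf$gt, idf$gt, idf$mask, k), 100)
})

test_that("angular error pools matched pairs and sees constructed rotations", {
  f <- make_fields(rep(1, 4), rep(1, 4), rot_deg = 10)
  ae <- angular_error_field(f$gt, f$pred, f$mask, 1)
  expect_equal(ae, 10, tolerance = 0.5)
  expect_equal(angular_error_field(f$gt, f$gt, f$mask, 1), 0, tolerance = 1e-6)
  expect_equal(mean(c(5, 15)), 10)   # pooling convention: mean over pairs
})

test_that("AFD error is the c00 integral difference and ignores high orders", {
  gs <- c(2L, 1L, 1L)
  gt <- matrix(0, 45, 2); gt[1, ] <- 1 / (2 * sqrt(pi))
  pr <- gt; pr[1, ] <- 0.75 / (2 * sqrt(pi))
  f_gt <- sh_field(gt, gs); f_pr <- sh_field(pr, gs)
  mask <- array(TRUE, gs)
  expect_equal(afd_error(f_gt, f_pr, mask), 0.25, tolerance = 1e-12)
  expect_equal(afd_error(f_gt, f_gt, mask), 0)
  pr2 <- pr; pr2[10, ] <- 5            # higher-order coefficients are ignored
  expect_equal(afd_error(f_gt, sh_field(pr2, gs), mask), 0.25)
})

test_that("the full report is exact on identity and partitions the mask", {
  spec <- region_spec(shares = c(0.4, 0.4, 0.2), wm_lo = c(1L, 1L, 1L),
                      wm_hi = c(6L, 6L, 6L))
  cfg <- sample_fiber_geometry(c(6L, 6L, 6L), spec, seed = 8)
  fod <- analytic_gt_fod(cfg)
  mask <- array(cfg$n_fibers > 0, c(6, 6, 6))
  rep_ <- evaluate_fods(fod, fod, mask)
  expect_equal(rep_$ar_by_k[!is.na(rep_$ar_by_k)],
               rep(100, sum(!is.na(rep_$ar_by_k))))
  expect_equal(rep_$ae_by_k[!is.na(rep_$ae_by_k)],
               rep(0, sum(!is.na(rep_$ae_by_k))), tolerance = 1e-5)
  expect_equal(rep_$afd_error, 0)
  expect_equal(sum(rep_$n_voxels_by_k) + rep_$n_zero_peak_gt, sum(mask))
  expect_error(evaluate_fods(fod, fod, array(FALSE, c(6, 6, 6))), "empty")
})

test_that("AE is symmetric in its arguments while AR is not", {
  f <- make_fields(c(1, 1, 1, 2), c(1, 1, 2, 2), rot_deg = 7)
  ae_fwd <- angular_error_field(f$gt, f$pred, f$mask, 1)
  ae_rev <- angular_error_field(f$pred, f$gt, f$mask, 1)
  # matched pairs are the same pairs either way for these fixtures
  expect_equal(ae_fwd, ae_rev, tolerance = 0.6)
  ar_fwd <- agreement_rate(f$gt, f$pred, f$mask, 1)
  ar_rev <- agreement_rate(f$pred, f$gt, f$mask, 1)
  expect_false(isTRUE(all.equal(ar_fwd, ar_rev)))
})

test_that("no perturbed prediction beats the identity on every metric", {
  f <- make_fields(c(1, 2, 1, 2), c(1, 2, 1, 2), rot_deg = 12)
  ident <- evaluate_fods(f$gt, f$gt, f$mask)
  pert <- evaluate_fods(f$gt, f$pred, f$mask)
  expect_true(all(ident$ar_by_k >= pert$ar_by_k, na.rm = TRUE))
  expect_true(all(ident$ae_by_k <= pert$ae_by_k, na.rm = TRUE))
  expect_lte(ident$afd_error, pert$afd_error)
})
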
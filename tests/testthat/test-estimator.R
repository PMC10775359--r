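test_that("the optimal six-direction subset is found exhaustively", {
  # icosahedral axes: the optimal order-2 sampling, embedded in a shell
  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(c(0, 1, phi), c(0, -1, phi), c(1, phi, 0),
               c(-1, phi, 0), c(phi, 0, 1), c(-phi, 0, 1))
  ico <- ico / sqrt(rowSums(ico^2))
  set.seed(42)
  extra <- random_dirs(14)
  dirs <- rbind(ico, extra)
  sc <- gradient_scheme(c(0, rep(1000, 20)), rbind(c(0, 0, 0), dirs))
  six <- select_six_directions(sc, 1000)
  expect_setequal(six, 2:7)     # the icosahedral set (offset by the b0)

  # exactly six directions: identity selection
  sc6 <- gradient_scheme(c(0, rep(1000, 6)), rbind(c(0, 0, 0), ico))
  expect_equal(select_six_directions(sc6, 1000), 2:7)

  # full rank of the returned design
  B <- sh_basis(sc$bvecs[six, ], 2)
  expect_equal(qr(B)$rank, 6L)
})

test_that("greedy-plus-exchange selection stays well-conditioned on large shells", {
  sc <- dhcp_scheme()           # 48-direction shell: beyond exhaustive search
  six <- select_six_directions(sc, 1000)
  expect_length(six, 6L)
  expect_identical(six, select_six_directions(sc, 1000))   # deterministic
  s <- svd(sh_basis(sc$bvecs[six, ], 2))$d
  expect_lt(s[1] / s[6], 10)
  expect_error(select_six_directions(sc, 700), "no b")
})

test_that("input preparation normalizes, projects and enumerates patches", {
  sc <- gradient_scheme(c(0, rep(1000, 6)),
                        rbind(c(0, 0, 0), ico6()))
  gs <- c(24L, 24L, 24L)
  dwi <- array(80, c(gs, 7))    # S = b0 everywhere: no decay
  prep <- prepare_input(dwi, sc, 2:7, patch_size = 16L)
  expect_equal(prep$field[1, ], rep(2 * sqrt(pi), prod(gs)), tolerance = 1e-9)
  expect_equal(max(abs(prep$field[-1, ])), 0, tolerance = 1e-9)
  # patch 16, stride 8 on 24^3: corner offsets {1, 9} per axis -> 8 patches
  expect_equal(nrow(prep$patch_corners), 8L)
  expect_setequal(unique(prep$patch_corners[, 1]), c(1L, 9L))

  # joint rescaling of dwi and b0 leaves the input unchanged
  prep3 <- prepare_input(dwi * 3, sc, 2:7, patch_size = 16L)
  expect_equal(prep3$field, prep$field, tolerance = 1e-12)

  expect_error(prepare_input(array(1, c(8, 8, 8, 7)), sc, 2:7,
                             patch_size = 16L), "larger than volume")
})

test_that("estimator configs validate their invariants", {
  expect_error(estimator_config(lr_finetune = 1e-3, lr_train = 1e-3),
               "lr_finetune")
  expect_error(estimator_config(patch_size = 6), "patch_size")
  expect_error(estimator_config(patch_size = 18, depth = 2), "patch_size")
})

# A trivially learnable task: every WM voxel has the same GT FOD.
sanity_subjects <- function(n, seed0 = 100) {
  sc <- gradient_scheme(c(0, rep(1000, 6)),
                        rbind(c(0, 0, 0), ico6()))
  lapply(seq_len(n), function(i) {
    cfg <- single_fiber_config(c(8L, 8L, 8L))
    s <- phantom_from_config(cfg, sc, seed = seed0 + i)
    s
  })
}

test_that("training converges on a constant-target sanity task", {
  subs <- sanity_subjects(2)
  cfg <- estimator_config(patch_size = 8L, depth = 1L, base_channels = 32L,
                          lr_train = 2e-2, lr_finetune = 1e-3,
                          epochs_train = 50L, dropout = 0, seed = 3L)
  m <- train_estimator(cfg, subs[1], subs[2], 2:7)
  expect_lt(min(m$history$val_mse), 1e-3)
  # the selected epoch attains the recorded minimum
  expect_equal(m$history$val_mse[m$selected_epoch], min(m$history$val_mse))
  # prediction on the training subject is as accurate as the val MSE
  pred <- predict_fod(m, subs[[1]])
  vox <- which(subs[[1]]$wm_mask)
  mse <- mean((pred$coefficients[, vox] -
                 subs[[1]]$gt_fod$coefficients[, vox])^2)
  expect_lt(mse, 1e-3)
  expect_equal(ncol(pred$coefficients), prod(pred$grid_shape))
  expect_equal(nrow(pred$coefficients), 45L)   # (8+1)(8+2)/2 at lmax 8
})

test_that("training is deterministic for a fixed seed", {
  subs <- sanity_subjects(2)
  cfg <- estimator_config(patch_size = 8L, depth = 1L, base_channels = 16L,
                          lr_train = 1e-2, lr_finetune = 1e-3,
                          epochs_train = 5L, seed = 9L)
  m1 <- train_estimator(cfg, subs[1], subs[2], 2:7)
  m2 <- train_estimator(cfg, subs[1], subs[2], 2:7)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("fine-tuning with zero learning rate is the identity", {
  subs <- sanity_subjects(3)
  cfg <- estimator_config(patch_size = 8L, depth = 1L, base_channels = 16L,
                          lr_train = 1e-2, lr_finetune = 1e-3,
                          epochs_train = 5L, seed = 4L)
  m <- train_estimator(cfg, subs[1], subs[2], 2:7)
  ft0 <- finetune_estimator(m, subs[3], lr = 0)
  expect_identical(ft0$params, m$params)
  expect_equal(ft0$provenance$n_finetune, 1L)

  # supported target counts are recorded in provenance
  for (n in c(1L, 2L)) {
    ftn <- finetune_estimator(m, subs[seq_len(n)], epochs = 2L)
    expect_equal(ftn$provenance$n_finetune, n)
  }
})

test_that("fine-tuning on shifted data lowers the target-domain error", {
  sc <- gradient_scheme(c(0, rep(1000, 6)),
                        rbind(c(0, 0, 0), ico6()))
  make_site <- function(offset, n, seed0) {
    lapply(seq_len(n), function(i) {
      cfg <- sample_fiber_geometry(c(8L, 8L, 8L),
                                   region_spec(shares = c(1, 0, 0),
                                               wm_lo = c(1L, 1L, 1L),
                                               wm_hi = c(8L, 8L, 8L),
                                               jitter_deg = 15),
                                   seed = seed0 + i)
      s <- phantom_from_config(cfg, sc, seed = seed0 + i)
      prof <- site_profile("shift", sc, rician_sigma = 0.01,
                           gain_field = array(1, c(8, 8, 8)),
                           offset_field = array(offset, c(8, 8, 8)))
      s$dwi <- apply_site_effects(s$dwi, prof, seed = seed0 + i, s0_ref = 100)
      s
    })
  }
  src <- make_site(0, 3, 200)
  tgt <- make_site(12, 3, 300)
  cfg <- estimator_config(patch_size = 8L, depth = 1L, base_channels = 32L,
                          lr_train = 5e-3, lr_finetune = 5e-4,
                          epochs_train = 60L, epochs_finetune = 40L,
                          dropout = 0, seed = 6L)
  m <- train_estimator(cfg, src[1:2], src[3], 2:7)
  mse_on <- function(model, s) {
    pred <- predict_fod(model, s)
    vox <- which(s$wm_mask)
    mean((pred$coefficients[, vox] - s$gt_fod$coefficients[, vox])^2)
  }
  before <- mse_on(m, tgt[[3]])
  ft <- finetune_estimator(m, tgt[1:2])
  after <- mse_on(ft, tgt[[3]])
  expect_lt(after, before)
})
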
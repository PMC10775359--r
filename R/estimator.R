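## The trainable FOD regressor: six-direction input preparation,
## training, fine-tuning and patch-based inference.
##
## The regressor is a small fully-convolutional network: a 3x3x3
## spatial convolution over the order-2 SH coefficients of the
## normalized six-direction signal (the first layer sees a 27-voxel
## neighbourhood, 162 features), followed by 1x1x1 layers, predicting
## the order-8 FOD SH coefficients (45 outputs) per voxel.  The spatial
## context is essential: with six noisy measurements the per-voxel
## direction information is weak, and — as with larger encoder-decoder
## backbones — the network recovers it by pooling coherent neighbours.
## The desk-scale model keeps the essential training contract of those
## backbones: patch sampling with a white-matter coverage floor, masked
## MSE loss, Adam with decoupled weight decay, dropout, validation-MSE
## model selection, and fine-tuning at a reduced learning rate.

#' Estimator configuration
#'
#' @param patch_size cubic patch edge (voxels); must be >= 8 and
#'   divisible by `2^depth`.
#' @param input_lmax SH order of the input signal field (2: six
#'   coefficients for six measurements).
#' @param output_lmax SH order of the predicted FOD (8: 45 coefficients).
#' @param base_channels hidden-layer width.
#' @param depth number of hidden layers.
#' @param dropout hidden-unit dropout rate during training.
#' @param lr_train,weight_decay,batch_train,epochs_train training
#'   hyperparameters (Adam; decoupled weight decay; batch counted in
#'   patches).  The defaults are desk-scale values sized to this
#'   package's small network and phantom volumes; the corresponding
#'   full-scale study protocol (learning rate 5e-5, weight decay 1e-3,
#'   batches of 35 sixteen-cubed patches, 1000 epochs, dropout 0.1)
#'   can be requested explicitly for larger runs.
#' @param lr_finetune,batch_finetune,epochs_finetune fine-tuning
#'   hyperparameters (`lr_finetune < lr_train`; full-scale protocol:
#'   learning rate 5e-6, batches of 10, 100 epochs).
#' @param min_wm_frac minimum white-matter coverage for a training patch.
#' @param context receptive field of the first layer: `"box3"` (3x3x3
#'   neighbourhood, the default), `"cross"` (centre + 6 face
#'   neighbours) or `"voxel"` (no spatial context).
#' @param seed master seed fanned out to initialization, batch order
#'   and dropout.
#' @return object of class `estimator_config`.
#' @export
estimator_config <- function(patch_size = 12L, input_lmax = 2L,
                             output_lmax = 8L, base_channels = 96L,
                             depth = 2L, dropout = 0.1,
                             lr_train = 2e-3, weight_decay = 1e-3,
                             batch_train = 4L, epochs_train = 80L,
                             lr_finetune = 2e-4, batch_finetune = 2L,
                             epochs_finetune = 50L,
                             min_wm_frac = 0.3, context = "box3", seed = 1L) {
  context <- match.arg(context, c("box3", "cross", "voxel"))
  if (!(lr_finetune < lr_train)) stop2("lr_finetune must be < lr_train")
  if (patch_size < 8L || patch_size %% (2^depth) != 0L) {
    stop2("patch_size must be >= 8 and divisible by 2^depth")
  }
  structure(list(patch_size = as.integer(patch_size),
                 input_lmax = as.integer(input_lmax),
                 output_lmax = as.integer(output_lmax),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), dropout = dropout,
                 lr_train = lr_train, weight_decay = weight_decay,
                 batch_train = as.integer(batch_train),
                 epochs_train = as.integer(epochs_train),
                 lr_finetune = lr_finetune,
                 batch_finetune = as.integer(batch_finetune),
                 epochs_finetune = as.integer(epochs_finetune),
                 min_wm_frac = min_wm_frac, context = context,
                 seed = as.integer(seed)),
            class = "estimator_config")
}

#' Select the six optimal gradient directions from a shell
#'
#' Returns the six-measurement subset of the shell minimizing the
#' condition number of the order-2 SH design matrix, so the exact 6 x 6
#' signal-to-SH solve is maximally stable.  The search is exhaustive
#' when `choose(n, 6) <= 50000`, otherwise greedy seeding plus
#' best-improvement exchange passes; both are deterministic.
#'
#' @param scheme a [gradient_scheme()].
#' @param shell_b shell b-value to draw from (default 1000 s/mm^2, a
#'   shell shared by both site protocols).
#' @return integer vector of six measurement indices into the scheme.
#' @export
select_six_directions <- function(scheme, shell_b = 1000) {
  idx <- shell_indices(scheme, shell_b)
  n <- length(idx)
  if (n < 6L) stop2("shell b=", shell_b, " has fewer than 6 directions")
  if (n == 6L) return(idx)
  B <- sh_basis(scheme$bvecs[idx, , drop = FALSE], 2L)
  cond_of <- function(rows) {
    s <- svd(B[rows, , drop = FALSE], nu = 0, nv = 0)$d
    k <- min(length(rows), 6L)
    if (s[k] < 1e-12) Inf else s[1] / s[k]
  }
  if (choose(n, 6) <= 50000) {
    subsets <- combn(n, 6)
    conds <- apply(subsets, 2, cond_of)
    best <- subsets[, which.min(conds)]
  } else {
    best <- 1L
    while (length(best) < 6L) {
      cand <- setdiff(seq_len(n), best)
      sc <- vapply(cand, function(j) cond_of(c(best, j)), numeric(1))
      best <- c(best, cand[which.min(sc)])
    }
    repeat {
      improved <- FALSE
      cur <- cond_of(best)
      for (i in seq_along(best)) {
        for (j in setdiff(seq_len(n), best)) {
          trial <- best; trial[i] <- j
          if (cond_of(trial) < cur - 1e-12) {
            best <- trial; cur <- cond_of(trial); improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    best <- sort(best)
  }
  idx[sort(best)]
}

#' Prepare the six-direction SH input for one volume
#'
#' Divides the six selected-direction signals by the voxelwise mean b0
#' (voxels with b0 below `eps` are flagged and excluded from training
#' losses), projects them onto the order-2 SH basis by the exact 6 x 6
#' solve, and enumerates patch corner offsets covering the volume.
#'
#' @param dwi 4D signal array.
#' @param scheme a [gradient_scheme()].
#' @param six_indices six measurement indices.
#' @param patch_size cubic patch edge.
#' @param stride patch stride (default `patch_size / 2`).
#' @param eps b0 floor.
#' @return list with `field` (6 x nvox input SH coefficients), `valid`
#'   (logical per voxel: positive b0), `grid_shape`, `patch_corners`
#'   (matrix of 1-based corner coordinates) and `patch_size`.
#' @export
prepare_input <- function(dwi, scheme, six_indices, patch_size = 16L,
                          stride = NULL, eps = 1e-6) {
  d <- dim(dwi)
  if (any(d[1:3] < patch_size)) {
    stop2("patch (", patch_size, ") larger than volume (",
          paste(d[1:3], collapse = "x"), "); pad or shrink the patch")
  }
  stride <- stride %||% max(1L, patch_size %/% 2L)
  S <- matrix(dwi, prod(d[1:3]), d[4])
  b0 <- rowMeans(S[, b0_indices(scheme), drop = FALSE])
  valid <- b0 > eps
  Sn <- S[, six_indices, drop = FALSE] / pmax(b0, eps)
  B6 <- sh_basis(scheme$bvecs[six_indices, , drop = FALSE], 2L)
  M <- solve(B6)                                 # exact 6x6 solve
  field <- M %*% t(Sn)                           # 6 x nvox
  starts <- lapply(d[1:3], function(n) {
    unique(c(seq(1L, n - patch_size + 1L, by = stride), n - patch_size + 1L))
  })
  corners <- as.matrix(expand.grid(x = starts[[1]], y = starts[[2]],
                                   z = starts[[3]]))
  list(field = field, valid = valid, grid_shape = d[1:3],
       patch_corners = corners, patch_size = as.integer(patch_size))
}

## Neighbourhood offsets for the first (spatial) layer.
context_offsets <- function(context = c("box3", "cross", "voxel")) {
  context <- match.arg(context)
  switch(context,
         voxel = matrix(0L, 1, 3),
         cross = rbind(c(0L, 0L, 0L), c(-1L, 0L, 0L), c(1L, 0L, 0L),
                       c(0L, -1L, 0L), c(0L, 1L, 0L),
                       c(0L, 0L, -1L), c(0L, 0L, 1L)),
         box3 = as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1)))
}

## Stack the input field over a voxel neighbourhood (replicated-edge
## clamping): returns an (nfeat_per_voxel * n_offsets) x nvox matrix.
neighborhood_features <- function(field, grid_shape, offsets) {
  nvox <- prod(grid_shape)
  co <- arrayInd(seq_len(nvox), grid_shape)
  blocks <- vector("list", nrow(offsets))
  for (i in seq_len(nrow(offsets))) {
    cx <- pmin(pmax(co[, 1] + offsets[i, 1], 1L), grid_shape[1])
    cy <- pmin(pmax(co[, 2] + offsets[i, 2], 1L), grid_shape[2])
    cz <- pmin(pmax(co[, 3] + offsets[i, 3], 1L), grid_shape[3])
    idx <- cx + (cy - 1L) * grid_shape[1] +
      (cz - 1L) * grid_shape[1] * grid_shape[2]
    blocks[[i]] <- field[, idx, drop = FALSE]
  }
  do.call(rbind, blocks)
}

## Linear voxel indices of the patch with the given corner.
patch_voxels <- function(corner, patch_size, grid_shape) {
  xs <- corner[1]:(corner[1] + patch_size - 1L)
  ys <- corner[2]:(corner[2] + patch_size - 1L)
  zs <- corner[3]:(corner[3] + patch_size - 1L)
  ix <- expand.grid(x = xs, y = ys, z = zs)
  ix$x + (ix$y - 1L) * grid_shape[1] + (ix$z - 1L) * grid_shape[1] * grid_shape[2]
}

## ---- minimal MLP with Adam ----

mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    W <- list(); b <- list()
    for (i in seq_len(length(sizes) - 1L)) {
      sd_ <- sqrt(2 / (sizes[i] + sizes[i + 1]))
      W[[i]] <- matrix(rnorm(sizes[i] * sizes[i + 1], sd = sd_),
                       sizes[i], sizes[i + 1])
      b[[i]] <- numeric(sizes[i + 1])
    }
    list(W = W, b = b)
  })
}

mlp_forward <- function(params, X, dropout = 0) {
  L <- length(params$W)
  acts <- vector("list", L + 1L)
  masks <- vector("list", L)
  acts[[1]] <- X
  for (i in seq_len(L)) {
    Z <- acts[[i]] %*% params$W[[i]] +
      matrix(params$b[[i]], nrow(X), length(params$b[[i]]), byrow = TRUE)
    if (i < L) {
      Z <- pmax(Z, 0)                     # ReLU
      if (dropout > 0) {
        m <- matrix(runif(length(Z)) >= dropout, nrow(Z), ncol(Z)) / (1 - dropout)
        Z <- Z * m
        masks[[i]] <- m
      }
    }
    acts[[i + 1L]] <- Z
  }
  list(acts = acts, masks = masks)
}

mlp_backward <- function(params, fwd, Y) {
  L <- length(params$W)
  n <- nrow(Y)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- 2 * (fwd$acts[[L + 1L]] - Y) / (n * ncol(Y))   # d MSE
  for (i in L:1) {
    gW[[i]] <- crossprod(fwd$acts[[i]], delta)
    gb[[i]] <- colSums(delta)
    if (i > 1) {
      delta <- delta %*% t(params$W[[i]])
      if (!is.null(fwd$masks[[i - 1L]])) delta <- delta * fwd$masks[[i - 1L]]
      delta <- delta * (fwd$acts[[i]] > 0)
    }
  }
  list(W = gW, b = gb)
}

adam_state <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(params$W), vW = zero_like(params$W),
       mb = zero_like(params$b), vb = zero_like(params$b), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (i in seq_along(params$W)) {
    state$mW[[i]] <- beta1 * state$mW[[i]] + (1 - beta1) * grads$W[[i]]
    state$vW[[i]] <- beta2 * state$vW[[i]] + (1 - beta2) * grads$W[[i]]^2
    params$W[[i]] <- params$W[[i]] * (1 - lr * weight_decay) -
      lr * (state$mW[[i]] / c1) / (sqrt(state$vW[[i]] / c2) + eps)
    state$mb[[i]] <- beta1 * state$mb[[i]] + (1 - beta1) * grads$b[[i]]
    state$vb[[i]] <- beta2 * state$vb[[i]] + (1 - beta2) * grads$b[[i]]^2
    params$b[[i]] <- params$b[[i]] -
      lr * (state$mb[[i]] / c1) / (sqrt(state$vb[[i]] / c2) + eps)
  }
  list(params = params, state = state)
}

## Assemble per-subject training tensors: input field, GT coefficients,
## WM voxel indices per qualifying patch.
subject_training_data <- function(subject, six_indices, config) {
  ## training uses a non-overlapping patch cover (stride = patch size);
  ## the half-patch stride is reserved for overlap-averaged inference
  prep <- prepare_input(subject$dwi, subject$scheme, six_indices,
                        patch_size = config$patch_size,
                        stride = config$patch_size)
  wm <- as.vector(subject$wm_mask) & prep$valid
  keep <- vapply(seq_len(nrow(prep$patch_corners)), function(i) {
    vox <- patch_voxels(prep$patch_corners[i, ], prep$patch_size,
                        prep$grid_shape)
    mean(wm[vox]) >= config$min_wm_frac
  }, logical(1))
  corners <- prep$patch_corners[keep, , drop = FALSE]
  patches <- lapply(seq_len(nrow(corners)), function(i) {
    vox <- patch_voxels(corners[i, ], prep$patch_size, prep$grid_shape)
    vox[wm[vox]]
  })
  feat <- neighborhood_features(prep$field, prep$grid_shape,
                                context_offsets(config$context))
  list(X = t(feat), Y = t(subject$gt_fod$coefficients),
       wm = wm, patches = patches)
}

## Mean squared error of the model on the WM voxels of subjects.
estimator_val_mse <- function(params, data_list) {
  num <- 0; den <- 0
  for (d in data_list) {
    vox <- which(d$wm)
    pred <- mlp_forward(params, d$X[vox, , drop = FALSE])$acts
    pred <- pred[[length(pred)]]
    num <- num + sum((pred - d$Y[vox, , drop = FALSE])^2)
    den <- den + length(vox) * ncol(d$Y)
  }
  num / den
}

run_training_loop <- function(params, state, data_list, val_list, config,
                              lr, batch_size, epochs, seed, phase,
                              select_best = TRUE) {
  ## flat list of (subject, patch) references
  pat_ref <- do.call(rbind, lapply(seq_along(data_list), function(s) {
    np <- length(data_list[[s]]$patches)
    if (np == 0L) return(NULL)
    cbind(rep.int(s, np), seq_len(np))
  }))
  if (is.null(pat_ref) || nrow(pat_ref) == 0L) {
    stop2("no training patches meet the white-matter coverage threshold")
  }
  history <- data.frame()
  best <- list(mse = Inf, params = params, epoch = 0L)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, paste0(phase, "-order-", ep)),
                     sample(nrow(pat_ref)))
    loss_sum <- 0; loss_n <- 0
    nb <- ceiling(length(ord) / batch_size)
    for (bi in seq_len(nb)) {
      sel <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, length(ord))]
      vox_by_s <- split(sel, pat_ref[sel, 1])
      Xb <- NULL; Yb <- NULL
      for (sname in names(vox_by_s)) {
        s <- as.integer(sname)
        vox <- unlist(data_list[[s]]$patches[pat_ref[vox_by_s[[sname]], 2]])
        Xb <- rbind(Xb, data_list[[s]]$X[vox, , drop = FALSE])
        Yb <- rbind(Yb, data_list[[s]]$Y[vox, , drop = FALSE])
      }
      if (is.null(Xb) || nrow(Xb) == 0L) next
      fwd <- with_seed(derive_seed(seed, paste0(phase, "-drop-", ep, "-", bi)),
                       mlp_forward(params, Xb, dropout = config$dropout))
      loss <- mean((fwd$acts[[length(fwd$acts)]] - Yb)^2)
      gr <- mlp_backward(params, fwd, Yb)
      up <- adam_step(params, gr, state, lr,
                      weight_decay = config$weight_decay)
      params <- up$params; state <- up$state
      loss_sum <- loss_sum + loss * nrow(Xb); loss_n <- loss_n + nrow(Xb)
    }
    val_mse <- if (length(val_list)) estimator_val_mse(params, val_list) else NA_real_
    history <- rbind(history,
                     data.frame(phase = phase, epoch = ep,
                                train_mse = loss_sum / max(loss_n, 1),
                                val_mse = val_mse))
    ## divergence guard: the 5-epoch moving average of the training
    ## loss should not grow well beyond its best value
    if (nrow(history) >= 10L) {
      ma <- stats::filter(history$train_mse, rep(1 / 5, 5), sides = 1)
      ma <- ma[!is.na(ma)]
      if (ma[length(ma)] > 2 * min(ma)) {
        warning("training loss is diverging (moving average doubled); ",
                "consider a lower learning rate", call. = FALSE)
      }
    }
    if (select_best && is.finite(val_mse) && val_mse < best$mse) {
      best <- list(mse = val_mse, params = params, epoch = ep)
    }
  }
  if (!select_best || !is.finite(best$mse)) {
    best <- list(mse = history$val_mse[nrow(history)], params = params,
                 epoch = nrow(history))
  }
  list(params = params, state = state, best = best, history = history)
}

#' Train the FOD estimator
#'
#' Minimizes the MSE between predicted and ground-truth FOD SH
#' coefficients over white-matter voxels, drawing batches of training
#' patches in a seeded order, and selects the epoch with the lowest
#' validation MSE.  Deterministic for a fixed seed (single-threaded
#' numerics).
#'
#' @param config an [estimator_config()].
#' @param train_subjects,val_subjects disjoint lists of
#'   `subject_phantom`s.
#' @param six_indices six measurement indices (from
#'   [select_six_directions()] on the subjects' scheme).
#' @return object of class `fod_estimator` with parameter state,
#'   history, selected epoch and provenance.
#' @export
train_estimator <- function(config, train_subjects, val_subjects,
                            six_indices) {
  if (!length(train_subjects) || !length(val_subjects)) {
    stop2("train and validation subject lists must be non-empty")
  }
  data_list <- lapply(train_subjects, subject_training_data,
                      six_indices = six_indices, config = config)
  val_list <- lapply(val_subjects, subject_training_data,
                     six_indices = six_indices, config = config)
  sizes <- c(sh_ncoef(config$input_lmax) *
               nrow(context_offsets(config$context)),
             rep(config$base_channels, config$depth),
             sh_ncoef(config$output_lmax))
  params <- mlp_init(sizes, derive_seed(config$seed, "init"))
  state <- adam_state(params)
  res <- run_training_loop(params, state, data_list, val_list, config,
                           lr = config$lr_train,
                           batch_size = config$batch_train,
                           epochs = config$epochs_train,
                           seed = config$seed, phase = "train")
  structure(list(params = res$best$params, last_params = res$params,
                 adam_state = res$state, config = config,
                 six_indices = six_indices,
                 history = res$history, selected_epoch = res$best$epoch,
                 val_mse = res$best$mse,
                 provenance = list(seed = config$seed,
                                   n_train = length(train_subjects),
                                   n_val = length(val_subjects),
                                   train_ids = vapply(train_subjects, `[[`, 0, "seed"),
                                   val_ids = vapply(val_subjects, `[[`, 0, "seed"))),
            class = "fod_estimator")
}

#' @export
print.fod_estimator <- function(x, ...) {
  cat(sprintf("<fod_estimator> lmax %d -> %d, hidden %s; %d epochs recorded, selected %d (val MSE %.3g)\n",
              x$config$input_lmax, x$config$output_lmax,
              paste(rep(x$config$base_channels, x$config$depth), collapse = "-"),
              nrow(x$history), x$selected_epoch, x$val_mse))
  invisible(x)
}

#' Fine-tune a trained estimator on target-domain subjects
#'
#' Continues optimization from the selected parameters at the reduced
#' fine-tuning learning rate and batch size.  With `n >= 2` target
#' subjects the last subject is held out for validation-MSE model
#' selection; with a single subject the final-epoch parameters are
#' kept.  `lr = 0` leaves the parameters unchanged.
#'
#' @param model a trained `fod_estimator`.
#' @param target_subjects list of 1+ target-domain `subject_phantom`s.
#' @param lr,epochs,batch_size optional overrides of the config's
#'   fine-tuning hyperparameters.
#' @param six_indices six selected-direction indices in the *target*
#'   scheme (defaults to the model's own; pass the target selection
#'   when the target site uses a different scheme).
#' @return a fine-tuned `fod_estimator` with appended history; its
#'   `six_indices` are updated to the target selection.
#' @export
finetune_estimator <- function(model, target_subjects,
                               lr = NULL, epochs = NULL, batch_size = NULL,
                               six_indices = NULL) {
  if (!length(target_subjects)) stop2("need >= 1 target subject")
  config <- model$config
  lr <- lr %||% config$lr_finetune
  epochs <- epochs %||% config$epochs_finetune
  batch_size <- batch_size %||% config$batch_finetune
  model$six_indices <- six_indices %||% model$six_indices
  n <- length(target_subjects)
  if (n >= 2L) {
    tr <- target_subjects[seq_len(n - 1L)]
    vl <- target_subjects[n]
  } else {
    tr <- target_subjects
    vl <- list()
  }
  data_list <- lapply(tr, subject_training_data,
                      six_indices = model$six_indices, config = config)
  val_list <- lapply(vl, subject_training_data,
                     six_indices = model$six_indices, config = config)
  if (lr == 0) {
    model$provenance$n_finetune <- n
    return(model)
  }
  res <- run_training_loop(model$params, adam_state(model$params),
                           data_list, val_list, config,
                           lr = lr, batch_size = batch_size, epochs = epochs,
                           seed = derive_seed(config$seed, paste0("ft-", n)),
                           phase = "finetune", select_best = n >= 2L)
  model$params <- res$best$params
  model$last_params <- res$params
  model$history <- rbind(model$history, res$history)
  model$selected_epoch <- nrow(model$history) - nrow(res$history) + res$best$epoch
  model$val_mse <- res$best$mse
  model$provenance$n_finetune <- n
  model$provenance$finetune_ids <- vapply(target_subjects, `[[`, 0, "seed")
  model
}

#' Predict an FOD field for a subject
#'
#' Sliding-window patch inference with stride `patch_size / 2` and
#' uniform averaging in overlaps; returns the predicted SH field at the
#' model's output order over the full grid.
#'
#' @param model a `fod_estimator`.
#' @param subject a `subject_phantom`.
#' @param six_indices six selected-direction indices in the subject's
#'   scheme (defaults to the model's own selection).
#' @return an [sh_field()].
#' @export
predict_fod <- function(model, subject, six_indices = NULL) {
  config <- model$config
  prep <- prepare_input(subject$dwi, subject$scheme,
                        six_indices %||% model$six_indices,
                        patch_size = config$patch_size)
  nvox <- prod(prep$grid_shape)
  nc <- sh_ncoef(config$output_lmax)
  acc <- matrix(0, nvox, nc)
  cnt <- numeric(nvox)
  X <- t(neighborhood_features(prep$field, prep$grid_shape,
                               context_offsets(config$context)))
  for (i in seq_len(nrow(prep$patch_corners))) {
    vox <- patch_voxels(prep$patch_corners[i, ], prep$patch_size,
                        prep$grid_shape)
    out <- mlp_forward(model$params, X[vox, , drop = FALSE])$acts
    acc[vox, ] <- acc[vox, ] + out[[length(out)]]
    cnt[vox] <- cnt[vox] + 1
  }
  cnt[cnt == 0] <- 1
  sh_field(t(acc / cnt), prep$grid_shape)
}
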
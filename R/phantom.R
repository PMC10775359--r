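## Synthetic two-site, age-structured dMRI cohorts with known crossing
## fiber geometry: the stand-in for real neonatal/baby cohorts that
## makes every downstream stage testable without data downloads.

#' Arctan growth model of white-matter FA versus age
#'
#' `FA(t) = a * atan(b * (t - t0)) + d`, with `t` in postnatal months.
#' This family captures the rapid early rise and later plateau of mean
#' white-matter fractional anisotropy during development.
#'
#' @param a,b,t0,d curve parameters (`a > 0`, `b > 0`).
#' @return object of class `age_model`.
#' @export
age_model <- function(a = 0.06, b = 0.35, t0 = 2, d = 0.22) {
  if (a <= 0 || b <= 0) stop2("age_model requires a > 0 and b > 0")
  structure(list(a = a, b = b, t0 = t0, d = d), class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("<age_model> FA(t) = %.4g * atan(%.4g * (t - %.4g)) + %.4g\n",
              x$a, x$b, x$t0, x$d))
  invisible(x)
}

#' Model FA at a given age
#' @param model an [age_model()].
#' @param age_months postnatal age(s) in months.
#' @return FA value(s).
#' @export
fa_at_age <- function(model, age_months) {
  model$a * atan(model$b * (age_months - model$t0)) + model$d
}

#' Convert post-menstrual weeks to postnatal months
#'
#' Subtracts the 40-week term gestation then divides by the mean month
#' length in weeks (4.345), so preterm scan ages map to small negative
#' postnatal months.
#'
#' @param pmw age in post-menstrual weeks.
#' @return age in postnatal months.
#' @export
pmw_to_months <- function(pmw) (pmw - 40) / 4.345

#' Acquisition-site profile: scheme, signal shift fields and noise
#'
#' Smooth multiplicative gain and additive offset fields emulate the
#' scanner/protocol signal differences between sites; Rician noise of
#' standard deviation `rician_sigma * S0` is applied after the shift.
#' Site-level fields are deterministic functions of the site name; a
#' small per-subject smooth perturbation (`subject_jitter`) emulates
#' positioning/coil-load differences between scans at the same site.
#'
#' @param name site label.
#' @param scheme the site's [gradient_scheme()].
#' @param rician_sigma noise SD relative to the b0 signal.
#' @param gain_base,gain_amp multiplicative field `gain_base * (1 +
#'   gain_amp * smooth)` (must stay positive).
#' @param offset_frac,offset_amp additive field `(offset_frac +
#'   offset_amp * smooth) * S0`, floored at 0.
#' @param subject_jitter relative per-subject modulation of both fields.
#' @param gain_field,offset_field optional explicit 3D arrays overriding
#'   the generated fields.
#' @return object of class `site_profile`.
#' @export
site_profile <- function(name, scheme, rician_sigma = 0.02,
                         gain_base = 1, gain_amp = 0,
                         offset_frac = 0, offset_amp = 0,
                         subject_jitter = 0,
                         gain_field = NULL, offset_field = NULL) {
  if (rician_sigma < 0) stop2("rician_sigma must be >= 0")
  if (gain_base <= 0) stop2("gain_base must be positive")
  structure(list(name = name, scheme = scheme,
                 rician_sigma = rician_sigma,
                 gain_base = gain_base, gain_amp = gain_amp,
                 offset_frac = offset_frac, offset_amp = offset_amp,
                 subject_jitter = subject_jitter,
                 gain_field = gain_field, offset_field = offset_field),
            class = "site_profile")
}

## Materialize per-subject gain/offset fields on a grid.
site_fields <- function(profile, grid_shape, subject_seed, s0_ref) {
  if (!is.null(profile$gain_field) && !is.null(profile$offset_field)) {
    return(list(gain = profile$gain_field, offset = profile$offset_field))
  }
  site_seed <- derive_seed(7, paste0("site-", profile$name))
  ## site-level fields are close to global: scanner gain/baseline
  ## differences vary only gently across the field of view
  f1 <- smooth_random_field(grid_shape, derive_seed(site_seed, "gain"),
                            max_cycles = 0.5)
  f2 <- smooth_random_field(grid_shape, derive_seed(site_seed, "offset"),
                            max_cycles = 0.5)
  gain <- profile$gain_base * (1 + profile$gain_amp * f1)
  offset <- pmax(0, (profile$offset_frac + profile$offset_amp * f2)) * s0_ref
  if (profile$subject_jitter > 0) {
    j1 <- smooth_random_field(grid_shape, derive_seed(subject_seed, "gain-jit"))
    j2 <- smooth_random_field(grid_shape, derive_seed(subject_seed, "off-jit"))
    gain <- gain * (1 + profile$subject_jitter * j1)
    offset <- offset * pmax(0, 1 + profile$subject_jitter * j2)
  }
  gain <- pmax(gain, 1e-3)
  list(gain = gain, offset = offset)
}

#' Region specification for phantom fiber geometry
#'
#' Describes the white-matter box inside the grid and how its voxels are
#' allocated to disjoint 1-, 2- and 3-fiber regions.
#'
#' @param shares length-3 non-negative vector of voxel shares for the
#'   1/2/3-fiber regions (summing to 1).
#' @param wm_lo,wm_hi inclusive voxel bounds (length-3, 1-based) of the
#'   white-matter box; `NULL` means a central box covering ~2/3 of each
#'   dimension.
#' @param crossing_range degrees; crossing angles are drawn uniformly
#'   from this range for 2-fiber regions.
#' @param jitter_deg smooth within-region direction variation (degrees).
#' @param base_dirs optional list of fixed base-direction matrices (one
#'   k x 3 matrix per region k = 1, 2, 3), overriding random sampling.
#' @return object of class `region_spec`.
#' @export
region_spec <- function(shares = c(0.3, 0.5, 0.2), wm_lo = NULL, wm_hi = NULL,
                        crossing_range = c(45, 90), jitter_deg = 8,
                        base_dirs = NULL) {
  if (length(shares) != 3L || any(shares < 0) || abs(sum(shares) - 1) > 1e-9) {
    stop2("shares must be 3 non-negative numbers summing to 1")
  }
  structure(list(shares = shares, wm_lo = wm_lo, wm_hi = wm_hi,
                 crossing_range = crossing_range, jitter_deg = jitter_deg,
                 base_dirs = base_dirs),
            class = "region_spec")
}

#' Sample per-voxel fiber geometry for a phantom
#'
#' Splits the white-matter box into contiguous slabs (along the first
#' axis) holding exactly the requested shares of 1-, 2- and 3-fiber
#' voxels.  The primary fiber direction is a smoothly varying random
#' unit-vector field, so each subject's white matter covers direction
#' space broadly (as real anatomy does) while neighbouring voxels stay
#' coherent.  Secondary fibers cross the primary at an angle drawn from
#' `crossing_range` (with mild smooth spatial variation); a third fiber
#' is orthogonal to the first two.  When `base_dirs` is supplied the
#' field is instead a fixed direction per region with `jitter_deg`
#' smooth perturbation (useful for controlled fixtures).  Deterministic
#' for a fixed seed.
#'
#' @param grid_shape length-3 integer grid dimensions.
#' @param spec a [region_spec()].
#' @param seed integer seed.
#' @return object of class `fiber_config` with fields `grid_shape`,
#'   `n_fibers` (per-voxel count), `directions` (nvox x 3 x 3 array) and
#'   `fractions` (nvox x 3).
#' @export
sample_fiber_geometry <- function(grid_shape, spec = region_spec(), seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  lo <- spec$wm_lo %||% (floor(grid_shape / 8) + 1L)
  hi <- spec$wm_hi %||% (grid_shape - floor(grid_shape / 8))
  if (any(lo < 1L) || any(hi > grid_shape) || any(lo > hi)) {
    stop2("white-matter region exceeds the grid")
  }
  nvox <- grid_nvox(grid_shape)
  n_fib <- integer(nvox)
  dirs <- array(NA_real_, c(nvox, 3, 3))
  fracs <- matrix(0, nvox, 3)

  ## linear indices of the WM box, ordered x-fastest
  ix <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  lin <- ix$x + (ix$y - 1L) * grid_shape[1] +
    (ix$z - 1L) * grid_shape[1] * grid_shape[2]
  o <- order(ix$x, ix$y, ix$z)
  lin <- lin[o]
  n_wm <- length(lin)
  n1 <- round(spec$shares[1] * n_wm)
  n2 <- round(spec$shares[2] * n_wm)
  n3 <- n_wm - n1 - n2
  region_of <- rep.int(c(1L, 2L, 3L), c(n1, n2, n3))

  normalize_rows <- function(m, fallback) {
    nr <- sqrt(rowSums(m^2))
    bad <- nr < 1e-8
    if (any(bad)) {
      m[bad, ] <- fallback[bad, , drop = FALSE]
      nr[bad] <- sqrt(rowSums(m[bad, , drop = FALSE]^2))
    }
    m / nr
  }
  ## smooth unit-vector field covering direction space across the grid
  smooth_dir_field <- function(tag) {
    f <- sapply(1:3, function(comp) {
      as.vector(smooth_random_field(grid_shape,
                                    derive_seed(seed, paste(tag, comp)),
                                    max_cycles = 1.0))
    })
    normalize_rows(f, matrix(c(0, 0, 1), nrow(f), 3, byrow = TRUE))
  }
  with_seed(seed, {
    if (is.null(spec$base_dirs)) {
      d1 <- smooth_dir_field("d1")
      ## second direction: primary rotated within its orthogonal plane
      ## by a crossing angle that varies mildly across space
      e2 <- smooth_dir_field("e2")
      e2 <- e2 - rowSums(e2 * d1) * d1
      ## fallback for voxels where e2 is parallel to d1: any orthogonal
      fb <- cbind(-d1[, 2], d1[, 1], 0)
      fb_bad <- rowSums(fb^2) < 1e-8
      fb[fb_bad, ] <- cbind(0, -d1[fb_bad, 3], d1[fb_bad, 2])
      e2 <- normalize_rows(e2, fb)
      mid <- mean(spec$crossing_range)
      amp <- diff(spec$crossing_range) / 2
      thf <- runif(1, -1, 1) +
        0.5 * as.vector(smooth_random_field(grid_shape,
                                            derive_seed(seed, "theta")))
      th <- (mid + amp * pmin(pmax(thf, -1), 1)) * pi / 180
      d2 <- d1 * cos(th) + e2 * sin(th)
      d3 <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
                  d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
                  d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
      d3 <- d3 / sqrt(rowSums(d3^2) + 1e-12)
      field <- list(d1, d2, d3)
      for (k in 1:3) {
        vox <- lin[region_of == k]
        if (!length(vox)) next
        n_fib[vox] <- k
        for (i in seq_len(k)) {
          dirs[vox, , i] <- field[[i]][vox, ]
          fracs[vox, i] <- 1 / k
        }
      }
    } else {
      jit <- sin(spec$jitter_deg * pi / 180)
      for (k in 1:3) {
        vox <- lin[region_of == k]
        if (!length(vox)) next
        base <- as_direction_matrix(spec$base_dirs[[k]], normalize = TRUE)
        n_fib[vox] <- nrow(base)
        for (i in seq_len(nrow(base))) {
          d <- matrix(base[i, ], length(vox), 3, byrow = TRUE)
          if (jit > 0) {
            for (comp in 1:3) {
              f <- smooth_random_field(grid_shape,
                                       derive_seed(seed, paste(k, i, comp)))
              d[, comp] <- d[, comp] + jit * f[vox]
            }
          }
          d <- d / sqrt(rowSums(d^2))
          dirs[vox, , i] <- d
          fracs[vox, i] <- 1 / nrow(base)
        }
      }
    }
  })
  structure(list(grid_shape = grid_shape, n_fibers = n_fib,
                 directions = dirs, fractions = fracs),
            class = "fiber_config")
}

#' @export
print.fiber_config <- function(x, ...) {
  cat("<fiber_config> grid ", paste(x$grid_shape, collapse = "x"),
      "; fiber counts: ", sep = "")
  print(table(x$n_fibers))
  invisible(x)
}

#' Map age to single-tensor diffusivities matching the model FA
#'
#' Holds the axial diffusivity fixed and solves the prolate-tensor FA
#' closed form `FA = (l1 - l3) / sqrt(l1^2 + 2 l3^2)` for the radial
#' diffusivity so that a single-fiber voxel's tensor FA equals the age
#' model's FA at that age.  Older age, higher FA, lower radial
#' diffusivity.
#'
#' @param age_months postnatal age in months.
#' @param model an [age_model()].
#' @param lambda_par axial diffusivity in mm^2/s (default 1.7e-3).
#' @return named vector `c(lambda_par, lambda_perp)` in mm^2/s.
#' @export
age_to_diffusivities <- function(age_months, model, lambda_par = 1.7e-3) {
  fa <- fa_at_age(model, age_months)
  if (fa < 0 || fa >= 1) stop2("target FA ", round(fa, 4), " outside [0, 1)")
  l1 <- lambda_par
  lp <- if (fa == 0) {
    l1
  } else if (abs(1 - 2 * fa^2) < 1e-12) {
    l1 * (1 - fa^2) / 2
  } else {
    ## (1 - 2 FA^2) x^2 - 2 l1 x + l1^2 (1 - FA^2) = 0
    aa <- 1 - 2 * fa^2
    disc <- sqrt(4 * l1^2 - 4 * aa * l1^2 * (1 - fa^2))
    roots <- (2 * l1 + c(-1, 1) * disc) / (2 * aa)
    cand <- roots[roots > 0 & roots <= l1 + 1e-15]
    if (!length(cand)) stop2("no admissible radial diffusivity for FA ", fa)
    min(cand)
  }
  c(lambda_par = l1, lambda_perp = lp)
}

#' Simulate the noiseless multi-compartment DWI signal
#'
#' Multi-tensor forward model: each fiber population contributes a
#' prolate tensor along its direction, the remaining volume fraction
#' (and fiber-free voxels) an isotropic compartment:
#' `S(b, g) = S0 * (sum_i f_i exp(-b g' D_i g) + (1 - sum f) exp(-b md_iso))`.
#'
#' @param config a [sample_fiber_geometry()] result.
#' @param diffusivities `c(lambda_par, lambda_perp)` in mm^2/s.
#' @param scheme a [gradient_scheme()].
#' @param S0 non-diffusion-weighted signal (default 100).
#' @param md_iso isotropic compartment diffusivity (mm^2/s).
#' @return 4D array `c(grid_shape, n_measurements)`.
#' @export
simulate_signal <- function(config, diffusivities, scheme, S0 = 100,
                            md_iso = 1.2e-3) {
  l1 <- diffusivities[[1]]; lp <- diffusivities[[2]]
  if (!(l1 > lp) || lp <= 0) stop2("need lambda_par > lambda_perp > 0")
  if (S0 <= 0) stop2("S0 must be positive")
  b <- scheme$bvals
  g <- scheme$bvecs
  nm <- length(b)
  nvox <- grid_nvox(config$grid_shape)
  f_tot <- rowSums(config$fractions)
  ## isotropic part for every voxel
  sig <- outer(exp(-b * md_iso), (1 - f_tot))      # nm x nvox
  for (k in 1:3) {
    vox <- which(config$n_fibers >= k)
    if (!length(vox)) next
    u <- config$directions[vox, , k, drop = FALSE]
    dim(u) <- c(length(vox), 3)
    dot <- g %*% t(u)                              # nm x nvox_k
    att <- exp(-b * (lp + (l1 - lp) * dot^2))      # b recycles down columns
    sig[, vox] <- sig[, vox] +
      att * matrix(config$fractions[vox, k], nm, length(vox), byrow = TRUE)
  }
  array(t(sig) * S0, dim = c(config$grid_shape, nm))
}

#' Apply site gain/offset fields and Rician noise to a clean volume
#'
#' `S_obs = sqrt((gain * S + offset + e1)^2 + e2^2)` with
#' `e1, e2 ~ N(0, sigma^2)`, `sigma = rician_sigma * s0_ref`.
#' Deterministic for a fixed seed.
#'
#' @param clean_dwi 4D noiseless signal array.
#' @param profile a [site_profile()].
#' @param seed integer seed (also keys the per-subject field jitter).
#' @param s0_ref reference b0 signal level; default the volume maximum.
#' @return observed 4D signal array.
#' @export
apply_site_effects <- function(clean_dwi, profile, seed, s0_ref = NULL) {
  d <- dim(clean_dwi)
  grid_shape <- d[1:3]
  s0_ref <- s0_ref %||% max(clean_dwi)
  fl <- site_fields(profile, grid_shape, seed, s0_ref)
  if (any(fl$gain <= 0)) stop2("gain field must be positive everywhere")
  x <- clean_dwi * as.numeric(fl$gain) + as.numeric(fl$offset)
  sigma <- profile$rician_sigma * s0_ref
  if (sigma > 0) {
    with_seed(derive_seed(seed, "rician"), {
      e1 <- array(rnorm(length(x), sd = sigma), d)
      e2 <- array(rnorm(length(x), sd = sigma), d)
      x <- sqrt((x + e1)^2 + e2^2)
    })
  }
  x
}

#' SH coefficient field container
#'
#' @param coefficients ncoef x nvox matrix (package SH ordering).
#' @param grid_shape length-3 grid dimensions.
#' @return object of class `sh_field`.
#' @export
sh_field <- function(coefficients, grid_shape) {
  coefficients <- as.matrix(coefficients)
  lmax <- lmax_from_ncoef(nrow(coefficients))
  if (ncol(coefficients) != grid_nvox(grid_shape)) {
    stop2("coefficient columns must match the voxel count")
  }
  structure(list(lmax = lmax, coefficients = coefficients,
                 grid_shape = as.integer(grid_shape),
                 basis_convention = "real-even-lmajor"),
            class = "sh_field")
}

#' @export
print.sh_field <- function(x, ...) {
  cat("<sh_field> lmax ", x$lmax, " (", nrow(x$coefficients),
      " coeffs) on grid ", paste(x$grid_shape, collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Analytic ground-truth FOD field from a fiber configuration
#'
#' Each fiber population contributes a band-limited apodized delta lobe
#' at its direction, weighted by its volume fraction, so the FOD's
#' sphere integral equals the total fiber fraction and its peaks sit at
#' the configured directions.
#'
#' @param config a [sample_fiber_geometry()] result.
#' @param lmax even SH order of the FOD (default 8).
#' @param kappa lobe sharpness of the apodized delta kernel.
#' @return an [sh_field()].
#' @export
analytic_gt_fod <- function(config, lmax = 8L, kappa = 12) {
  kl <- apodized_delta_kernel(lmax, kappa)
  idx <- sh_index_table(lmax)
  wl <- (4 * pi / (2 * idx$l + 1)) * kl[match(idx$l, seq(0, lmax, by = 2))]
  nvox <- grid_nvox(config$grid_shape)
  C <- matrix(0, sh_ncoef(lmax), nvox)
  for (k in 1:3) {
    vox <- which(config$n_fibers >= k)
    if (!length(vox)) next
    u <- config$directions[vox, , k, drop = FALSE]
    dim(u) <- c(length(vox), 3)
    Y <- sh_basis(u, lmax)                          # nvox_k x ncoef
    C[, vox] <- C[, vox] + t(Y) *
      matrix(config$fractions[vox, k], nrow(C), length(vox), byrow = TRUE)
  }
  sh_field(C * wl, config$grid_shape)
}

#' Generate a synthetic cohort for one site
#'
#' Ages are sampled uniformly in `age_range`; each subject gets its own
#' reproducible seed derived from the master seed, a fiber geometry,
#' age-matched diffusivities, a clean multi-shell signal, site effects
#' with Rician noise, a white-matter mask (fiber-bearing voxels) and an
#' analytic ground-truth FOD.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param age_range length-2 postnatal months range.
#' @param profile a [site_profile()].
#' @param model an [age_model()].
#' @param spec a [region_spec()].
#' @param seed master seed.
#' @param grid_shape grid dimensions (default 24^3 at a nominal 1.5 mm
#'   isotropic resolution).
#' @param S0 b0 signal level.
#' @param lmax GT FOD order.
#' @return list of `subject_phantom` objects.
#' @export
generate_cohort <- function(n_subjects, age_range, profile, model,
                            spec = region_spec(), seed = 1L,
                            grid_shape = c(24L, 24L, 24L), S0 = 100,
                            lmax = 8L) {
  if (n_subjects < 1) stop2("n_subjects must be >= 1")
  if (length(age_range) != 2L || diff(range(age_range)) <= 0) {
    stop2("age_range must be a non-empty interval")
  }
  ages <- with_seed(derive_seed(seed, paste0("ages-", profile$name)),
                    runif(n_subjects, age_range[1], age_range[2]))
  lapply(seq_len(n_subjects), function(i) {
    sseed <- derive_seed(seed, paste0(profile$name, "-subject-", i))
    config <- sample_fiber_geometry(grid_shape, spec,
                                    seed = derive_seed(sseed, "geom"))
    dv <- age_to_diffusivities(ages[i], model)
    clean <- simulate_signal(config, dv, profile$scheme, S0 = S0)
    dwi <- apply_site_effects(clean, profile, seed = sseed, s0_ref = S0)
    structure(list(dwi = dwi, scheme = profile$scheme,
                   gt_fod = analytic_gt_fod(config, lmax = lmax),
                   fiber_config = config,
                   wm_mask = array(config$n_fibers > 0, dim = grid_shape),
                   age = ages[i], site = profile$name, seed = sseed,
                   S0 = S0),
              class = "subject_phantom")
  })
}

#' @export
print.subject_phantom <- function(x, ...) {
  cat(sprintf("<subject_phantom> site %s, age %.2f months, grid %s, %d WM voxels\n",
              x$site, x$age, paste(dim(x$wm_mask), collapse = "x"),
              sum(x$wm_mask)))
  invisible(x)
}

#' Write a subject phantom to disk (NIfTI + FSL text + JSON)
#'
#' Writes `dwi.nii.gz`, `wm_mask.nii.gz`, `gt_fod.nii.gz` (4D, last
#' dimension = SH coefficient in the package ordering, recorded in the
#' NIfTI `descrip` header field), `bvals`/`bvecs`, and `subject.json`.
#'
#' @param subject a `subject_phantom`.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pix <- c(1.5, 1.5, 1.5)
  RNifti::writeNifti(RNifti::asNifti(subject$dwi, pixdim = pix),
                     file.path(dir, "dwi.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(subject$wm_mask * 1L, pixdim = pix),
                     file.path(dir, "wm_mask.nii.gz"))
  fod <- array(t(subject$gt_fod$coefficients),
               dim = c(subject$gt_fod$grid_shape, nrow(subject$gt_fod$coefficients)))
  img <- RNifti::asNifti(fod, pixdim = pix)
  img <- RNifti::asNifti(img, descrip = paste0("SH:real-even-lmajor;lmax=",
                                               subject$gt_fod$lmax))
  RNifti::writeNifti(img, file.path(dir, "gt_fod.nii.gz"))
  write_bvals_bvecs(subject$scheme, file.path(dir, "bvals"),
                    file.path(dir, "bvecs"))
  jsonlite::write_json(list(age_months = subject$age, site = subject$site,
                            seed = subject$seed, S0 = subject$S0),
                       file.path(dir, "subject.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a subject phantom written by [write_subject()]
#'
#' @param dir directory containing the subject files.
#' @return a `subject_phantom` (without the fiber configuration, which
#'   is not serialized).
#' @export
read_subject <- function(dir) {
  dwi <- as.array(RNifti::readNifti(file.path(dir, "dwi.nii.gz")))
  mask <- as.array(RNifti::readNifti(file.path(dir, "wm_mask.nii.gz"))) > 0
  fod_img <- RNifti::readNifti(file.path(dir, "gt_fod.nii.gz"))
  fod <- as.array(fod_img)
  d <- dim(fod)
  meta <- jsonlite::read_json(file.path(dir, "subject.json"))
  scheme <- read_bvals_bvecs(file.path(dir, "bvals"), file.path(dir, "bvecs"))
  coeffs <- t(matrix(fod, prod(d[1:3]), d[4]))
  structure(list(dwi = dwi, scheme = scheme,
                 gt_fod = sh_field(coeffs, d[1:3]),
                 fiber_config = NULL, wm_mask = mask,
                 age = meta$age_months, site = meta$site, seed = meta$seed,
                 S0 = meta$S0 %||% max(dwi)),
            class = "subject_phantom")
}
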
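## Diffusion-tensor fitting, FA/MD maps, the white-matter mask rules,
## and the arctan growth analysis of mean white-matter FA versus age.

#' Log-linear least-squares diffusion tensor fit
#'
#' Fits `ln S = ln S0 - b g' D g` per voxel by ordinary least squares,
#' using only shells with `b <= b_max` (Gaussian-regime convention;
#' default 1000 s/mm^2) plus the b0s.  Non-positive signals are clamped
#' to a small floor before taking logs; the number of clamped values is
#' reported as an attribute.
#'
#' @param dwi 4D signal array.
#' @param scheme a [gradient_scheme()].
#' @param b_max largest b-value used in the fit.
#' @param clamp signal floor applied before the log.
#' @return object of class `tensor_field`: list with `tensors` (nvox x 6
#'   matrix: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `log_s0`, `grid_shape`, and
#'   attribute `n_clamped`.
#' @export
fit_tensor <- function(dwi, scheme, b_max = 1000, clamp = 1e-6) {
  d <- dim(dwi)
  use <- which(scheme$bvals <= b_max + scheme$shell_tol)
  b <- scheme$bvals[use]
  g <- scheme$bvecs[use, , drop = FALSE]
  if (sum(b > scheme$shell_tol) < 6L || !any(b <= scheme$shell_tol)) {
    stop2("tensor fit needs >= 6 diffusion-weighted measurements and a b0")
  }
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  if (qr(X)$rank < 7L) {
    stop2("gradient directions are degenerate (rank-deficient tensor design)")
  }
  S <- matrix(dwi, prod(d[1:3]), d[4])[, use, drop = FALSE]
  n_clamped <- sum(S < clamp)
  if (n_clamped > 0) {
    warning(n_clamped, " non-positive signal values clamped before log",
            call. = FALSE)
    S[S < clamp] <- clamp
  }
  Y <- t(log(S))                                  # nmeas x nvox
  beta <- solve(crossprod(X), crossprod(X, Y))    # 7 x nvox
  structure(list(tensors = t(beta[2:7, , drop = FALSE]),
                 log_s0 = beta[1, ], grid_shape = d[1:3]),
            class = "tensor_field", n_clamped = n_clamped)
}

## Eigenvalues of many symmetric 3x3 tensors (rows Dxx,Dyy,Dzz,Dxy,Dxz,Dyz),
## via the trigonometric closed form; returned in decreasing order.
tensor_eigenvalues <- function(tensors) {
  xx <- tensors[, 1]; yy <- tensors[, 2]; zz <- tensors[, 3]
  xy <- tensors[, 4]; xz <- tensors[, 5]; yz <- tensors[, 6]
  q <- (xx + yy + zz) / 3
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * (xy^2 + xz^2 + yz^2)
  p <- sqrt(pmax(p2 / 6, 0))
  iso <- p < 1e-14 * pmax(abs(q), 1e-300)
  p_safe <- ifelse(iso, 1, p)
  bxx <- (xx - q) / p_safe; byy <- (yy - q) / p_safe; bzz <- (zz - q) / p_safe
  bxy <- xy / p_safe; bxz <- xz / p_safe; byz <- yz / p_safe
  detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(1, pmax(-1, detB / 2))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  out <- cbind(e1, e2, e3)
  out[iso, ] <- q[iso]
  out
}

#' FA and MD maps from a tensor field
#'
#' Standard closed forms from the (non-negativity-clipped) eigenvalues;
#' an all-zero tensor yields FA = 0 and MD = 0 by convention.
#'
#' @param tensor_field a [fit_tensor()] result.
#' @return list with 3D arrays `fa` (unitless, in `[0, 1]`) and `md`
#'   (mm^2/s).
#' @export
compute_fa_md <- function(tensor_field) {
  ev <- pmax(tensor_eigenvalues(tensor_field$tensors), 0)
  md <- rowMeans(ev)
  num <- sqrt(((ev[, 1] - ev[, 2])^2 + (ev[, 2] - ev[, 3])^2 +
                 (ev[, 1] - ev[, 3])^2) / 2)
  den <- sqrt(rowSums(ev^2))
  fa <- ifelse(den > 0, pmin(1, num / den), 0)
  list(fa = array(fa, tensor_field$grid_shape),
       md = array(md, tensor_field$grid_shape))
}

## Principal eigenvectors (nvox x 3) of a tensor field, for response
## estimation.  Falls back to +z for isotropic voxels.
tensor_principal_dirs <- function(tensor_field) {
  tf <- tensor_field$tensors
  n <- nrow(tf)
  out <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  for (i in seq_len(n)) {
    D <- matrix(c(tf[i, 1], tf[i, 4], tf[i, 5],
                  tf[i, 4], tf[i, 2], tf[i, 6],
                  tf[i, 5], tf[i, 6], tf[i, 3]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    if (e$values[1] - e$values[2] > 1e-12) out[i, ] <- e$vectors[, 1]
  }
  out
}

#' White-matter mask rules
#'
#' The two site-specific mask constructions:
#' * `"dhcp"`: tissue mask OR `FA > 0.3`;
#' * `"bcp"`: tissue mask OR `FA > 0.4` OR (`FA > 0.15` AND
#'   `MD > 0.0011` mm^2/s).
#'
#' All comparisons are strict.
#'
#' @param fa_map,md_map 3D arrays from [compute_fa_md()].
#' @param tissue_mask 3D logical array (an anatomical WM/brainstem mask,
#'   taken as input).
#' @param rule `"dhcp"` or `"bcp"`.
#' @param fa_dhcp,fa_bcp,fa_low,md_low rule thresholds.
#' @return 3D logical mask.
#' @export
build_wm_mask <- function(fa_map, md_map, tissue_mask, rule = c("dhcp", "bcp"),
                          fa_dhcp = 0.3, fa_bcp = 0.4, fa_low = 0.15,
                          md_low = 0.0011) {
  rule <- match.arg(rule)
  if (!all(dim(fa_map) == dim(tissue_mask)) ||
      !all(dim(fa_map) == dim(md_map))) {
    stop2("fa_map, md_map and tissue_mask must share one grid")
  }
  tm <- tissue_mask > 0
  out <- if (rule == "dhcp") {
    tm | (fa_map > fa_dhcp)
  } else {
    tm | (fa_map > fa_bcp) | (fa_map > fa_low & md_map > md_low)
  }
  array(out, dim(fa_map))
}

#' Mean FA within a white-matter mask
#'
#' @param fa_map 3D FA array.
#' @param wm_mask 3D logical mask (non-empty).
#' @return scalar mean FA.
#' @export
mean_wm_fa <- function(fa_map, wm_mask) {
  if (!any(wm_mask)) stop2("white-matter mask is empty")
  mean(fa_map[wm_mask > 0])
}

#' Fit the arctan growth curve of mean FA versus age
#'
#' Nonlinear least squares of `FA(t) = a * atan(b * (t - t0)) + d` with
#' multi-start initialization over a grid of growth rates and inflection
#' ages.  A fit whose growth term is negligible over the observed range
#' (flat data) is flagged `degenerate`.
#'
#' @param ages postnatal ages in months (>= 8 points).
#' @param mean_fas mean WM FA per subject.
#' @return list of class `arctan_fit` with the fitted [age_model()],
#'   `rss`, `rms`, `degenerate` flag and the `fit` object.
#' @export
fit_arctan_growth <- function(ages, mean_fas) {
  if (length(ages) < 8L || length(ages) != length(mean_fas)) {
    stop2("need >= 8 (age, FA) pairs")
  }
  dat <- data.frame(t = ages, fa = mean_fas)
  spread <- diff(range(ages))
  starts <- expand.grid(b = c(0.05, 0.2, 0.5, 2) / max(1, spread / 20),
                        t0 = quantile(ages, c(0.25, 0.5, 0.75), names = FALSE))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(a = max(stats::sd(mean_fas), 1e-3), b = starts$b[i],
               t0 = starts$t0[i], d = mean(mean_fas))
    fit <- tryCatch(
      minpack.lm::nlsLM(fa ~ a * atan(b * (t - t0)) + d, data = dat,
                        start = st,
                        lower = c(a = 1e-6, b = 1e-6, t0 = -Inf, d = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop2("arctan growth fit failed to converge from every start")
  }
  cf <- coef(best$fit)
  model <- age_model(a = max(cf[["a"]], 1e-12), b = max(cf[["b"]], 1e-12),
                     t0 = cf[["t0"]], d = cf[["d"]])
  rng <- range(ages)
  swing <- abs(fa_at_age(model, rng[2]) - fa_at_age(model, rng[1]))
  structure(list(model = model, rss = best$rss,
                 rms = sqrt(best$rss / length(ages)),
                 degenerate = swing < 1e-3 || cf[["b"]] < 1e-4,
                 fit = best$fit),
            class = "arctan_fit")
}

#' @export
print.arctan_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  residual RMS %.5f%s\n", x$rms,
              if (x$degenerate) "  [degenerate: flat growth]" else ""))
  invisible(x)
}

#' Mean-FA-versus-age table for a cohort
#'
#' Refits the tensor per subject, rebuilds the site's WM mask rule from
#' the FA/MD maps (using the phantom's own mask as the anatomical
#' tissue input) and records mean WM FA.
#'
#' @param subjects list of `subject_phantom`s.
#' @param rule mask rule passed to [build_wm_mask()].
#' @return data.frame with `subject`, `site`, `age_months`, `mean_wm_fa`.
#' @export
cohort_fa_table <- function(subjects, rule = "dhcp") {
  rows <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    tf <- fit_tensor(s$dwi, s$scheme)
    maps <- compute_fa_md(tf)
    mask <- build_wm_mask(maps$fa, maps$md, s$wm_mask, rule = rule)
    data.frame(subject = i, site = s$site, age_months = s$age,
               mean_wm_fa = mean_wm_fa(maps$fa, mask))
  })
  do.call(rbind, rows)
}
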
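## Acquisition gradient schemes: b-values + unit directions, FSL-style
## bvals/bvecs text I/O, shell bookkeeping, and the two desk-scale
## multi-shell protocols the synthetic cohorts emulate.

#' Construct a gradient scheme
#'
#' @param bvals numeric b-values in s/mm^2 (>= 0, at least one b = 0).
#' @param bvecs n x 3 matrix of unit gradient directions (the b = 0
#'   rows may be zero vectors, as in FSL convention).
#' @param shell_tol b-values within this tolerance (s/mm^2) belong to
#'   the same shell.
#' @return object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(bvals, bvecs, shell_tol = 50) {
  bvecs <- as.matrix(bvecs)
  if (length(bvals) != nrow(bvecs)) stop2("len(bvals) must equal nrow(bvecs)")
  if (any(bvals < 0)) stop2("b-values must be non-negative")
  if (!any(bvals <= shell_tol)) stop2("scheme needs at least one b = 0 entry")
  nz <- bvals > shell_tol
  if (any(nz)) {
    nrm <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6)) stop2("non-b0 gradient directions must be unit vectors")
  }
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs,
                 shell_tol = shell_tol),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  sh <- scheme_shells(x)
  cat("<gradient_scheme> ", length(x$bvals), " measurements; shells: ",
      paste0("b", round(sh$b), " (n=", sh$n, ")", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Shell table of a scheme
#'
#' @param scheme a [gradient_scheme()].
#' @return data.frame with nominal `b` per shell and direction count `n`.
#' @export
scheme_shells <- function(scheme) {
  cl <- round(scheme$bvals / (2 * scheme$shell_tol)) * 2 * scheme$shell_tol
  tb <- table(cl)
  data.frame(b = as.numeric(names(tb)), n = as.integer(tb))
}

#' Indices of the measurements on one shell
#'
#' @param scheme a [gradient_scheme()].
#' @param b nominal shell b-value (s/mm^2); `b = 0` selects the b0s.
#' @return integer vector of measurement indices.
#' @export
shell_indices <- function(scheme, b) {
  idx <- which(abs(scheme$bvals - b) <= scheme$shell_tol)
  if (!length(idx)) stop2("scheme has no b = ", b, " shell")
  idx
}

#' Indices of the b = 0 measurements
#' @param scheme a [gradient_scheme()].
#' @return integer vector.
#' @export
b0_indices <- function(scheme) which(scheme$bvals <= scheme$shell_tol)

## Evenly spread n directions on the upper hemisphere (golden spiral),
## rotated by a small deterministic twist per shell so different shells
## do not share directions.
hemisphere_dirs <- function(n, twist = 0) {
  i <- seq_len(n)
  z <- (i - 0.5) / n
  phi <- i * pi * (3 - sqrt(5)) + twist
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Desk-scale dHCP-like multi-shell scheme
#'
#' Shells b = {0, 400, 1000, 2600} s/mm^2 as in the neonatal protocol it
#' emulates, with direction counts scaled down for desk-scale phantoms
#' (defaults 2/20/48/48).
#'
#' @param n_b0,n400,n1000,n2600 measurements per shell.
#' @return a [gradient_scheme()].
#' @export
dhcp_scheme <- function(n_b0 = 2L, n400 = 20L, n1000 = 48L, n2600 = 48L) {
  bvals <- c(rep(0, n_b0), rep(400, n400), rep(1000, n1000), rep(2600, n2600))
  bvecs <- rbind(matrix(0, n_b0, 3),
                 hemisphere_dirs(n400, 0.1),
                 hemisphere_dirs(n1000, 0.7),
                 hemisphere_dirs(n2600, 1.3))
  gradient_scheme(bvals, bvecs)
}

#' Desk-scale BCP-like multi-shell scheme
#'
#' Shells b = {0, 500, 1000, 1500, 2000, 2500, 3000} s/mm^2 as in the
#' baby protocol it emulates (default 16 directions per shell).
#'
#' @param n_b0 number of b = 0 measurements.
#' @param n_per_shell directions per non-zero shell.
#' @return a [gradient_scheme()].
#' @export
bcp_scheme <- function(n_b0 = 2L, n_per_shell = 16L) {
  bs <- seq(500, 3000, by = 500)
  bvals <- c(rep(0, n_b0), rep(bs, each = n_per_shell))
  bvecs <- rbind(matrix(0, n_b0, 3),
                 do.call(rbind, lapply(seq_along(bs), function(i) {
                   hemisphere_dirs(n_per_shell, 0.37 * i)
                 })))
  gradient_scheme(bvals, bvecs)
}

#' Write a scheme as FSL-style bvals/bvecs text files
#'
#' `bvals` is one space-separated row; `bvecs` is three rows (x, y, z).
#'
#' @param scheme a [gradient_scheme()].
#' @param bvals_path,bvecs_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_bvals_bvecs <- function(scheme, bvals_path, bvecs_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bvals_path)
  writeLines(apply(t(scheme$bvecs), 1, function(r) {
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")
  }), bvecs_path)
  invisible(c(bvals_path, bvecs_path))
}

#' Read FSL-style bvals/bvecs text files into a gradient scheme
#'
#' @param bvals_path,bvecs_path input file paths.
#' @param shell_tol shell grouping tolerance (s/mm^2).
#' @return a [gradient_scheme()].
#' @export
read_bvals_bvecs <- function(bvals_path, bvecs_path, shell_tol = 50) {
  bvals <- scan(bvals_path, quiet = TRUE)
  rows <- lapply(readLines(bvecs_path), function(l) scan(text = l, quiet = TRUE))
  rows <- rows[vapply(rows, length, 1L) > 0]
  if (length(rows) != 3L) stop2("bvecs file must have three rows (x, y, z)")
  bvecs <- t(do.call(rbind, rows))
  gradient_scheme(bvals, bvecs, shell_tol = shell_tol)
}
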
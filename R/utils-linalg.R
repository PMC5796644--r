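# Small symmetric-matrix helpers shared by the inversion and BMR code.
# Conventions: all "covariance" matrices are symmetric; eigendecompositions
# use symmetric = TRUE; pseudo-inverses truncate at a relative tolerance.

.sym <- function(M) (M + t(M)) / 2

# vec/unvec in column-major order; the Kronecker projector algebra and the
# parameter packing both rely on this ordering.
.vec <- function(M) as.vector(M)
.unvec <- function(v, n) matrix(v, n, n)

# Log pseudo-determinant of a PSD matrix (sum of log positive eigenvalues).
.logdet_psd <- function(M, tol = 1e-12) {
  ev <- eigen(.sym(M), symmetric = TRUE, only.values = TRUE)$values
  sum(log(ev[ev > tol * max(ev, .Machine$double.eps)]))
}

# Inverse of a symmetric PSD matrix whose eigenvalues are first floored at
# `floor`: always defined, and a floored direction behaves as a variance of
# exactly `floor` (used by model reduction, where removal priors sit at the
# floor on purpose).
.inv_floored <- function(M, floor = 1e-8) {
  e <- eigen(.sym(M), symmetric = TRUE)
  vals <- pmax(e$values, floor)
  .sym(e$vectors %*% (t(e$vectors) / vals))
}

.is_square <- function(M) is.matrix(M) && nrow(M) == ncol(M)

.stop_if_not_square <- function(M, what = "matrix") {
  if (!.is_square(M) || !is.numeric(M) || anyNA(M) || any(!is.finite(M)))
    stop(what, " must be a square numeric matrix with finite entries",
         call. = FALSE)
  invisible(M)
}
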
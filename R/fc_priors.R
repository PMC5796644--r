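# Functional-connectivity-mode priors: SVD of the data, the Kronecker
# projector K_m over vec(A), rank-reduced prior covariance, and the
# free-energy sweep over the number of retained modes.

#' Functional-connectivity modes of a data matrix
#'
#' Singular value decomposition `Y = U S V'` of the (row-centered)
#' region-by-time matrix; the left singular vectors are the principal
#' spatial modes of functional connectivity.  Columns of `U` carry a
#' deterministic sign convention (the largest-magnitude loading is
#' positive).
#'
#' @param ts A [timeseries_data()] object with `n >= 2` regions.
#' @return Object of class `dcm_modes`: `U` (`n` x `n`, orthonormal),
#'   `values` (non-increasing singular values), `n`.
#' @export
functional_modes <- function(ts) {
  stopifnot(inherits(ts, "dcm_timeseries"))
  Y <- ts$Y - rowMeans(ts$Y)
  n <- nrow(Y)
  if (n < 2) stop("need at least 2 regions", call. = FALSE)
  if (max(abs(Y)) == 0) stop("degenerate (constant) data", call. = FALSE)
  sv <- svd(Y, nu = n)
  U <- sv$u
  for (j in seq_len(n)) {
    i_max <- which.max(abs(U[, j]))
    if (U[i_max, j] < 0) U[, j] <- -U[, j]
  }
  structure(list(U = U, values = sv$d[seq_len(n)], n = n),
            class = "dcm_modes")
}

#' Kronecker mode projector over vec(A)
#'
#' For `m` retained modes with orthonormal loadings `U_m`, the projector
#' \eqn{K_m = (U_m U_m^\top) \otimes (U_m U_m^\top)} maps vec(A)
#' (column-major) onto couplings *among modes* rather than among nodes.  It
#' is kept in factored form (the `n` x `n` node-space projector); use
#' `as.matrix()` to materialize the `n^2` x `n^2` matrix, which is
#' symmetric, idempotent and of rank `m^2`.  With `m = n` it is the
#' identity: effectively no prior constraint.
#'
#' @param modes A `dcm_modes` object, or an `n` x `m` matrix with
#'   orthonormal columns.
#' @param m Number of retained modes (when `modes` is a `dcm_modes`).
#' @return Object of class `dcm_projector` with fields `P`
#'   (`U_m U_m^\top`), `m`, `n`.
#' @export
mode_projector <- function(modes, m = NULL) {
  if (inherits(modes, "dcm_modes")) {
    if (is.null(m)) stop("supply the number of modes m", call. = FALSE)
    if (m < 1 || m > modes$n)
      stop("m must lie in [1, n]", call. = FALSE)
    Um <- modes$U[, seq_len(m), drop = FALSE]
  } else {
    Um <- as.matrix(modes)
    m <- ncol(Um)
  }
  if (max(abs(crossprod(Um) - diag(m))) > 1e-8)
    stop("mode loadings are not orthonormal", call. = FALSE)
  structure(list(P = tcrossprod(Um), m = m, n = nrow(Um)),
            class = "dcm_projector")
}

#' @export
as.matrix.dcm_projector <- function(x, ...) kronecker(x$P, x$P)

# Apply K_m = P (x) P to each column of an n^2 x k matrix without
# materializing K_m: a column c is reshaped to n x n, conjugated by P, and
# re-vectorized (column-major throughout).
.apply_kron_proj <- function(P, M) {
  n <- nrow(P)
  out <- M
  for (j in seq_len(ncol(M)))
    out[, j] <- .vec(P %*% .unvec(M[, j], n) %*% P)
  out
}

#' Rank-reduce a prior covariance onto functional modes
#'
#' Computes \eqn{\Sigma_m = K_m \Sigma K_m^\top} for a covariance over the
#' `n^2` coupling parameters (vec(A), column-major).  The result is
#' symmetric PSD with rank at most `m^2`; prior correlations between
#' couplings are generally nonzero for `m < n`, which is exactly how the
#' effective number of free parameters is reduced.  With `m = n` the
#' covariance is returned unchanged.
#'
#' @param Sigma `n^2` x `n^2` PSD covariance over vec(A).
#' @param projector A [mode_projector()].
#' @return The reduced covariance \eqn{\Sigma_m}.
#' @export
reduce_prior_covariance <- function(Sigma, projector) {
  stopifnot(inherits(projector, "dcm_projector"))
  n <- projector$n
  if (!.is_square(Sigma) || nrow(Sigma) != n * n)
    stop("Sigma must be ", n * n, " x ", n * n, call. = FALSE)
  if (projector$m == n) return(Sigma)
  .sym(.apply_kron_proj(projector$P,
                        t(.apply_kron_proj(projector$P, Sigma))))
}

#' Mode-reduce a full prior specification
#'
#' Applies [reduce_prior_covariance()] to the coupling (A) block of a
#' [prior_spec()]; fluctuation and hemodynamic blocks are untouched.  The
#' mode constraint concerns *extrinsic* (between-region) coupling, so the
#' intrinsic self-connection slots retain their own prior variance on top
#' of whatever the projector leaves them.
#'
#' @param prior A `dcm_prior`.
#' @param projector A [mode_projector()].
#' @return A `dcm_prior` with rank-reduced coupling covariance.
#' @export
reduce_prior <- function(prior, projector) {
  stopifnot(inherits(prior, "dcm_prior"))
  map <- prior$map
  iA <- map$A
  out <- prior
  out$cov[iA, iA] <- reduce_prior_covariance(prior$cov[iA, iA, drop = FALSE],
                                             projector)
  if (projector$m < map$n) {
    i_self <- map$A_diag
    out$cov[cbind(i_self, i_self)] <- out$cov[cbind(i_self, i_self)] +
      prior$cov[cbind(i_self, i_self)]
  }
  out
}

#' Free-energy sweep over the number of prior modes
#'
#' Scores, by Bayesian model reduction of a full (unconstrained-prior)
#' inversion, the model variants whose coupling prior covariance is
#' restricted to `m` functional-connectivity modes, for every `m` in
#' `m_grid`.  The `m = n` entry uses the full prior itself (the projector
#' is analytically the identity) and therefore has `dF = 0` exactly.  The
#' selected `m*` maximizes the reduced free energy, ties broken toward
#' smaller `m`; the curve is also reported relative to the `m = 1` entry.
#'
#' @param posterior A `dcm_posterior` from the full inversion.
#' @param modes A [functional_modes()] basis.
#' @param m_grid Mode counts to evaluate (default `1:n`).
#' @return Object of class `dcm_sweep`: `table` (data frame with `m`,
#'   `dF` relative to the full model, `F_rel` relative to `m = 1`),
#'   `m_star`.
#' @export
sweep_modes <- function(posterior, modes, m_grid = NULL) {
  stopifnot(inherits(posterior, "dcm_posterior"),
            inherits(modes, "dcm_modes"))
  n <- posterior$map$n
  if (modes$n != n) stop("mode basis does not match the model",
                         call. = FALSE)
  m_grid <- sort(unique(as.integer(m_grid %||% seq_len(n))))
  if (min(m_grid) < 1 || max(m_grid) > n)
    stop("m_grid must lie within [1, n]", call. = FALSE)
  prior <- posterior$prior
  dF <- vapply(m_grid, function(m) {
    rp <- reduce_prior(prior, mode_projector(modes, m))
    reduce_model(prior, posterior, rp)$dF
  }, numeric(1))
  F_rel <- if (1L %in% m_grid) dF - dF[match(1L, m_grid)] else
    dF - dF[1]
  m_star <- m_grid[which.max(dF)]
  structure(list(table = data.frame(m = m_grid, dF = dF, F_rel = F_rel),
                 m_star = m_star),
            class = "dcm_sweep")
}

#' @export
print.dcm_sweep <- function(x, ...) {
  cat("Functional-connectivity mode sweep: m* =", x$m_star, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write sweep results as CSV (+ JSON with the selected m)
#'
#' @param sweep A `dcm_sweep`.
#' @param path CSV path; a sibling `.json` carries `m_star`.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "dcm_sweep"))
  write.csv(sweep$table, path, row.names = FALSE)
  jsonlite::write_json(list(m_star = sweep$m_star),
                       sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
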
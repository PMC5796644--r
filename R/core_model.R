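# Core model: parameter space (coupling, fluctuation spectra, hemodynamics),
# packing/unpacking, and the neuronal-level linear-systems operations.

#' Fixed hemodynamic constants
#'
#' Constants of the balloon-Windkessel observation model that are held fixed
#' (identical) across regions.  Only the transit time and the ratio of
#' intra- to extravascular signal (`epsilon`) are estimated per region; both
#' are log-parameterized as deviations around the baselines given here.
#'
#' @return Named list: `kappa` signal decay rate (1/s), `gamma`
#'   autoregulatory feedback rate (1/s), `tau0` baseline venous transit time
#'   (s), `grubb` Grubb's vessel-stiffness exponent, `E0` resting oxygen
#'   extraction fraction, `TE` echo time (s), `V0` resting venous volume
#'   fraction (percent signal units), `nu0` and `r0` field-dependent output
#'   constants (1/s), `eps0` baseline intra/extravascular ratio.
#' @export
hemo_constants <- function() {
  list(kappa = 0.64, gamma = 0.32, tau0 = 2.0, grubb = 0.32, E0 = 0.4,
       TE = 0.04, V0 = 4, nu0 = 40.3, r0 = 25, eps0 = 1)
}

#' Model parameters (deviation scale)
#'
#' Creates the full parameter set of the spectral DCM in its estimation
#' (deviation) parameterization, zero-initialized at the prior mean.
#'
#' The coupling matrix `A` holds off-diagonal entries directly in Hz
#' (`A[i, j]` = influence of region `j` on region `i`), while diagonal
#' entries are *log-scaling* parameters of the intrinsic self-inhibition:
#' the effective self-connection is `-0.5 * exp(A[i, i])` Hz, negative by
#' construction.  Fluctuation and observation-noise amplitudes are
#' log-deviations around 1; the shared spectral exponents are additive
#' deviations around 1 (1/f fluctuations); hemodynamic transit time and
#' intra/extravascular ratio are log-deviations around the
#' [hemo_constants()] baselines.
#'
#' @param n Number of regions.
#' @param A `n` x `n` coupling parameter matrix (deviation scale, see above).
#' @param alpha_v,alpha_e Length-`n` log-amplitude deviations of neuronal
#'   fluctuations and observation noise.
#' @param beta_v,beta_e Scalar deviations of the shared spectral exponents.
#' @param transit,epsilon Length-`n` hemodynamic log-deviations.
#' @return An object of class `dcm_params`.
#' @seealso [pack_params()], [effective_connectivity()]
#' @export
dcm_params <- function(n,
                       A = matrix(0, n, n),
                       alpha_v = numeric(n), beta_v = 0,
                       alpha_e = numeric(n), beta_e = 0,
                       transit = numeric(n), epsilon = numeric(n)) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (!is.matrix(A) || any(dim(A) != n))
    stop("A must be an ", n, " x ", n, " matrix", call. = FALSE)
  for (nm in c("alpha_v", "alpha_e", "transit", "epsilon")) {
    v <- get(nm)
    if (length(v) != n)
      stop("component '", nm, "' has length ", length(v),
           ", expected ", n, call. = FALSE)
  }
  if (length(beta_v) != 1L || length(beta_e) != 1L)
    stop("component 'beta_v'/'beta_e' must be scalar", call. = FALSE)
  structure(list(n = n, A = A,
                 alpha_v = as.numeric(alpha_v), beta_v = as.numeric(beta_v),
                 alpha_e = as.numeric(alpha_e), beta_e = as.numeric(beta_e),
                 transit = as.numeric(transit),
                 epsilon = as.numeric(epsilon)),
            class = "dcm_params")
}

#' Index map of the packed parameter vector
#'
#' The packed vector is laid out as: `vec(A)` in column-major order (length
#' `n^2`), then `alpha_v` (`n`), `beta_v` (1), `alpha_e` (`n`), `beta_e` (1),
#' `transit` (`n`), `epsilon` (`n`).  The map records which slots belong to
#' the A block (and which of those are self-connections) -- needed by the
#' functional-connectivity priors and by edge pruning.
#'
#' @param n Number of regions.
#' @return List of integer index vectors with an element per block, plus
#'   `A_diag`/`A_offdiag` within the A block and the total length `d`.
#' @export
param_index_map <- function(n) {
  nA <- n * n
  diag_idx <- (seq_len(n) - 1L) * n + seq_len(n)  # column-major diagonal
  at <- nA
  blk <- function(len) {
    idx <- at + seq_len(len)
    at <<- at + len
    idx
  }
  map <- list(A = seq_len(nA),
              A_diag = diag_idx,
              A_offdiag = setdiff(seq_len(nA), diag_idx),
              alpha_v = blk(n), beta_v = blk(1L),
              alpha_e = blk(n), beta_e = blk(1L),
              transit = blk(n), epsilon = blk(n))
  map$d <- at
  map$n <- n
  map
}

#' Pack model parameters into a flat vector
#'
#' Bijective packing in the layout documented by [param_index_map()];
#' `unpack_params(pack_params(p), p$n)` recovers `p` exactly.
#'
#' @param p A [dcm_params()] object.
#' @return Numeric vector of length `param_index_map(n)$d`.
#' @export
pack_params <- function(p) {
  stopifnot(inherits(p, "dcm_params"))
  c(as.vector(p$A), p$alpha_v, p$beta_v, p$alpha_e, p$beta_e,
    p$transit, p$epsilon)
}

#' @rdname pack_params
#' @param theta Packed parameter vector.
#' @param n Number of regions.
#' @export
unpack_params <- function(theta, n) {
  map <- param_index_map(n)
  if (length(theta) != map$d)
    stop("parameter vector has length ", length(theta), ", expected ",
         map$d, " for n = ", n, call. = FALSE)
  dcm_params(n,
             A = matrix(theta[map$A], n, n),
             alpha_v = theta[map$alpha_v], beta_v = theta[map$beta_v],
             alpha_e = theta[map$alpha_e], beta_e = theta[map$beta_e],
             transit = theta[map$transit], epsilon = theta[map$epsilon])
}

#' Effective connectivity in natural units
#'
#' Maps the deviation-scale coupling parameters to the coupling matrix in Hz:
#' off-diagonal entries pass through unchanged, diagonal entries become
#' `-0.5 * exp(deviation)` so that self-connections are inhibitory by
#' construction.
#'
#' @param p A [dcm_params()] object (or a deviation-scale `A` matrix).
#' @return `n` x `n` coupling matrix in Hz.
#' @export
effective_connectivity <- function(p) {
  A <- if (inherits(p, "dcm_params")) p$A else p
  .stop_if_not_square(A, "A")
  diag(A) <- -0.5 * exp(diag(A))
  A
}

#' Natural-unit fluctuation and hemodynamic parameters
#'
#' @param p A [dcm_params()] object.
#' @return List with `alpha_v`, `beta_v`, `alpha_e`, `beta_e` (natural
#'   units), `transit` (s) and `epsilon` per region.
#' @export
natural_params <- function(p) {
  stopifnot(inherits(p, "dcm_params"))
  k <- hemo_constants()
  list(alpha_v = exp(p$alpha_v), beta_v = 1 + p$beta_v,
       alpha_e = exp(p$alpha_e), beta_e = 1 + p$beta_e,
       transit = k$tau0 * exp(p$transit), epsilon = k$eps0 * exp(p$epsilon))
}

#' Stability margin of a coupling matrix
#'
#' Largest real part among the eigenvalues of `A`; negative if and only if
#' the linear dynamics `dx/dt = A x` are asymptotically stable around the
#' fixed point.
#'
#' @param A Square coupling matrix (Hz).
#' @return Scalar stability margin (Hz).
#' @export
stability_margin <- function(A) {
  .stop_if_not_square(A, "A")
  max(Re(eigen(A, only.values = TRUE)$values))
}

#' Neuronal transfer function
#'
#' Frequency-domain solution of the linear state equation: the complex
#' matrix \eqn{(i\omega I - A)^{-1}} mapping endogenous fluctuations to
#' neuronal states at angular frequency `omega`.
#'
#' @param A Stable square coupling matrix (Hz).
#' @param omega Angular frequency (rad/s), strictly positive.
#' @return Complex `n` x `n` matrix.
#' @export
neural_transfer <- function(A, omega) {
  .stop_if_not_square(A, "A")
  if (length(omega) != 1L || omega <= 0)
    stop("omega must be a single positive angular frequency", call. = FALSE)
  n <- nrow(A)
  M <- diag(1i * omega, n) - A
  out <- tryCatch(solve(M), error = function(e)
    stop("(i*omega*I - A) is singular at omega = ", omega, call. = FALSE))
  out
}

#' Resting-state model specification
#'
#' Fixes the dimensions, frequency grid and repetition time of a model.  At
#' rest there are no exogenous inputs: `C` and `u` exist as fields but are
#' frozen at zero, and the inversion entry point rejects nonzero values.
#'
#' @param n Number of regions.
#' @param TR Repetition time in seconds.
#' @param band Analysis band in Hz (default 0.0078--0.1 Hz).
#' @param n_freq Number of linearly spaced frequency bins in the band.
#' @param C Exogenous input matrix; must be all zero for resting state.
#' @return Object of class `dcm_model_spec` with fields `n`, `TR`,
#'   `freq_hz`, `omega` (rad/s), `C`, `u`.
#' @export
model_spec <- function(n, TR = 2, band = c(0.0078, 0.1), n_freq = 32,
                       C = matrix(0, n, 1)) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("band must be strictly positive and increasing", call. = FALSE)
  freq_hz <- seq(band[1], band[2], length.out = n_freq)
  structure(list(n = n, TR = TR, freq_hz = freq_hz,
                 omega = 2 * pi * freq_hz, C = C, u = 0),
            class = "dcm_model_spec")
}
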
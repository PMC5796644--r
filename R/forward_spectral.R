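# Forward spectral model: deterministic mapping from parameters to predicted
# complex cross-spectral densities of the BOLD signal.
#
# Spectral convention used throughout the package: densities are two-sided,
# in units of a.u.^2/Hz, indexed by frequency f in Hz, with the power laws
# and transfer functions evaluated at angular frequency omega = 2*pi*f.

#' Cross-spectral density container
#'
#' @param G Complex array `n` x `n` x `n_freq`; Hermitian at each frequency.
#' @param freq_hz Frequency grid (Hz).
#' @param kind `"observed"` or `"predicted"`.
#' @param labels Optional region labels.
#' @return Object of class `dcm_csd`.
#' @export
new_csd <- function(G, freq_hz, kind = c("observed", "predicted"),
                    labels = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.array(G), length(dim(G)) == 3L, dim(G)[1] == dim(G)[2],
            dim(G)[3] == length(freq_hz))
  structure(list(G = G, freq_hz = freq_hz, kind = kind,
                 labels = labels %||% paste0("R", seq_len(dim(G)[1]))),
            class = "dcm_csd")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Power-law fluctuation spectrum
#'
#' Spectral density \eqn{g(\omega) = \alpha \, \omega^{-\beta}} evaluated at
#' `omega = 2*pi*freq_hz`; the parametric form of both the endogenous
#' neuronal fluctuations and the observation noise.
#'
#' @param alpha Amplitude, strictly positive (a.u.^2/Hz at omega = 1).
#' @param beta Spectral exponent (dimensionless); `beta = 0` is white.
#' @param freq_hz Strictly positive frequencies in Hz.
#' @return Vector of densities, one per frequency.
#' @export
fluctuation_spectrum <- function(alpha, beta, freq_hz) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a single strictly positive amplitude", call. = FALSE)
  if (!is.finite(beta)) stop("beta must be finite", call. = FALSE)
  if (any(freq_hz <= 0))
    stop("power-law spectrum undefined at non-positive frequency",
         call. = FALSE)
  alpha * (2 * pi * freq_hz)^(-beta)
}

# Jacobian of the balloon-Windkessel states (s, f, v, q) at the fixed point
# (0, 1, 1, 1), the input vector (neural activity enters ds/dt), and the
# BOLD output gradient. Used by both the linearized transfer function and
# the tests that compare against time-domain simulation.
.balloon_linearization <- function(transit, epsilon, k = hemo_constants()) {
  E0 <- k$E0
  k1 <- 4.3 * k$nu0 * E0 * k$TE
  k2 <- epsilon * k$r0 * E0 * k$TE
  k3 <- 1 - epsilon
  dEf <- 1 + (1 - E0) * log(1 - E0) / E0  # d[f E(f)/E0]/df at f = 1
  J <- matrix(c(
    -k$kappa, -k$gamma,              0,                    0,
     1,        0,                    0,                    0,
     0,        1 / transit,         -1 / (transit * k$grubb), 0,
     0,        dEf / transit,       -(1 / k$grubb - 1) / transit, -1 / transit
  ), 4, 4, byrow = TRUE)
  list(J = J,
       B = c(1, 0, 0, 0),
       C = c(0, 0, k$V0 * (k2 - k3), -k$V0 * (k1 + k2)))
}

#' Linearized hemodynamic transfer function
#'
#' First-order frequency response of the balloon-Windkessel observation
#' model around its resting fixed point: the complex gain from neuronal
#' activity to BOLD signal in each region.  The response is low-pass, with
#' `|B(omega)| -> 0` at high frequency.
#'
#' @param transit Per-region venous transit time(s) in seconds.
#' @param epsilon Per-region intra/extravascular signal ratio(s).
#' @param freq_hz Frequencies in Hz.
#' @param constants Fixed constants, see [hemo_constants()].
#' @return Complex matrix, regions x frequencies.
#' @export
hemodynamic_transfer <- function(transit, epsilon, freq_hz,
                                 constants = hemo_constants()) {
  if (any(transit <= 0)) stop("transit times must be positive", call. = FALSE)
  n <- length(transit)
  epsilon <- rep_len(epsilon, n)
  out <- matrix(0i, n, length(freq_hz))
  for (i in seq_len(n)) {
    lin <- .balloon_linearization(transit[i], epsilon[i], constants)
    for (kf in seq_along(freq_hz)) {
      w <- 2 * pi * freq_hz[kf]
      out[i, kf] <- sum(lin$C * solve(diag(1i * w, 4) - lin$J, lin$B))
    }
  }
  out
}

#' Predicted cross-spectral density
#'
#' The deterministic generative model of spectral DCM: with neuronal
#' transfer \eqn{T(\omega) = (i\omega I - A)^{-1}}, hemodynamic gains
#' \eqn{B(\omega)} and fluctuation/noise spectra \eqn{g_v, g_e}, the
#' predicted BOLD cross spectra are
#' \deqn{G_y(\omega) = H(\omega)\, G_v(\omega)\, H(\omega)^\dagger +
#'   G_e(\omega), \qquad H(\omega) = \mathrm{diag}(B(\omega))\,T(\omega),}
#' with diagonal \eqn{G_v} (independent per-region fluctuations) and
#' diagonal \eqn{G_e}.
#'
#' @param p A [dcm_params()] object (deviation scale).
#' @param spec A [model_spec()].
#' @param include_noise Include the observation-noise spectrum `G_e`
#'   (default `TRUE`).
#' @param unit_gain Replace the hemodynamic gain by 1 (used by analytic
#'   oracles; default `FALSE`).
#' @return A `dcm_csd` of kind `"predicted"`; Hermitian and positive
#'   semidefinite at every frequency.
#' @export
predict_csd <- function(p, spec, include_noise = TRUE, unit_gain = FALSE) {
  stopifnot(inherits(p, "dcm_params"), inherits(spec, "dcm_model_spec"))
  if (p$n != spec$n) stop("parameter/model dimension mismatch", call. = FALSE)
  A <- effective_connectivity(p)
  if (stability_margin(A) >= 0)
    stop("coupling matrix is unstable; deepen self-inhibition before ",
         "predicting spectra", call. = FALSE)
  np <- natural_params(p)
  n <- p$n
  nf <- length(spec$freq_hz)
  gv <- vapply(seq_len(n), function(i)
    fluctuation_spectrum(np$alpha_v[i], np$beta_v, spec$freq_hz),
    numeric(nf))                       # nf x n
  Bw <- if (unit_gain) matrix(1 + 0i, n, nf) else
    hemodynamic_transfer(np$transit, np$epsilon, spec$freq_hz)
  G <- array(0i, c(n, n, nf))
  for (kf in seq_len(nf)) {
    Tw <- neural_transfer(A, spec$omega[kf])
    H <- Bw[, kf] * Tw                 # diag(B) %*% T
    Gk <- H %*% (gv[kf, ] * Conj(t(H)))
    Gk <- (Gk + Conj(t(Gk))) / 2       # enforce exact Hermitian symmetry
    G[, , kf] <- Gk
  }
  if (include_noise) {
    ge <- vapply(seq_len(n), function(i)
      fluctuation_spectrum(np$alpha_e[i], np$beta_e, spec$freq_hz),
      numeric(nf))
    for (kf in seq_len(nf)) for (i in seq_len(n))
      G[i, i, kf] <- G[i, i, kf] + ge[kf, i]
  }
  new_csd(G, spec$freq_hz, "predicted")
}

#' Serialize / read cross spectra as columnar CSV
#'
#' Plain-text dump with columns `freq`, `i`, `j`, `re`, `im`, one row per
#' (frequency, region pair); all `n^2` pairs are written so the file
#' round-trips bit-exactly through `read_csd()`.
#'
#' @param csd A `dcm_csd` object.
#' @param path Output CSV path.
#' @export
write_csd <- function(csd, path) {
  stopifnot(inherits(csd, "dcm_csd"))
  n <- dim(csd$G)[1]
  grid <- expand.grid(i = seq_len(n), j = seq_len(n),
                      k = seq_along(csd$freq_hz))
  # %.17g round-trips IEEE doubles exactly
  df <- data.frame(freq = sprintf("%.17g", csd$freq_hz[grid$k]),
                   i = grid$i, j = grid$j,
                   re = sprintf("%.17g",
                                Re(csd$G[cbind(grid$i, grid$j, grid$k)])),
                   im = sprintf("%.17g",
                                Im(csd$G[cbind(grid$i, grid$j, grid$k)])))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_csd
#' @param kind Kind tag to attach on reading.
#' @export
read_csd <- function(path, kind = "observed") {
  df <- read.csv(path)
  freq <- sort(unique(df$freq))
  n <- max(df$i)
  G <- array(0i, c(n, n, length(freq)))
  k <- match(df$freq, freq)
  G[cbind(df$i, df$j, k)] <- complex(real = df$re, imaginary = df$im)
  new_csd(G, freq, kind)
}
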
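# Ground-truth simulator: stable random coupling matrices, spectrally
# shaped endogenous fluctuations, Euler integration of the neural states,
# nonlinear balloon hemodynamics, downsampling to TR and observation noise.

#' Sample a ground-truth model
#'
#' Draws a random directed coupling matrix with the requested edge density:
#' off-diagonal support is sampled uniformly (`round(density * n * (n-1))`
#' edges), weights get random signs with magnitudes uniform in
#' `[0.5, 1.5] * coupling_scale`, and the diagonal starts at -0.5 Hz.  If
#' the resulting system is unstable the self-inhibition is deepened
#' (diagonal scaled by 1.25) until the stability margin is below -0.05 Hz.
#'
#' Observation-noise amplitudes are set relative to the predicted signal
#' spectra: `alpha_e` is chosen so the noise density at the band center
#' equals `noise_frac` times each region's mean auto-spectral power, fixing
#' the signal-to-noise regime rather than an absolute scale.
#'
#' @param n Number of regions (>= 2).
#' @param density Off-diagonal edge density in (0, 1]; ignored when `rank`
#'   is given.
#' @param rank Optional mode rank: instead of sparse support, the coupling
#'   deviation is built as `U W U'` with a random `n` x `rank` orthonormal
#'   basis `U` and random couplings `W` among those modes, rescaled so the
#'   root-mean-square off-diagonal coupling equals `coupling_scale`.  Used
#'   to emulate networks whose effective connectivity lives on a few
#'   functional modes.
#' @param coupling_scale Typical coupling magnitude (Hz).
#' @param seed Integer seed (recorded in the output).
#' @param alpha_v Per-region fluctuation amplitude (a.u.), or `NULL`
#'   (default) to calibrate the amplitudes so every region's in-band BOLD
#'   fluctuation has standard deviation `bold_sd` under the linearized
#'   model.
#' @param bold_sd Target in-band BOLD fluctuation (percent signal units,
#'   default 0.75) -- on the order of resting-state gray-matter
#'   fluctuations, and comfortably within the regime where the hemodynamic
#'   linearization holds.
#' @param beta_v,beta_e Spectral exponents (default 1, scale-free).
#' @param noise_frac Observation-noise density at band center as a fraction
#'   of signal auto-spectral power (default 0.1).
#' @param band Analysis band used to calibrate the noise (Hz).
#' @return Object of class `dcm_ground_truth`: fields `params`
#'   ([dcm_params()] at the true values), `A` (Hz), `mask` (true
#'   off-diagonal support), `n`, `seed`, and the call arguments.
#' @export
make_ground_truth <- function(n, density = 0.4, coupling_scale = 0.25,
                              seed = 1, rank = NULL, alpha_v = NULL,
                              beta_v = 1, beta_e = 1, noise_frac = 0.1,
                              bold_sd = 0.75, band = c(0.0078, 0.1)) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (density < 0 || density > 1)
    stop("density must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  off <- which(row(diag(n)) != col(diag(n)))
  if (is.null(rank)) {
    n_edges <- round(density * length(off))
    support <- sort(sample(off, n_edges))
    A <- matrix(0, n, n)
    if (n_edges > 0)
      A[support] <- sample(c(-1, 1), n_edges, replace = TRUE) *
        runif(n_edges, 0.5, 1.5) * coupling_scale
  } else {
    if (rank < 1 || rank > n) stop("rank must lie in [1, n]", call. = FALSE)
    # coupling among a few modes, the way large-scale networks are
    # organized: net-excitatory (symmetric positive definite) within-mode
    # coupling, which amplifies variance along the mode span so the modes
    # are visible to functional connectivity, plus an antisymmetric
    # (directed) part
    U <- qr.Q(qr(matrix(rnorm(n * rank), n, rank)))
    Q <- qr.Q(qr(matrix(rnorm(rank * rank), rank, rank)))
    S <- Q %*% (runif(rank, 0.8, 1.2) * 1.4 * coupling_scale * t(Q))
    K <- matrix(rnorm(rank * rank, 0, 0.6 * coupling_scale), rank, rank)
    A <- U %*% (S + (K - t(K)) / 2) %*% t(U)
    support <- off[A[off] != 0]
  }
  diag(A) <- -0.5
  for (iter in seq_len(64)) {
    if (stability_margin(A) < -0.05) break
    diag(A) <- diag(A) * 1.25
  }
  if (stability_margin(A) >= -0.05)
    stop("could not stabilize coupling matrix; reduce coupling_scale",
         call. = FALSE)
  mask <- matrix(FALSE, n, n)
  mask[support] <- TRUE
  # deviation-scale parameters reproducing A exactly
  A_dev <- A
  diag(A_dev) <- log(diag(A) / -0.5)
  p <- dcm_params(n, A = A_dev, beta_v = beta_v - 1, beta_e = beta_e - 1)
  spec <- model_spec(n, band = band)
  if (is.null(alpha_v)) {
    # calibrate fluctuation amplitudes so the in-band BOLD fluctuation has
    # standard deviation `bold_sd` (percent signal units) under the
    # linearized model, whatever the network's stability margin.  Sparse
    # networks are calibrated per region; mode-rank networks share one
    # amplitude, since per-region rescaling would distort the very mode
    # geometry they are built from.
    p$alpha_v <- numeric(n)
    G1 <- predict_csd(p, spec, include_noise = FALSE)
    df <- diff(spec$freq_hz[1:2])
    var1 <- vapply(seq_len(n), function(i)
      2 * sum(Re(G1$G[i, i, ])) * df, numeric(1))
    p$alpha_v <- if (is.null(rank)) log(bold_sd^2 / var1) else
      rep(log(bold_sd^2 / mean(var1)), n)
  } else {
    p$alpha_v <- log(rep_len(alpha_v, n))
  }
  # calibrate observation noise to the signal spectra
  Gs <- predict_csd(p, spec, include_noise = FALSE)
  pow <- vapply(seq_len(n), function(i) mean(Re(Gs$G[i, i, ])), numeric(1))
  f_mid <- mean(band)
  p$alpha_e <- log(noise_frac * pow * (2 * pi * f_mid)^beta_e)
  structure(list(params = p, A = A, mask = mask, n = n, seed = seed,
                 density = density, rank = rank,
                 coupling_scale = coupling_scale,
                 noise_frac = noise_frac, bold_sd = bold_sd, band = band),
            class = "dcm_ground_truth")
}

#' Sample a power-law time series by spectral factorization
#'
#' Shapes the FFT of white Gaussian noise by the square root of the target
#' two-sided density \eqn{\alpha(2\pi f)^{-\beta}}, so the realized
#' periodogram matches the target in expectation.  Frequencies below
#' `floor_hz` are clamped to the floor density, which keeps
#' non-integrable low-frequency divergences (large `beta`) finite.
#'
#' @param alpha Amplitude (> 0); `alpha = 0` returns a zero series.
#' @param beta Spectral exponent.
#' @param n_samples Series length.
#' @param dt Sampling interval (s).
#' @param seed Optional integer seed.
#' @param floor_hz Low-frequency floor (Hz, default 0.001).
#' @return Real time series of length `n_samples`.
#' @export
sample_fluctuations <- function(alpha, beta, n_samples, dt, seed = NULL,
                                floor_hz = 1e-3) {
  if (!is.null(seed)) set.seed(seed)
  if (alpha == 0) return(numeric(n_samples))
  N <- n_samples
  f <- seq_len(N - 1) / (N * dt)
  f <- pmin(f, 1 / dt - f)            # fold to physical frequency
  S <- fluctuation_spectrum(alpha, beta, pmax(f, floor_hz))
  amp <- sqrt(S * N / dt)
  half <- seq_len(floor((N - 1) / 2))
  X <- complex(length.out = N)
  z <- complex(real = rnorm(length(half)), imaginary = rnorm(length(half))) /
    sqrt(2)
  X[1 + half] <- amp[half] * z
  X[1 + (N - half)] <- Conj(X[1 + half])
  if (N %% 2 == 0) X[1 + N / 2] <- amp[N / 2] * rnorm(1)
  Re(fft(X, inverse = TRUE)) / N
}

# Matrix exponential by scaling-and-squaring of a Taylor series; adequate
# for the small coupling matrices handled here.
.expm_small <- function(M, order = 12) {
  nrm <- max(abs(M))
  s <- max(0L, ceiling(log2(max(nrm, 1e-16))) + 1L)
  Ms <- M / 2^s
  E <- diag(nrow(M))
  term <- diag(nrow(M))
  for (k in seq_len(order)) {
    term <- term %*% Ms / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

# Pure-R integrator for the nonlinear balloon model, all regions at once:
# classical RK4 with the neural input held constant over each step.  Flow,
# volume and deoxyhemoglobin are integrated in log space (positivity by
# construction, the convention of the hemodynamic-modeling literature); the
# vasodilatory signal s stays in natural units.  Returns the n x N BOLD
# fluctuation around baseline.  simulate_bold() uses the compiled
# equivalent (.balloon_rk4); this version is retained as the independent
# reference implementation for the tests.
.balloon_integrate <- function(x, dt, transit, epsilon,
                               k = hemo_constants(), substeps = 5L) {
  E0 <- k$E0
  k1 <- 4.3 * k$nu0 * E0 * k$TE
  k2 <- epsilon * k$r0 * E0 * k$TE
  k3 <- 1 - epsilon
  n <- nrow(x)
  N <- ncol(x)
  inv_grubb <- 1 / k$grubb
  deriv <- function(st, u) {
    s <- st[[1]]
    # floors keep the classic balloon equations defined under extreme
    # excursions (flow -> 0 is a boundary of the model, far from the
    # calibrated operating regime)
    f <- pmax(exp(st[[2]]), 0.05)
    v <- pmax(exp(st[[3]]), 0.05)
    q <- pmax(exp(st[[4]]), 0.05)
    fv <- v^inv_grubb
    Ef <- (1 - (1 - E0)^(1 / f)) / E0
    list(u - k$kappa * s - k$gamma * (f - 1),
         s / f,
         (f - fv) / (transit * v),
         (f * Ef - fv * q / v) / (transit * q))
  }
  st <- list(numeric(n), numeric(n), numeric(n), numeric(n))
  y <- matrix(0, n, N)
  h <- dt / substeps                  # sub-stepping tames the stiffness of
  for (t in seq_len(N)) {             # the log-flow equation when f is low
    u <- x[, t]
    for (ss in seq_len(substeps)) {
      d1 <- deriv(st, u)
      d2 <- deriv(Map(function(a, b) a + h / 2 * b, st, d1), u)
      d3 <- deriv(Map(function(a, b) a + h / 2 * b, st, d2), u)
      d4 <- deriv(Map(function(a, b) a + h * b, st, d3), u)
      st <- Map(function(a, b1, b2, b3, b4)
        a + h / 6 * (b1 + 2 * b2 + 2 * b3 + b4), st, d1, d2, d3, d4)
    }
    if (any(!vapply(st, function(z) all(is.finite(z)), logical(1))))
      stop("hemodynamic integration blew up at step ", t, call. = FALSE)
    v_t <- exp(st[[3]]); q_t <- exp(st[[4]])
    y[, t] <- k$V0 * (k1 * (1 - q_t) + k2 * (1 - q_t / v_t) +
                        k3 * (1 - v_t))
  }
  y
}

#' Simulate BOLD time series from a ground-truth model
#'
#' Integrates the neural states \eqn{\dot x = A x + v(t)} at fine
#' resolution `dt` by exact zero-order-hold stepping (matrix exponential;
#' the endogenous fluctuations, synthesized by [sample_fluctuations()], are
#' held constant within each step), passes them through the nonlinear
#' balloon-model hemodynamics (RK4), downsamples to `TR` by zero-order
#' hold, and adds observation noise with spectrum \eqn{g_e} at TR
#' resolution.  Bit-identical under a fixed seed.
#'
#' @param gt A [make_ground_truth()] object.
#' @param duration Scan duration in seconds (after the burn-in).
#' @param TR Repetition time (s); must be a multiple of `dt`.
#' @param seed Integer seed.
#' @param obs_noise Add observation noise (default `TRUE`).
#' @param dt Integration step (s, default 0.1).
#' @param burn_in Discarded initial period (s, default 32).
#' @return A [timeseries_data()] object (`n` regions x `duration/TR`
#'   volumes).
#' @export
simulate_bold <- function(gt, duration, TR = 2, seed = 1, obs_noise = TRUE,
                          dt = 0.1, burn_in = 32) {
  stopifnot(inherits(gt, "dcm_ground_truth"))
  if (abs(TR / dt - round(TR / dt)) > 1e-9)
    stop("TR must be an integer multiple of dt", call. = FALSE)
  n <- gt$n
  np <- natural_params(gt$params)
  A <- gt$A
  if (stability_margin(A) >= 0) stop("unstable ground truth", call. = FALSE)
  N_burn <- round(burn_in / dt)
  N <- round(duration / dt) + N_burn
  set.seed(seed)
  v <- vapply(seq_len(n), function(i)
    sample_fluctuations(np$alpha_v[i], np$beta_v, N, dt), numeric(N))
  Ed <- .expm_small(A * dt)
  Bd <- solve(A, Ed - diag(n))          # ZOH input matrix
  x <- .neural_zoh(Ed, Bd, v)
  y <- .balloon_rk4(x, dt, np$transit, np$epsilon, hemo_constants(), 5L)
  keep <- seq(N_burn + 1L, N, by = round(TR / dt))
  Yb <- y[, keep, drop = FALSE]
  if (obs_noise) {
    noise <- vapply(seq_len(n), function(i)
      sample_fluctuations(np$alpha_e[i], np$beta_e, length(keep), TR),
      numeric(length(keep)))
    Yb <- Yb + t(noise)
  }
  timeseries_data(Yb, TR = TR)
}

#' Write / read a ground truth as JSON (exact rerun provenance)
#'
#' @param gt A `dcm_ground_truth` object.
#' @param path JSON path.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "dcm_ground_truth"))
  out <- list(n = gt$n, seed = gt$seed, density = gt$density,
              rank = gt$rank, coupling_scale = gt$coupling_scale,
              noise_frac = gt$noise_frac, bold_sd = gt$bold_sd,
              band = gt$band, A = gt$A, mask = gt$mask * 1L,
              theta = pack_params(gt$params))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- x$n
  if (!length(x$rank)) x$rank <- NULL   # NULL serializes as {}
  stored <- structure(
    list(params = unpack_params(x$theta, n),
         A = matrix(x$A, n, n), mask = matrix(x$mask == 1, n, n),
         n = n, seed = x$seed, density = x$density,
         rank = x$rank, coupling_scale = x$coupling_scale,
         noise_frac = x$noise_frac, bold_sd = x$bold_sd, band = x$band),
    class = "dcm_ground_truth")
  # regenerate from the recorded arguments: when it matches the stored
  # values (it does unless the truth was edited by hand), return the
  # regenerated object, which is exact to the last bit
  regen <- tryCatch(
    make_ground_truth(n, density = x$density, rank = x$rank,
                      coupling_scale = x$coupling_scale, seed = x$seed,
                      noise_frac = x$noise_frac, bold_sd = x$bold_sd,
                      band = x$band),
    error = function(e) NULL)
  if (!is.null(regen) &&
      max(abs(pack_params(regen$params) - pack_params(stored$params)),
          na.rm = TRUE) < 1e-9)
    return(regen)
  stored
}
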
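# Variational-Laplace inversion of the spectral generative model:
# Gauss-Newton ascent on the free energy with Levenberg regularization and
# step-halving, EM-style updates of the log noise precisions, and a Gaussian
# posterior over the packed parameter vector.

#' Prior specification over the packed parameter vector
#'
#' Shrinkage priors in the deviation parameterization: off-diagonal coupling
#' entries N(0, 1/64), self-connection log-scalings N(0, 1/256),
#' fluctuation and noise log-amplitudes/exponents N(0, 1/64), hemodynamic
#' log-deviations N(0, 1/256).  All variances are exposed as arguments.
#' The hyperprior on the log noise precision(s) is Gaussian with the stated
#' mean and variance; a mean of `NA` (the default) centers it empirically at
#' the precision implied by the prior-mean prediction error during
#' inversion.
#'
#' @param n Number of regions.
#' @param v_a,v_self,v_fluct,v_hemo Prior variances per block.
#' @param lambda_mean,lambda_var Hyperprior on log precision.
#' @return Object of class `dcm_prior`: fields `mean`, `cov` (diagonal
#'   unless reduced), `map`, `hyper`.
#' @export
prior_spec <- function(n, v_a = 1 / 64, v_self = 1 / 256,
                       v_fluct = 1 / 64, v_hemo = 1 / 256,
                       lambda_mean = NA, lambda_var = 16) {
  map <- param_index_map(n)
  v <- numeric(map$d)
  v[map$A_offdiag] <- v_a
  v[map$A_diag] <- v_self
  v[c(map$alpha_v, map$beta_v, map$alpha_e, map$beta_e)] <- v_fluct
  v[c(map$transit, map$epsilon)] <- v_hemo
  structure(list(mean = numeric(map$d), cov = diag(v), map = map,
                 hyper = list(mean = lambda_mean, var = lambda_var)),
            class = "dcm_prior")
}

#' Pack complex cross spectra into a real feature vector
#'
#' Frequency-major concatenation of the real parts of the upper triangle
#' (including the diagonal) and the imaginary parts of the strict upper
#' triangle -- `n^2` real numbers per frequency, lossless for Hermitian
#' arrays (`unpack_features()` is the exact inverse).
#'
#' @param csd A `dcm_csd` object.
#' @param tol Maximum tolerated Hermitian asymmetry.
#' @return Numeric vector of length `n^2 * n_freq`.
#' @export
pack_features <- function(csd, tol = 1e-6) {
  stopifnot(inherits(csd, "dcm_csd"))
  G <- csd$G
  n <- dim(G)[1]
  scale <- max(abs(G), 1e-12)
  for (k in seq_len(dim(G)[3]))
    if (max(abs(G[, , k] - Conj(t(G[, , k])))) > tol * scale)
      stop("cross spectra are not Hermitian within tolerance", call. = FALSE)
  iu <- which(upper.tri(diag(n), diag = TRUE))
  iu2 <- which(upper.tri(diag(n)))
  unlist(lapply(seq_len(dim(G)[3]), function(k)
    c(Re(G[, , k][iu]), Im(G[, , k][iu2]))))
}

#' @rdname pack_features
#' @param y Packed feature vector.
#' @param n Number of regions.
#' @param freq_hz Frequency grid of the original array.
#' @export
unpack_features <- function(y, n, freq_hz) {
  nf <- length(freq_hz)
  per <- n * n
  stopifnot(length(y) == per * nf)
  iu <- which(upper.tri(diag(n), diag = TRUE))
  iu2 <- which(upper.tri(diag(n)))
  G <- array(0i, c(n, n, nf))
  for (k in seq_len(nf)) {
    seg <- y[(k - 1) * per + seq_len(per)]
    M <- matrix(0i, n, n)
    M[iu] <- seg[seq_along(iu)]
    M[iu2] <- M[iu2] + 1i * seg[length(iu) + seq_along(iu2)]
    Mfull <- M + Conj(t(M))
    diag(Mfull) <- Re(diag(M))
    G[, , k] <- Mfull
  }
  new_csd(G, freq_hz, "observed")
}

# Gaussian KL divergence KL(N(mu, S) || N(0, diag(D))) in the prior
# eigenbasis (c-space).
.kl_gauss_c <- function(mu_c, S_c, D) {
  ld_S <- determinant(S_c, logarithm = TRUE)$modulus
  0.5 * (sum(diag(S_c) / D) + sum(mu_c^2 / D) - length(D) +
           sum(log(D)) - as.numeric(ld_S))
}

# Per-precision-band sufficient statistics of a (residual, Jacobian) pair:
# everything the free energy needs, so that precision line searches do not
# re-touch the feature-length arrays.
.vl_parts <- function(e, J, band_idx, n_bands) {
  H_b <- vector("list", n_bands)
  g_b <- matrix(0, ncol(J), n_bands)
  sse <- numeric(n_bands)
  N_b <- numeric(n_bands)
  for (b in seq_len(n_bands)) {
    sel <- band_idx == b
    Jb <- J[sel, , drop = FALSE]
    H_b[[b]] <- crossprod(Jb)
    g_b[, b] <- crossprod(Jb, e[sel])
    sse[b] <- sum(e[sel]^2)
    N_b[b] <- sum(sel)
  }
  list(H_b = H_b, g_b = g_b, sse = sse, N_b = N_b)
}

# Full variational free energy at a point in c-space, from precomputed
# band statistics.  Components per the Laplace assumption: Gaussian
# log-likelihood of the residuals, minus KL(posterior || prior) over
# parameters, minus the KL penalty on the log precisions.
.vl_free_energy <- function(parts, c_cur, D, lambda, hyper) {
  wb <- exp(lambda)
  k <- length(D)
  H <- matrix(0, k, k)
  for (b in seq_along(wb)) H <- H + wb[b] * parts$H_b[[b]]
  Pp <- H + diag(1 / D, k)
  S_c <- tryCatch(chol2inv(chol(Pp)), error = function(err) NULL)
  if (is.null(S_c)) return(NULL)
  Fv <- -0.5 * sum(wb * parts$sse) + 0.5 * sum(parts$N_b * lambda) -
    0.5 * sum(parts$N_b) * log(2 * pi) -
    .kl_gauss_c(c_cur, S_c, D) -
    0.5 * sum((lambda - hyper$mean)^2 / hyper$var)
  list(F = Fv, S_c = S_c, H = H,
       grad = drop(parts$g_b %*% wb) - c_cur / D)
}

#' Variational free energy of a parameter point
#'
#' Evaluates the variational Laplace objective
#' \eqn{F = \langle \log p(y|\theta) \rangle_q - KL(q \| p)} for observed
#' spectral features, a parameter point (taken as the posterior mean), a
#' prior, and log noise precisions.  With a posterior equal to the prior the
#' complexity term vanishes; with zero prediction error the remaining terms
#' are the Gaussian log-normalization alone.
#'
#' @param observed Observed feature vector (see [pack_features()]).
#' @param params A [dcm_params()] point.
#' @param spec A [model_spec()].
#' @param prior A [prior_spec()] object.
#' @param log_precision Log noise precision (scalar).
#' @param posterior_cov Optional posterior covariance in parameter space;
#'   defaults to the prior covariance (posterior = prior).
#' @return Scalar free energy in nats.
#' @export
free_energy <- function(observed, params, spec, prior, log_precision,
                        posterior_cov = NULL) {
  stopifnot(inherits(prior, "dcm_prior"))
  theta <- pack_params(params)
  pred <- pack_features(predict_csd(params, spec))
  if (length(pred) != length(observed))
    stop("observed features do not match the model's grid", call. = FALSE)
  e <- observed - pred
  N <- length(e)
  w <- exp(log_precision)
  eg <- eigen(.sym(prior$cov), symmetric = TRUE)
  keep <- eg$values > 1e-8 * max(eg$values)
  V <- eg$vectors[, keep, drop = FALSE]
  D <- eg$values[keep]
  mu_c <- drop(t(V) %*% (theta - prior$mean))
  S_c <- if (is.null(posterior_cov)) diag(D, length(D)) else
    .sym(t(V) %*% posterior_cov %*% V)
  -0.5 * w * sum(e^2) + 0.5 * N * log_precision - 0.5 * N * log(2 * pi) -
    .kl_gauss_c(mu_c, S_c, D)
}

# Forward finite-difference Jacobian of the prediction in c-space.
.fd_jacobian <- function(g_fun, c_cur, g0, h = 1e-3) {
  k <- length(c_cur)
  J <- matrix(0, length(g0), k)
  for (j in seq_len(k)) {
    cp <- c_cur
    cp[j] <- cp[j] + h
    gp <- g_fun(cp)
    if (is.null(gp)) {
      cp[j] <- c_cur[j] - h
      gm <- g_fun(cp)
      if (is.null(gm)) next
      J[, j] <- (g0 - gm) / h
    } else {
      J[, j] <- (gp - g0) / h
    }
  }
  J
}

#' Invert a spectral DCM
#'
#' Fits the generative model to observed cross spectra by Gauss-Newton
#' ascent on the variational free energy.  Steps are Levenberg-regularized
#' and only accepted when they do not decrease `F`, so the free-energy trace
#' over accepted iterations is non-decreasing by construction; the log noise
#' precision is updated between parameter steps (also under the
#' no-decrease rule).  Convergence: `dF < tol` for `patience` consecutive
#' iterations, or the iteration cap.
#'
#' Rank-deficient prior covariances (e.g. after functional-connectivity mode
#' reduction) are handled by estimating coefficients in the column space of
#' the prior covariance (eigen-truncation at relative 1e-8).
#'
#' Because the amplitude priors are tight, the observed spectra are first
#' rescaled so their mean auto-spectral power matches the prior-mean
#' prediction; the factor is returned as `$scale` (coupling estimates are
#' unaffected).
#'
#' @param csd_obs Observed `dcm_csd` on the model's frequency grid.
#' @param spec A [model_spec()]; must have `C = 0` (resting state).
#' @param prior A [prior_spec()] (possibly mode-reduced); default priors
#'   are used when `NULL`.
#' @param control List of optimizer settings: `max_iter` (128), `tol`
#'   (0.01 nats), `patience` (3), `h` (FD step 1e-3), `verbose`.
#' @return Object of class `dcm_posterior`: `mu`, `Sigma` (parameter
#'   space), `F`, `trace` (accepted free energies), `lambda`, `converged`,
#'   `iterations`, `scale`, plus the `prior`, `spec` and index `map`.
#' @export
invert <- function(csd_obs, spec, prior = NULL, control = list()) {
  stopifnot(inherits(csd_obs, "dcm_csd"), inherits(spec, "dcm_model_spec"))
  if (any(spec$C != 0))
    stop("resting-state inversion requires C = 0 (no exogenous inputs)",
         call. = FALSE)
  if (length(csd_obs$freq_hz) != length(spec$freq_hz) ||
      max(abs(csd_obs$freq_hz - spec$freq_hz)) > 1e-9)
    stop("observed spectra are not on the model's frequency grid",
         call. = FALSE)
  ctl <- modifyList(list(max_iter = 128, tol = 0.01, patience = 3,
                         h = 1e-3, n_bands = 8, verbose = FALSE), control)
  n <- spec$n
  prior <- prior %||% prior_spec(n)
  map <- prior$map

  # rescale data to the scale of the prior-mean prediction
  pred0 <- predict_csd(unpack_params(prior$mean, n), spec)
  auto_obs <- mean(vapply(seq_len(n), function(i)
    mean(Re(csd_obs$G[i, i, ])), numeric(1)))
  auto_mod <- mean(vapply(seq_len(n), function(i)
    mean(Re(pred0$G[i, i, ])), numeric(1)))
  if (auto_obs <= 0) stop("degenerate observed spectra", call. = FALSE)
  scale <- auto_mod / auto_obs
  y <- pack_features(csd_obs) * scale
  N <- length(y)
  # noise-precision components: the frequency grid is split into
  # `n_bands` contiguous bands, each with its own log precision, because
  # residual magnitudes vary strongly over a power-law band
  nf <- length(spec$freq_hz)
  n_bands <- max(1L, min(ctl$n_bands, nf))
  band_of_freq <- ceiling(seq_len(nf) / nf * n_bands)
  band_idx <- rep(band_of_freq, each = n * n)

  # prior eigenbasis (c-space)
  eg <- eigen(.sym(prior$cov), symmetric = TRUE)
  keep <- eg$values > 1e-8 * max(eg$values)
  V <- eg$vectors[, keep, drop = FALSE]
  D <- eg$values[keep]
  k <- length(D)

  g_fun <- function(c_cur) {
    theta <- prior$mean + drop(V %*% c_cur)
    tryCatch(pack_features(predict_csd(unpack_params(theta, n), spec)),
             error = function(e) NULL)
  }

  c_cur <- numeric(k)
  g0 <- g_fun(c_cur)
  if (is.null(g0))
    stop("prediction failed at the prior mean", call. = FALSE)
  e <- y - g0
  hyper <- prior$hyper
  if (anyNA(hyper$mean))
    hyper$mean <- vapply(seq_len(n_bands), function(b) {
      eb <- e[band_idx == b]
      # capped so an exact fit at the prior mean stays finite
      min(log(length(eb) / max(sum(eb^2), 1e-300)), 32)
    }, numeric(1))
  hyper$mean <- rep_len(hyper$mean, n_bands)
  hyper$var <- rep_len(hyper$var, n_bands)
  lambda <- hyper$mean

  J <- .fd_jacobian(g_fun, c_cur, g0, ctl$h)
  parts <- .vl_parts(e, J, band_idx, n_bands)
  ev <- .vl_free_energy(parts, c_cur, D, lambda, hyper)
  if (is.null(ev)) stop("singular curvature at initialization", call. = FALSE)
  F_cur <- ev$F
  trace <- F_cur
  lm <- 1 / 64
  stall <- 0L
  converged <- FALSE
  iter <- 0L

  while (iter < ctl$max_iter) {
    iter <- iter + 1L
    # precision updates, one component at a time (deterministic line
    # searches; a component update is kept only if it does not decrease F)
    for (b in seq_len(n_bands)) {
      opt <- optimize(function(l) {
        lam <- lambda; lam[b] <- l
        v <- .vl_free_energy(parts, c_cur, D, lam, hyper)
        if (is.null(v)) -1e300 else v$F   # finite so optimize() is quiet
      }, interval = c(lambda[b] - 4, lambda[b] + 4), maximum = TRUE,
      tol = 1e-3)
      if (is.finite(opt$objective) && opt$objective > F_cur) {
        lambda[b] <- opt$maximum
        F_cur <- opt$objective
      }
    }
    ev <- .vl_free_energy(parts, c_cur, D, lambda, hyper)
    F_cur <- ev$F
    # Gauss-Newton / Levenberg step with full re-evaluation at the trial
    grad <- ev$grad
    M0 <- ev$H + diag(1 / D, k)
    accepted <- FALSE
    lm_try <- lm
    for (half in seq_len(8)) {
      dc <- tryCatch(solve(M0 + diag(lm_try * mean(diag(M0)), k), grad),
                     error = function(err) NULL)
      if (!is.null(dc)) {
        c_try <- c_cur + dc
        g_try <- g_fun(c_try)
        if (!is.null(g_try)) {
          e_try <- y - g_try
          J_try <- .fd_jacobian(g_fun, c_try, g_try, ctl$h)
          parts_try <- .vl_parts(e_try, J_try, band_idx, n_bands)
          ev_try <- .vl_free_energy(parts_try, c_try, D, lambda, hyper)
          if (!is.null(ev_try) && ev_try$F >= F_cur) {
            c_cur <- c_try; e <- e_try; J <- J_try
            parts <- parts_try; ev <- ev_try
            F_cur <- ev_try$F
            lm <- lm_try / 2
            accepted <- TRUE
            break
          }
        }
      }
      lm_try <- max(lm_try, 1 / 64) * 8
    }
    trace <- c(trace, F_cur)
    if (ctl$verbose)
      message(sprintf("iter %3d  F = %.3f  %s", iter, F_cur,
                      if (accepted) "" else "(no step)"))
    dF_iter <- trace[length(trace)] - trace[length(trace) - 1]
    stall <- if (dF_iter < ctl$tol) stall + 1L else 0L
    if (stall >= ctl$patience) { converged <- TRUE; break }
  }

  mu <- prior$mean + drop(V %*% c_cur)
  Sigma <- .sym(V %*% ev$S_c %*% t(V))
  A_hat <- effective_connectivity(unpack_params(mu, n))
  unstable <- stability_margin(A_hat) >= 0
  if (unstable)
    warning("posterior-mean coupling matrix is not stable")
  structure(list(mu = mu, Sigma = Sigma, F = F_cur, trace = trace,
                 lambda = lambda, converged = converged, iterations = iter,
                 scale = scale, prior = prior, spec = spec, map = map,
                 unstable = unstable),
            class = "dcm_posterior")
}

#' @export
print.dcm_posterior <- function(x, ...) {
  cat("Spectral DCM posterior:", x$map$n, "regions,",
      length(x$mu), "parameters\n")
  cat(sprintf("  free energy %.2f nats after %d iterations (%s)\n",
              x$F, x$iterations,
              if (x$converged) "converged" else "iteration cap"))
  cat(sprintf("  log noise precision %s, data scale %.3g\n",
              paste(sprintf("%.1f", range(x$lambda)), collapse = ".."),
              x$scale))
  invisible(x)
}

#' Posterior-mean effective connectivity
#'
#' @param posterior A `dcm_posterior`.
#' @return Coupling matrix in Hz.
#' @export
posterior_connectivity <- function(posterior) {
  stopifnot(inherits(posterior, "dcm_posterior"))
  effective_connectivity(unpack_params(posterior$mu, posterior$map$n))
}
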
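# Shared fixtures, built in code.  Heavy objects are memoized so several
# test files can reuse one inversion.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a random stable coupling matrix in natural units
random_stable_A <- function(n, seed = 1, scale = 0.2) {
  set.seed(seed)
  A <- matrix(rnorm(n * n, 0, scale), n, n)
  diag(A) <- -0.5
  while (stability_margin(A) >= -0.05) diag(A) <- diag(A) * 1.25
  A
}

# random dcm_params with small deviations (always stable by construction
# of the diagonal)
random_params <- function(n, seed = 1, coupling_sd = 0.1) {
  set.seed(seed)
  p <- dcm_params(n)
  p$A <- matrix(rnorm(n * n, 0, coupling_sd), n, n)
  diag(p$A) <- rnorm(n, 0, 0.1)
  while (stability_margin(effective_connectivity(p)) >= -0.02)
    diag(p$A) <- diag(p$A) + 0.2
  p$alpha_v <- rnorm(n, 0, 0.2)
  p$beta_v <- rnorm(1, 0, 0.1)
  p$alpha_e <- rnorm(n, -2, 0.2)
  p$beta_e <- rnorm(1, 0, 0.1)
  p$transit <- rnorm(n, 0, 0.1)
  p$epsilon <- rnorm(n, 0, 0.1)
  p
}

# a quick 3-node inversion reused by several tests
quick_inversion <- function() {
  fixture("quick_inv", function() {
    gt <- make_ground_truth(3, density = 0.5, seed = 11)
    ts <- simulate_bold(gt, duration = 512, TR = 2, seed = 21)
    spec <- model_spec(3, n_freq = 8)
    csd <- estimate_csd(ts, spec$freq_hz, order = 16)
    list(gt = gt, ts = ts, spec = spec, csd = csd,
         post = invert(csd, spec))
  })
}

# independent hand-coded multivariate Gaussian log-density (oracle for the
# BMR evidence checks; deliberately not using any package code)
gauss_logpdf <- function(x, mu, Sigma) {
  d <- length(x)
  L <- chol(Sigma)
  z <- backsolve(L, x - mu, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

# exact log evidence of the conjugate linear-Gaussian model
# y = X theta + eps, eps ~ N(0, s2 I), theta ~ N(m0, V0):
# y ~ N(X m0, s2 I + X V0 X')
exact_evidence <- function(y, X, s2, m0, V0) {
  gauss_logpdf(y, drop(X %*% m0),
               diag(s2, length(y)) + X %*% V0 %*% t(X))
}

# exact conjugate posterior for the same model
exact_posterior <- function(y, X, s2, m0, V0) {
  P <- solve(V0) + crossprod(X) / s2
  S <- solve(P)
  list(mean = drop(S %*% (solve(V0, m0) + crossprod(X, y) / s2)), cov = S)
}
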
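# Variational-Laplace inversion: feature packing, free energy, and the
# optimizer's contracts.

test_that("feature packing is lossless for Hermitian arrays", {
  # n = 1: only real auto-spectra
  G1 <- predict_csd(dcm_params(1), model_spec(1, n_freq = 4))
  expect_length(pack_features(G1), 4)

  # n = 2, 8 frequencies: (3 real + 1 imaginary) per frequency
  p2 <- random_params(2, seed = 1)
  G2 <- predict_csd(p2, model_spec(2, n_freq = 8))
  y <- pack_features(G2)
  expect_length(y, 32)
  G2b <- unpack_features(y, 2, G2$freq_hz)
  expect_equal(G2b$G, G2$G)

  # random Hermitian round trip
  set.seed(2)
  n <- 4
  G <- array(0i, c(n, n, 3))
  for (k in 1:3) {
    M <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4)
    G[, , k] <- (M + Conj(t(M))) / 2
  }
  csd <- new_csd(G, c(0.01, 0.02, 0.03))
  expect_equal(unpack_features(pack_features(csd), 4, csd$freq_hz)$G, G)

  # non-Hermitian input is rejected
  G[1, 2, 1] <- G[1, 2, 1] + 1
  expect_error(pack_features(new_csd(G, c(0.01, 0.02, 0.03))), "Hermitian")
})

test_that("free energy reduces to its closed-form pieces", {
  p <- random_params(2, seed = 3)
  spec <- model_spec(2, n_freq = 6)
  prior <- prior_spec(2)
  y <- pack_features(predict_csd(p, spec))
  N <- length(y)
  lam <- 1.3

  # zero prediction error, posterior = prior (params at prior mean would
  # not give zero error, so evaluate at the generating parameters with the
  # prior centered there)
  prior0 <- prior
  prior0$mean <- pack_params(p)
  F0 <- free_energy(y, p, spec, prior0, lam)
  expect_equal(F0, 0.5 * N * lam - 0.5 * N * log(2 * pi), tolerance = 1e-8)

  # larger squared error at fixed precision strictly decreases F
  y_half <- y + rnorm(N, 0, 0.05 * sd(y))
  y_full <- y + 2 * (y_half - y)
  expect_gt(free_energy(y_half, p, spec, prior0, lam),
            free_energy(y_full, p, spec, prior0, lam))

  # moving the point away from the prior mean adds a KL penalty (and
  # prediction error), so F drops strictly below the zero-error value
  theta_shift <- pack_params(p)
  theta_shift[2] <- theta_shift[2] + 0.2
  F_dev <- free_energy(y, unpack_params(theta_shift, 2), spec, prior0, lam)
  expect_lt(F_dev, F0)
})

test_that("inversion is self-consistent at the prior mean", {
  spec <- model_spec(3, n_freq = 8)
  prior <- prior_spec(3)
  p0 <- unpack_params(prior$mean, 3)
  csd0 <- predict_csd(p0, spec)
  post <- invert(csd0, spec, prior)
  sd0 <- sqrt(diag(prior$cov))
  expect_true(all(abs(post$mu - prior$mean) <= 2 * sd0 + 1e-6))
  expect_true(all(diff(post$trace) >= 0))
})

test_that("inversion contracts: grids, inputs, reduced-rank priors", {
  qi <- quick_inversion()
  expect_s3_class(qi$post, "dcm_posterior")
  expect_true(all(diff(qi$post$trace) >= 0))
  expect_true(is.finite(qi$post$F))
  # posterior covariance is symmetric PSD
  ev <- eigen(qi$post$Sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10 * max(ev)))

  # nonzero exogenous inputs are rejected at rest
  spec_bad <- qi$spec
  spec_bad$C <- matrix(1, 3, 1)
  expect_error(invert(qi$csd, spec_bad), "C = 0")

  # wrong frequency grid is rejected
  spec_wrong <- model_spec(3, n_freq = 9)
  expect_error(invert(qi$csd, spec_wrong), "grid")

  # rank-deficient prior covariance (mode-reduced) still inverts
  prior_red <- reduce_prior(prior_spec(3),
                            mode_projector(functional_modes(qi$ts), 2))
  expect_lt(qr(prior_red$cov[1:9, 1:9])$rank, 9)
  post_red <- invert(qi$csd, qi$spec, prior_red)
  expect_true(is.finite(post_red$F))
  expect_true(all(diff(post_red$trace) >= 0))
})

test_that("couplings of a simulated 3-node network are recovered in sign", {
  hits <- 0L
  total <- 0L
  for (s in 1:10) {
    gt <- make_ground_truth(3, density = 0.5, seed = 500 + s)
    ts <- simulate_bold(gt, duration = 1024, TR = 2, seed = 600 + s)
    spec <- model_spec(3, n_freq = 8)
    post <- invert(estimate_csd(ts, spec$freq_hz, order = 16), spec)
    expect_true(all(diff(post$trace) >= 0))
    A_hat <- posterior_connectivity(post)
    big <- (row(gt$A) != col(gt$A)) & abs(gt$A) >= 0.2
    hits <- hits + sum(sign(A_hat[big]) == sign(gt$A[big]))
    total <- total + sum(big)
  }
  expect_gte(hits / total, 0.9)
})

test_that("the true sparse prior structure is favored by the evidence", {
  wins <- 0L
  for (s in 1:10) {
    gt <- make_ground_truth(3, density = 0.5, seed = 700 + s)
    ts <- simulate_bold(gt, duration = 512, TR = 2, seed = 800 + s)
    spec <- model_spec(3, n_freq = 8)
    csd <- estimate_csd(ts, spec$freq_hz, order = 16)
    map <- param_index_map(3)
    absent <- map$A_offdiag[!gt$mask[row(gt$A) != col(gt$A)]]
    present <- map$A_offdiag[gt$mask[row(gt$A) != col(gt$A)]]
    if (!length(absent) || !length(present)) next
    prior_true <- prior_spec(3)
    diag(prior_true$cov)[absent] <- 1e-8
    prior_bad <- prior_spec(3)
    diag(prior_bad$cov)[present[1]] <- 1e-8
    F_true <- invert(csd, spec, prior_true)$F
    F_bad <- invert(csd, spec, prior_bad)$F
    wins <- wins + (F_true > F_bad)
  }
  expect_gte(wins, 6)
})

test_that("posteriors serialize and reload exactly", {
  qi <- quick_inversion()
  dir <- tempfile()
  write_posterior(qi$post, dir)
  p2 <- read_posterior(dir)
  expect_equal(p2$mu, qi$post$mu, tolerance = 1e-12)
  expect_equal(p2$Sigma, qi$post$Sigma, tolerance = 1e-10)
  expect_equal(p2$F, qi$post$F)
  expect_equal(p2$prior$cov, qi$post$prior$cov, tolerance = 1e-12)
})
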
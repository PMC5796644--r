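# Ground-truth simulator: coupling sampling, spectral noise synthesis,
# BOLD generation.

test_that("ground truths are stable with the documented edge count", {
  gt0 <- make_ground_truth(4, density = 0, seed = 1)
  expect_equal(gt0$A - diag(diag(gt0$A)), matrix(0, 4, 4))
  expect_false(any(gt0$mask))

  for (s in 1:10) {
    gt <- make_ground_truth(6, density = 0.4, seed = s)
    expect_lt(stability_margin(gt$A), -0.05)
    expect_equal(sum(gt$mask), round(0.4 * 30))  # 12 edges
    expect_true(all(diag(gt$A) < 0))
    # deviation-scale params reproduce A exactly
    expect_equal(effective_connectivity(gt$params), gt$A)
  }

  # mode-rank construction: the off-diagonal couplings admit a diagonal
  # completion of rank 3 (the diagonal of U W U' was overwritten by the
  # self-connections), recovered here by alternating projections between
  # the rank-3 set and the known off-diagonal entries
  gtr <- make_ground_truth(8, rank = 3, seed = 2)
  expect_lt(stability_margin(gtr$A), -0.05)
  off <- row(gtr$A) != col(gtr$A)
  expect_true(all(gtr$A[off] != 0))
  M <- gtr$A
  diag(M) <- 0
  for (it in 1:500) {
    sv <- svd(M)
    M3 <- sv$u[, 1:3] %*% (sv$d[1:3] * t(sv$v[, 1:3]))
    M <- M3
    M[off] <- gtr$A[off]
  }
  sv <- svd(M)
  M3 <- sv$u[, 1:3] %*% (sv$d[1:3] * t(sv$v[, 1:3]))
  expect_lt(max(abs(M3[off] - gtr$A[off])), 1e-3)
  expect_error(make_ground_truth(4, rank = 9), "rank")
})

test_that("spectral factorization produces the target power law", {
  # reproducibility
  expect_identical(sample_fluctuations(1, 1, 1024, 0.5, seed = 7),
                   sample_fluctuations(1, 1, 1024, 0.5, seed = 7))
  expect_equal(sample_fluctuations(0, 1, 256, 0.5), numeric(256))

  # beta = 0: white noise, negligible lag-1 autocorrelation
  x <- sample_fluctuations(1, 0, 2^14, 0.5, seed = 8)
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 0.05)

  # beta = 1: fitted log-log periodogram slope within +-0.2 of -1
  x <- sample_fluctuations(1, 1, 2^16, 0.5, seed = 9)
  N <- length(x)
  pg <- Mod(fft(x))^2 * 0.5 / N
  f <- (1:(N / 2 - 1)) / (N * 0.5)
  sel <- f > 2e-3 & f < 0.5      # modeled band, above the synthesis floor
  fit <- lm(log(pg[1 + which(sel)]) ~ log(2 * pi * f[sel]))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.2)
})

test_that("BOLD simulation is deterministic and anchored at baseline", {
  gt <- make_ground_truth(3, density = 0.5, seed = 3)
  ts1 <- simulate_bold(gt, duration = 128, TR = 2, seed = 30)
  ts2 <- simulate_bold(gt, duration = 128, TR = 2, seed = 30)
  expect_identical(ts1$Y, ts2$Y)
  expect_equal(dim(ts1$Y), c(3L, 64L))

  # no fluctuations, no noise -> the system sits at its fixed point
  gt0 <- gt
  gt0$params$alpha_v <- rep(-Inf, 3)
  ts0 <- simulate_bold(gt0, duration = 64, TR = 2, seed = 31,
                       obs_noise = FALSE)
  expect_equal(ts0$Y, matrix(0, 3, 32))

  expect_error(simulate_bold(gt, duration = 64, TR = 0.35, seed = 1),
               "multiple")
})

test_that("compiled and reference hemodynamic integrators agree", {
  set.seed(12)
  x <- matrix(rnorm(3 * 500, 0, 0.05), 3)
  yR <- specdcm:::.balloon_integrate(x, 0.1, transit = c(1.5, 2, 2.5),
                                     epsilon = c(0.8, 1, 1.2),
                                     substeps = 2L)
  yC <- specdcm:::.balloon_rk4(x, 0.1, c(1.5, 2, 2.5), c(0.8, 1, 1.2),
                               hemo_constants(), 2L)
  expect_equal(yC, yR, tolerance = 1e-12)
})

test_that("neural variance scales with drive and self-inhibition", {
  gt <- make_ground_truth(3, density = 0.3, seed = 4, alpha_v = 1e-3)
  hi <- gt
  hi$params$alpha_v <- gt$params$alpha_v + log(4)
  v_lo <- mean(apply(simulate_bold(gt, 512, TR = 2, seed = 40,
                                   obs_noise = FALSE)$Y, 1, var))
  v_hi <- mean(apply(simulate_bold(hi, 512, TR = 2, seed = 40,
                                   obs_noise = FALSE)$Y, 1, var))
  expect_gt(v_hi, 2 * v_lo)

  deep <- gt
  deep$A <- gt$A; diag(deep$A) <- 4 * diag(gt$A)
  diag(deep$params$A) <- log(diag(deep$A) / -0.5)
  v_deep <- mean(apply(simulate_bold(deep, 512, TR = 2, seed = 40,
                                     obs_noise = FALSE)$Y, 1, var))
  expect_lt(v_deep, v_lo)
})

test_that("ground truths serialize for exact rerun", {
  gt <- make_ground_truth(5, density = 0.4, seed = 17)
  path <- tempfile(fileext = ".json")
  write_ground_truth(gt, path)
  gt2 <- read_ground_truth(path)
  expect_equal(gt2$A, gt$A)
  expect_equal(gt2$mask, gt$mask)
  expect_equal(pack_params(gt2$params), pack_params(gt$params))
  ts1 <- simulate_bold(gt, duration = 64, TR = 2, seed = 5)
  ts2 <- simulate_bold(gt2, duration = 64, TR = 2, seed = 5)
  expect_identical(ts1$Y, ts2$Y)
})
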
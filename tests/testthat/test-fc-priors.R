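# Functional-connectivity modes, the Kronecker projector, rank-reduced
# priors and the mode sweep's algebraic contracts.

test_that("functional modes are an orthonormal, ordered, signed basis", {
  set.seed(1)
  # orthogonal rows -> U is a signed permutation of the identity
  Y <- rbind(c(1, 1, -1, -1, 0, 0) * 4,
             c(1, -1, 1, -1, 0, 0) * 2,
             c(0, 0, 0, 0, 1, -1))
  fm <- functional_modes(timeseries_data(Y, TR = 2))
  expect_equal(abs(fm$U), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(crossprod(fm$U), diag(3), tolerance = 1e-12)
  expect_true(all(diff(fm$values) <= 1e-12))

  # rank-2 synthetic data: third singular value ~ 0
  s1 <- rnorm(200); s2 <- rnorm(200)
  Y2 <- rbind(outer(c(1, 0.5, -0.3, 0.2), s1) +
                outer(c(0, 1, 0.4, -0.5), s2))
  fm2 <- functional_modes(timeseries_data(Y2, TR = 2))
  expect_lt(fm2$values[3] / fm2$values[1], 1e-10)

  # deterministic sign: largest-magnitude loading positive
  for (j in 1:4) expect_gt(fm2$U[which.max(abs(fm2$U[, j])), j], 0)

  expect_error(functional_modes(timeseries_data(matrix(0, 3, 10), TR = 2)),
               "degenerate")
})

test_that("the Kronecker projector is symmetric, idempotent, rank m^2", {
  set.seed(2)
  # random orthonormal U_m, n = 5, m = 2, against the explicit matrix
  U <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:2]
  proj <- mode_projector(U)
  K <- as.matrix(proj)
  expect_equal(dim(K), c(25L, 25L))
  expect_equal(K, t(K))
  expect_equal(K %*% K, K, tolerance = 1e-12)
  sv <- svd(K)$d
  expect_equal(sum(sv > 1e-8), 4L)  # rank m^2
  expect_equal(K, kronecker(tcrossprod(U), tcrossprod(U)))

  # m = n: identity on n^2-space -- effectively no prior constraint
  Un <- qr.Q(qr(matrix(rnorm(16), 4)))
  expect_equal(as.matrix(mode_projector(Un)), diag(16), tolerance = 1e-12)

  # m = 1: rank-one node projector
  expect_equal(sum(svd(as.matrix(mode_projector(Un[, 1, drop = FALSE])))$d
                   > 1e-8), 1L)

  # nested bases commute: K_m K_m' = K_m for U_m inside U_m'
  K2 <- as.matrix(mode_projector(Un[, 1:2]))
  K3 <- as.matrix(mode_projector(Un[, 1:3]))
  expect_equal(K2 %*% K3, K2, tolerance = 1e-12)
  expect_equal(K3 %*% K2, K2, tolerance = 1e-12)

  expect_error(mode_projector(matrix(1, 4, 2)), "orthonormal")
})

test_that("prior covariance reduction is a PSD congruence of rank <= m^2", {
  set.seed(3)
  n <- 5
  B <- matrix(rnorm(n^2 * n^2), n^2)
  Sigma <- crossprod(B) / n^2
  U <- qr.Q(qr(matrix(rnorm(n * n), n)))[, 1:2]
  proj <- mode_projector(U)
  Sm <- reduce_prior_covariance(Sigma, proj)
  K <- as.matrix(proj)
  expect_equal(Sm, K %*% Sigma %*% t(K), tolerance = 1e-10)
  expect_equal(Sm, t(Sm))
  ev <- eigen(Sm, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10 * max(ev)))
  expect_lte(sum(ev > 1e-10 * max(ev)), 4)

  # m = n leaves the covariance untouched (identity projector)
  Un <- qr.Q(qr(matrix(rnorm(n * n), n)))
  expect_identical(reduce_prior_covariance(Sigma, mode_projector(Un)),
                   Sigma)
  expect_error(reduce_prior_covariance(Sigma[1:10, 1:10], proj), "x")
})

test_that("projector ordering matches the packed vec(A) layout", {
  # cross-module contract: applying K_m to the A block of the packed
  # vector equals vec(P %*% A %*% P) for the matrix it encodes
  set.seed(4)
  n <- 4
  U <- qr.Q(qr(matrix(rnorm(n * n), n)))[, 1:2]
  proj <- mode_projector(U)
  P <- proj$P
  A <- matrix(rnorm(n * n), n)
  p <- dcm_params(n, A = A)
  map <- param_index_map(n)
  a_block <- pack_params(p)[map$A]
  expect_equal(as.matrix(proj) %*% a_block, as.vector(P %*% A %*% P),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the mode sweep scores reduced priors and is exact at m = n", {
  qi <- quick_inversion()
  fm <- functional_modes(qi$ts)
  sw <- sweep_modes(qi$post, fm)
  expect_equal(nrow(sw$table), 3L)
  expect_identical(sw$table$dF[3], 0)          # m = n: same prior
  expect_equal(sw$table$F_rel, sw$table$dF - sw$table$dF[1])
  expect_true(sw$m_star %in% 1:3)
  expect_error(sweep_modes(qi$post, fm, m_grid = c(0, 2)), "within")
  expect_error(sweep_modes(qi$post, fm, m_grid = 5), "within")

  path <- tempfile(fileext = ".csv")
  write_sweep(sw, path)
  expect_equal(read.csv(path)$dF, sw$table$dF, tolerance = 1e-12)
})
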
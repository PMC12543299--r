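test_that("data preparation centers, scales, and validates", {
  # constant column without standardization is centered to zeros
  raw <- cbind(a = rep(1, 10), b = rnorm(10))
  d <- prepare_data(raw, standardize = FALSE)
  expect_equal(d$X[, 1], rep(0, 10))

  # U / T equals the maximum-likelihood sample covariance
  set.seed(20)
  raw <- matrix(rnorm(500), 100, 5)
  d <- prepare_data(raw, standardize = FALSE)
  Xc <- scale(raw, scale = FALSE)
  expect_equal(d$U / d$T, crossprod(Xc) / 100, tolerance = 1e-12,
               ignore_attr = TRUE)
  # standardized columns have unit ML variance
  ds <- prepare_data(raw, standardize = TRUE)
  expect_equal(colMeans(ds$X^2), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(prepare_data(matrix(1, 1, 3)), "T = 2")
  expect_error(prepare_data(cbind(a = rep(2, 10), b = rnorm(10))),
               "constant column.*a")
  expect_error(prepare_data(cbind(rnorm(10), c(NA, rnorm(9)))),
               "non-finite")
})

test_that("GGM log-likelihood matches closed forms and per-observation sums", {
  # P = 1, T = 2, X = (1, -1), Omega = 1: -log 2pi - 1
  d1 <- list(U = matrix(2), T = 2, P = 1)
  expect_equal(ggm_log_likelihood(d1, matrix(1)), -log(2 * pi) - 1)

  # identity precision: -(TP/2) log 2pi - tr(U)/2
  set.seed(21)
  raw <- matrix(rnorm(200), 50, 4)
  d <- prepare_data(raw, standardize = FALSE)
  expect_equal(ggm_log_likelihood(d, diag(4)),
               -(50 * 4 / 2) * log(2 * pi) - sum(diag(d$U)) / 2)

  # equals the sum of per-observation multivariate-normal log densities
  A <- matrix(rnorm(16), 4)
  Omega <- crossprod(A) + diag(4)
  per_obs <- sum(apply(d$X, 1, function(x) {
    -4 / 2 * log(2 * pi) + 0.5 * determinant(Omega)$modulus -
      0.5 * drop(x %*% Omega %*% x)
  }))
  expect_equal(ggm_log_likelihood(d, Omega), per_obs, tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(ggm_log_likelihood(d, -diag(4)), "positive definite")
})

test_that("edge indicators follow the slab/spike density ratio", {
  sp <- edge_space(3)
  hy <- spike_slab_hyper(v0 = 0.02, v1 = 1)
  # omega = 0.5 on edge (1,2), prior log-odds 0
  Om <- diag(3); Om[1, 2] <- Om[2, 1] <- 0.5
  st <- precision_state(sp, Omega = Om)
  p_expect <- plogis(dnorm(0.5, 0, 1, log = TRUE) -
                       dnorm(0.5, 0, 0.02, log = TRUE))
  set.seed(22)
  freq <- mean(replicate(4000, sample_edge_indicators(st, hy)$gamma[1]))
  expect_lt(abs(freq - p_expect), 3.5 * sqrt(p_expect * (1 - p_expect) / 4000) + 1e-6)

  # omega exactly 0: spike favored by log(v0/v1) relative to the prior odds
  st0 <- precision_state(sp)
  p0 <- plogis(log(0.02 / 1))
  set.seed(23)
  freq0 <- mean(replicate(4000, sample_edge_indicators(st0, hy)$gamma[1]))
  expect_lt(abs(freq0 - p0), 3.5 * sqrt(p0 * (1 - p0) / 4000))

  # overwhelming prior log-odds force inclusion
  set.seed(24)
  g <- sample_edge_indicators(st0, hy, prior_logodds = 700)$gamma
  expect_equal(g, rep(1L, 3))
  g <- sample_edge_indicators(st0, hy, prior_logodds = -700)$gamma
  expect_equal(g, rep(0L, 3))

  expect_error(spike_slab_hyper(v0 = 1, v1 = 0.5))
})

test_that("sweeps preserve symmetry and positive definiteness and are seeded", {
  set.seed(25)
  sp <- edge_space(5)
  raw <- matrix(rnorm(5 * 80), 80, 5)
  d <- prepare_data(raw)
  hy <- spike_slab_hyper()
  st <- precision_state(sp)
  set.seed(26)
  for (it in 1:200) {
    st <- ggm_sweep(st, d, hy, 0)
    expect_true(isSymmetric(st$Omega, tol = 1e-12))
    expect_gt(min(eigen(st$Omega, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
  # determinism
  set.seed(27); a <- ggm_sweep(precision_state(sp), d, hy, 0, n_sweeps = 25)
  set.seed(27); b <- ggm_sweep(precision_state(sp), d, hy, 0, n_sweeps = 25)
  expect_identical(a$Omega, b$Omega)
  expect_identical(a$gamma, b$gamma)
})

test_that("a prior-only chain reproduces the exact prior inclusion", {
  # Under the spike-and-slab prior restricted to the positive-definite
  # cone, the marginal prior inclusion probability is NOT exactly one
  # half at the default hyperparameters: the wide slab is truncated more
  # by positive definiteness than the narrow spike. At P = 3 the graph
  # weights C(gamma) = P(PD) under the componentwise prior are cheap to
  # estimate by direct Monte Carlo, giving an independent oracle.
  sp <- edge_space(3)
  hy <- spike_slab_hyper()  # v0 = 0.02, v1 = 1, lambda = 1
  set.seed(28)
  Cg <- vapply(0:7, function(code) {
    g <- as.integer(intToBits(code))[1:3]
    v <- ifelse(g == 1, hy$v1, hy$v0)
    n <- 2e5
    w12 <- rnorm(n, 0, v[1]); w13 <- rnorm(n, 0, v[2])
    w23 <- rnorm(n, 0, v[3])
    d <- matrix(rexp(3 * n, rate = hy$lambda / 2), n, 3)
    m2 <- d[, 1] * d[, 2] - w12^2
    det3 <- d[, 1] * (d[, 2] * d[, 3] - w23^2) -
      w12 * (w12 * d[, 3] - w13 * w23) +
      w13 * (w12 * w23 - d[, 2] * w13)
    mean(m2 > 0 & det3 > 0)
  }, 0)
  oracle <- vapply(1:3, function(e) {
    on <- vapply(0:7, function(code) as.integer(intToBits(code))[e] == 1L,
                 TRUE)
    sum(Cg[on]) / sum(Cg)
  }, 0)

  d0 <- mlggm:::null_data(3)
  st <- precision_state(sp)
  n_it <- 40000
  freq <- numeric(sp$E)
  for (it in seq_len(n_it)) {
    st <- ggm_sweep(st, d0, hy, 0)
    freq <- freq + st$gamma
  }
  freq <- freq / n_it
  # the indicator chain is sticky (slab states persist); allow a
  # generous autocorrelation-inflated tolerance
  expect_true(all(abs(freq - oracle) < 0.025))
  # and the bias away from one half is real and matches the oracle sign
  expect_true(all(oracle < 0.45))
  expect_true(all(freq < 0.45))
})

test_that("posterior mean partial correlations approach the truth as T grows", {
  set.seed(29)
  sp <- edge_space(5)
  g <- chain_graph(sp)
  K <- sample_gwishart(g, sp, df = 5)
  pc_true <- partial_correlations(K, sp)
  hy <- spike_slab_hyper()
  rmse <- vapply(c(400, 4000), function(T) {
    X <- simulate_participant_data(K, T)
    d <- prepare_data(X, standardize = FALSE)
    st <- precision_state(sp)
    st <- ggm_sweep(st, d, hy, 0, n_sweeps = 100)  # burn-in
    acc <- numeric(sp$E)
    for (it in 1:300) {
      st <- ggm_sweep(st, d, hy, 0)
      acc <- acc + partial_correlations(st$Omega, sp)
    }
    sqrt(mean((acc / 300 - pc_true)^2))
  }, 0)
  expect_lt(rmse[2], rmse[1])
  expect_lt(rmse[2], 0.05)
})
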
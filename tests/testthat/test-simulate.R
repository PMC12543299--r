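test_that("group graphs are Erdos-Renyi on the edge set", {
  sp <- edge_space(40)
  expect_equal(simulate_group_graph(sp, 1e-12), rep(0L, sp$E))
  set.seed(30)
  counts <- replicate(300, sum(simulate_group_graph(sp, 0.16)))
  # binomial mean 0.16 * 780 = 124.8
  se <- sqrt(780 * 0.16 * 0.84 / 300)
  expect_lt(abs(mean(counts) - 124.8), 4 * se)
  set.seed(31); g1 <- simulate_group_graph(sp, 0.16)
  set.seed(31); g2 <- simulate_group_graph(sp, 0.16)
  expect_identical(g1, g2)
})

test_that("main effects are sign-truncated normals scaled by homogeneity", {
  cfg <- simulation_config()
  g <- c(1L, 0L, 1L, 0L, 0L, 1L)
  expect_equal(simulate_mu(g, 0, cfg), rep(0, 6))

  set.seed(32)
  mu <- simulate_mu(g, 100, cfg)
  expect_true(all(mu[g == 1] > 0))
  expect_true(all(mu[g == 0] < 0))

  # moments of the positive side at rho = 100 against the closed form
  set.seed(33)
  draws <- simulate_mu(rep(1L, 2e4), 100, cfg)
  a <- -2.73 / 2.33
  m_true <- 2.73 + 2.33 * dnorm(a) / (1 - pnorm(a))
  expect_lt(abs(mean(draws) - m_true), 4 * sd(draws) / sqrt(2e4))

  # rho = 30 scales both location and scale by 0.3
  set.seed(34)
  d30 <- simulate_mu(rep(0L, 2e4), 30, cfg)
  a_n <- 0.948 / 1.005
  m_neg <- -0.948 - 1.005 * dnorm(a_n) / pnorm(a_n)
  expect_lt(abs(mean(d30) - m_neg), 4 * sd(d30) / sqrt(2e4))
})

test_that("G-Wishart draws honor the graph exactly and are PD", {
  sp <- edge_space(6)
  set.seed(35)
  # empty graph: diagonal precision
  K0 <- sample_gwishart(rep(0L, sp$E), sp, df = 3)
  expect_equal(K0 - diag(diag(K0)), matrix(0, 6, 6), tolerance = 1e-12)

  # complete graph reduces to a plain Wishart draw
  set.seed(36); Kc <- sample_gwishart(rep(1L, sp$E), sp, df = 3)
  set.seed(36); Kw <- drop(rWishart(1, 3 + 5, diag(6)))
  expect_equal(Kc, Kw)

  # random graphs: standardized zeros at non-edges, PD
  set.seed(37)
  for (r in 1:10) {
    g <- simulate_group_graph(sp, 0.4)
    K <- sample_gwishart(g, sp, df = 3)
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), 0)
    pc <- partial_correlations(K, sp)
    if (any(g == 0)) expect_lt(max(abs(pc[g == 0])), 1e-6)
  }
})

test_that("G-Wishart matches an independent decomposable-graph sampler", {
  sp <- edge_space(4)
  g <- chain_graph(sp)
  n <- 4000
  set.seed(38)
  m1 <- Reduce(`+`, lapply(seq_len(n), function(i)
    sample_gwishart(g, sp, df = 3))) / n
  set.seed(39)
  m2 <- Reduce(`+`, lapply(seq_len(n), function(i)
    rgwish_decomposable(g, sp, df = 3))) / n
  # free elements: diagonal and chain edges; MC tolerance
  free <- rbind(cbind(1:4, 1:4), cbind(1:3, 2:4))
  for (k in seq_len(nrow(free))) {
    i <- free[k, 1]; j <- free[k, 2]
    expect_lt(abs(m1[i, j] - m2[i, j]),
              0.15 * max(1, abs(m2[i, j])))
  }
  # the oracle itself respects the zero pattern
  set.seed(40)
  Ko <- rgwish_decomposable(g, sp, df = 3)
  expect_lt(max(abs(Ko[cbind(c(1, 1, 2), c(3, 4, 4))])), 1e-12)
  expect_gt(min(eigen(Ko, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("time series have the implied covariance", {
  set.seed(41)
  X <- simulate_participant_data(diag(3), 1e4)
  expect_true(all(abs(crossprod(X) / 1e4 - diag(3)) < 0.05))
  # P = 2: empirical correlation sign is opposite the precision off-diagonal
  Om <- matrix(c(2, 0.8, 0.8, 2), 2)
  X2 <- simulate_participant_data(Om, 3000)
  expect_lt(cor(X2)[1, 2], 0)
  set.seed(42); a <- simulate_participant_data(diag(2), 5)
  set.seed(42); b <- simulate_participant_data(diag(2), 5)
  expect_identical(a, b)
})

test_that("a full study chains the pipeline with consistent truth", {
  cfg <- simulation_config(P = 6, N = 30, T = 40, rho = 50, seed = 43)
  truth <- simulate_study(cfg)
  sp <- truth$space
  expect_equal(dim(truth$individual_graphs), c(30, sp$E))
  expect_length(truth$precisions, 30)
  expect_equal(dim(truth$timeseries[[1]]), c(40, 6))
  for (n in c(1, 15, 30)) {
    K <- truth$precisions[[n]]
    g <- truth$individual_graphs[n, ]
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), 0)
    pc <- partial_correlations(K, sp)
    if (any(g == 0)) expect_lt(max(abs(pc[g == 0])), 1e-6)
  }
  # reproducibility from the config seed
  truth2 <- simulate_study(cfg)
  expect_identical(truth$individual_graphs, truth2$individual_graphs)
  expect_identical(truth$timeseries[[3]], truth2$timeseries[[3]])
})

test_that("individual-graph frequencies match the model marginals", {
  cfg <- simulation_config(P = 6, N = 600, T = 5, rho = 50, seed = 44)
  truth <- simulate_study(cfg)
  st <- group_state(truth$mu, truth$sigma, truth$space)
  m <- cw_marginal_probs(st)
  se <- sqrt(m * (1 - m) / 600)
  expect_true(all(abs(colMeans(truth$individual_graphs) - m) < 3.5 * se))
})

test_that("rho = 0 yields exchangeable Bernoulli(1/2) graphs", {
  cfg <- simulation_config(P = 6, N = 800, T = 5, rho = 0, sigma = 0,
                           seed = 45)
  truth <- simulate_study(cfg)
  freq <- colMeans(truth$individual_graphs)
  expect_true(all(abs(freq - 0.5) < 3.5 * sqrt(0.25 / 800)))
})

test_that("mixture studies flip the stated share of edges", {
  cfg <- simulation_config(P = 10, N = 20, T = 10, rho = 100, seed = 46,
                           mixture = TRUE, flip_frac = 0.2)
  truth <- simulate_study(cfg)
  E <- truth$space$E
  n_diff <- sum(truth$group_graph != truth$group_graph2)
  expect_equal(n_diff, round(0.2 * E))
  expect_equal(sum(truth$labels == 1), 16)
  expect_equal(sum(truth$labels == 2), 4)
  # flipping the differing edges again restores the first graph
  flip <- which(truth$group_graph != truth$group_graph2)
  g2 <- truth$group_graph2
  g2[flip] <- 1L - g2[flip]
  expect_identical(g2, truth$group_graph)
})

test_that("datasets round-trip through the manifest format", {
  cfg <- simulation_config(P = 4, N = 3, T = 25, rho = 100, seed = 47)
  truth <- simulate_study(cfg)
  dir <- file.path(tempdir(), "mlggm-ds")
  unlink(dir, recursive = TRUE)
  write_dataset(truth, dir)
  dl <- read_dataset(file.path(dir, "manifest.tsv"), standardize = FALSE)
  expect_length(dl, 3)
  expect_equal(dl[[2]]$T, 25)
  # values survive the round trip up to centering
  Xc <- scale(truth$timeseries[[2]], scale = FALSE)
  expect_equal(dl[[2]]$X, Xc, tolerance = 1e-6, ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
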
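# Shared test utilities: brute-force oracles kept independent of the
# package's own computational paths.

# all 2^E edge configurations as a matrix (rows = states)
enumerate_states <- function(E) {
  as.matrix(expand.grid(rep(list(0:1), E)))
}

# brute-force Curie-Weiss log probabilities for every state
cw_brute_logp <- function(mu, sigma, E) {
  G <- enumerate_states(E)
  lp <- drop(G %*% mu) + sigma / E * rowSums(G)^2
  list(states = G, logp = lp - log(sum(exp(lp))),
       log_z = log(sum(exp(lp))))
}

# rank-statistic AUC with half credit for ties (Mann-Whitney)
auc_rank <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# chain graph 1-2-3-...-P as an edge vector
chain_graph <- function(space) {
  g <- integer(space$E)
  for (i in seq_len(space$P - 1L))
    g[edge_index(i, i + 1L, space)] <- 1L
  g
}

# Independent G-Wishart sampler for decomposable graphs with identity
# scale and a perfect vertex ordering: K = t(Psi) %*% Psi with
# Psi[i,i]^2 ~ chisq(df + nu_i), nu_i = #{j > i adjacent to i},
# Psi[i,j] ~ N(0,1) on edges, and the completion
# Psi[i,j] = -sum_{k<i} Psi[k,i] Psi[k,j] / Psi[i,i] on non-edges.
rgwish_decomposable <- function(graph, space, df) {
  P <- space$P
  A <- edges_to_adjacency(graph, space) == 1
  nu <- vapply(seq_len(P), function(i) sum(A[i, ][seq_len(P) > i]), 0L)
  Psi <- matrix(0, P, P)
  for (i in seq_len(P)) {
    Psi[i, i] <- sqrt(stats::rchisq(1, df + nu[i]))
    if (i < P) for (j in seq.int(i + 1L, P)) {
      if (A[i, j]) {
        Psi[i, j] <- stats::rnorm(1)
      } else if (i > 1L) {
        Psi[i, j] <- -sum(Psi[seq_len(i - 1L), i] *
                            Psi[seq_len(i - 1L), j]) / Psi[i, i]
      }
    }
  }
  crossprod(Psi)
}

# small simulated cohort reused by sampler tests
tiny_cohort <- function(P = 6, N = 4, T = 120, rho = 100, seed = 99) {
  cfg <- simulation_config(P = P, N = N, T = T, rho = rho, seed = seed)
  truth <- simulate_study(cfg)
  list(truth = truth,
       data = lapply(truth$timeseries, prepare_data))
}
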
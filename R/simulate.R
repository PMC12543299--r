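#' Configuration of the generative simulation
#'
#' Defaults follow the first simulation design used throughout the
#' package: `P = 40` nodes, group density 0.16, Curie-Weiss interaction
#' `sigma = 0.1`, and sign-truncated-normal main effects whose location
#' and scale parameters (2.73/2.33 on the positive, group-present side;
#' 3.16/3.35 magnitudes on the negative, group-absent side) are scaled
#' linearly by the homogeneity percentage `rho / 100`. At `rho = 0` all
#' main effects are zero and participants are independent with edge
#' probability one half; at `rho = 100` cohesion is at the level
#' estimated from empirical resting-state data.
#'
#' @param P Nodes. @param N Participants. @param T Time points.
#' @param rho Homogeneity percentage in `[0, 100]`.
#' @param sigma Curie-Weiss interaction (average per-pair; the model uses
#'   `sigma/E` times the squared edge count).
#' @param density Group-graph edge probability.
#' @param mu_pos_loc,mu_pos_scale Positive-side truncated-normal location
#'   and scale (before `rho` scaling).
#' @param mu_neg_loc,mu_neg_scale Negative-side magnitudes.
#' @param gwishart_df G-Wishart degrees of freedom.
#' @param seed Master seed.
#' @param mixture If `TRUE`, simulate from two group graphs: the second
#'   is obtained by flipping `flip_frac` of the edges of the first, and
#'   participants are split according to `mixture_sizes`.
#' @param flip_frac Fraction of edges flipped for the second group graph.
#' @param mixture_sizes Length-2 participant split (defaults to 80/20
#'   proportions of `N`).
#' @export
simulation_config <- function(P = 40L, N = 50L, T = 500L, rho = 30,
                              sigma = 0.1, density = 0.16,
                              mu_pos_loc = 2.73, mu_pos_scale = 2.33,
                              mu_neg_loc = 3.16, mu_neg_scale = 3.35,
                              gwishart_df = 3, seed = 1L,
                              mixture = FALSE, flip_frac = 0.2,
                              mixture_sizes = NULL) {
  stopifnot(rho >= 0, rho <= 100, density > 0, density < 1,
            mu_pos_scale > 0, mu_neg_scale > 0, sigma >= 0,
            gwishart_df > 2)
  if (mixture && is.null(mixture_sizes)) {
    n1 <- round(0.8 * N)
    mixture_sizes <- c(n1, N - n1)
  }
  if (mixture) stopifnot(length(mixture_sizes) == 2L,
                         sum(mixture_sizes) == N)
  structure(list(P = as.integer(P), N = as.integer(N), T = as.integer(T),
                 rho = rho, sigma = sigma, density = density,
                 mu_pos_loc = mu_pos_loc, mu_pos_scale = mu_pos_scale,
                 mu_neg_loc = mu_neg_loc, mu_neg_scale = mu_neg_scale,
                 gwishart_df = gwishart_df, seed = as.integer(seed),
                 mixture = mixture, flip_frac = flip_frac,
                 mixture_sizes = mixture_sizes),
            class = "simulation_config")
}

#' Simulate a group-level graph
#'
#' Each of the `E` edges is included independently with probability
#' `density` (Erdos-Renyi on the edge set).
#'
#' @param space An [edge_space()].
#' @param density Edge probability in `[0, 1)`.
#' @return An integer 0/1 vector of length `E`.
#' @export
simulate_group_graph <- function(space, density) {
  stopifnot(inherits(space, "edge_space"), density >= 0, density < 1)
  stats::rbinom(space$E, 1L, density)
}

#' Simulate Curie-Weiss main effects from a group graph
#'
#' For a group-present edge, `mu_e` is drawn from a normal with location
#' `mu_pos_loc * r` and scale `mu_pos_scale * r` truncated to `(0, Inf)`;
#' for a group-absent edge from a normal with location `-mu_neg_loc * r`
#' and scale `mu_neg_scale * r` truncated to `(-Inf, 0)`, where
#' the scaling factor is `rho / 100`. At `rho = 0` the vector is exactly
#' zero.
#'
#' @param group_graph Binary vector of length `E`.
#' @param rho Homogeneity percentage.
#' @param config A [simulation_config()] supplying the location/scale
#'   parameters.
#' @return Numeric vector of length `E`.
#' @export
simulate_mu <- function(group_graph, rho, config = simulation_config()) {
  stopifnot(rho >= 0, rho <= 100)
  E <- length(group_graph)
  r <- rho / 100
  if (r == 0) return(numeric(E))
  mu <- numeric(E)
  on <- group_graph == 1L
  # draw in edge order so results do not depend on the graph's layout
  for (e in seq_len(E)) {
    mu[e] <- if (on[e]) {
      rtruncnorm_sign(1L, config$mu_pos_loc * r, config$mu_pos_scale * r,
                      "pos")
    } else {
      rtruncnorm_sign(1L, -config$mu_neg_loc * r, config$mu_neg_scale * r,
                      "neg")
    }
  }
  mu
}

#' Sample a precision matrix from the G-Wishart distribution
#'
#' Direct sampler: draw an unconstrained Wishart matrix, invert it, and
#' apply the cyclic per-node maximum-determinant completion of the
#' implied covariance over non-neighbor entries (for each node, the
#' covariance column is regressed onto the node's neighbors) until the
#' maximum absolute change is below `tol`; the inverse of the completed
#' covariance is positive definite with exact zeros at the non-edges.
#'
#' @param graph Binary edge vector of length `E`.
#' @param space An [edge_space()].
#' @param df Degrees of freedom (> 2).
#' @param scale `P x P` positive-definite scale matrix (default identity).
#' @param tol Completion convergence tolerance.
#' @param max_cycles Maximum completion cycles.
#' @return A `P x P` positive-definite precision matrix.
#' @export
sample_gwishart <- function(graph, space, df = 3, scale = NULL,
                            tol = 1e-9, max_cycles = 1000L) {
  stopifnot(inherits(space, "edge_space"), df > 2,
            length(graph) == space$E)
  P <- space$P
  if (is.null(scale)) scale <- diag(P)
  # the G-Wishart density is det(K)^((df-2)/2) exp(-tr(K D)/2); on the
  # complete graph this is Wishart(df + P - 1, D^{-1})
  K <- drop(stats::rWishart(1L, df + P - 1, chol2inv(chol(scale))))
  Sigma <- chol2inv(chol(K))
  if (all(graph == 1L)) {
    return(K)  # complete graph: plain Wishart draw, no completion needed
  }
  A <- edges_to_adjacency(graph, space) == 1
  W <- Sigma
  for (cycle in seq_len(max_cycles)) {
    delta <- 0
    for (j in seq_len(P)) {
      nb <- which(A[, j])
      w_new <- numeric(P - 1L)
      if (length(nb)) {
        beta <- solve(W[nb, nb, drop = FALSE], Sigma[nb, j])
        w_new <- drop(W[-j, nb, drop = FALSE] %*% beta)
      }
      delta <- max(delta, max(abs(W[-j, j] - w_new)))
      W[-j, j] <- w_new
      W[j, -j] <- w_new
    }
    if (delta < tol) break
    if (cycle == max_cycles)
      stop("G-Wishart completion did not converge (",
           sum(graph), " of ", space$E, " edges, P = ", P, ")")
  }
  K_G <- chol2inv(chol(W))
  # exact zeros at the non-edges
  Z <- edges_to_adjacency(1 - graph, space) == 1
  K_G[Z] <- 0
  K_G
}

#' Simulate one participant's time series
#'
#' `T` i.i.d. draws from `N(0, Omega^{-1})` via a Cholesky factorization
#' of the covariance.
#'
#' @param Omega Positive-definite precision matrix.
#' @param T Number of time points.
#' @return A `T x P` matrix.
#' @export
simulate_participant_data <- function(Omega, T) {
  P <- nrow(Omega)
  R <- chol(chol2inv(chol(Omega)))   # upper, R'R = Omega^{-1}
  matrix(stats::rnorm(T * P), T, P) %*% R
}

#' Simulate a full multilevel study
#'
#' Chains the generative pipeline: group graph, Curie-Weiss main effects,
#' individual graphs sampled exactly from the Curie-Weiss model,
#' G-Wishart precision matrices supported on each individual graph, and
#' Gaussian time series. With `mixture = TRUE` a second group graph is
#' created by flipping `flip_frac` of the edges of the first, and the
#' participant cohort is split between the two.
#'
#' @param config A [simulation_config()].
#' @return An object of class `simulation_truth`: `group_graph` (and
#'   `group_graph2`, `labels` for mixtures), `mu`, `sigma`,
#'   `individual_graphs` (`N x E`), `precisions` (list of `N` matrices),
#'   `timeseries` (list of `N` `T x P` matrices), `space`, `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  space <- edge_space(config$P)
  E <- space$E
  g1 <- simulate_group_graph(space, config$density)
  mu1 <- simulate_mu(g1, config$rho, config)

  if (config$mixture) {
    flip <- sample.int(E, round(config$flip_frac * E))
    g2 <- g1
    g2[flip] <- 1L - g2[flip]
    # the two groups share the main effects on the unflipped edges, so
    # the subgroups differ systematically on exactly the flipped set
    mu2 <- mu1
    mu2[flip] <- simulate_mu(g2, config$rho, config)[flip]
    labels <- rep(1:2, config$mixture_sizes)
    st1 <- group_state(mu1, config$sigma, space)
    st2 <- group_state(mu2, config$sigma, space)
    gam <- rbind(cw_sample(st1, config$mixture_sizes[1]),
                 cw_sample(st2, config$mixture_sizes[2]))
  } else {
    g2 <- NULL
    labels <- NULL
    st1 <- group_state(mu1, config$sigma, space)
    gam <- cw_sample(st1, config$N)
  }

  precisions <- vector("list", config$N)
  timeseries <- vector("list", config$N)
  for (n in seq_len(config$N)) {
    precisions[[n]] <- sample_gwishart(gam[n, ], space,
                                       df = config$gwishart_df)
    timeseries[[n]] <- simulate_participant_data(precisions[[n]], config$T)
    colnames(timeseries[[n]]) <- paste0("V", seq_len(config$P))
  }
  structure(list(group_graph = g1, group_graph2 = g2, labels = labels,
                 mu = mu1, sigma = config$sigma,
                 individual_graphs = gam, precisions = precisions,
                 timeseries = timeseries, space = space, config = config),
            class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cfg <- x$config
  cat("simulation_truth: N =", cfg$N, "participants, P =", cfg$P,
      "nodes, T =", cfg$T, "time points\n")
  cat("  group density:", mean(x$group_graph),
      " rho =", cfg$rho, " sigma =", cfg$sigma,
      if (cfg$mixture) " (mixture)" else "", "\n")
  invisible(x)
}

#' Write a simulated study to a dataset directory
#'
#' Writes `manifest.tsv` (participant_id, path, T), one time-series TSV
#' per participant (header row of node labels), and a `truth/`
#' subdirectory with the generating group graph(s), main effects,
#' interaction, individual graphs, and mixture labels.
#'
#' @param truth A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(truth, dir) {
  stopifnot(inherits(truth, "simulation_truth"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "series"), showWarnings = FALSE)
  N <- truth$config$N
  ids <- sprintf("p%03d", seq_len(N))
  paths <- file.path("series", paste0(ids, ".tsv"))
  for (n in seq_len(N)) {
    utils::write.table(truth$timeseries[[n]], file.path(dir, paths[n]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- data.frame(participant_id = ids, path = paths,
                         T = truth$config$T)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sp <- truth$space
  edges <- data.frame(edge_id = seq_len(sp$E),
                      node_i = sp$pairs[, 1], node_j = sp$pairs[, 2],
                      included = truth$group_graph)
  utils::write.table(edges, file.path(dir, "truth", "group_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(edge_id = seq_len(sp$E), mu = truth$mu),
                     file.path(dir, "truth", "mu.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(format(truth$sigma), file.path(dir, "truth", "sigma.txt"))
  utils::write.table(cbind(participant_id = ids,
                           as.data.frame(truth$individual_graphs)),
                     file.path(dir, "truth", "individual_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth$labels))
    utils::write.table(data.frame(participant_id = ids,
                                  group = truth$labels),
                       file.path(dir, "truth", "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth$group_graph2)) {
    edges2 <- data.frame(edge_id = seq_len(sp$E),
                         node_i = sp$pairs[, 1], node_j = sp$pairs[, 2],
                         included = truth$group_graph2)
    utils::write.table(edges2, file.path(dir, "truth", "group_edges2.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
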
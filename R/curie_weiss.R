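#' Group-level Curie-Weiss model over edge indicators
#'
#' The group network is a Curie-Weiss model on the `E` binary
#' edge-inclusion indicators: for an edge configuration `gamma` with
#' `s = sum(gamma)` active edges,
#' \deqn{p(\gamma \mid \mu, \sigma) = Z(\mu,\sigma)^{-1}
#'   \exp\{\sum_e \gamma_e \mu_e + (\sigma/E)\, s^2\},}
#' where `mu` is the vector of per-edge main effects (log-odds scale) and
#' `sigma >= 0` is the average pairwise interaction among edges. The
#' interaction enters as `sigma/E` times the squared edge count, so that
#' `sigma` is the *average* interaction per pair and stays comparable
#' across network sizes; the unscaled parameterization is recovered by
#' passing `sigma * E`. At `sigma = 0` the model reduces to independent
#' Bernoulli edges with probabilities `plogis(mu)`.
#'
#' @param mu Numeric vector of length `E` (finite).
#' @param sigma Nonnegative scalar interaction.
#' @param space An [edge_space()].
#' @return An object of class `group_state`.
#' @export
group_state <- function(mu, sigma, space) {
  stopifnot(inherits(space, "edge_space"))
  if (length(mu) == 1L) mu <- rep(as.numeric(mu), space$E)
  if (length(mu) != space$E) stop("'mu' must have length E = ", space$E)
  if (!all(is.finite(mu))) stop("'mu' must be finite")
  if (length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("'sigma' must be a single nonnegative number")
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma),
                 space = space),
            class = "group_state")
}

#' @export
print.group_state <- function(x, ...) {
  cat("group_state: E =", x$space$E, " sigma =", format(x$sigma),
      " mean(mu) =", format(mean(x$mu)), "\n")
  invisible(x)
}

#' Prior on the Curie-Weiss group parameters
#'
#' Independent `N(0, mu_prior_sd^2)` priors on each main effect and a
#' half-normal prior with the given scale on `sigma`.
#'
#' @param mu_prior_sd Prior standard deviation of each `mu_e` (default 10).
#' @param sigma_prior_scale Scale of the half-normal prior on `sigma`
#'   (default 1).
#' @export
group_prior <- function(mu_prior_sd = 10, sigma_prior_scale = 1) {
  stopifnot(mu_prior_sd > 0, is.finite(mu_prior_sd),
            sigma_prior_scale > 0, is.finite(sigma_prior_scale))
  structure(list(mu_prior_sd = mu_prior_sd,
                 sigma_prior_scale = sigma_prior_scale),
            class = "group_prior")
}

gh_nodes <- local({
  cache <- list()
  function(n_quad) {
    key <- as.character(n_quad)
    gh <- cache[[key]]
    if (is.null(gh)) {
      gh <- pracma::gaussHermite(n_quad)
      gh$lw <- log(gh$w)
      cache[[key]] <<- gh
    }
    gh
  }
})

# Adaptive Gauss-Hermite grid for the latent-tilt representation
#   exp(a s^2) = E[exp(s t)],  t ~ N(0, 2a),  a = sigma/E,
# so that Z = int N(t; 0, 2a) prod_e (1 + exp(mu_e + t)) dt.
# The integrand's log, h(t) = -t^2/(2v) + sum_e softplus(mu_e + t) with
# v = 2 sigma/E, has its mode t* in (0, 2 sigma] (t* solves
# t = v sum_e plogis(mu_e + t)); centering the nodes at t* with the
# local Laplace scale keeps the rule accurate even when the tilt moves
# the mass many envelope standard deviations from zero. Returns nodes t
# and log-coefficients lw with log Z = logsumexp(lw + A(t)),
# A(t) = sum_e softplus(mu_e + t).
cw_quad_grid <- function(mu, sigma, E, n_quad = 64L) {
  gh <- gh_nodes(n_quad)
  v <- 2 * sigma / E
  hp <- function(t) -t / v + sum(stats::plogis(mu + t))
  t_hi <- 2 * sigma + 10 * sqrt(v)
  t_star <- if (hp(0) <= 0) 0 else
    stats::uniroot(hp, c(0, t_hi), tol = 1e-12)$root
  p <- stats::plogis(mu + t_star)
  curv <- 1 / v - sum(p * (1 - p))
  s <- if (curv > 0) min(1 / sqrt(curv), 100 * (sqrt(v) + sigma)) else
    sqrt(v) + sigma
  t <- t_star + sqrt(2) * s * gh$x
  lw <- gh$lw + gh$x^2 + 0.5 * log(2) + log(s) +
    stats::dnorm(t, 0, sqrt(v), log = TRUE)
  list(t = t, lw = lw)
}

#' Log normalizing constant of the Curie-Weiss model
#'
#' Two independent routes to `log Z(mu, sigma)`:
#' * `"count_dp"`: `log sum_k exp((sigma/E) k^2) e_k(exp(mu))`, where
#'   `e_k` is the k-th elementary symmetric polynomial, accumulated by a
#'   log-stable O(E^2) recurrence;
#' * `"quadrature"`: Gauss-Hermite quadrature of
#'   `int N(t; 0, 2 sigma/E) prod_e (1 + exp(mu_e + t)) dt`, using the
#'   Gaussian identity `exp(a s^2) = E[exp(s t)]` with `t ~ N(0, 2a)`.
#'
#' Both reduce to `sum(softplus(mu))` at `sigma = 0`.
#'
#' @param state A [group_state()].
#' @param method `"count_dp"` or `"quadrature"`.
#' @param n_quad Number of Gauss-Hermite nodes (quadrature method).
#' @return The scalar `log Z`.
#' @export
cw_log_z <- function(state, method = c("quadrature", "count_dp"),
                     n_quad = 64L) {
  stopifnot(inherits(state, "group_state"))
  method <- match.arg(method)
  E <- state$space$E
  mu <- state$mu
  sigma <- state$sigma
  if (sigma == 0) return(sum(softplus(mu)))
  if (method == "count_dp") {
    # log elementary symmetric polynomials of exp(mu)
    le <- c(0, rep(-Inf, E))
    for (m in mu) {
      le[2:(E + 1)] <- logaddexp(le[2:(E + 1)], m + le[1:E])
    }
    k <- 0:E
    logsumexp((sigma / E) * k^2 + le)
  } else {
    g <- cw_quad_grid(mu, sigma, E, n_quad)
    a <- vapply(g$t, function(t) sum(softplus(mu + t)), 0)
    logsumexp(g$lw + a)
  }
}

#' Curie-Weiss log probability mass
#'
#' @param gamma Binary edge vector of length `E`.
#' @param state A [group_state()].
#' @param ... Passed to [cw_log_z()].
#' @return The log probability of the configuration.
#' @export
cw_log_pmf <- function(gamma, state, ...) {
  stopifnot(inherits(state, "group_state"))
  if (length(gamma) != state$space$E)
    stop("'gamma' must have length E = ", state$space$E)
  s <- sum(gamma)
  sum(gamma * state$mu) + state$sigma / state$space$E * s^2 -
    cw_log_z(state, ...)
}

#' Full-conditional log-odds of each edge indicator
#'
#' `log[p(gamma_e = 1 | gamma_-e) / p(gamma_e = 0 | gamma_-e)]
#'  = mu_e + (sigma/E) (2 s_-e + 1)` where `s_-e` counts the active edges
#' excluding `e`; the normalizing constant cancels. This is also the prior
#' edge log-odds fed to each participant's graphical-model update in the
#' multilevel sampler.
#'
#' @param gamma Binary edge vector (the conditioning state, including `e`;
#'   its own entry is excluded via `s_-e`).
#' @param state A [group_state()].
#' @param e Optional edge id(s); default all edges.
#' @return Numeric vector of conditional log-odds.
#' @export
cw_conditional_logodds <- function(gamma, state, e = NULL) {
  stopifnot(inherits(state, "group_state"))
  if (length(gamma) != state$space$E)
    stop("'gamma' must have length E = ", state$space$E)
  E <- state$space$E
  s_minus <- sum(gamma) - gamma
  lo <- state$mu + state$sigma / E * (2 * s_minus + 1)
  if (is.null(e)) lo else lo[e]
}

#' Marginal edge-inclusion probabilities of the Curie-Weiss model
#'
#' `P(gamma_e = 1 | mu, sigma)`, computed by tilted quadrature: the latent
#' tilt `t` has density proportional to
#' `N(t; 0, 2 sigma/E) prod_e (1 + exp(mu_e + t))`, and conditionally on
#' `t` the edges are independent `Bernoulli(plogis(mu_e + t))`.
#'
#' @param state A [group_state()].
#' @param n_quad Number of Gauss-Hermite nodes.
#' @return Probability vector of length `E`.
#' @export
cw_marginal_probs <- function(state, n_quad = 64L) {
  stopifnot(inherits(state, "group_state"))
  if (state$sigma == 0) return(stats::plogis(state$mu))
  E <- state$space$E
  g <- cw_quad_grid(state$mu, state$sigma, E, n_quad)
  a <- vapply(g$t, function(t) sum(softplus(state$mu + t)), 0)
  lw <- g$lw + a
  w <- exp(lw - logsumexp(lw))
  drop(stats::plogis(outer(state$mu, g$t, "+")) %*% w)
}

#' Exact sampling from the Curie-Weiss model
#'
#' Draws i.i.d. configurations via the latent-tilt mixture: sample `t`
#' from the 1-D tilt density (grid inverse-CDF with linear interpolation),
#' then each edge independently `Bernoulli(plogis(mu_e + t))`.
#'
#' @param state A [group_state()].
#' @param n Number of draws.
#' @param grid_points Size of the inverse-CDF grid.
#' @return An `n x E` integer 0/1 matrix, one configuration per row.
#' @export
cw_sample <- function(state, n, grid_points = 2049L) {
  stopifnot(inherits(state, "group_state"), n >= 1L)
  E <- state$space$E
  mu <- state$mu
  sigma <- state$sigma
  if (sigma == 0) {
    p <- stats::plogis(mu)
    return(matrix(stats::rbinom(n * E, 1L, rep(p, each = n)), n, E))
  }
  v <- 2 * sigma / E
  sd <- sqrt(v)
  # the tilt mode solves t = v * sum(plogis(mu + t)) and lies in [0, 2 sigma]
  lo <- min(-8 * sd, min(-mu))
  hi <- max(2 * sigma + 8 * sd, max(-mu))
  tg <- seq(lo, hi, length.out = grid_points)
  ld <- -tg^2 / (2 * v) + vapply(tg, function(t) sum(softplus(mu + t)), 0)
  d <- exp(ld - max(ld))
  # trapezoid CDF with linear inverse
  cdf <- c(0, cumsum((d[-1] + d[-length(d)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  t_draw <- stats::approx(cdf, tg, xout = u, ties = "ordered")$y
  p <- stats::plogis(outer(t_draw, mu, "+"))
  matrix(stats::rbinom(n * E, 1L, p), n, E)
}

# Adaptive Metropolis tuning state for the group update: log proposal sds
# for each mu_e and for log sigma, Robbins-Monro adapted toward 0.44
# acceptance while 'adapt' is TRUE, plus running acceptance counts.
cw_tuning <- function(E, init_sd = 0.5) {
  tun <- new.env(parent = emptyenv())
  tun$log_sd_mu <- rep(log(init_sd), E)
  tun$log_sd_sigma <- log(init_sd)
  tun$log_sd_shift <- log(init_sd)
  tun$log_sd_ridge <- log(init_sd)
  tun$ridge_c <- 1
  tun$sweep <- 0L
  tun$acc_mu <- 0
  tun$prop_mu <- 0
  tun$acc_sigma <- 0
  tun$prop_sigma <- 0
  tun$acc_shift <- 0
  tun$prop_shift <- 0
  tun
}

#' One Metropolis-within-Gibbs sweep over the group parameters
#'
#' Updates `(mu, sigma)` given `N` sampled edge configurations: a
#' random-walk Metropolis step for each `mu_e` (normal prior) and one for
#' `log sigma` (half-normal prior on `sigma`), with the likelihood
#' `prod_n exp(gamma_n' mu + (sigma/E) s_n^2) / Z(mu, sigma)^N` and
#' `log Z` evaluated by Gauss-Hermite quadrature. Per-node quadrature
#' log-sums are cached so a single `mu_e` proposal costs O(Q) and a
#' `sigma` proposal O(EQ). Proposal scales adapt toward 0.44 acceptance
#' (Robbins-Monro) while `adapt = TRUE` and are frozen afterwards.
#'
#' @param gammas `N x E` binary matrix of edge configurations.
#' @param state A [group_state()].
#' @param prior A [group_prior()].
#' @param tuning Tuning environment from `cw_tuning()`; created if `NULL`.
#' @param adapt Adapt proposal scales this sweep?
#' @param n_quad Number of Gauss-Hermite nodes.
#' @param n_global Repetitions per sweep of the global moves (the
#'   `sigma` walk, a joint translation of all `mu_e`, and a correlated
#'   `sigma`-plus-translation "ridge" move); these target the slowest
#'   posterior directions and cost O(EQ) each.
#' @return A list with the updated `state` and the `tuning` environment.
#' @export
cw_update_params <- function(gammas, state, prior = group_prior(),
                             tuning = NULL, adapt = FALSE, n_quad = 64L,
                             n_global = 5L) {
  stopifnot(inherits(state, "group_state"), inherits(prior, "group_prior"))
  gammas <- as.matrix(gammas)
  E <- state$space$E
  if (ncol(gammas) != E) stop("'gammas' must have E = ", E, " columns")
  N <- nrow(gammas)
  if (is.null(tuning)) tuning <- cw_tuning(E)
  tuning$sweep <- tuning$sweep + 1L
  rm_gain <- function() tuning$sweep^(-0.6)

  mu <- state$mu
  sigma <- state$sigma
  m_e <- colSums(gammas)            # sufficient stat for mu
  q <- sum(rowSums(gammas)^2)       # sufficient stat for sigma

  grid <- cw_quad_grid(mu, max(sigma, 1e-12), E, n_quad)
  sp_mat <- outer_softplus(mu, grid$t)       # E x Q
  A <- colSums(sp_mat)                       # per-node log products
  log_z <- logsumexp(grid$lw + A)
  if (!is.finite(log_z))
    stop("non-finite Curie-Weiss likelihood at sigma = ", sigma)

  # --- mu updates -----------------------------------------------------
  sds <- exp(tuning$log_sd_mu)
  steps <- stats::rnorm(E, 0, sds)
  log_us <- log(stats::runif(E))
  n_acc <- 0
  for (e in seq_len(E)) {
    mu_new <- mu[e] + steps[e]
    sp_new <- softplus(mu_new + grid$t)
    A_new <- A - sp_mat[e, ] + sp_new
    log_z_new <- logsumexp(grid$lw + A_new)
    log_ratio <- (mu_new - mu[e]) * m_e[e] - N * (log_z_new - log_z) +
      stats::dnorm(mu_new, 0, prior$mu_prior_sd, log = TRUE) -
      stats::dnorm(mu[e], 0, prior$mu_prior_sd, log = TRUE)
    if (is.finite(log_ratio) && log_us[e] < log_ratio) {
      mu[e] <- mu_new
      sp_mat[e, ] <- sp_new
      A <- A_new
      log_z <- log_z_new
      n_acc <- n_acc + 1
    }
    if (adapt)
      tuning$log_sd_mu[e] <- tuning$log_sd_mu[e] +
        rm_gain() * ((log_us[e] < log_ratio && is.finite(log_ratio)) - 0.44)
  }
  tuning$prop_mu <- tuning$prop_mu + E
  tuning$acc_mu <- tuning$acc_mu + n_acc

  # --- global moves ---------------------------------------------------
  # Repeated each sweep: they cost O(EQ) apiece, far less than the E
  # componentwise updates, and they govern the slowest posterior
  # directions.
  for (g in seq_len(n_global)) {
    # (1) random walk on log sigma (half-normal prior + Jacobian)
    ls <- log(max(sigma, 1e-12))
    ls_new <- ls + stats::rnorm(1, 0, exp(tuning$log_sd_sigma))
    sigma_new <- exp(ls_new)
    grid_new <- cw_quad_grid(mu, sigma_new, E, n_quad)
    A_new <- colSums(outer_softplus(mu, grid_new$t))
    log_z_new <- logsumexp(grid_new$lw + A_new)
    log_ratio <- (sigma_new - sigma) / E * q - N * (log_z_new - log_z) +
      (-sigma_new^2 + sigma^2) / (2 * prior$sigma_prior_scale^2) +
      (ls_new - ls)
    acc <- is.finite(log_ratio) && log(stats::runif(1)) < log_ratio
    if (acc) {
      sigma <- sigma_new
      grid <- grid_new
      A <- A_new
      log_z <- log_z_new
    }
    if (adapt)
      tuning$log_sd_sigma <- tuning$log_sd_sigma + rm_gain() * (acc - 0.44)
    tuning$prop_sigma <- tuning$prop_sigma + 1
    tuning$acc_sigma <- tuning$acc_sigma + acc

    # (2) joint translation of mu: the latent tilt can absorb a common
    # shift of the main effects, leaving a near-flat direction
    delta <- stats::rnorm(1, 0, exp(tuning$log_sd_shift))
    mu_new <- mu + delta
    A_new <- colSums(outer_softplus(mu_new, grid$t))
    log_z_new <- logsumexp(grid$lw + A_new)
    log_ratio <- delta * sum(m_e) - N * (log_z_new - log_z) +
      sum(stats::dnorm(mu_new, 0, prior$mu_prior_sd, log = TRUE) -
            stats::dnorm(mu, 0, prior$mu_prior_sd, log = TRUE))
    acc <- is.finite(log_ratio) && log(stats::runif(1)) < log_ratio
    if (acc) {
      mu <- mu_new
      A <- A_new
      log_z <- log_z_new
    }
    if (adapt)
      tuning$log_sd_shift <- tuning$log_sd_shift + rm_gain() * (acc - 0.44)
    tuning$prop_shift <- tuning$prop_shift + 1
    tuning$acc_shift <- tuning$acc_shift + acc

    # (3) ridge move: sigma together with a compensating mu translation.
    # Increasing sigma raises the typical tilt t* ~ (2 sigma/E) sum(p);
    # centering the shift at -c (sigma' - sigma) follows that ridge. c is
    # a per-step constant (adapted during burn-in, frozen after), so the
    # joint proposal is symmetric and detailed balance holds.
    if (adapt) {
      v <- 2 * sigma / E
      p <- stats::plogis(mu + v * sum(stats::plogis(mu)))
      denom <- max(1 - v * sum(p * (1 - p)), 0.1)
      tuning$ridge_c <- max(2 * mean(p) / denom, 0)
    }
    c_r <- tuning$ridge_c
    ls <- log(max(sigma, 1e-12))
    ls_new <- ls + stats::rnorm(1, 0, exp(tuning$log_sd_ridge))
    sigma_new <- exp(ls_new)
    delta <- -c_r * (sigma_new - sigma) +
      stats::rnorm(1, 0, 0.25 * exp(tuning$log_sd_ridge))
    mu_new <- mu + delta
    grid_new <- cw_quad_grid(mu_new, sigma_new, E, n_quad)
    A_new <- colSums(outer_softplus(mu_new, grid_new$t))
    log_z_new <- logsumexp(grid_new$lw + A_new)
    log_ratio <- delta * sum(m_e) + (sigma_new - sigma) / E * q -
      N * (log_z_new - log_z) +
      sum(stats::dnorm(mu_new, 0, prior$mu_prior_sd, log = TRUE) -
            stats::dnorm(mu, 0, prior$mu_prior_sd, log = TRUE)) +
      (-sigma_new^2 + sigma^2) / (2 * prior$sigma_prior_scale^2) +
      (ls_new - ls)
    acc <- is.finite(log_ratio) && log(stats::runif(1)) < log_ratio
    if (acc) {
      mu <- mu_new
      sigma <- sigma_new
      grid <- grid_new
      A <- A_new
      log_z <- log_z_new
    }
    if (adapt)
      tuning$log_sd_ridge <- tuning$log_sd_ridge + rm_gain() * (acc - 0.44)
  }

  list(state = group_state(mu, sigma, state$space), tuning = tuning)
}

# softplus(mu_e + t_i) as an E x Q matrix
outer_softplus <- function(mu, t) {
  x <- outer(mu, t, "+")
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Posterior sampling of the group parameters from fixed configurations
#'
#' Convenience driver running [cw_update_params()] for `iterations`
#' sweeps (adapting during `burnin`) on a fixed set of edge
#' configurations, e.g. to recover `(mu, sigma)` from simulated networks.
#'
#' @param gammas `N x E` binary matrix.
#' @param space An [edge_space()].
#' @param prior A [group_prior()].
#' @param iterations,burnin Total and discarded sweeps.
#' @param init Optional initial [group_state()].
#' @param n_quad Number of Gauss-Hermite nodes.
#' @return A list with posterior draw matrices `mu` (retained sweeps x E)
#'   and `sigma`, posterior means/sds, and final acceptance rates.
#' @export
cw_fit_group <- function(gammas, space, prior = group_prior(),
                         iterations = 2000L, burnin = 500L, init = NULL,
                         n_quad = 64L) {
  stopifnot(burnin < iterations)
  gammas <- as.matrix(gammas)
  state <- if (is.null(init)) group_state(0, 0.1, space) else init
  tuning <- cw_tuning(space$E)
  n_keep <- iterations - burnin
  mu_draws <- matrix(NA_real_, n_keep, space$E)
  sigma_draws <- numeric(n_keep)
  for (it in seq_len(iterations)) {
    res <- cw_update_params(gammas, state, prior, tuning,
                            adapt = it <= burnin, n_quad = n_quad)
    state <- res$state
    if (it > burnin) {
      mu_draws[it - burnin, ] <- state$mu
      sigma_draws[it - burnin] <- state$sigma
    }
  }
  list(mu = mu_draws, sigma = sigma_draws,
       mu_mean = colMeans(mu_draws), mu_sd = apply(mu_draws, 2, stats::sd),
       sigma_mean = mean(sigma_draws), sigma_sd = stats::sd(sigma_draws),
       acc_mu = tuning$acc_mu / tuning$prop_mu,
       acc_sigma = tuning$acc_sigma / tuning$prop_sigma,
       final_state = state)
}
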
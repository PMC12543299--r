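#' Configuration of a model fit
#'
#' @param iterations Total Gibbs sweeps per chain.
#' @param burnin Discarded sweeps (adaptation happens here).
#' @param chains Number of independent chains.
#' @param seed Master seed; together with the configuration it fully
#'   determines every output.
#' @param method `"multilevel"`, `"individual"`, or `"aggregate"`.
#' @param hyper A [spike_slab_hyper()].
#' @param prior A [group_prior()].
#' @param standardize Standardize node series (applied in
#'   [prepare_data()] / [read_dataset()]).
#' @param parallel_workers Accepted for interface compatibility; each
#'   participant consumes its own RNG substream, so results are identical
#'   for any worker count (updates are executed sequentially).
#' @param n_quad Gauss-Hermite nodes for the Curie-Weiss quadrature.
#' @export
fit_config <- function(iterations = 2000L, burnin = 500L, chains = 2L,
                       seed = 1L,
                       method = c("multilevel", "individual", "aggregate"),
                       hyper = spike_slab_hyper(), prior = group_prior(),
                       standardize = TRUE, parallel_workers = 1L,
                       n_quad = 64L) {
  method <- match.arg(method)
  stopifnot(burnin < iterations, burnin >= 0, chains >= 1)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), chains = as.integer(chains),
                 seed = as.integer(seed), method = method, hyper = hyper,
                 prior = prior, standardize = standardize,
                 parallel_workers = as.integer(parallel_workers),
                 n_quad = as.integer(n_quad)),
            class = "fit_config")
}

# One chain of the (possibly group-frozen) Gibbs sampler.
# data_list: list of participant_data sharing P. frozen_group: NULL for the
# multilevel model, else a group_state held fixed (individual baseline uses
# mu = 0, sigma = 0).
run_chain <- function(data_list, config, space, streams, store,
                      frozen_group = NULL) {
  N <- length(data_list)
  E <- space$E
  it_total <- config$iterations
  burnin <- config$burnin
  n_keep <- it_total - burnin

  states <- lapply(seq_len(N), function(n) precision_state(space))
  tb <- edge_tables(space)
  hy <- config$hyper
  zero_lo <- numeric(E)
  multilevel <- is.null(frozen_group)
  group <- if (multilevel) group_state(0, 0.1, space) else frozen_group
  tuning <- cw_tuning(E)
  gam <- matrix(0L, N, E)

  mu_draws <- if (multilevel) matrix(NA_real_, n_keep, E) else NULL
  sigma_draws <- if (multilevel) rep(NA_real_, n_keep) else NULL
  marg_sum <- numeric(E)

  for (it in seq_len(it_total)) {
    if (multilevel) {
      s_row <- rowSums(gam)
      coef <- group$sigma / E
      # participant-specific Curie-Weiss full-conditional log-odds
      lo_mat <- matrix(group$mu, N, E, byrow = TRUE) +
        coef * (2 * (s_row - gam) + 1)
    }
    for (n in seq_len(N)) {
      lo <- if (multilevel) lo_mat[n, ] else zero_lo
      res <- with_stream(streams[[n]],
                         ggm_sweep_cpp(states[[n]]$Omega, states[[n]]$gamma,
                                       data_list[[n]]$U, data_list[[n]]$T,
                                       hy$v0, hy$v1, hy$lambda, lo,
                                       tb$pairs0, tb$eid0, 1L))
      states[[n]]$Omega <- res$value$Omega
      states[[n]]$gamma <- res$value$gamma
      streams[[n]] <- res$stream
      gam[n, ] <- res$value$gamma
    }
    if (multilevel) {
      res <- with_stream(streams[[N + 1L]],
                         cw_update_params(gam, group, config$prior, tuning,
                                          adapt = it <= burnin,
                                          n_quad = config$n_quad))
      group <- res$value$state
      streams[[N + 1L]] <- res$stream
    }
    if (it > burnin) {
      pcor <- t(vapply(states, function(s)
        partial_correlations(s$Omega, space), numeric(E)))
      store_append(store, gam, pcor,
                   mu = if (multilevel) group$mu,
                   sigma = if (multilevel) group$sigma)
      if (multilevel) {
        k <- it - burnin
        mu_draws[k, ] <- group$mu
        sigma_draws[k] <- group$sigma
        marg_sum <- marg_sum + cw_marginal_probs(group, config$n_quad)
      }
    }
  }
  list(mu_draws = mu_draws, sigma_draws = sigma_draws,
       marg_sum = marg_sum, tuning = tuning, final_group = group)
}

finish_fit <- function(method, data_list, config, space, store, chains_out,
                       individual_probs = NULL, group_probs = NULL) {
  summ <- posterior_summary(store)
  if (is.null(individual_probs)) individual_probs <- summ$prob
  multilevel <- method == "multilevel"
  n_keep <- config$iterations - config$burnin
  if (multilevel) {
    group_probs <- Reduce(`+`, lapply(chains_out, `[[`, "marg_sum")) /
      (config$chains * n_keep)
    mu_all <- do.call(rbind, lapply(chains_out, `[[`, "mu_draws"))
    sigma_all <- unlist(lapply(chains_out, `[[`, "sigma_draws"))
    mu_mean <- colMeans(mu_all)
    mu_sd <- apply(mu_all, 2, stats::sd)
    sigma_mean <- mean(sigma_all)
    sigma_sd <- stats::sd(sigma_all)
    rhat <- split_rhat(lapply(chains_out, function(ch)
      cbind(ch$mu_draws, sigma = ch$sigma_draws)))
    names(rhat) <- c(paste0("mu_", seq_len(space$E)), "sigma")
    tun <- chains_out[[1]]$tuning
    acc <- c(mu = tun$acc_mu / max(tun$prop_mu, 1),
             sigma = tun$acc_sigma / max(tun$prop_sigma, 1))
  } else {
    if (is.null(group_probs)) group_probs <- colMeans(individual_probs)
    mu_mean <- mu_sd <- NULL
    sigma_mean <- sigma_sd <- NULL
    rhat <- NULL
    acc <- NULL
  }
  structure(list(method = method, store = store,
                 group_probs = group_probs,
                 individual_probs = individual_probs,
                 pcor_mean = summ$pcor_mean, prob_sd = summ$sd,
                 mu_mean = mu_mean, mu_sd = mu_sd,
                 sigma_mean = sigma_mean, sigma_sd = sigma_sd,
                 rhat = rhat, acceptance = acc, space = space,
                 config = config,
                 participant_ids = vapply(data_list, function(d)
                   if (is.null(d$id)) "" else as.character(d$id), "")),
            class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  cat("ml_fit (", x$method, "): ", nrow(x$individual_probs),
      " participants, ", x$space$P, " nodes, ",
      x$config$chains, " chain(s) x ", x$config$iterations,
      " sweeps (burnin ", x$config$burnin, ")\n", sep = "")
  if (!is.null(x$rhat))
    cat("  max split-Rhat (Curie-Weiss parameters):",
        format(max(x$rhat), digits = 4), "\n")
  invisible(x)
}

check_shared_P <- function(data_list) {
  Ps <- vapply(data_list, function(d) d$P, 0L)
  if (length(unique(Ps)) != 1L)
    stop("all participants must share the same number of nodes; got ",
         paste(unique(Ps), collapse = ", "))
  Ps[1]
}

#' Fit the multilevel model
#'
#' Alternates (a) one spike-and-slab Gibbs sweep per participant, with
#' prior edge log-odds given by the Curie-Weiss full conditional under
#' the current group state and the participant's own indicators, and
#' (b) one Metropolis-within-Gibbs sweep over the group parameters given
#' all indicator vectors. Participants are conditionally independent
#' given the group, and each consumes a dedicated RNG substream, so the
#' result is invariant to update scheduling and worker count.
#'
#' @param data_list List of [prepare_data()] objects sharing `P`.
#' @param config A [fit_config()].
#' @return An object of class `ml_fit` with per-edge posterior summaries
#'   at both levels: `individual_probs` (`N x E` inclusion
#'   probabilities), `pcor_mean`, `group_probs` (posterior mean of the
#'   Curie-Weiss marginal inclusion probabilities), `mu_mean`, `mu_sd`,
#'   `sigma_mean`, `sigma_sd`, split-`rhat` for all Curie-Weiss
#'   parameters, and the bit-packed `store` of indicator draws.
#' @export
fit_multilevel <- function(data_list, config = fit_config()) {
  P <- check_shared_P(data_list)
  space <- edge_space(P)
  N <- length(data_list)
  streams <- make_streams(config$seed, config$chains * (N + 1L))
  store <- posterior_store(N, space)
  chains_out <- lapply(seq_len(config$chains), function(ch) {
    idx <- (ch - 1L) * (N + 1L) + seq_len(N + 1L)
    run_chain(data_list, config, space, streams[idx], store)
  })
  finish_fit("multilevel", data_list, config, space, store, chains_out)
}

#' Fit each participant independently (baseline)
#'
#' Identical to the multilevel sampler with the group state frozen at
#' `mu = 0`, `sigma = 0` (prior edge-inclusion probability one half for
#' every participant) and no group update. The `group_probs` reported are
#' the across-participant means of the individual inclusion
#' probabilities, used only for group-recovery comparisons.
#'
#' @inheritParams fit_multilevel
#' @export
fit_individual <- function(data_list, config = fit_config()) {
  P <- check_shared_P(data_list)
  space <- edge_space(P)
  N <- length(data_list)
  streams <- make_streams(config$seed, config$chains * (N + 1L))
  store <- posterior_store(N, space)
  frozen <- group_state(0, 0, space)
  chains_out <- lapply(seq_len(config$chains), function(ch) {
    idx <- (ch - 1L) * (N + 1L) + seq_len(N + 1L)
    run_chain(data_list, config, space, streams[idx], store,
              frozen_group = frozen)
  })
  finish_fit("individual", data_list, config, space, store, chains_out)
}

#' Fit a single aggregated model (baseline)
#'
#' Aggregates by averaging the per-participant sample precision matrices
#' `(U_n / T_n)^{-1}`, inverting the average to a surrogate covariance,
#' and fitting one spike-and-slab GGM (prior edge log-odds 0) on the
#' surrogate scatter `T_eff * C` with `T_eff = round(mean(T_n))`. A small
#' ridge `1e-3 tr(U_n/T_n)/P` is added only when a sample covariance is
#' not invertible (e.g. `T_n <= P`). Every participant is assigned the
#' same fitted network.
#'
#' @inheritParams fit_multilevel
#' @param t_eff Override for the surrogate observation count.
#' @export
fit_aggregate <- function(data_list, config = fit_config(), t_eff = NULL) {
  P <- check_shared_P(data_list)
  space <- edge_space(P)
  N <- length(data_list)
  agg <- aggregate_data(data_list, t_eff)
  streams <- make_streams(config$seed, config$chains * 2L)
  store <- posterior_store(1L, space)
  frozen <- group_state(0, 0, space)
  chains_out <- lapply(seq_len(config$chains), function(ch) {
    idx <- (ch - 1L) * 2L + 1:2
    run_chain(list(agg), config, space, streams[idx], store,
              frozen_group = frozen)
  })
  probs1 <- posterior_summary(store)$prob
  fit <- finish_fit("aggregate", list(agg), config, space, store,
                    chains_out,
                    individual_probs =
                      matrix(probs1, N, space$E, byrow = TRUE),
                    group_probs = drop(probs1))
  fit$pcor_mean <- matrix(fit$pcor_mean, N, space$E, byrow = TRUE)
  fit
}

# Average the per-participant sample precision matrices and build the
# surrogate single-participant scatter for the aggregate baseline.
aggregate_data <- function(data_list, t_eff = NULL) {
  P <- data_list[[1]]$P
  N <- length(data_list)
  prec <- lapply(data_list, function(d) {
    S <- d$U / d$T
    K <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
    if (is.null(K)) {
      S <- S + diag(1e-3 * sum(diag(S)) / P, P)
      K <- tryCatch(chol2inv(chol(S)), error = function(e)
        stop("sample covariance is singular even after ridging; ",
             "consider a larger ridge"))
    }
    K
  })
  K_bar <- Reduce(`+`, prec) / N
  C <- tryCatch(chol2inv(chol(K_bar)), error = function(e)
    stop("averaged precision matrix is singular; consider a larger ridge"))
  if (is.null(t_eff))
    t_eff <- round(mean(vapply(data_list, function(d) d$T, 0)))
  structure(list(X = NULL, U = t_eff * C, T = t_eff, P = P,
                 labels = data_list[[1]]$labels, id = "aggregate",
                 precision_mean = K_bar),
            class = "participant_data")
}

#' Split-chain potential scale reduction diagnostic
#'
#' Each chain is split in half; the statistic compares between- and
#' within-half variances, `sqrt(((n-1)/n W + B/n) / W)`. Values near 1
#' indicate convergence (criterion used here: below 1.05). Parameters
#' with zero variance everywhere are reported as 1.
#'
#' @param chains A list of chains: numeric vectors, or matrices with one
#'   column per parameter (draws in rows).
#' @return Named numeric vector of per-parameter statistics.
#' @export
split_rhat <- function(chains) {
  if (!is.list(chains)) chains <- list(chains)
  chains <- lapply(chains, function(ch) {
    if (is.null(dim(ch))) matrix(ch, ncol = 1L) else as.matrix(ch)
  })
  n <- unique(vapply(chains, nrow, 0L))
  if (length(n) != 1L)
    stop("all chains must have the same number of draws")
  if (n < 4L)
    stop("split-Rhat needs at least 4 draws per chain")
  half <- n %/% 2L
  halves <- list()
  for (ch in chains) {
    halves <- c(halves, list(ch[seq_len(half), , drop = FALSE],
                             ch[seq.int(n - half + 1L, n), , drop = FALSE]))
  }
  m <- length(halves)
  means <- vapply(halves, colMeans, numeric(ncol(halves[[1]])))
  vars <- vapply(halves, function(h) apply(h, 2, stats::var),
                 numeric(ncol(halves[[1]])))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1L)
    vars <- matrix(vars, nrow = 1L)
  }
  W <- rowMeans(vars)
  B <- half * apply(means, 1, stats::var)
  out <- sqrt(((half - 1) / half * W + B / half) / W)
  out[W == 0 & B == 0] <- 1
  out[W == 0 & B > 0] <- Inf
  out
}
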
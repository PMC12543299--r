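#' Spike-and-slab hyperparameters for the precision prior
#'
#' Off-diagonal precision elements have a two-component normal prior:
#' a narrow spike `N(0, v0^2)` shrinking the element to near zero and a
#' wide slab `N(0, v1^2)`, selected by the binary edge indicator. The
#' diagonal has an exponential prior governed by `lambda` (rate
#' `lambda/2`, the parameterization under which the column-wise Gibbs
#' conditionals below are exact).
#'
#' @param v0 Spike standard deviation (default 0.02).
#' @param v1 Slab standard deviation (default 1). Must exceed `v0`.
#' @param lambda Diagonal exponential hyperparameter (default 1).
#' @export
spike_slab_hyper <- function(v0 = 0.02, v1 = 1, lambda = 1) {
  stopifnot(v0 > 0, v1 > v0, lambda > 0)
  structure(list(v0 = v0, v1 = v1, lambda = lambda),
            class = "spike_slab_hyper")
}

#' Prepare one participant's time series for the GGM
#'
#' Centers each column (node) to mean zero and, when `standardize` is on,
#' scales it to unit variance (maximum-likelihood convention, denominator
#' `T`). Stores the scatter matrix `U = X'X = T * S` where `S` is the
#' sample covariance of the centered series.
#'
#' @param raw A `T x P` numeric matrix; rows are time points.
#' @param standardize Scale columns to unit sample variance? Default TRUE.
#' @param id Optional participant id carried through to outputs.
#' @return An object of class `participant_data` with elements `X`, `U`,
#'   `T`, `P`, `labels`, `id`.
#' @export
prepare_data <- function(raw, standardize = TRUE, id = NULL) {
  raw <- as.matrix(raw)
  if (nrow(raw) < 2L) stop("need at least T = 2 time points")
  if (ncol(raw) < 2L) stop("need at least P = 2 nodes")
  if (!all(is.finite(raw))) stop("time series contains non-finite values")
  labels <- colnames(raw)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(raw)))
  X <- scale(raw, center = TRUE, scale = FALSE)
  if (standardize) {
    s <- sqrt(colMeans(X^2))
    bad <- which(s == 0)
    if (length(bad))
      stop("cannot standardize constant column(s): ",
           paste(labels[bad], collapse = ", "))
    X <- sweep(X, 2L, s, "/")
  }
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  structure(list(X = X, U = crossprod(X), T = nrow(X), P = ncol(X),
                 labels = labels, id = id),
            class = "participant_data")
}

#' @export
print.participant_data <- function(x, ...) {
  cat("participant_data:", x$T, "time points x", x$P, "nodes",
      if (!is.null(x$id)) paste0("(", x$id, ")"), "\n")
  invisible(x)
}

#' Gaussian graphical model log-likelihood
#'
#' `-(TP/2) log 2 pi + (T/2) log det(Omega) - tr(Omega U)/2`, the
#' multivariate-normal log-likelihood of the centered series under
#' precision matrix `Omega`.
#'
#' @param data A [prepare_data()] object (or any list with `U`, `T`, `P`).
#' @param Omega A `P x P` positive-definite precision matrix.
#' @export
ggm_log_likelihood <- function(data, Omega) {
  R <- tryCatch(chol(Omega), error = function(e)
    stop("'Omega' is not positive definite"))
  -data$T * data$P / 2 * log(2 * pi) + data$T * sum(log(diag(R))) -
    sum(Omega * data$U) / 2
}

#' Precision-matrix state of one participant
#'
#' Bundles the precision matrix and its edge indicators; initialized at
#' the identity with an empty graph.
#'
#' @param space An [edge_space()].
#' @param Omega Optional initial precision matrix (default identity).
#' @param gamma Optional initial indicator vector (default all zero).
#' @export
precision_state <- function(space, Omega = NULL, gamma = NULL) {
  stopifnot(inherits(space, "edge_space"))
  if (is.null(Omega)) Omega <- diag(space$P)
  if (is.null(gamma)) gamma <- integer(space$E)
  stopifnot(nrow(Omega) == space$P, length(gamma) == space$E)
  structure(list(Omega = Omega, gamma = as.integer(gamma), space = space),
            class = "precision_state")
}

# 0-based lookup tables for the C++ kernels
edge_tables <- function(space) {
  list(pairs0 = space$pairs - 1L,
       eid0 = matrix(as.integer(edges_to_adjacency(seq_len(space$E), space) - 1),
                     space$P, space$P))
}

#' Gibbs update of the edge indicators given the precision matrix
#'
#' Each indicator is drawn independently with log-odds equal to the slab
#' vs. spike log-density ratio at the current off-diagonal element plus
#' the prior edge log-odds (the Curie-Weiss full conditional in the
#' multilevel sampler, zero for an individual-only fit).
#'
#' @param state A [precision_state()].
#' @param hyper A [spike_slab_hyper()].
#' @param prior_logodds Scalar or length-`E` vector of prior log-odds.
#' @return The updated `precision_state`.
#' @export
sample_edge_indicators <- function(state, hyper, prior_logodds = 0) {
  stopifnot(inherits(state, "precision_state"),
            inherits(hyper, "spike_slab_hyper"))
  lo <- rep_len(as.numeric(prior_logodds), state$space$E)
  if (anyNA(lo)) stop("'prior_logodds' must not contain NA")
  tb <- edge_tables(state$space)
  state$gamma <- as.integer(sample_edge_indicators_cpp(
    state$Omega, tb$pairs0, hyper$v0, hyper$v1, lo))
  state
}

#' Gibbs update of one precision-matrix column
#'
#' Draws column `j` of the precision matrix from its exact full
#' conditional under the spike-and-slab prior: the off-diagonal block
#' `u = Omega[-j, j]` is `N(-C U[-j, j], C)` with
#' `C = [(U_jj + lambda) Omega[-j,-j]^{-1} + D^{-1}]^{-1}`, `D` the
#' diagonal of spike/slab variances of the edges incident to `j`, and
#' `Omega_jj = g + u' Omega[-j,-j]^{-1} u` with
#' `g ~ Gamma(1 + T/2, rate (U_jj + lambda)/2)`. The result is symmetric
#' positive definite by construction.
#'
#' @param state A [precision_state()].
#' @param data A [prepare_data()] object (or `T = 0`, `U = 0` for a
#'   prior-only chain).
#' @param hyper A [spike_slab_hyper()].
#' @param j Column index in `1:P`.
#' @return The updated `precision_state`.
#' @export
sample_precision_column <- function(state, data, hyper, j) {
  stopifnot(inherits(state, "precision_state"), j >= 1, j <= state$space$P)
  tb <- edge_tables(state$space)
  state$Omega <- sample_precision_column_cpp(
    state$Omega, state$gamma, data$U, data$T,
    hyper$v0, hyper$v1, hyper$lambda, as.integer(j), tb$eid0)
  state
}

#' One full Gibbs sweep of a participant's graphical model
#'
#' Applies [sample_edge_indicators()] once, then
#' [sample_precision_column()] for columns `1..P` in order.
#'
#' @inheritParams sample_edge_indicators
#' @param data A [prepare_data()] object.
#' @param n_sweeps Number of consecutive sweeps (default 1).
#' @return The updated `precision_state`.
#' @export
ggm_sweep <- function(state, data, hyper, prior_logodds = 0, n_sweeps = 1L) {
  stopifnot(inherits(state, "precision_state"),
            inherits(hyper, "spike_slab_hyper"),
            data$P == state$space$P)
  lo <- rep_len(as.numeric(prior_logodds), state$space$E)
  if (anyNA(lo)) stop("'prior_logodds' must not contain NA")
  tb <- edge_tables(state$space)
  res <- ggm_sweep_cpp(state$Omega, state$gamma, data$U, data$T,
                       hyper$v0, hyper$v1, hyper$lambda, lo,
                       tb$pairs0, tb$eid0, as.integer(n_sweeps))
  state$Omega <- res$Omega
  state$gamma <- as.integer(res$gamma)
  state
}

#' Partial correlations of a precision matrix
#'
#' `r_e = -omega_ij / sqrt(omega_ii omega_jj)` in edge order.
#'
#' @param Omega A `P x P` precision matrix.
#' @param space An [edge_space()].
#' @return Numeric vector of length `E`, each entry in (-1, 1).
#' @export
partial_correlations <- function(Omega, space) {
  d <- sqrt(diag(Omega))
  -adjacency_to_edges(Omega, space) /
    (d[space$pairs[, 1]] * d[space$pairs[, 2]])
}

# a zero-data participant_data surrogate used by prior-only chains
null_data <- function(P) {
  structure(list(X = NULL, U = matrix(0, P, P), T = 0, P = P,
                 labels = paste0("V", seq_len(P)), id = NULL),
            class = "participant_data")
}
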
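#' Edge space of an undirected network
#'
#' Indexes the `E = P(P-1)/2` node pairs of an undirected network on `P`
#' nodes. Edges are ordered lexicographically over pairs `(i, j)` with
#' `i < j`, 1-based: `(1,2), (1,3), ..., (1,P), (2,3), ...`. All edge
#' vectors in the package use this ordering.
#'
#' @param P Number of nodes (integer, at least 2).
#' @return An object of class `edge_space` with elements `P`, `E`, and
#'   `pairs`, an `E x 2` integer matrix whose row `e` is the node pair of
#'   edge `e`.
#' @examples
#' sp <- edge_space(4)
#' sp$E            # 6
#' sp$pairs[6, ]   # c(3, 4)
#' @export
edge_space <- function(P) {
  P <- as.integer(P)
  if (length(P) != 1L || is.na(P) || P < 2L)
    stop("'P' must be a single integer >= 2")
  pairs <- do.call(rbind, lapply(seq_len(P - 1L), function(i) {
    cbind(i, seq.int(i + 1L, P))
  }))
  storage.mode(pairs) <- "integer"
  dimnames(pairs) <- list(NULL, c("node_i", "node_j"))
  structure(list(P = P, E = (P * (P - 1L)) %/% 2L, pairs = pairs),
            class = "edge_space")
}

#' @export
print.edge_space <- function(x, ...) {
  cat("edge_space: P =", x$P, "nodes,", x$E, "edges (lexicographic i < j)\n")
  invisible(x)
}

#' Map a node pair to its edge index
#'
#' @param i,j Node ids with `1 <= i < j <= P`.
#' @param space An [edge_space()].
#' @return The edge id in `1:E`.
#' @seealso [edge_pair()] for the inverse map.
#' @export
edge_index <- function(i, j, space) {
  stopifnot(inherits(space, "edge_space"))
  P <- space$P
  if (any(i < 1L | j <= i | j > P))
    stop("invalid node pair: need 1 <= i < j <= P")
  # edges in rows before i: sum_{k < i} (P - k)
  (i - 1L) * P - (i * (i - 1L)) %/% 2L + (j - i)
}

#' Map an edge index back to its node pair
#'
#' @param e Edge id(s) in `1:E`.
#' @param space An [edge_space()].
#' @return An integer matrix with columns `node_i`, `node_j`.
#' @export
edge_pair <- function(e, space) {
  stopifnot(inherits(space, "edge_space"))
  if (any(e < 1L | e > space$E)) stop("edge id out of range")
  space$pairs[e, , drop = FALSE]
}

#' Convert between adjacency matrices and edge vectors
#'
#' `adjacency_to_edges()` extracts the upper triangle of a symmetric matrix
#' in lexicographic edge order; `edges_to_adjacency()` is its inverse (with
#' zero diagonal).
#'
#' @param A A `P x P` symmetric matrix.
#' @param v A vector of length `E`.
#' @param space An [edge_space()].
#' @export
adjacency_to_edges <- function(A, space) {
  stopifnot(inherits(space, "edge_space"), nrow(A) == space$P)
  A[space$pairs]
}

#' @rdname adjacency_to_edges
#' @export
edges_to_adjacency <- function(v, space) {
  stopifnot(inherits(space, "edge_space"), length(v) == space$E)
  A <- matrix(0, space$P, space$P)
  A[space$pairs] <- v
  A[space$pairs[, 2:1, drop = FALSE]] <- v
  A
}

#' Bit-pack a binary edge vector
#'
#' Packs a 0/1 (or logical) vector into a raw vector using one bit per
#' entry, padding to the next byte; [unpack_edges()] recovers the original
#' vector given its length.
#'
#' @param v Binary vector.
#' @param packed Raw vector produced by `pack_edges()`.
#' @param n Original length.
#' @return `pack_edges()`: a raw vector of `ceiling(length(v)/8)` bytes;
#'   `unpack_edges()`: an integer 0/1 vector of length `n`.
#' @export
pack_edges <- function(v) {
  v <- as.logical(v)
  if (anyNA(v)) stop("edge vector contains NA")
  pad <- (-length(v)) %% 8L
  packBits(c(v, rep(FALSE, pad)), type = "raw")
}

#' @rdname pack_edges
#' @export
unpack_edges <- function(packed, n) {
  if (n > 8L * length(packed)) stop("packed vector too short for 'n'")
  as.integer(rawToBits(packed)[seq_len(n)])
}

#' Bit-packed store of posterior edge-indicator draws
#'
#' Accumulates retained MCMC draws of the `N x E` edge-indicator matrix
#' using one bit per (participant, edge, iteration) triple, together with
#' running per-edge inclusion counts and partial-correlation sums, and the
#' per-iteration group-level parameter draws.
#'
#' @param n_participants Number of participants `N`.
#' @param space An [edge_space()].
#' @return An environment of class `posterior_store`. Draws are appended
#'   with [store_append()] and summarized with [posterior_summary()].
#' @export
posterior_store <- function(n_participants, space) {
  stopifnot(inherits(space, "edge_space"), n_participants >= 1L)
  st <- new.env(parent = emptyenv())
  st$n_participants <- as.integer(n_participants)
  st$space <- space
  st$n_iterations <- 0L
  st$packed <- list()                       # one raw vector per iteration
  st$incl_counts <- matrix(0, n_participants, space$E)
  st$pcor_sum <- matrix(0, n_participants, space$E)
  st$mu_draws <- list()
  st$sigma_draws <- numeric(0)
  class(st) <- "posterior_store"
  st
}

#' Append one retained draw to a posterior store
#'
#' @param store A [posterior_store()].
#' @param gamma_mat `N x E` binary matrix of edge indicators.
#' @param pcor_mat Optional `N x E` matrix of partial correlations.
#' @param mu,sigma Optional group-level parameter draw.
#' @export
store_append <- function(store, gamma_mat, pcor_mat = NULL,
                         mu = NULL, sigma = NULL) {
  stopifnot(inherits(store, "posterior_store"),
            nrow(gamma_mat) == store$n_participants,
            ncol(gamma_mat) == store$space$E)
  store$n_iterations <- store$n_iterations + 1L
  store$packed[[store$n_iterations]] <- pack_edges(as.vector(gamma_mat))
  store$incl_counts <- store$incl_counts + gamma_mat
  if (!is.null(pcor_mat)) store$pcor_sum <- store$pcor_sum + pcor_mat
  if (!is.null(mu)) store$mu_draws[[store$n_iterations]] <- mu
  if (!is.null(sigma)) store$sigma_draws[store$n_iterations] <- sigma
  invisible(store)
}

#' Retrieve one retained draw from a posterior store
#'
#' @param store A [posterior_store()].
#' @param iteration Retained-iteration index.
#' @return The `N x E` binary indicator matrix of that draw.
#' @export
store_draw <- function(store, iteration) {
  stopifnot(inherits(store, "posterior_store"),
            iteration >= 1L, iteration <= store$n_iterations)
  matrix(unpack_edges(store$packed[[iteration]],
                      store$n_participants * store$space$E),
         store$n_participants, store$space$E)
}

#' Posterior summaries of the stored indicator draws
#'
#' Per-participant, per-edge inclusion probabilities and their posterior
#' standard deviations. The draws are Bernoulli, so the standard deviation
#' is `sqrt(p (1 - p))`, at most 0.5.
#'
#' @param store A [posterior_store()].
#' @return A list with `N x E` matrices `prob` and `sd`, and `pcor_mean`
#'   (running mean of partial correlations, if ever supplied).
#' @export
posterior_summary <- function(store) {
  stopifnot(inherits(store, "posterior_store"))
  if (store$n_iterations < 1L) stop("posterior store is empty")
  p <- store$incl_counts / store$n_iterations
  list(prob = p,
       sd = sqrt(p * (1 - p)),
       pcor_mean = store$pcor_sum / store$n_iterations)
}

#' @export
print.posterior_store <- function(x, ...) {
  cat("posterior_store:", x$n_participants, "participants,",
      x$space$E, "edges,", x$n_iterations, "retained draws\n")
  bytes <- sum(vapply(x$packed, length, 1L))
  cat("  packed indicator draws:", bytes, "bytes\n")
  invisible(x)
}
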
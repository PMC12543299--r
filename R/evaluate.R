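#' ROC curve and AUC
#'
#' Threshold sweep over the unique score values, from the most permissive
#' to the strictest. Ties receive half credit, so the trapezoidal area
#' equals the tie-corrected Mann-Whitney rank statistic.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (0/1 or logical) of the same length; both
#'   classes must occur.
#' @return An object of class `roc_curve` with nondecreasing `fpr` and
#'   `tpr` starting at (0, 0) and ending at (1, 1), and the scalar `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have the same length")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: labels contain a single class")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # collapse tied scores into single thresholds
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last]
  fp <- cumsum(1L - l)[last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("roc_curve:", length(x$fpr), "points, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' AUC for individual-level edge recovery
#'
#' Pools all (participant, edge) pairs into one score/label set: scores
#' are the fitted individual inclusion probabilities, labels the true
#' individual graphs. With `mode = "averaged"` the per-participant AUCs
#' are averaged instead (participants whose true graph has a single
#' class are skipped).
#'
#' @param fit An `ml_fit`.
#' @param truth A [simulate_study()] result.
#' @param mode `"pooled"` (default) or `"averaged"`.
#' @return Scalar AUC.
#' @export
individual_edge_auc <- function(fit, truth, mode = c("pooled", "averaged")) {
  mode <- match.arg(mode)
  probs <- fit$individual_probs
  g <- truth$individual_graphs
  stopifnot(all(dim(probs) == dim(g)))
  if (mode == "pooled")
    return(roc_curve(as.vector(probs), as.vector(g))$auc)
  aucs <- vapply(seq_len(nrow(g)), function(n) {
    if (length(unique(g[n, ])) < 2L) return(NA_real_)
    roc_curve(probs[n, ], g[n, ])$auc
  }, 0)
  mean(aucs, na.rm = TRUE)
}

#' AUC for group-level edge recovery
#'
#' Scores are the fitted group-level inclusion probabilities, labels the
#' true group graph.
#'
#' @inheritParams individual_edge_auc
#' @export
group_edge_auc <- function(fit, truth) {
  roc_curve(fit$group_probs, truth$group_graph)$auc
}

#' Predict individual networks from the group network
#'
#' Thresholds each participant's posterior inclusion probabilities at
#' `threshold` (the median probability model at 0.5) to obtain binary
#' individual networks, then scores them with the group-level inclusion
#' probabilities: one ROC curve per participant. The 95% band is the
#' pointwise 2.5%/97.5% quantile of the per-participant TPR curves on a
#' common 101-point FPR grid (vertical averaging). A multimodality flag
#' is raised when some adjacent gap in the sorted per-participant AUCs
#' with at least 10% of participants on each side exceeds 5 times the
#' median adjacent gap and 0.03 on the AUC scale -- a heuristic for two
#' distinct bundles of ROC curves, the signature of a misspecified
#' (mixture) group level. Posterior shrinkage blurs the bundles, so the
#' flag's sensitivity is limited when the subgroup shift is comparable
#' to the within-subgroup spread (see the methods vignette).
#'
#' @param fit An `ml_fit`.
#' @param threshold Inclusion-probability threshold in (0, 1).
#' @return An object of class `banded_roc`: `fpr_grid`, `mean_tpr`,
#'   `lower`, `upper`, `per_participant_auc` (sorted), `mean_auc`,
#'   `multimodal` flag, and indices of `excluded` participants (those
#'   with single-class thresholded networks).
#' @export
group_to_individual_roc <- function(fit, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  probs <- fit$individual_probs
  g_scores <- fit$group_probs
  N <- nrow(probs)
  grid <- seq(0, 1, length.out = 101L)
  tpr_mat <- matrix(NA_real_, N, length(grid))
  aucs <- rep(NA_real_, N)
  excluded <- integer(0)
  for (n in seq_len(N)) {
    lab <- as.integer(probs[n, ] > threshold)
    if (length(unique(lab)) < 2L) {
      excluded <- c(excluded, n)
      next
    }
    rc <- roc_curve(g_scores, lab)
    aucs[n] <- rc$auc
    tpr_mat[n, ] <- stats::approx(rc$fpr, rc$tpr, xout = grid,
                                  ties = max, rule = 2)$y
  }
  if (length(excluded))
    message("excluded ", length(excluded),
            " participant(s) with single-class thresholded networks")
  keep <- setdiff(seq_len(N), excluded)
  if (!length(keep)) stop("no participant has a two-class network")
  tpr_mat <- tpr_mat[keep, , drop = FALSE]
  aucs <- sort(aucs[keep])
  gaps <- diff(aucs)
  # two bundles: an adjacent gap that dwarfs the typical gap, is large
  # on the AUC scale, and has a real cluster (>= 10% of participants)
  # on each side -- the absolute floor and the cluster-size condition
  # suppress false alarms from near-identical AUCs and lone outliers
  multimodal <- FALSE
  if (length(gaps) >= 2L) {
    n_a <- length(aucs)
    k_min <- max(2L, ceiling(0.1 * n_a))
    interior <- seq_along(gaps) >= k_min &
      seq_along(gaps) <= n_a - k_min
    if (any(interior)) {
      big <- max(gaps[interior])
      med <- stats::median(gaps)
      rel <- if (med > 1e-12) big > 5 * med else big > 0.05
      multimodal <- rel && big > 0.03
    }
  }
  structure(list(fpr_grid = grid,
                 mean_tpr = colMeans(tpr_mat),
                 lower = apply(tpr_mat, 2, stats::quantile, 0.025),
                 upper = apply(tpr_mat, 2, stats::quantile, 0.975),
                 per_participant_auc = aucs,
                 mean_auc = mean(aucs),
                 multimodal = multimodal,
                 excluded = excluded),
            class = "banded_roc")
}

#' @export
print.banded_roc <- function(x, ...) {
  cat("banded_roc:", length(x$per_participant_auc),
      "participants, mean AUC =", format(x$mean_auc, digits = 4),
      if (x$multimodal) "(multimodal)" else "", "\n")
  invisible(x)
}

#' Inclusion Bayes factor
#'
#' The change from prior to posterior inclusion odds,
#' `BF = [p/(1-p)] / [q/(1-q)]`. Under a prior inclusion probability of
#' one half, thresholding the posterior probability at 0.5 (the median
#' probability model) is equivalent to `BF = 1`. Conventional evidence
#' categories: include when `BF >= 3`, exclude when `BF <= 1/3`,
#' insufficient otherwise.
#'
#' @param posterior_prob Posterior inclusion probability/ies in `[0, 1]`;
#'   exact 0 or 1 (a finite-draw artifact) maps to `0`/`Inf` with a
#'   warning.
#' @param prior_prob Prior inclusion probability in (0, 1); default 0.5.
#' @return Bayes factor(s).
#' @export
inclusion_bf <- function(posterior_prob, prior_prob = 0.5) {
  if (any(prior_prob <= 0 | prior_prob >= 1))
    stop("prior inclusion probability must lie strictly in (0, 1)")
  if (any(posterior_prob < 0 | posterior_prob > 1))
    stop("posterior inclusion probability must lie in [0, 1]")
  if (any(posterior_prob %in% c(0, 1)))
    warning("posterior probability of exactly 0 or 1: Bayes factor is ",
            "0/Inf; with finite MCMC draws this reflects sampling ",
            "resolution, not infinite evidence")
  (posterior_prob / (1 - posterior_prob)) /
    (prior_prob / (1 - prior_prob))
}

#' @rdname inclusion_bf
#' @param bf Bayes factor(s).
#' @return `bf_category()`: factor with levels `include`, `exclude`,
#'   `insufficient`.
#' @export
bf_category <- function(bf) {
  out <- ifelse(bf >= 3, "include",
                ifelse(bf <= 1 / 3, "exclude", "insufficient"))
  factor(out, levels = c("include", "exclude", "insufficient"))
}

#' Edge-level heterogeneity variance
#'
#' Variance of the individual-level inclusion probabilities around the
#' group-level probability (not the sample mean):
#' `var_e = mean_n (p_ne - g_e)^2`. By the bias decomposition this equals
#' the centered variance plus `(mean_n p_ne - g_e)^2`, so it is never
#' smaller than the centered variance.
#'
#' @param individual_probs `N x E` matrix.
#' @param group_probs Length-`E` vector.
#' @return Length-`E` vector of variances.
#' @export
heterogeneity_variance <- function(individual_probs, group_probs) {
  individual_probs <- as.matrix(individual_probs)
  stopifnot(ncol(individual_probs) == length(group_probs))
  colMeans(sweep(individual_probs, 2L, group_probs)^2)
}

#' Discordance between individual and group networks
#'
#' `extra_rate`: mean over participants of the fraction of group-absent
#' edges present in the individual network; `miss_rate`: mean fraction of
#' group-present edges absent individually.
#'
#' @param individual_graphs `N x E` binary matrix.
#' @param group_graph Binary vector of length `E` with at least one
#'   present and one absent edge.
#' @return Named numeric vector `c(extra_rate, miss_rate)`.
#' @export
discordance_rates <- function(individual_graphs, group_graph) {
  individual_graphs <- as.matrix(individual_graphs)
  stopifnot(ncol(individual_graphs) == length(group_graph))
  on <- group_graph == 1L
  if (!any(on) || all(on))
    stop("group graph must contain at least one present and one absent edge")
  extra <- mean(rowSums(individual_graphs[, !on, drop = FALSE] == 1L) /
                  sum(!on))
  miss <- mean(rowSums(individual_graphs[, on, drop = FALSE] == 0L) /
                 sum(on))
  c(extra_rate = extra, miss_rate = miss)
}

#' Edge-recovery experiment over a simulation grid
#'
#' For each grid cell and repetition: simulate a study, fit it with each
#' requested method, and record the individual- and group-level AUCs.
#' Cell failures are caught, flagged in the output, and the run
#' continues.
#'
#' @param grid A data frame with columns among `P`, `N`, `T`, `rho`,
#'   `sigma`, `density` (missing columns use [simulation_config()]
#'   defaults).
#' @param methods Character subset of `c("multilevel", "individual",
#'   "aggregate")`.
#' @param reps Repetitions per cell.
#' @param iterations,burnin,chains Sampler settings for every fit.
#' @param seed Master seed; cell/repetition seeds are derived from it.
#' @param out Optional path of a TSV to write the tidy results table to.
#' @return A data frame with one row per (cell, rep, method):
#'   `T, N, P, rho, rep, method, auc_individual, auc_group, seed, ok`.
#' @export
recovery_experiment <- function(grid,
                                methods = c("multilevel", "individual",
                                            "aggregate"),
                                reps = 1L, iterations = 400L,
                                burnin = 100L, chains = 1L, seed = 1L,
                                out = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  grid <- as.data.frame(grid)
  rows <- list()
  for (cell in seq_len(nrow(grid))) {
    for (rep in seq_len(reps)) {
      cell_seed <- (seed * 10000L + cell * 100L + rep) %%
        .Machine$integer.max
      cfg_args <- as.list(grid[cell, , drop = FALSE])
      cfg_args <- cfg_args[names(cfg_args) %in%
                             c("P", "N", "T", "rho", "sigma", "density")]
      cfg <- do.call(simulation_config, c(cfg_args, seed = cell_seed))
      row_base <- data.frame(T = cfg$T, N = cfg$N, P = cfg$P,
                             rho = cfg$rho, rep = rep, seed = cell_seed)
      res <- tryCatch({
        truth <- simulate_study(cfg)
        data_list <- lapply(seq_len(cfg$N), function(n)
          prepare_data(truth$timeseries[[n]], id = sprintf("p%03d", n)))
        lapply(methods, function(m) {
          fc <- fit_config(iterations = iterations, burnin = burnin,
                           chains = chains, seed = cell_seed, method = m)
          fit <- switch(m,
                        multilevel = fit_multilevel(data_list, fc),
                        individual = fit_individual(data_list, fc),
                        aggregate = fit_aggregate(data_list, fc))
          cbind(row_base, method = m,
                auc_individual = individual_edge_auc(fit, truth),
                auc_group = group_edge_auc(fit, truth), ok = TRUE)
        })
      }, error = function(e) {
        warning("cell ", cell, " rep ", rep, " failed: ",
                conditionMessage(e))
        list(cbind(row_base, method = NA_character_,
                   auc_individual = NA_real_, auc_group = NA_real_,
                   ok = FALSE))
      })
      rows <- c(rows, res)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out))
    utils::write.table(tab, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}
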
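test_that("ROC curves handle separation, ties, and small cases", {
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$fpr[1], 0)
  expect_equal(utils::tail(r$fpr, 1), 1)
  expect_equal(utils::tail(r$tpr, 1), 1)

  # all scores tied: chance with half credit
  expect_equal(roc_curve(rep(0.3, 10), rep(c(0, 1), 5))$auc, 0.5)

  # four-point hand enumeration: every positive outranks every negative
  expect_equal(roc_curve(c(0.9, 0.4, 0.6, 0.1), c(1, 0, 1, 0))$auc, 1)

  expect_error(roc_curve(1:4, rep(1, 4)), "single class")
})

test_that("trapezoid AUC equals the tie-corrected rank statistic", {
  set.seed(60)
  for (r in 1:20) {
    n <- sample(10:60, 1)
    scores <- round(runif(n), sample(c(1, 2, 7), 1))  # induce ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_curve(scores, labels)$auc, auc_rank(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(61)
  scores <- runif(80)
  labels <- rbinom(80, 1, 0.4)
  expect_equal(roc_curve(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("edge-recovery AUCs read the right fit slots", {
  sp <- edge_space(4)
  truth <- list(individual_graphs = rbind(c(1, 0, 1, 0, 1, 0),
                                          c(0, 1, 1, 0, 0, 1)),
                group_graph = c(1, 0, 1, 0, 0, 1),
                space = sp)
  exact <- list(individual_probs = truth$individual_graphs * 0.8 + 0.1,
                group_probs = truth$group_graph * 0.8 + 0.1)
  expect_equal(individual_edge_auc(exact, truth), 1)
  expect_equal(group_edge_auc(exact, truth), 1)
  # averaged mode on the same exact fit is also perfect
  expect_equal(individual_edge_auc(exact, truth, mode = "averaged"), 1)
  # random scores hover near one half
  set.seed(62)
  noise <- list(individual_probs = matrix(runif(2 * 6 * 500), 1000, 6),
                group_probs = runif(6))
  big_truth <- list(individual_graphs =
                      matrix(rbinom(6000, 1, 0.5), 1000, 6))
  expect_lt(abs(individual_edge_auc(noise, big_truth) - 0.5), 0.03)
})

test_that("group-to-individual prediction bands and the mixture flag work", {
  # all individuals identical to the group: perfect prediction, no band
  g <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.05)
  fit1 <- list(individual_probs = matrix(rep(g, 10), 10, 6, byrow = TRUE),
               group_probs = g)
  br <- group_to_individual_roc(fit1, 0.5)
  expect_true(all(br$per_participant_auc == 1))
  expect_equal(br$mean_auc, 1)
  expect_equal(br$lower, br$upper)
  expect_false(br$multimodal)
  expect_true(all(br$lower <= br$mean_tpr + 1e-12) &&
                all(br$mean_tpr <= br$upper + 1e-12))

  # two sub-populations: one aligned with the group scores, one flipped
  set.seed(63)
  sp <- edge_space(8)
  gg <- rbinom(sp$E, 1, 0.4)
  gp <- ifelse(gg == 1, 0.8, 0.2) + rnorm(sp$E, 0, 0.02)
  aligned <- matrix(rep(ifelse(gg == 1, 0.9, 0.1), 16), 16, sp$E,
                    byrow = TRUE)
  flipped <- matrix(rep(ifelse(gg == 1, 0.1, 0.9), 4), 4, sp$E,
                    byrow = TRUE)
  fit2 <- list(individual_probs = rbind(aligned, flipped), group_probs = gp)
  br2 <- group_to_individual_roc(fit2, 0.5)
  expect_true(br2$multimodal)
  expect_gt(diff(range(br2$per_participant_auc)), 0.5)

  # participants with single-class thresholded networks are excluded
  fit3 <- list(individual_probs = rbind(rep(0.9, 6), g), group_probs = g)
  expect_message(br3 <- group_to_individual_roc(fit3, 0.5), "excluded")
  expect_equal(br3$excluded, 1L)
  expect_error(group_to_individual_roc(fit1, 1.2))
})

test_that("inclusion Bayes factors follow the odds-ratio definition", {
  expect_identical(inclusion_bf(0.5, 0.5), 1)
  expect_equal(inclusion_bf(0.75, 0.5), 3)
  expect_equal(inclusion_bf(0.2, 0.5), 0.25)
  expect_equal(bf_category(c(3, 1/3, 1, 10, 0.1)),
               factor(c("include", "exclude", "insufficient", "include",
                        "exclude"),
                      levels = c("include", "exclude", "insufficient")))
  # properties: BF(p, 1/2) = p/(1-p); reciprocal identity; monotone
  p <- seq(0.05, 0.95, by = 0.1)
  expect_equal(inclusion_bf(p, 0.5), p / (1 - p))
  q <- 0.3
  expect_equal(inclusion_bf(0.5, q) * inclusion_bf(q, 0.5), 1)
  expect_true(all(diff(inclusion_bf(p, 0.5)) > 0))
  expect_warning(bf0 <- inclusion_bf(c(0, 1), 0.5), "finite MCMC")
  expect_equal(bf0, c(0, Inf))
  expect_error(inclusion_bf(0.5, 0), "strictly")
  expect_error(inclusion_bf(1.2, 0.5))
})

test_that("heterogeneity variance decomposes around the group probability", {
  expect_equal(heterogeneity_variance(rbind(c(0.3, 0.7)), c(0.3, 0.7)),
               c(0, 0))
  expect_equal(heterogeneity_variance(cbind(c(0, 1)), 0.5), 0.25)
  set.seed(64)
  p <- matrix(runif(60), 12, 5)
  gp <- runif(5)
  v <- heterogeneity_variance(p, gp)
  centered <- colMeans(sweep(p, 2, colMeans(p))^2)
  expect_equal(v, centered + (colMeans(p) - gp)^2, tolerance = 1e-12)
  expect_true(all(v >= centered - 1e-15))
})

test_that("discordance rates count extra and missing edges per participant", {
  g <- c(1, 0, 1, 0)
  expect_equal(discordance_rates(rbind(g, g), g),
               c(extra_rate = 0, miss_rate = 0))
  expect_equal(discordance_rates(rbind(c(1, 1, 0, 0)), g),
               c(extra_rate = 0.5, miss_rate = 0.5))
  # averaging over participants
  expect_equal(discordance_rates(rbind(g, c(1, 1, 1, 1)), g),
               c(extra_rate = 0.5, miss_rate = 0))
  expect_error(discordance_rates(rbind(g), rep(1, 4)), "at least one")
})

test_that("the recovery-experiment driver writes a deterministic table", {
  grid <- data.frame(P = 5, N = 3, T = 60, rho = 100)
  out <- file.path(tempdir(), "recovery.tsv")
  tab <- recovery_experiment(grid, methods = c("individual", "aggregate"),
                             reps = 1, iterations = 40, burnin = 10,
                             seed = 3, out = out)
  expect_true(file.exists(out))
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$method, c("individual", "aggregate"))
  expect_true(all(tab$ok))
  expect_true(all(tab$auc_individual >= 0 & tab$auc_individual <= 1))
  tab2 <- recovery_experiment(grid, methods = c("individual", "aggregate"),
                              reps = 1, iterations = 40, burnin = 10,
                              seed = 3)
  expect_equal(tab, tab2)
  unlink(out)
})
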
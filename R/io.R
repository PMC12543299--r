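#' Read a dataset directory via its manifest
#'
#' The manifest is a TSV with columns `participant_id`, `path`
#' (relative to the manifest's directory), and `T` (expected time-point
#' count). Each series file is a numeric TSV with one header row of node
#' labels and one row per time point; all files must share the same
#' header. Centering/standardization is applied via [prepare_data()].
#'
#' @param manifest_path Path to `manifest.tsv`.
#' @param standardize Passed to [prepare_data()].
#' @return A list of `participant_data` objects in manifest order.
#' @export
read_dataset <- function(manifest_path, standardize = TRUE) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("participant_id", "path", "T")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(man$participant_id))
    stop("duplicate participant ids in manifest")
  base <- dirname(manifest_path)
  header <- NULL
  header_file <- NULL
  out <- vector("list", nrow(man))
  for (k in seq_len(nrow(man))) {
    f <- file.path(base, man$path[k])
    if (!file.exists(f)) stop("series file missing: ", f)
    raw <- utils::read.delim(f, stringsAsFactors = FALSE)
    if (!all(vapply(raw, is.numeric, TRUE))) {
      bad <- names(raw)[!vapply(raw, is.numeric, TRUE)][1]
      stop("non-numeric values in ", f, ", column ", bad)
    }
    if (is.null(header)) {
      header <- names(raw)
      header_file <- f
    } else if (!identical(names(raw), header)) {
      stop("node-label header of ", f, " differs from ", header_file)
    }
    if (nrow(raw) != man$T[k])
      stop("file ", f, " has ", nrow(raw), " rows; manifest expects ",
           man$T[k])
    out[[k]] <- prepare_data(as.matrix(raw), standardize = standardize,
                             id = man$participant_id[k])
  }
  out
}

#' Write a fit result as a directory of TSV tables
#'
#' Writes `group_edges.tsv` (`edge_id node_i node_j mu_mean mu_sd
#' incl_prob bf`), `sigma.tsv`, `individual_edges.tsv` (long table with
#' per-participant inclusion probabilities and mean partial
#' correlations), `rhat.tsv`, and `run.log` with the resolved
#' configuration, seed, acceptance rates, and convergence summary.
#'
#' @param fit An `ml_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "ml_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- fit$space
  grp <- data.frame(edge_id = seq_len(sp$E),
                    node_i = sp$pairs[, 1], node_j = sp$pairs[, 2],
                    mu_mean = if (is.null(fit$mu_mean)) NA else fit$mu_mean,
                    mu_sd = if (is.null(fit$mu_sd)) NA else fit$mu_sd,
                    incl_prob = fit$group_probs,
                    bf = suppressWarnings(inclusion_bf(fit$group_probs)))
  utils::write.table(grp, file.path(dir, "group_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sigma_mean = fit$sigma_mean %||% NA,
                                sigma_sd = fit$sigma_sd %||% NA),
                     file.path(dir, "sigma.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  N <- nrow(fit$individual_probs)
  ids <- fit$participant_ids
  if (all(ids == "")) ids <- sprintf("p%03d", seq_len(N))
  if (length(ids) != N) ids <- sprintf("p%03d", seq_len(N))
  long <- data.frame(participant_id = rep(ids, each = sp$E),
                     edge_id = rep(seq_len(sp$E), N),
                     node_i = rep(sp$pairs[, 1], N),
                     node_j = rep(sp$pairs[, 2], N),
                     incl_prob = as.vector(t(fit$individual_probs)),
                     pcor_mean = as.vector(t(fit$pcor_mean)))
  utils::write.table(long, file.path(dir, "individual_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fit$rhat))
    utils::write.table(data.frame(parameter = names(fit$rhat),
                                  rhat = fit$rhat),
                       file.path(dir, "rhat.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  cfg <- fit$config
  log_lines <- c(
    paste0("method: ", fit$method),
    paste0("seed: ", cfg$seed),
    paste0("iterations: ", cfg$iterations),
    paste0("burnin: ", cfg$burnin),
    paste0("chains: ", cfg$chains),
    paste0("standardize: ", cfg$standardize),
    paste0("v0: ", cfg$hyper$v0), paste0("v1: ", cfg$hyper$v1),
    paste0("lambda: ", cfg$hyper$lambda),
    paste0("mu_prior_sd: ", cfg$prior$mu_prior_sd),
    paste0("sigma_prior_scale: ", cfg$prior$sigma_prior_scale),
    if (!is.null(fit$acceptance))
      paste0("acceptance_mu: ", format(fit$acceptance["mu"], digits = 3)),
    if (!is.null(fit$acceptance))
      paste0("acceptance_sigma: ",
             format(fit$acceptance["sigma"], digits = 3)),
    if (!is.null(fit$rhat))
      paste0("max_rhat: ", format(max(fit$rhat), digits = 4)))
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- command-line interface -------------------------------------------

cli_usage <- paste(
  "usage: mlggm <command> [--flag value ...]",
  "",
  "commands:",
  "  simulate             --out DIR [--nodes P --participants N",
  "                       --timepoints T --rho R --sigma S --density D",
  "                       --seed K --mixture 0|1 --flip-frac F]",
  "  fit                  --data DIR --out DIR [--method multilevel|",
  "                       individual|aggregate --iterations I --burnin B",
  "                       --chains C --seed K --standardize 0|1]",
  "  evaluate             --fit DIR --truth DIR --out DIR",
  "  predict-individuals  --fit DIR --out DIR [--threshold 0.5]",
  "  recovery-experiment  --out FILE [--rhos '0,100' --nodes P",
  "                       --participants N --timepoints T --reps R",
  "                       --iterations I --burnin B --seed K]",
  sep = "\n")

parse_flags <- function(args, spec) {
  # spec: named list of default values; types taken from the defaults
  vals <- spec
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3L))
    if (!key %in% names(spec))
      stop("unknown flag: ", a)
    if (i + 1L > length(args)) stop("missing value for ", a)
    v <- args[i + 1L]
    vals[[key]] <- switch(class(spec[[key]])[1],
                          numeric = as.numeric(v),
                          integer = as.integer(v),
                          logical = as.logical(as.integer(v)),
                          v)
    i <- i + 2L
  }
  vals
}

read_truth_dir <- function(dir) {
  ge <- utils::read.delim(file.path(dir, "group_edges.tsv"))
  ig <- utils::read.delim(file.path(dir, "individual_edges.tsv"))
  gam <- as.matrix(ig[, -1, drop = FALSE])
  P <- max(ge$node_j)
  list(group_graph = ge$included, individual_graphs = gam,
       space = edge_space(P))
}

#' Command-line entry point
#'
#' Subcommands `simulate`, `fit`, `evaluate`, `predict-individuals`, and
#' `recovery-experiment` tie the package into shell pipelines; see
#' `run_cli("help")` for the flag reference. A thin wrapper script is
#' installed at `system.file("scripts", "mlggm", package = "mlggm")`.
#'
#' @param argv Character vector of arguments (subcommand first).
#' @return Exit status, invisibly: 0 on success.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(argv) || argv[1] %in% c("help", "--help", "-h")) {
      cat(cli_usage, "\n")
      return(invisible(0L))
    }
    cmd <- argv[1]
    args <- argv[-1]
    switch(cmd,
      simulate = {
        f <- parse_flags(args, list(
          out = "", nodes = 10L, participants = 8L, timepoints = 150L,
          rho = 100, sigma = 0.1, density = 0.16, seed = 1L,
          mixture = FALSE, flip_frac = 0.2))
        if (f$out == "") stop("--out is required")
        cfg <- simulation_config(P = f$nodes, N = f$participants,
                                 T = f$timepoints, rho = f$rho,
                                 sigma = f$sigma, density = f$density,
                                 seed = f$seed, mixture = f$mixture,
                                 flip_frac = f$flip_frac)
        truth <- simulate_study(cfg)
        write_dataset(truth, f$out)
        message("wrote dataset to ", f$out)
      },
      fit = {
        f <- parse_flags(args, list(
          data = "", out = "", method = "multilevel", iterations = 400L,
          burnin = 100L, chains = 1L, seed = 1L, standardize = TRUE))
        if (f$data == "" || f$out == "")
          stop("--data and --out are required")
        data_list <- read_dataset(file.path(f$data, "manifest.tsv"),
                                  standardize = f$standardize)
        fc <- fit_config(iterations = f$iterations, burnin = f$burnin,
                         chains = f$chains, seed = f$seed,
                         method = f$method, standardize = f$standardize)
        fit <- switch(f$method,
                      multilevel = fit_multilevel(data_list, fc),
                      individual = fit_individual(data_list, fc),
                      aggregate = fit_aggregate(data_list, fc),
                      stop("unknown method: ", f$method))
        write_fit(fit, f$out)
        saveRDS_path <- file.path(f$out, "fit.rds")
        saveRDS(fit, saveRDS_path)
        message("wrote fit to ", f$out)
      },
      evaluate = {
        f <- parse_flags(args, list(fit = "", truth = "", out = ""))
        if (f$fit == "" || f$truth == "" || f$out == "")
          stop("--fit, --truth and --out are required")
        fit <- readRDS(file.path(f$fit, "fit.rds"))
        tr <- read_truth_dir(f$truth)
        dir.create(f$out, recursive = TRUE, showWarnings = FALSE)
        aucs <- data.frame(
          method = fit$method,
          auc_individual = individual_edge_auc(fit, tr),
          auc_group = group_edge_auc(fit, tr))
        utils::write.table(aucs, file.path(f$out, "aucs.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        bf <- suppressWarnings(inclusion_bf(fit$group_probs))
        sp <- fit$space
        utils::write.table(
          data.frame(edge_id = seq_len(sp$E), node_i = sp$pairs[, 1],
                     node_j = sp$pairs[, 2], incl_prob = fit$group_probs,
                     bf = bf, category = bf_category(bf)),
          file.path(f$out, "bf_edges.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
        utils::write.table(
          data.frame(edge_id = seq_len(sp$E),
                     variance = heterogeneity_variance(
                       fit$individual_probs, fit$group_probs)),
          file.path(f$out, "heterogeneity.tsv"), sep = "\t",
          quote = FALSE, row.names = FALSE)
        message("wrote evaluation tables to ", f$out)
      },
      `predict-individuals` = {
        f <- parse_flags(args, list(fit = "", out = "", threshold = 0.5))
        if (f$fit == "" || f$out == "")
          stop("--fit and --out are required")
        fit <- readRDS(file.path(f$fit, "fit.rds"))
        br <- group_to_individual_roc(fit, f$threshold)
        dir.create(f$out, recursive = TRUE, showWarnings = FALSE)
        utils::write.table(
          data.frame(fpr = br$fpr_grid, mean_tpr = br$mean_tpr,
                     lower = br$lower, upper = br$upper),
          file.path(f$out, "band.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
        utils::write.table(
          data.frame(auc = br$per_participant_auc),
          file.path(f$out, "participant_aucs.tsv"), sep = "\t",
          quote = FALSE, row.names = FALSE)
        message("mean AUC ", format(br$mean_auc, digits = 4),
                if (br$multimodal) " (multimodal AUC distribution)" else "")
      },
      `recovery-experiment` = {
        f <- parse_flags(args, list(
          out = "", rhos = "0,100", nodes = 10L, participants = 8L,
          timepoints = 150L, reps = 1L, iterations = 300L, burnin = 100L,
          seed = 1L))
        if (f$out == "") stop("--out is required")
        rhos <- as.numeric(strsplit(f$rhos, ",")[[1]])
        grid <- data.frame(P = f$nodes, N = f$participants,
                           T = f$timepoints, rho = rhos)
        recovery_experiment(grid, reps = f$reps,
                            iterations = f$iterations, burnin = f$burnin,
                            seed = f$seed, out = f$out)
        message("wrote results table to ", f$out)
      },
      {
        cat(cli_usage, "\n")
        stop("unknown command: ", cmd)
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
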
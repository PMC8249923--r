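#' Run the full explant-secretome analysis pipeline
#'
#' Drives read (or simulate) -> log transform -> imputation ->
#' decomposition -> significance -> membership/activity -> associations ->
#' networks, writing every intermediate artifact plus a `manifest.json`
#' (input checksums, seed, package version, all parameters) into `outdir`.
#' Identical config + inputs + seed produce byte-identical outputs.
#'
#' The config is a named list (or path to a YAML file) with fields:
#' \describe{
#'   \item{`secretome`}{Path to a concentration CSV/TSV, or instead}
#'   \item{`simulate`}{A list of [synthetic_truth()] arguments.}
#'   \item{`infiltrates`, `metadata`, `edges`}{Optional input paths.}
#'   \item{`detection_floor`}{Pseudocount in pg/mL (default 1).}
#'   \item{`decompose`}{Options: `rank`, `tol`, `n_boot`, `noise_sd`,
#'     `fold`, `quantile`, `activity_threshold`.}
#'   \item{`associate`}{Options: `aggregate`, `distance`, `linkage`,
#'     `n_components`, `per_animal`.}
#'   \item{`network`}{Options: `min_score`.}
#' }
#'
#' @param config Named list or path to a YAML config file.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed for every stochastic step (simulation and the
#'   Monte-Carlo null).
#' @param log_level `"info"` (one message per stage, with shapes and elapsed
#'   time) or `"quiet"`.
#' @return Invisibly, a list of the in-memory results (`secretome`,
#'   `decomposition`, `processes`, `reports`, `manifest`).
#' @export
run_pipeline <- function(config, outdir, seed = 1L,
                         log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$secretome) && is.null(config$simulate)) {
    stop("pipeline config error: provide either `secretome` (path) or `simulate` (parameters)",
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  say <- function(stage, fmt, ...) {
    if (log_level == "info") {
      message(sprintf("[%s] %s (%.2fs)", stage, sprintf(fmt, ...),
                      proc.time()[["elapsed"]] - t0))
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  # real multiplex reads floor at 1 pg/mL; simulated data keeps the
  # generator's floor, which sits below its dynamic range
  floorv <- config$detection_floor %||%
    (if (is.null(config$simulate)) 1 else 1e-4)
  dco <- config$decompose %||% list()
  aco <- config$associate %||% list()
  nco <- config$network %||% list()
  input_files <- character(0)

  ## ---- inputs ----
  truth <- NULL
  infiltrates <- NULL
  metadata <- NULL
  edges <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- seed
    truth <- stage("simulate", do.call(synthetic_truth, sim))
    gen <- gen_secretome(truth, detection_floor = floorv)
    secretome <- gen$secretome
    metadata <- gen_metadata(truth)
    if (length(truth$infiltrate_link)) {
      infiltrates <- gen_infiltrates(truth)
    }
    write_secretome(secretome, file.path(outdir, "secretome.csv"))
    utils::write.table(metadata, file.path(outdir, "metadata.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
    if (!is.null(infiltrates)) {
      write_infiltrates(infiltrates, file.path(outdir, "infiltrates.csv"))
    }
    jsonlite::write_json(
      list(parameters = truth[c("n_cytokines", "n_samples", "k_true",
                                "noise_sd", "snr", "missing_fraction",
                                "seed")],
           baseline_log_levels = truth$baseline_log_levels,
           planted_G = truth$planted_G,
           planted_lambda = truth$planted_lambda,
           infiltrate_link = truth$infiltrate_link),
      file.path(outdir, "truth.json"), digits = NA, auto_unbox = TRUE)
    say("simulate", "%d cytokines x %d samples, k_true = %d",
        nrow(secretome), ncol(secretome), truth$k_true)
  } else {
    secretome <- stage("read", read_secretome(config$secretome,
                                              detection_floor = floorv))
    input_files <- c(input_files, secretome = config$secretome)
    say("read", "secretome %d x %d (%d missing)", nrow(secretome),
        ncol(secretome), sum(is.na(secretome)))
  }
  if (!is.null(config$infiltrates)) {
    infiltrates <- stage("read", read_infiltrates(config$infiltrates))
    input_files <- c(input_files, infiltrates = config$infiltrates)
  }
  if (!is.null(config$metadata)) {
    metadata <- stage("read", read_metadata(config$metadata))
    input_files <- c(input_files, metadata = config$metadata)
  }
  if (!is.null(config$edges)) {
    edges <- stage("read", read_edge_list(config$edges))
    input_files <- c(input_files, edges = config$edges)
  }

  ## ---- transform, impute, decompose ----
  lnX <- stage("log_transform", log_transform(secretome))
  if (anyNA(lnX)) {
    lnX <- stage("impute", impute_missing_svd(lnX, rank = dco$rank,
                                              tol = dco$tol %||% 1e-6))
    say("impute", "%d entries imputed in %d iteration(s)",
        sum(attr(lnX, "imputed")), attr(lnX, "iterations"))
  }
  dec <- stage("decompose", surprisal_decompose(lnX))
  say("decompose", "%d components, top singular value %.4g",
      ncol(dec$G), dec$singular_values[1L])

  noise_sd <- dco$noise_sd %||% "estimate"
  groups <- if (!is.null(metadata)) {
    metadata$animal_id[match(sample_ids(secretome), metadata$sample_id)]
  }
  dec <- stage("significance",
               count_significant_processes(dec, noise_sd = noise_sd,
                                           groups = groups,
                                           n_boot = dco$n_boot %||% 200L,
                                           seed = seed))
  say("significance", "K = %d (noise sd %.4g, null q95 %.4g)",
      dec$K_significant, dec$noise_sd_est, dec$null_q95)

  ## ---- membership, activity, networks ----
  K <- dec$K_significant
  processes <- list()
  proc_rows <- list()
  act_rows <- list()
  net_dir <- file.path(outdir, "networks")
  if (K > 0) dir.create(net_dir, showWarnings = FALSE)
  for (a in seq_len(K)) {
    pr <- stage("membership",
                process_membership(dec, a, fold = dco$fold %||% 20,
                                   quantile = dco$quantile %||% 0.20))
    pr <- stage("activity",
                process_activity(dec, a,
                                 threshold = dco$activity_threshold %||% "auto",
                                 process = pr))
    processes[[a]] <- pr
    member <- dec$cytokine_ids %in% pr$member_ids
    proc_rows[[a]] <- data.frame(alpha = a, cytokine = dec$cytokine_ids,
                                 G = dec$G[, a + 1L], member = member,
                                 stringsAsFactors = FALSE)
    act_rows[[a]] <- data.frame(alpha = a, sample = dec$sample_ids,
                                lambda = dec$lambda[a + 1L, ],
                                call = unname(pr$activity_calls),
                                stringsAsFactors = FALSE)
    net <- stage("network",
                 build_subnetwork(pr, edges %||%
                                    data.frame(from = character(0),
                                               to = character(0)),
                                  min_score = nco$min_score))
    write_subnetwork(net, file.path(net_dir, sprintf("process%d.graphml", a)))
  }
  if (K > 0) {
    .write_csv(do.call(rbind, proc_rows), file.path(outdir, "processes.csv"))
    .write_csv(do.call(rbind, act_rows), file.path(outdir, "activity.csv"))
    say("processes", "membership + activity for %d process(es)", K)
  }
  jsonlite::write_json(
    list(cytokine_ids = dec$cytokine_ids, sample_ids = dec$sample_ids,
         G = dec$G, lambda = dec$lambda,
         singular_values = dec$singular_values,
         K_significant = dec$K_significant,
         noise_sd_est = dec$noise_sd_est, null_q95 = dec$null_q95,
         significance = "Monte-Carlo noise-percentile null"),
    file.path(outdir, "decomposition.json"), digits = NA, auto_unbox = TRUE)

  ## ---- associations ----
  reports <- list()
  if (!is.null(infiltrates)) {
    alignment <- if (!is.null(metadata)) {
      al <- align_tables(secretome, infiltrates, metadata)
      if (nrow(al$mapping)) al else NULL
    }
    sec_agg <- if (!is.null(alignment)) {
      aggregate_secretome(secretome, metadata,
                          fun = aco$aggregate %||% "mean")
    } else {
      unclass(secretome)
    }
    rep_ci <- stage("associate", pearson_matrix(sec_agg, infiltrates))
    rep_ci <- cluster_order(rep_ci, distance = aco$distance %||% "maximum",
                            linkage = aco$linkage %||% "average")
    reports$cytokine_infiltrate <- rep_ci
    .write_corr_csv(rep_ci, file.path(outdir, "correlation.csv"))
    if (K >= 1) {
      rep_ai <- stage("associate",
                      amplitude_infiltrate_correlation(
                        dec, infiltrates, alignment = alignment,
                        aggregate = aco$aggregate %||% "mean"))
      reports$amplitude_infiltrate <- rep_ai
      .write_corr_csv(rep_ai, file.path(outdir,
                                        "amplitude_correlation.csv"))
    }
    jsonlite::write_json(
      list(row_order = rep_ci$row_order, col_order = rep_ci$col_order,
           linkage_params = rep_ci$linkage_params),
      file.path(outdir, "orders.json"), digits = NA, auto_unbox = TRUE)
    say("associate", "correlation reports written")
  }
  pca <- stage("pca", pca_scores(log_transform(secretome),
                                 n_components = aco$n_components %||% 2L,
                                 impute_rank = dco$rank))
  .write_csv(data.frame(sample = rownames(pca$scores), pca$scores,
                        stringsAsFactors = FALSE),
             file.path(outdir, "pca_scores.csv"))
  if (!is.null(metadata) &&
      length(setdiff(unique(metadata$treatment), "untreated"))) {
    stats_df <- tryCatch(
      compare_all_treatments(secretome, metadata,
                             per_animal = isTRUE(aco$per_animal)),
      error = function(e) NULL)
    if (!is.null(stats_df)) {
      .write_csv(stats_df, file.path(outdir, "treatment_stats.csv"))
      say("treatments", "%d comparison(s)", nrow(stats_df))
    }
  }

  ## ---- manifest ----
  outputs <- sort(setdiff(list.files(outdir, recursive = TRUE),
                          "manifest.json"))
  manifest <- list(
    package = "secretoscope",
    version = as.character(utils::packageVersion("secretoscope")),
    seed = as.integer(seed),
    config = config,
    input_checksums = as.list(if (length(input_files))
      tools::md5sum(input_files) else stats::setNames(list(), character(0))),
    output_checksums = as.list(tools::md5sum(file.path(outdir, outputs))) |>
      stats::setNames(outputs)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  say("done", "%d output file(s) in %s", length(outputs) + 1L, outdir)
  invisible(list(secretome = secretome, decomposition = dec,
                 processes = processes, reports = reports,
                 manifest = manifest))
}

.write_csv <- function(df, path) {
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# tidy row/col/r/n export of a correlation report
.write_corr_csv <- function(report, path) {
  df <- data.frame(
    row = rep(report$row_ids, times = length(report$col_ids)),
    col = rep(report$col_ids, each = length(report$row_ids)),
    r = as.vector(report$r_values),
    n = as.vector(report$n_pairs),
    stringsAsFactors = FALSE
  )
  .write_csv(df, path)
}
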
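#' Assemble a run configuration
#'
#' A single JSON-serialisable list drives every pipeline stage: simulation
#' block (passed to [sim_config()]), mvpa block (passed to
#' [decode_params()]), group-inference block, output directory and master
#' seed. Values given in `config_path` (a JSON file) override the
#' defaults; `overrides` (a nested list) overrides both -- the precedence
#' used by the command-line driver. Every stochastic stage derives its
#' seed deterministically from the master seed and the stage name, and
#' the full configuration is persisted into the run manifest.
#'
#' @param config_path optional path to a JSON configuration file.
#' @param overrides optional nested list of final overrides.
#' @return object of class `run_config`.
#' @export
run_config <- function(config_path = NULL, overrides = list()) {
  cfg <- list(
    paths = list(output_dir = "erpdecode-run"),
    sim = list(),
    mvpa = list(),
    group = list(alpha_forming = 0.05, alpha_cluster = 0.05,
                 n_permutations = 1000),
    seed = 1L,
    verbosity = 1L
  )
  if (!is.null(config_path)) {
    if (!file.exists(config_path))
      stop_invalid("config file not found: %s", config_path)
    user <- jsonlite::read_json(config_path, simplifyVector = TRUE)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg <- utils::modifyList(cfg, overrides)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

log_msg <- function(cfg, ...) {
  if ((cfg$verbosity %||% 1) > 0) message(sprintf(...))
}

cfg_sim_config <- function(cfg) {
  sim <- cfg$sim
  # JSON objects deserialize as named lists; sim_config wants vectors
  if (!is.null(sim$group_sizes)) sim$group_sizes <- unlist(sim$group_sizes)
  if (!is.null(sim$behavior_params))
    sim$behavior_params <- lapply(sim$behavior_params,
                                  function(x) if (is.list(x)) unlist(x) else x)
  do.call(sim_config, sim)
}

cfg_decode_params <- function(cfg) do.call(decode_params, cfg$mvpa)

study_dir <- function(cfg) file.path(cfg$paths$output_dir, "study")

require_path <- function(path, hint) {
  if (!file.exists(path))
    stop_invalid("missing input: %s -- %s", path, hint)
  path
}

#' Simulate a study and write it to the run directory
#'
#' Generates the synthetic study defined by the configuration's `sim`
#' block and writes one epoch container per participant plus the
#' behavioral table, the trial-level responses, the ground-truth latent
#' appeal (CSV) and a run manifest.
#'
#' @param cfg a [run_config()].
#' @return invisibly, the generated study list.
#' @export
stage_simulate <- function(cfg) {
  sc <- cfg_sim_config(cfg)
  out <- cfg$paths$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  study <- generate_study(sc, seed = derive_seed(cfg$seed, "simulate"))
  sdir <- study_dir(cfg)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  for (ds in study$datasets)
    write_container(ds, file.path(sdir, ds$participant_id))
  utils::write.csv(study$behavior, file.path(out, "behavior.csv"),
                   row.names = FALSE)
  utils::write.csv(study$responses, file.path(out, "responses.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(participant = rownames(study$truth$latent_appeal),
               study$truth$latent_appeal, check.names = FALSE),
    file.path(out, "truth_latent.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(signal_channels = study$truth$signal_channels,
         groups = as.character(study$truth$groups)),
    file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(stage = "simulate", config = unclass(cfg)),
                       file.path(out, "manifest_simulate.json"),
                       auto_unbox = TRUE, digits = NA)
  log_msg(cfg, "simulated %d participants into %s", length(study$datasets), sdir)
  invisible(study)
}

read_study <- function(cfg) {
  sdir <- require_path(study_dir(cfg),
                       "run stage_simulate(cfg) (or point paths$output_dir at an existing run) first")
  pids <- sort(list.dirs(sdir, recursive = FALSE, full.names = FALSE))
  if (length(pids) == 0)
    stop_invalid("missing input: no participant containers under %s", sdir)
  lapply(pids, function(p) read_container(file.path(sdir, p)))
}

preprocess <- function(ds, threshold = 150) {
  ds <- baseline_correct(ds)
  reject_amplitude(ds, threshold)$dataset
}

#' Run moving-window decoding for every participant
#'
#' Reads the study containers, baseline-corrects, applies the +/-150 uV
#' rejection, and runs the per-participant moving-window analysis for the
#' requested mode and dimension(s). Tidy results and an eligibility
#' manifest are written per mode x dimension.
#'
#' @param cfg a [run_config()].
#' @param mode `"svm"` or `"svr"`.
#' @param dimension one dimension or `"all"`.
#' @return invisibly, a named list of tidy result data.frames.
#' @export
stage_decode <- function(cfg, mode = c("svm", "svr"),
                         dimension = c("all", "appealing", "curiosity", "wanting")) {
  mode <- match.arg(mode)
  dimension <- match.arg(dimension)
  dims <- if (dimension == "all")
    c("appealing", "curiosity", "wanting") else dimension
  params <- cfg_decode_params(cfg)
  datasets <- lapply(read_study(cfg), preprocess)
  grid <- build_windows(datasets[[1]]$times, datasets[[1]]$sampling_rate,
                        params$window_ms)
  out <- cfg$paths$output_dir
  results <- list()
  for (dm in dims) {
    rows <- list(); elig <- list()
    for (ds in datasets) {
      res <- run_participant(ds, dm, mode, grid, params,
                             seed = derive_seed(cfg$seed, "decode", mode,
                                                dm, ds$participant_id))
      elig[[ds$participant_id]] <- !is.null(res)
      if (!is.null(res)) rows[[length(rows) + 1L]] <- as.data.frame(res)
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(participant = character(), dimension = character(),
                 mode = character(), window_time_ms = numeric(),
                 value_true = numeric(), value_null = numeric())
    f <- file.path(out, sprintf("decode_%s_%s.csv", mode, dm))
    utils::write.csv(df, f, row.names = FALSE)
    jsonlite::write_json(
      list(stage = "decode", mode = mode, dimension = dm,
           params = unclass(params), seed = cfg$seed, eligible = elig),
      file.path(out, sprintf("decode_%s_%s_manifest.json", mode, dm)),
      auto_unbox = TRUE, digits = NA)
    log_msg(cfg, "decoded %s/%s: %d eligible of %d participants -> %s",
            mode, dm, sum(unlist(elig)), length(elig), f)
    results[[dm]] <- df
  }
  invisible(results)
}

#' Group-level cluster-permutation inference for one decode run
#'
#' Reads a tidy decode result, forms the participants x windows matrix of
#' true-minus-null differences, runs the cluster-based permutation test,
#' and writes the per-window statistics (CSV) plus a cluster summary
#' (JSON). For SVM runs with a significant cluster, the feature-weight
#' topography of the first significant cluster is computed and written as
#' well.
#'
#' @param cfg a [run_config()].
#' @param mode `"svm"` or `"svr"`.
#' @param dimension question dimension.
#' @param feature_weights compute the topography (SVM only).
#' @return invisibly, the [cluster_permutation_test()] result.
#' @export
stage_group <- function(cfg, mode = c("svm", "svr"),
                        dimension = c("appealing", "curiosity", "wanting"),
                        feature_weights = TRUE) {
  mode <- match.arg(mode)
  dimension <- match.arg(dimension)
  out <- cfg$paths$output_dir
  f <- require_path(file.path(out, sprintf("decode_%s_%s.csv", mode, dimension)),
                    sprintf("run stage_decode(cfg, mode = \"%s\") first", mode))
  df <- utils::read.csv(f, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop_invalid("decode result %s is empty", f)
  pids <- unique(df$participant)
  times <- sort(unique(df$window_time_ms))
  diffs <- t(vapply(pids, function(p) {
    dp <- df[df$participant == p, ]
    dp <- dp[order(dp$window_time_ms), ]
    dp$value_true - dp$value_null
  }, numeric(length(times))))
  res <- cluster_permutation_test(
    diffs, n_permutations = cfg$group$n_permutations,
    alpha_forming = cfg$group$alpha_forming,
    alpha_cluster = cfg$group$alpha_cluster,
    seed = derive_seed(cfg$seed, "group", mode, dimension),
    times_ms = times)

  cluster_id <- rep(NA_integer_, length(times))
  cluster_p <- rep(NA_real_, length(times))
  for (i in seq_len(nrow(res$clusters))) {
    idx <- res$clusters$start[i]:res$clusters$end[i]
    cluster_id[idx] <- i
    cluster_p[idx] <- res$clusters$cluster_p[i]
  }
  utils::write.csv(
    data.frame(window_time_ms = times, t = res$t,
               p_uncorrected = res$p_uncorrected, cluster_id = cluster_id,
               cluster_p = cluster_p, significant = res$significant),
    file.path(out, sprintf("group_%s_%s.csv", mode, dimension)),
    row.names = FALSE)
  jsonlite::write_json(
    list(stage = "group", mode = mode, dimension = dimension,
         n_participants = res$n_participants,
         n_permutations = res$n_cluster_permutations,
         alpha_forming = res$alpha_forming,
         alpha_cluster = res$alpha_cluster,
         clusters = res$clusters, seed = cfg$seed),
    file.path(out, sprintf("group_%s_%s.json", mode, dimension)),
    auto_unbox = TRUE, digits = NA)

  sig <- which(res$clusters$cluster_p < res$alpha_cluster)
  if (feature_weights && mode == "svm" && length(sig)) {
    first <- sig[1]
    cl_windows <- res$clusters$start[first]:res$clusters$end[first]
    datasets <- lapply(read_study(cfg), preprocess)
    grid <- build_windows(datasets[[1]]$times, datasets[[1]]$sampling_rate,
                          cfg_decode_params(cfg)$window_ms)
    fw <- feature_weight_map(datasets, dimension, cl_windows, grid,
                             cfg_decode_params(cfg),
                             seed = derive_seed(cfg$seed, "fw", dimension))
    utils::write.csv(
      data.frame(channel = fw$channel_labels, weight_z = fw$weight_z,
                 t = fw$t, p = fw$p, significant = fw$significant),
      file.path(out, sprintf("featureweights_%s_%s.csv", mode, dimension)),
      row.names = FALSE)
  } else if (feature_weights && mode == "svm") {
    log_msg(cfg, "no significant cluster for %s/%s; feature-weight map skipped",
            mode, dimension)
  }
  invisible(res)
}

#' Behavioral descriptives, ANOVAs and image-level correlations
#'
#' Consumes the trial-level responses written by [stage_simulate()] and
#' writes the stratified descriptive table, one-way ANOVAs (with
#' Bonferroni post hocs) of Yes counts and mean ratings by vaping status,
#' and image-level response/rating correlations, per dimension.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the computed tables.
#' @export
stage_behavior <- function(cfg) {
  out <- cfg$paths$output_dir
  f <- require_path(file.path(out, "responses.csv"),
                    "run stage_simulate(cfg) first")
  responses <- utils::read.csv(f, stringsAsFactors = FALSE)
  tab <- behavioral_table(responses)
  desc <- behavior_descriptives(tab)
  utils::write.csv(desc, file.path(out, "behavior_descriptives.csv"),
                   row.names = FALSE)

  anova_rows <- list(); posthoc_rows <- list(); corr_rows <- list()
  for (dm in unique(tab$dimension)) {
    td <- tab[tab$dimension == dm, ]
    for (variable in c("yes_count", "mean_rating")) {
      a <- tryCatch(oneway_anova_bonferroni(td[[variable]], td$group),
                    error = function(e) NULL)
      if (is.null(a)) {
        # too few usable groups for this dimension: record, don't abort
        anova_rows[[length(anova_rows) + 1L]] <- data.frame(
          dimension = dm, variable = variable, F = NA_real_, p = NA_real_,
          df1 = NA_real_, df2 = NA_real_, degenerate = TRUE)
        next
      }
      anova_rows[[length(anova_rows) + 1L]] <- data.frame(
        dimension = dm, variable = variable, F = a$F, p = a$p,
        df1 = a$df[1], df2 = a$df[2], degenerate = a$degenerate)
      ph <- a$posthoc
      ph$dimension <- dm; ph$variable <- variable
      posthoc_rows[[length(posthoc_rows) + 1L]] <- ph
    }
    co <- image_level_correlation(responses, dm)
    corr_rows[[length(corr_rows) + 1L]] <- data.frame(
      dimension = dm, r_yes = co$r_yes, p_yes = co$p_yes,
      r_no = co$r_no, p_no = co$p_no, flagged = co$flagged)
  }
  anova_df <- do.call(rbind, anova_rows)
  posthoc_df <- if (length(posthoc_rows)) do.call(rbind, posthoc_rows) else
    data.frame(group1 = character(), group2 = character(), t = numeric(),
               p_raw = numeric(), p_adj = numeric(), significant = logical(),
               dimension = character(), variable = character())
  corr_df <- do.call(rbind, corr_rows)
  utils::write.csv(anova_df, file.path(out, "behavior_anova.csv"),
                   row.names = FALSE)
  utils::write.csv(posthoc_df, file.path(out, "behavior_posthoc.csv"),
                   row.names = FALSE)
  utils::write.csv(corr_df, file.path(out, "behavior_correlations.csv"),
                   row.names = FALSE)
  log_msg(cfg, "behavioral tables written to %s", out)
  invisible(list(table = tab, descriptives = desc, anova = anova_df,
                 posthoc = posthoc_df, correlations = corr_df))
}

#' Summarise a run
#'
#' Collects every group-inference output present in the run directory
#' into a single report: significant window ranges per mode and
#' dimension, the eligibility log, and tidy time-course data (group mean
#' true/null series with the significance mask) for plotting.
#'
#' @param cfg a [run_config()].
#' @return invisibly, the report list.
#' @export
stage_report <- function(cfg) {
  out <- cfg$paths$output_dir
  gf <- list.files(out, pattern = "^group_(svm|svr)_.*\\.csv$")
  if (length(gf) == 0)
    stop_invalid("missing input: no group_*.csv under %s -- run stage_group first", out)
  summary <- list(); tc_rows <- list()
  for (f in gf) {
    parts <- strsplit(sub("\\.csv$", "", f), "_")[[1]]
    mode <- parts[2]; dm <- parts[3]
    g <- utils::read.csv(file.path(out, f), stringsAsFactors = FALSE)
    d <- utils::read.csv(file.path(out, sprintf("decode_%s_%s.csv", mode, dm)),
                         stringsAsFactors = FALSE)
    agg <- stats::aggregate(cbind(value_true, value_null) ~ window_time_ms,
                            d, mean)
    agg <- agg[order(agg$window_time_ms), ]
    sig_t <- g$window_time_ms[g$significant]
    summary[[paste(mode, dm, sep = "_")]] <- list(
      mode = mode, dimension = dm,
      n_significant_windows = length(sig_t),
      significant_range_ms = if (length(sig_t)) range(sig_t) else NULL)
    tc_rows[[f]] <- data.frame(mode = mode, dimension = dm,
                               window_time_ms = agg$window_time_ms,
                               mean_true = agg$value_true,
                               mean_null = agg$value_null,
                               significant = g$significant[
                                 match(agg$window_time_ms, g$window_time_ms)])
  }
  elig_files <- list.files(out, pattern = "^decode_.*_manifest\\.json$")
  eligibility <- lapply(file.path(out, elig_files), jsonlite::read_json,
                        simplifyVector = TRUE)
  names(eligibility) <- sub("_manifest\\.json$", "", elig_files)
  report <- list(stage = "report", seed = cfg$seed, summary = summary,
                 eligibility = lapply(eligibility, `[[`, "eligible"))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(do.call(rbind, tc_rows),
                   file.path(out, "report_timecourse.csv"), row.names = FALSE)
  log_msg(cfg, "report written to %s", file.path(out, "report.json"))
  invisible(report)
}
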
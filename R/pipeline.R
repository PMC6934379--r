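# End-to-end orchestration: simulate (optional) -> qc -> score -> stats ->
# cluster, with all stage outputs and a run manifest written to disk.

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML path")
  config
}

build_cohort_config <- function(sim, seed) {
  args <- sim[intersect(names(sim),
                        names(formals(cohort_config)))]
  if (!is.null(args$baseline)) args$baseline <- do.call(trial_model_params,
                                                        args$baseline)
  if (!is.null(args$transgenic_delta)) {
    args$transgenic_delta <- unlist(args$transgenic_delta)
  }
  if (identical(sim$presets, "performance")) args$presets <- performance_presets()
  args$seed <- args$seed %||% seed
  do.call(cohort_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order — `simulate` (optional synthetic
#' cohort with optional defect injection), `qc` (batch screening), `score`
#' (per-session measures with probe-pair averaging), `stats` (per-stratum
#' genotype x stimulus-duration split-plot ANOVAs and effect calls) and
#' `cluster` (trajectory k-means, high/mid/low labelling and genotype
#' membership tests) — writing every stage's outputs as CSV/JSON plus a run
#' manifest under `out_dir`. Configuration is a YAML file or an equivalent
#' nested list; every source of randomness derives from `seed`.
#'
#' @param config path to a YAML config, or a nested list. Recognised
#'   sections: `simulate` ([cohort_config()] fields, plus `defects` rates),
#'   `input_dir` (directory of XML files when not simulating), `roster`
#'   (CSV path; simulated runs use the generated roster), `qc`
#'   (`min_trials`, `min_duration_min`, `iqr_multiplier`), `stats`
#'   (`measures`), `cluster` (`variables`, `k`, `restarts`),
#'   `stages` (subset of the five stage names).
#' @param seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return invisibly, a list with the manifest and in-memory stage results.
#' @export
run_pipeline <- function(config, seed = 1, out_dir = "tscog-out",
                         log_level = c("info", "quiet", "debug")) {
  log_level <- match.arg(log_level)
  say <- function(fmt, ...) {
    if (log_level != "quiet") message(sprintf(paste0("[tscog] ", fmt), ...))
  }
  cfg <- read_pipeline_config(config)
  stages <- cfg$stages %||% c("simulate", "qc", "score", "stats", "cluster")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  # --- simulate ------------------------------------------------------------
  files <- NULL; roster <- NULL; truth <- NULL
  if ("simulate" %in% stages && !is.null(cfg$simulate)) {
    cc <- build_cohort_config(cfg$simulate, seed)
    say("simulate: %s cohort, seed %s", cc$task, cc$seed)
    sim <- simulate_cohort(cc)
    files <- sim$files; roster <- sim$roster; truth <- sim$truth
    if (!is.null(cfg$simulate$defects)) {
      dargs <- cfg$simulate$defects
      ds <- defect_spec(dargs$rate_duplicate %||% 0.05,
                        dargs$rate_bad_id %||% 0.05,
                        dargs$rate_truncation %||% 0.05)
      inj <- inject_defects(files, ds, seed = child_seed(seed, 17))
      files <- inj$files
      utils::write.csv(inj$truth_log, file.path(out_dir, "defect_truth.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    utils::write.csv(roster, file.path(out_dir, "roster.csv"),
                     row.names = FALSE)
    results$truth <- truth
  } else {
    input_dir <- cfg$input_dir
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      stopf("config key 'input_dir' missing or directory not found")
    }
    paths <- list.files(input_dir, pattern = "\\.xml$", full.names = TRUE)
    files <- setNames(paths, basename(paths))
    if (!is.null(cfg$roster)) {
      roster <- utils::read.csv(cfg$roster, stringsAsFactors = FALSE)
    }
  }

  # --- qc ------------------------------------------------------------------
  qc <- NULL
  if ("qc" %in% stages) {
    qcfg <- cfg$qc %||% list()
    say("qc: screening %d files", length(files))
    qc <- run_qc_batch(
      files, roster = roster %||% character(),
      params = iqr_filter_params(qcfg$iqr_multiplier %||% 3),
      min_trials = qcfg$min_trials %||% 10,
      min_duration_min = qcfg$min_duration_min %||% 10)
    write_qc_report(qc$report, file.path(out_dir, "qc_flags.csv"),
                    file.path(out_dir, "qc_summary.json"))
    say("qc: %d pass, %d fixed, %d discarded (%.1f%% flagged)",
        qc$report$n_pass, qc$report$n_fixed, qc$report$n_discarded,
        qc$report$pct_flagged)
    results$qc <- qc$report
  }

  # --- score ---------------------------------------------------------------
  metrics <- NULL; probe <- NULL
  if ("score" %in% stages && !is.null(qc)) {
    say("score: %d clean sessions", length(qc$clean))
    metrics <- do.call(rbind, lapply(qc$clean, score_session,
                                     latency_thresholds = qc$report))
    if (!is.null(metrics)) {
      export_metrics_csv(metrics, file.path(out_dir, "session_metrics.csv"))
      if (any(metrics$schedule == "probe")) {
        pm <- metrics[metrics$schedule == "probe", , drop = FALSE]
        key <- interaction(pm$animal_id, pm$age_bin, drop = TRUE)
        probe <- do.call(rbind, lapply(split(pm, key), function(sub) {
          ap <- suppressWarnings(average_probe_pairs(sub))
          cbind(data.frame(
            observation_id = sprintf("%s_%s", sub$animal_id[1], sub$age_bin[1]),
            animal_id = sub$animal_id[1], strain = sub$strain[1],
            genotype = sub$genotype[1], sex = sub$sex[1],
            age_bin = sub$age_bin[1], stringsAsFactors = FALSE), ap)
        }))
        row.names(probe) <- NULL
        utils::write.csv(probe, file.path(out_dir, "probe_metrics.csv"),
                         row.names = FALSE)
      }
    }
    results$metrics <- metrics; results$probe <- probe
  }

  # --- stats ---------------------------------------------------------------
  if ("stats" %in% stages && !is.null(probe)) {
    measures <- (cfg$stats %||% list())$measures %||%
      c("accuracy_pct", "omission_pct", "premature_count",
        "perseverative_count", "mean_correct_latency_s",
        "mean_reward_latency_s")
    say("stats: split-plot ANOVAs on %d measures", length(measures))
    anova_rows <- list(); call_rows <- list()
    strata <- unique(probe[, c("strain", "sex", "age_bin")])
    for (i in seq_len(nrow(strata))) {
      sel <- probe$strain == strata$strain[i] & probe$sex == strata$sex[i] &
        probe$age_bin == strata$age_bin[i]
      sub <- probe[sel, , drop = FALSE]
      for (m in measures) {
        d <- data.frame(subject = sub$observation_id,
                        between = sub$genotype,
                        within = sub$stimulus_duration_s,
                        value = sub[[m]], stringsAsFactors = FALSE)
        d <- d[!is.na(d$value), , drop = FALSE]
        keep <- names(which(table(d$subject) == length(unique(d$within))))
        d <- d[d$subject %in% keep, , drop = FALSE]
        fit <- tryCatch(splitplot_anova(d), error = function(e) NULL)
        if (is.null(fit)) next
        tb <- fit$table
        tb <- cbind(strata[i, , drop = FALSE], measure = m, tb,
                    row.names = NULL)
        anova_rows[[length(anova_rows) + 1]] <- tb
        polarity <- if (m %in% c("accuracy_pct")) "higher-is-better" else
          "lower-is-better"
        call_rows[[length(call_rows) + 1]] <- cbind(
          strata[i, , drop = FALSE],
          summarize_effect(fit, measure = m, polarity = polarity),
          row.names = NULL)
      }
    }
    if (length(anova_rows)) {
      utils::write.csv(do.call(rbind, anova_rows),
                       file.path(out_dir, "anova_tables.csv"),
                       row.names = FALSE)
      calls <- do.call(rbind, call_rows)
      utils::write.csv(calls, file.path(out_dir, "effect_calls.csv"),
                       row.names = FALSE)
      results$effect_calls <- calls
    }
  }

  # --- cluster -------------------------------------------------------------
  if ("cluster" %in% stages && !is.null(probe)) {
    ccfg <- cfg$cluster %||% list()
    vars <- ccfg$variables %||%
      c("accuracy_pct", "omission_pct", "premature_count",
        "perseverative_count", "mean_correct_latency_s",
        "mean_reward_latency_s")
    long <- stats::reshape(
      probe[, c("observation_id", "stimulus_duration_s", vars)],
      direction = "long", varying = vars, v.names = "value",
      times = vars, timevar = "variable", idvar = "rowid")
    long$timepoint <- long$stimulus_duration_s
    ts <- build_trajectories(long, variables = vars,
                             timepoints = sort(unique(long$timepoint),
                                               decreasing = TRUE))
    say("cluster: %d observations", length(ts$ids))
    km <- kmeans_longitudinal(ts, k = ccfg$k %||% 3,
                              restarts = ccfg$restarts %||% 20,
                              seed = child_seed(seed, 23))
    km <- label_clusters(km, ts)
    groups <- unique(probe[, c("observation_id", "strain", "sex", "age_bin",
                               "genotype")])
    groups <- groups[groups$observation_id %in% names(km$labelled), ,
                     drop = FALSE]
    assign_df <- merge(
      data.frame(observation_id = names(km$labelled),
                 cluster = unname(km$assignments),
                 label = unname(km$labelled), stringsAsFactors = FALSE),
      groups, by = "observation_id")
    utils::write.csv(assign_df, file.path(out_dir, "cluster_assignments.csv"),
                     row.names = FALSE)
    tests <- compare_membership(km, groups)
    utils::write.csv(as.data.frame(tests),
                     file.path(out_dir, "membership_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(membership_percent(km, groups),
                     file.path(out_dir, "membership_percent.csv"),
                     row.names = FALSE)
    results$cluster <- km; results$membership_tests <- tests
  }

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    command = "run_pipeline",
    seed = seed,
    stages = stages,
    out_dir = out_dir,
    tool_version = as.character(utils::packageVersion("tscog")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    counts = if (!is.null(qc)) list(
      files_in = qc$report$n_total, n_pass = qc$report$n_pass,
      n_fixed = qc$report$n_fixed, n_discarded = qc$report$n_discarded,
      pct_flagged = qc$report$pct_flagged) else NULL
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  say("done: outputs in %s", out_dir)
  invisible(results)
}
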
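# Per-session behavioural measures and their aggregations: probe-pair
# averaging (5-CSRTT), vigilance blocks, session bins (PAL), and
# sessions-to-criterion.

score_trials <- function(trials, latency_thresholds = NULL) {
  nc <- trials[!trials$is_correction, , drop = FALSE]
  n_correct <- sum(nc$outcome == "correct")
  n_incorrect <- sum(nc$outcome == "incorrect")
  n_omission <- sum(nc$outcome == "omission")
  n_premature <- sum(nc$outcome == "premature")
  n_resp <- n_correct + n_incorrect

  accuracy <- if (n_resp == 0) NA_real_ else 100 * n_correct / n_resp
  om_den <- n_correct + n_incorrect + n_omission
  omission <- if (om_den == 0) NA_real_ else 100 * n_omission / om_den

  lat <- nc[nc$outcome == "correct", c("touch_latency", "reward_latency"),
            drop = FALSE]
  masked_mean <- function(v, thr) {
    v <- v[!is.na(v)]
    raw <- if (length(v)) mean(v) else NA_real_
    if (!is.null(thr) && is.finite(thr)) v <- v[v <= thr]
    list(raw = raw, masked = if (length(v)) mean(v) else NA_real_)
  }
  thr_touch <- latency_thresholds$touch_latency %||% NULL
  thr_reward <- latency_thresholds$reward_latency %||% NULL
  tl <- masked_mean(lat$touch_latency, thr_touch)
  rl <- masked_mean(lat$reward_latency, thr_reward)

  data.frame(
    n_trials = nrow(nc),
    n_correct = n_correct,
    n_incorrect = n_incorrect,
    n_omission = n_omission,
    n_premature = n_premature,
    n_correction = sum(trials$is_correction),
    accuracy_pct = accuracy,
    omission_pct = omission,
    premature_count = n_premature,
    perseverative_count = sum(nc$persev, na.rm = TRUE),
    mean_correct_latency_s = tl$masked,
    mean_reward_latency_s = rl$masked,
    mean_correct_latency_raw_s = tl$raw,
    mean_reward_latency_raw_s = rl$raw,
    stringsAsFactors = FALSE
  )
}

#' Score one session
#'
#' Computes the standard behavioural measures over the session's
#' non-correction trials. Accuracy is the percentage correct of responded
#' trials (correct + incorrect); omissions and premature responses do not
#' count towards accuracy. The omission percentage is taken over trials that
#' reached stimulus presentation (correct + incorrect + omission); premature
#' trials never present a stimulus. Correction trials are counted separately
#' and never enter the overall trial count. Latency means are computed over
#' correct trials, optionally excluding batch-level extreme outliers via the
#' thresholds attached to a QC report; unmasked means are retained in
#' `mean_*_raw_s` columns for audit.
#'
#' @param record a [session_record()] that passed QC.
#' @param latency_thresholds optional list with `touch_latency` and/or
#'   `reward_latency` upper fences (seconds) from [run_qc_batch()]'s
#'   `iqr_thresholds`, or a `qc_report` (the task's row is looked up).
#' @return one-row data frame of class `session_metrics` including subject
#'   metadata columns.
#' @export
score_session <- function(record, latency_thresholds = NULL) {
  if (inherits(latency_thresholds, "qc_report")) {
    th <- latency_thresholds$iqr_thresholds
    th <- th[th$task == record$task, , drop = FALSE]
    latency_thresholds <- list(
      touch_latency = th$threshold[th$feature == "touch_latency"][1],
      reward_latency = th$threshold[th$feature == "reward_latency"][1])
  }
  m <- score_trials(record$trials, latency_thresholds)
  if (m$n_correct + m$n_incorrect == 0) {
    warnf("session '%s': no responded trials; accuracy undefined",
          record$file_ref)
  }
  out <- cbind(
    data.frame(
      file_ref = record$file_ref,
      animal_id = record$meta$animal_id,
      strain = record$meta$strain,
      genotype = record$meta$genotype,
      sex = record$meta$sex,
      age_months = record$meta$age_months,
      age_bin = record$meta$age_bin,
      site = record$meta$site,
      task = record$task,
      schedule = record$schedule,
      session_date = record$session_date,
      stimulus_duration_s = record$stim_dur_s,
      stringsAsFactors = FALSE
    ),
    m
  )
  class(out) <- c("session_metrics", "data.frame")
  out
}

#' Vigilance profile: measures across within-session trial blocks
#'
#' Sustained attention is assessed by partitioning a 5-CSRTT session's
#' non-correction trials into consecutive blocks (default 10 trials, so a
#' full 50-trial session gives 5 blocks) and scoring each block. A final
#' partial block is retained and marked so that per-block counts always sum
#' to the session counts.
#'
#' @param record a 5-CSRTT [session_record()].
#' @param block_size trials per block (default 10).
#' @return data frame, one row per block, with `block_index`, `partial` and
#'   the [score_session()] measure columns.
#' @export
vigilance_blocks <- function(record, block_size = 10) {
  if (!identical(record$task, "5-CSRTT")) {
    stopf("vigilance blocks are defined for 5-CSRTT sessions")
  }
  nc_idx <- which(!record$trials$is_correction)
  n <- length(nc_idx)
  if (n == 0) {
    out <- cbind(data.frame(block_index = integer(), partial = logical()),
                 score_trials(empty_trials())[0, ])
    return(out)
  }
  n_blocks <- ceiling(n / block_size)
  rows <- lapply(seq_len(n_blocks), function(b) {
    lo <- (b - 1) * block_size + 1
    hi <- min(b * block_size, n)
    blk <- record$trials[nc_idx[lo:hi], , drop = FALSE]
    cbind(data.frame(block_index = b, partial = (hi - lo + 1) < block_size),
          score_trials(blk))
  })
  do.call(rbind, rows)
}

#' Average probe-session pairs per stimulus duration
#'
#' 5-CSRTT probe testing presents each reduced stimulus duration (1.5, 1.0,
#' 0.8, 0.6 s) on two consecutive days; measures are analysed as the average
#' of each pair. A duration represented by a single session passes through
#' with a completeness warning; three or more sessions at one duration is an
#' error (duplicates should have been resolved by QC).
#'
#' @param metrics data frame of per-session metrics (rows from
#'   [score_session()]) for one subject at one testing age, including the
#'   `stimulus_duration_s` column.
#' @return data frame with one row per duration present (ordered 1.5, 1.0,
#'   0.8, 0.6): `stimulus_duration_s`, `n_sessions`, and the mean of every
#'   numeric measure column.
#' @export
average_probe_pairs <- function(metrics) {
  d <- metrics$stimulus_duration_s
  if (any(is.na(d)) || !all(d %in% PROBE_DURATIONS)) {
    stopf("probe stimulus durations must be in {1.5, 1.0, 0.8, 0.6}")
  }
  counts <- table(d)
  if (any(counts > 2)) {
    stopf("more than two probe sessions at duration(s) %s",
          paste(names(counts)[counts > 2], collapse = ", "))
  }
  if (any(counts == 1)) {
    warnf("single probe session at duration(s) %s",
          paste(names(counts)[counts == 1], collapse = ", "))
  }
  measure_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  measure_cols <- setdiff(measure_cols, c("age_months", "stimulus_duration_s"))
  present <- PROBE_DURATIONS[PROBE_DURATIONS %in% d]
  rows <- lapply(present, function(dd) {
    sub <- metrics[d == dd, , drop = FALSE]
    means <- vapply(measure_cols,
                    function(cc) mean(sub[[cc]], na.rm = TRUE), numeric(1))
    means[is.nan(means)] <- NA_real_
    cbind(data.frame(stimulus_duration_s = dd, n_sessions = nrow(sub)),
          as.data.frame(as.list(means)))
  })
  do.call(rbind, rows)
}

#' Training-criterion specification
#'
#' Performance criterion for advancing between training stages, e.g. for
#' 5-CSRTT training: accuracy strictly above 80%, omissions strictly below
#' 20%, and 30-50 trials completed, on three consecutive sessions, within a
#' 30-session cap. The PD acquisition form (24/30 correct on two consecutive
#' days) is expressed as `criterion_spec(80, 100, c(30, 30), 2)`.
#'
#' @param min_accuracy_pct accuracy must exceed this (strict).
#' @param max_omission_pct omissions must be below this (strict).
#' @param trial_range inclusive `(min, max)` completed non-correction trials.
#' @param consecutive_sessions length of the qualifying run.
#' @param session_cap give up after this many sessions (`Inf` for none).
#' @return an object of class `criterion_spec`.
#' @export
criterion_spec <- function(min_accuracy_pct = 80, max_omission_pct = 20,
                           trial_range = c(30, 50),
                           consecutive_sessions = 3, session_cap = 30) {
  stopifnot(min_accuracy_pct > 0, max_omission_pct > 0,
            length(trial_range) == 2, consecutive_sessions >= 1)
  structure(list(min_accuracy_pct = min_accuracy_pct,
                 max_omission_pct = max_omission_pct,
                 trial_range = trial_range,
                 consecutive_sessions = consecutive_sessions,
                 session_cap = session_cap),
            class = "criterion_spec")
}

#' Sessions to criterion
#'
#' Scans a date-ordered sequence of session metrics for the first run of
#' `consecutive_sessions` sessions that each satisfy the criterion
#' (inequalities are strict, trial range inclusive) and returns the 1-based
#' index of the run's last session — the number of sessions needed to reach
#' criterion. Returns `NA` (not reached) when no qualifying run ends within
#' the session cap; subjects that never reach criterion within the cap are
#' eliminated from further testing.
#'
#' @param metrics data frame with `accuracy_pct`, `omission_pct`, `n_trials`,
#'   ordered by session date.
#' @param spec a [criterion_spec()].
#' @return integer session count, or `NA_integer_` if not reached.
#' @export
sessions_to_criterion <- function(metrics, spec = criterion_spec()) {
  n <- nrow(metrics)
  if (n == 0) return(NA_integer_)
  horizon <- min(n, spec$session_cap)
  ok <- !is.na(metrics$accuracy_pct) &
    metrics$accuracy_pct > spec$min_accuracy_pct &
    !is.na(metrics$omission_pct) &
    metrics$omission_pct < spec$max_omission_pct &
    metrics$n_trials >= spec$trial_range[1] &
    metrics$n_trials <= spec$trial_range[2]
  run <- 0L
  for (i in seq_len(horizon)) {
    run <- if (ok[i]) run + 1L else 0L
    if (run >= spec$consecutive_sessions) return(i)
  }
  NA_integer_
}

#' Bin sessions into fixed-size intervals
#'
#' Longitudinal testing over many daily sessions (e.g. the 45 PAL sessions)
#' is analysed in bins of consecutive sessions: bin 1 is sessions 1-5
#' ("week 1"), bin 2 sessions 6-10, and so on for the default bin size of 5.
#' Each numeric measure is averaged within the bin. A final partial bin is
#' retained and marked rather than dropped.
#'
#' @param metrics session-ordered data frame of per-session metrics.
#' @param bin_size sessions per bin (default 5).
#' @return data frame with `bin_index`, `n_sessions`, `partial`, and the mean
#'   of every numeric measure column.
#' @export
bin_sessions <- function(metrics, bin_size = 5) {
  n <- nrow(metrics)
  measure_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  measure_cols <- setdiff(measure_cols, c("age_months", "stimulus_duration_s"))
  if (n == 0) {
    return(cbind(data.frame(bin_index = integer(), n_sessions = integer(),
                            partial = logical()),
                 metrics[0, measure_cols, drop = FALSE]))
  }
  n_bins <- ceiling(n / bin_size)
  if (n %% bin_size != 0) {
    warnf("session count %d not a multiple of bin size %d; final bin partial",
          n, bin_size)
  }
  rows <- lapply(seq_len(n_bins), function(b) {
    lo <- (b - 1) * bin_size + 1
    hi <- min(b * bin_size, n)
    sub <- metrics[lo:hi, , drop = FALSE]
    means <- vapply(measure_cols,
                    function(cc) mean(sub[[cc]], na.rm = TRUE), numeric(1))
    means[is.nan(means)] <- NA_real_
    cbind(data.frame(bin_index = b, n_sessions = hi - lo + 1,
                     partial = (hi - lo + 1) < bin_size),
          as.data.frame(as.list(means)))
  })
  do.call(rbind, rows)
}
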
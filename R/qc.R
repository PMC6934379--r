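# Automated quality control: per-file validation rules, duplicate-session
# resolution, and the one-sided Q3 + k*IQR extreme-outlier filter applied to
# temporal features.

QC_RULES <- c("SCHEMA_MISSING", "BAD_ANIMAL_ID", "DUPLICATE_SESSION",
              "INCOMPLETE_SESSION", "VALUE_OUT_OF_RANGE")

qc_flag <- function(rule_id, severity, message, file_ref = NA_character_) {
  stopifnot(rule_id %in% QC_RULES, severity %in% c("fixable", "fatal"))
  data.frame(rule_id = rule_id, severity = severity, message = message,
             file_ref = file_ref, stringsAsFactors = FALSE)
}

no_flags <- function() {
  data.frame(rule_id = character(), severity = character(),
             message = character(), file_ref = character(),
             stringsAsFactors = FALSE)
}

#' Extreme-outlier filter parameters
#'
#' Parameters of the one-sided interquartile-range filter used on temporal
#' features (response latencies): a value is an extreme outlier when it
#' exceeds Q3 + `multiplier` * IQR. The default multiplier of 3 targets
#' extreme outliers only.
#'
#' @param multiplier positive fence multiplier (default 3).
#' @return an object of class `iqr_filter_params`.
#' @export
iqr_filter_params <- function(multiplier = 3) {
  stopifnot(is.numeric(multiplier), multiplier > 0)
  structure(list(multiplier = multiplier), class = "iqr_filter_params")
}

#' Quartile by linear interpolation of order statistics
#'
#' With sorted values `x[0..n-1]` and `h = (n-1) * p`, returns
#' `x[floor(h)] + (h - floor(h)) * (x[floor(h) + 1] - x[floor(h)])`
#' (the convention of `stats::quantile(type = 7)`, to which this delegates).
#'
#' @param values non-empty numeric vector.
#' @param p probability in \[0, 1\].
#' @return the interpolated quantile.
#' @export
#' @examples
#' compute_quartile(c(1, 2, 3, 4), 0.75)  # 3.25
compute_quartile <- function(values, p) {
  if (length(values) == 0) stopf("compute_quartile: empty input")
  stopifnot(p >= 0, p <= 1)
  unname(stats::quantile(values, probs = p, type = 7, names = FALSE))
}

#' Flag extreme outliers above Q3 + k * IQR
#'
#' One-sided fence: `mask[i]` is `TRUE` iff
#' `values[i] > Q3 + multiplier * (Q3 - Q1)`. Latencies are bounded below by
#' zero, so no lower fence is applied. Flagged values are excluded from
#' downstream aggregation but never removed from raw storage.
#'
#' @param values numeric vector; all entries must be finite.
#' @param params an [iqr_filter_params()].
#' @return logical mask the length of `values`. With fewer than 4 values the
#'   mask is all-`FALSE` and a warning is raised (quartiles are unstable).
#' @export
#' @examples
#' iqr_outlier_mask(c(1:8, 100))  # only 100 flagged
iqr_outlier_mask <- function(values, params = iqr_filter_params()) {
  bad <- which(!is.finite(values))
  if (length(bad)) {
    stopf("non-finite values at positions: %s",
          paste(bad, collapse = ", "))
  }
  if (length(values) < 4) {
    warnf("fewer than 4 values; outlier mask suppressed")
    return(rep(FALSE, length(values)))
  }
  q1 <- compute_quartile(values, 0.25)
  q3 <- compute_quartile(values, 0.75)
  values > q3 + params$multiplier * (q3 - q1)
}

#' Validate one session against the QC rule set
#'
#' Emits `SCHEMA_MISSING` (fixable) per required field the parser found
#' missing, `BAD_ANIMAL_ID` (fixable) when the animal is not on the roster,
#' `INCOMPLETE_SESSION` (fatal) when the session has both fewer than
#' `min_trials` non-correction trials and a duration under `min_duration_min`
#' (the signature of a software failure at session start), and
#' `VALUE_OUT_OF_RANGE` (fatal) for negative latencies, trial counts above
#' the task maximum, or a 5-CSRTT probe stimulus duration outside
#' \{1.5, 1.0, 0.8, 0.6\} s.
#'
#' @param record a parsed [session_record()].
#' @param roster data frame with an `animal_id` column (unique IDs), or a
#'   character vector of IDs.
#' @param min_trials,min_duration_min incomplete-session thresholds
#'   (defaults 10 trials / 10 minutes; both must be violated).
#' @return a flag data frame (zero rows when the session is clean).
#' @export
validate_session <- function(record, roster, min_trials = 10,
                             min_duration_min = 10) {
  ids <- if (is.data.frame(roster)) roster$animal_id else roster
  if (anyDuplicated(ids)) stopf("roster animal_ids are not unique")
  fr <- record$file_ref
  flags <- no_flags()

  for (ann in record$annotations) {
    if (startsWith(ann, "missing:")) {
      flags <- rbind(flags, qc_flag(
        "SCHEMA_MISSING", "fixable",
        sprintf("required field '%s' missing", sub("^missing:", "", ann)), fr))
    }
  }
  if (!is.na(record$meta$animal_id) && !(record$meta$animal_id %in% ids)) {
    flags <- rbind(flags, qc_flag(
      "BAD_ANIMAL_ID", "fixable",
      sprintf("animal_id '%s' not on roster", record$meta$animal_id), fr))
  }
  n_trials <- n_noncorrection(record)
  if (!is.na(record$duration_min) &&
      n_trials < min_trials && record$duration_min < min_duration_min) {
    flags <- rbind(flags, qc_flag(
      "INCOMPLETE_SESSION", "fatal",
      sprintf("only %d trials in %.1f min", n_trials, record$duration_min), fr))
  }
  tr <- record$trials
  neg <- (!is.na(tr$touch_latency) & tr$touch_latency < 0) |
    (!is.na(tr$reward_latency) & tr$reward_latency < 0)
  if (any(neg)) {
    flags <- rbind(flags, qc_flag(
      "VALUE_OUT_OF_RANGE", "fatal",
      sprintf("negative latency at trial(s) %s",
              paste(tr$index[neg], collapse = ", ")), fr))
  }
  if (record$task %in% TSCOG_TASKS &&
      n_trials > task_max_trials(record$task)) {
    flags <- rbind(flags, qc_flag(
      "VALUE_OUT_OF_RANGE", "fatal",
      sprintf("%d non-correction trials exceeds task maximum %d",
              n_trials, task_max_trials(record$task)), fr))
  }
  if (identical(record$task, "5-CSRTT") && identical(record$schedule, "probe") &&
      !is.na(record$stim_dur_s) && !(record$stim_dur_s %in% PROBE_DURATIONS)) {
    flags <- rbind(flags, qc_flag(
      "VALUE_OUT_OF_RANGE", "fatal",
      sprintf("probe stimulus duration %s s not in {1.5, 1.0, 0.8, 0.6}",
              record$stim_dur_s), fr))
  }
  flags
}

#' Resolve duplicate session files
#'
#' A software failure at session start followed by a restart produces two
#' files for the same mouse on the same day; the incomplete one must be
#' flagged and dropped. Records are grouped by (animal_id, session_date,
#' task, schedule); within each group the record with the most non-correction
#' trials is kept (ties: longer duration, then lexicographically smallest
#' `file_ref`); all others receive a fatal `DUPLICATE_SESSION` flag.
#'
#' @param records list of [session_record()]s.
#' @return `list(kept = <records>, flagged = <flag data frame>)`.
#' @export
resolve_duplicates <- function(records) {
  if (length(records) == 0) {
    return(list(kept = list(), flagged = no_flags()))
  }
  key <- vapply(records, function(r) {
    paste(r$meta$animal_id, format(r$session_date), r$task, r$schedule,
          sep = "|")
  }, character(1))
  keep <- logical(length(records))
  flagged <- no_flags()
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) == 1) { keep[idx] <- TRUE; next }
    n_tr <- vapply(records[idx], n_noncorrection, integer(1))
    dur <- vapply(records[idx], function(r) r$duration_min %||% NA_real_,
                  numeric(1))
    dur[is.na(dur)] <- -Inf
    refs <- vapply(records[idx], function(r) r$file_ref, character(1))
    ord <- order(-n_tr, -dur, refs)
    winner <- idx[ord[1]]
    keep[winner] <- TRUE
    for (j in idx[ord[-1]]) {
      flagged <- rbind(flagged, qc_flag(
        "DUPLICATE_SESSION", "fatal",
        sprintf("duplicate of '%s' (%d vs %d trials)",
                records[[winner]]$file_ref,
                n_noncorrection(records[[j]]), n_noncorrection(records[[winner]])),
        records[[j]]$file_ref))
    }
  }
  list(kept = records[keep], flagged = flagged)
}

#' QC throughput arithmetic
#'
#' Batch-level percentages from counts: the share of files carrying at least
#' one QC flag and the complementary passing share, each rounded to one
#' decimal as reported in run summaries.
#'
#' @param n_total total number of files screened.
#' @param n_flagged number of files with at least one flag.
#' @return list with `n_total`, `n_flagged`, `pct_flagged`, `pct_passed`.
#' @export
#' @examples
#' qc_throughput(62411, 487)  # 0.8% flagged, 99.2% passed
qc_throughput <- function(n_total, n_flagged) {
  stopifnot(n_total >= 0, n_flagged >= 0, n_flagged <= n_total)
  pct_flagged <- if (n_total == 0) NA_real_ else
    round(100 * n_flagged / n_total, 1)
  pct_passed <- if (n_total == 0) NA_real_ else
    round(100 * (n_total - n_flagged) / n_total, 1)
  list(n_total = n_total, n_flagged = n_flagged,
       pct_flagged = pct_flagged, pct_passed = pct_passed)
}
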
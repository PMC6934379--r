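#' Subject metadata
#'
#' Describes one animal: identity, strain, genotype, sex, age (with the
#' derived longitudinal age bin), test site and housing conditions.
#'
#' @param animal_id non-empty identifier token.
#' @param strain one of the supported mouse lines (see `TSCOG_STRAINS`).
#' @param genotype `"wildtype"` or `"transgenic"`.
#' @param sex `"female"` or `"male"`.
#' @param age_months integer age in months; the age bin (3-6, 7-10, 11-13)
#'   is derived from it.
#' @param site test-site token.
#' @param housing `"single"` or `"group"`.
#' @param light_cycle `"standard"` or `"reversed"`.
#' @return an object of class `subject_meta`.
#' @export
subject_meta <- function(animal_id, strain = "C57BL6/J", genotype = "wildtype",
                         sex = "female", age_months = 4L, site = "site1",
                         housing = "group", light_cycle = "reversed") {
  meta <- structure(
    list(
      animal_id = as.character(animal_id),
      strain = as.character(strain),
      genotype = as.character(genotype),
      sex = as.character(sex),
      age_months = as.integer(age_months),
      age_bin = age_bin_of(as.integer(age_months)),
      site = as.character(site),
      housing = as.character(housing),
      light_cycle = as.character(light_cycle)
    ),
    class = "subject_meta"
  )
  meta
}

validate_meta <- function(meta) {
  bad <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) msg else character()
  bad <- c(
    bad,
    chk(!is.na(meta$animal_id) && nzchar(meta$animal_id), "animal_id empty"),
    chk(is.na(meta$strain) || meta$strain %in% TSCOG_STRAINS,
        sprintf("strain '%s' not recognised", meta$strain)),
    chk(is.na(meta$genotype) || meta$genotype %in% TSCOG_GENOTYPES,
        sprintf("genotype '%s' invalid", meta$genotype)),
    chk(is.na(meta$sex) || meta$sex %in% TSCOG_SEXES,
        sprintf("sex '%s' invalid", meta$sex)),
    chk(is.na(meta$housing) || meta$housing %in% TSCOG_HOUSING,
        sprintf("housing '%s' invalid", meta$housing)),
    chk(is.na(meta$light_cycle) || meta$light_cycle %in% TSCOG_LIGHT_CYCLE,
        sprintf("light_cycle '%s' invalid", meta$light_cycle))
  )
  bad
}

#' Empty trial-event table
#'
#' The canonical trial-level representation: one row per screen event in
#' session order, correction trials included (flagged by `is_correction`).
#'
#' @return a zero-row data frame with the trial-event columns.
#' @export
empty_trials <- function() {
  data.frame(
    index = integer(),
    outcome = character(),
    is_correction = logical(),
    window = integer(),
    stim_dur = double(),
    touch_latency = double(),
    reward_latency = double(),
    persev = integer(),
    stringsAsFactors = FALSE
  )
}

#' One mouse-session event log
#'
#' A `session_record` is the unit of the pipeline: one file, one mouse, one
#' session. It holds subject metadata, the task/schedule context and the
#' ordered trial events. Parse annotations (e.g. missing fields found by the
#' lenient reader) ride along for the QC stage; unrecognised XML elements are
#' preserved in `extra` so that writing a parsed file loses nothing.
#'
#' @param meta a [subject_meta()] object.
#' @param task `"5-CSRTT"`, `"PD"` or `"PAL"`.
#' @param schedule training/testing schedule label (see `TSCOG_SCHEDULES`).
#' @param session_date a `Date` (or ISO-8601 string).
#' @param duration_min session duration, minutes in (0, 60].
#' @param stim_dur_s nominal stimulus duration in seconds (5-CSRTT only;
#'   `NA` otherwise).
#' @param trials trial-event data frame as produced by [empty_trials()].
#' @param annotations character vector of parse annotations.
#' @param extra named list of pass-through elements.
#' @param file_ref originating file reference (used in QC reports).
#' @return an object of class `session_record`.
#' @export
session_record <- function(meta, task, schedule, session_date, duration_min,
                           stim_dur_s = NA_real_, trials = empty_trials(),
                           annotations = character(), extra = list(),
                           file_ref = NA_character_) {
  structure(
    list(
      meta = meta,
      task = as.character(task),
      schedule = as.character(schedule),
      session_date = as.Date(session_date),
      duration_min = as.numeric(duration_min),
      stim_dur_s = as.numeric(stim_dur_s),
      trials = trials,
      annotations = annotations,
      extra = extra,
      file_ref = as.character(file_ref)
    ),
    class = "session_record"
  )
}

# Number of non-correction trials.
n_noncorrection <- function(record) sum(!record$trials$is_correction)

#' Check session-record invariants
#'
#' Returns the list of violated invariants (empty when the record is valid):
#' metadata enums, trial-count limits, monotone trial indices, the
#' latency-presence rule (latencies exactly on correct trials), the
#' correction-trial precedence rule, and probe stimulus durations.
#'
#' @param record a [session_record()].
#' @return character vector of violation messages.
#' @export
validate_record <- function(record) {
  bad <- validate_meta(record$meta)
  tr <- record$trials
  chk <- function(cond, msg) if (!isTRUE(cond)) msg else character()

  bad <- c(
    bad,
    chk(record$task %in% TSCOG_TASKS,
        sprintf("task '%s' invalid", record$task)),
    chk(record$schedule %in% TSCOG_SCHEDULES,
        sprintf("schedule '%s' invalid", record$schedule)),
    chk(!is.na(record$session_date), "session_date missing"),
    chk(is.na(record$duration_min) ||
          (record$duration_min > 0 && record$duration_min <= 60),
        "duration_min outside (0, 60]")
  )
  if (record$task %in% TSCOG_TASKS) {
    bad <- c(bad, chk(
      n_noncorrection(record) <= task_max_trials(record$task),
      sprintf("more than %d non-correction trials", task_max_trials(record$task))
    ))
  }
  if (identical(record$task, "5-CSRTT") && identical(record$schedule, "probe")) {
    bad <- c(bad, chk(
      is.na(record$stim_dur_s) || record$stim_dur_s %in% PROBE_DURATIONS,
      sprintf("probe stimulus duration %s not in {1.5, 1.0, 0.8, 0.6}",
              record$stim_dur_s)
    ))
  }

  if (nrow(tr) > 0) {
    bad <- c(
      bad,
      chk(all(tr$outcome %in% TSCOG_OUTCOMES), "unknown trial outcome"),
      chk(all(diff(tr$index) > 0), "trial indices not strictly increasing"),
      chk(all(is.na(tr$touch_latency) | tr$touch_latency >= 0),
          "negative touch latency"),
      chk(all(is.na(tr$reward_latency) | tr$reward_latency >= 0),
          "negative reward latency"),
      chk(all(is.na(tr$persev) | tr$persev >= 0),
          "negative perseveration count"),
      # latencies present exactly on correct trials
      chk(all(ifelse(tr$outcome == "correct",
                     !is.na(tr$touch_latency) & !is.na(tr$reward_latency),
                     is.na(tr$touch_latency) & is.na(tr$reward_latency))),
          "latencies must be present exactly on correct trials"),
      chk(all(ifelse(tr$outcome == "premature", is.na(tr$window), TRUE)),
          "premature trials must not carry a stimulus window")
    )
    # each correction run must be opened by an incorrect non-correction trial
    if (any(tr$is_correction)) {
      opens <- which(tr$is_correction)
      ok <- vapply(opens, function(i) {
        prev <- tr[seq_len(i - 1), , drop = FALSE]
        prev <- prev[!prev$is_correction, , drop = FALSE]
        nrow(prev) > 0 && utils::tail(prev$outcome, 1) == "incorrect"
      }, logical(1))
      bad <- c(bad, chk(all(ok),
                        "correction trial without preceding incorrect trial"))
    }
  }
  bad
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s %s | %s | %s\n",
              x$task, x$schedule, x$meta$animal_id,
              format(x$session_date)))
  cat(sprintf("  %d trials (%d non-correction), %.1f min",
              nrow(x$trials), n_noncorrection(x), x$duration_min))
  if (!is.na(x$stim_dur_s)) cat(sprintf(", stimulus %.1f s", x$stim_dur_s))
  cat("\n")
  if (length(x$annotations)) {
    cat("  annotations:", paste(x$annotations, collapse = ", "), "\n")
  }
  invisible(x)
}
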
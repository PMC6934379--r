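# Synthetic cohort generator. Trial outcomes follow a simple generative
# model: a premature touch with probability p_premature; otherwise an
# omission with probability p_omission; otherwise a response that is correct
# with probability p_correct(d) = plogis(b0 + b1 * d) at stimulus duration d
# (accuracy rises with longer stimuli). Correct trials draw log-normal touch
# and reward-collection latencies and a Poisson perseveration count. In PD
# and PAL, an incorrect trial is followed by correction trials repeating
# until a simulated correct choice. Everything is reproducible from a seed.

#' Trial-level generative model parameters
#'
#' @param p_premature probability of a premature response per trial.
#' @param p_omission probability of an omission given no premature response.
#' @param acc_intercept,acc_slope logistic accuracy model
#'   `p_correct(d) = plogis(acc_intercept + acc_slope * d)` in the stimulus
#'   duration `d` (seconds); the slope must be non-negative (a longer
#'   stimulus never reduces accuracy).
#' @param lat_log_mean,lat_log_sd log-scale mean and SD of the correct-touch
#'   latency (seconds); the reward-collection latency uses the same SD
#'   around `lat_log_mean + log(1.25)`.
#' @param persev_rate Poisson mean of per-trial perseverative responses on
#'   correct trials.
#' @return object of class `trial_model_params`.
#' @export
trial_model_params <- function(p_premature = 0.06, p_omission = 0.12,
                               acc_intercept = 0.3, acc_slope = 1.4,
                               lat_log_mean = log(1.0), lat_log_sd = 0.45,
                               persev_rate = 0.5) {
  stopifnot(p_premature >= 0, p_premature <= 1,
            p_omission >= 0, p_omission <= 1,
            acc_slope >= 0, lat_log_sd > 0, persev_rate >= 0)
  structure(list(p_premature = p_premature, p_omission = p_omission,
                 acc_intercept = acc_intercept, acc_slope = acc_slope,
                 lat_log_mean = lat_log_mean, lat_log_sd = lat_log_sd,
                 persev_rate = persev_rate),
            class = "trial_model_params")
}

p_correct_at <- function(params, d) {
  stats::plogis(params$acc_intercept + params$acc_slope * d)
}

#' Performance presets for planted cluster structure
#'
#' Three parameter sets representing high, mid and low performers, used to
#' plant recoverable group structure in simulated cohorts: high performers
#' are accurate, rarely omit and respond fast; low performers are
#' inaccurate, omit often and respond slowly; mid performers sit between,
#' with elevated premature responding.
#'
#' @return named list of [trial_model_params()] (`high`, `mid`, `low`).
#' @export
performance_presets <- function() {
  list(
    high = trial_model_params(p_premature = 0.04, p_omission = 0.05,
                              acc_intercept = 1.2, acc_slope = 1.6,
                              lat_log_mean = log(0.8), lat_log_sd = 0.35,
                              persev_rate = 1.2),
    mid = trial_model_params(p_premature = 0.12, p_omission = 0.15,
                             acc_intercept = 0.2, acc_slope = 1.3,
                             lat_log_mean = log(1.3), lat_log_sd = 0.45,
                             persev_rate = 0.5),
    low = trial_model_params(p_premature = 0.08, p_omission = 0.30,
                             acc_intercept = -0.8, acc_slope = 1.0,
                             lat_log_mean = log(2.0), lat_log_sd = 0.55,
                             persev_rate = 0.2)
  )
}

# Cap on correction-trial chains so a pathological p_correct cannot produce
# unbounded sessions.
MAX_CORRECTION_CHAIN <- 25L

#' Simulate one session
#'
#' Generates a full [session_record()] under the trial model. Latencies are
#' rounded to 3 decimals (the serialised precision) so a simulated record
#' round-trips exactly through [write_session_xml()] /
#' [parse_session_xml()].
#'
#' @param params a [trial_model_params()].
#' @param task `"5-CSRTT"`, `"PD"` or `"PAL"`.
#' @param schedule schedule label (default `"probe"` for 5-CSRTT).
#' @param stim_dur_s stimulus duration in seconds (5-CSRTT; default 2 for
#'   training schedules, required for probes).
#' @param n_trials non-correction trials to simulate (default: task
#'   maximum).
#' @param meta a [subject_meta()].
#' @param session_date session date.
#' @param seed integer seed (RNG state is restored afterwards).
#' @param file_ref file reference stored in the record.
#' @param vigilance_decrement optional within-session fatigue: the logistic
#'   accuracy intercept drops by this amount per completed 10-trial block
#'   (default 0, i.e. no fatigue).
#' @return a [session_record()].
#' @export
simulate_session <- function(params = trial_model_params(),
                             task = "5-CSRTT", schedule = "probe",
                             stim_dur_s = if (task == "5-CSRTT") 1.0 else NA,
                             n_trials = task_max_trials(task),
                             meta = subject_meta("M0001"),
                             session_date = as.Date("2020-01-06"),
                             seed = 1, file_ref = NA_character_,
                             vigilance_decrement = 0) {
  d_eff <- if (is.na(stim_dur_s)) 2.0 else stim_dur_s
  n_win <- task_n_windows(task)

  rows <- with_seed(seed, {
    out <- list()
    idx <- 0L
    for (t in seq_len(n_trials)) {
      idx <- idx + 1L
      pc <- stats::plogis(params$acc_intercept + params$acc_slope * d_eff -
                            vigilance_decrement * ((t - 1) %/% 10))
      u <- stats::runif(1)
      if (u < params$p_premature) {
        out[[length(out) + 1]] <- list(
          index = idx, outcome = "premature", is_correction = FALSE,
          window = NA_integer_, stim_dur = NA_real_,
          touch_latency = NA_real_, reward_latency = NA_real_, persev = 0L)
        next
      }
      win <- sample.int(n_win, 1)
      if (stats::runif(1) < params$p_omission) {
        out[[length(out) + 1]] <- list(
          index = idx, outcome = "omission", is_correction = FALSE,
          window = win, stim_dur = d_eff,
          touch_latency = NA_real_, reward_latency = NA_real_, persev = 0L)
        next
      }
      correct <- stats::runif(1) < pc
      make_row <- function(i, outcome, correction) {
        if (outcome == "correct") {
          list(index = i, outcome = "correct", is_correction = correction,
               window = win, stim_dur = d_eff,
               touch_latency = round(exp(stats::rnorm(
                 1, params$lat_log_mean, params$lat_log_sd)), 3),
               reward_latency = round(exp(stats::rnorm(
                 1, params$lat_log_mean + log(1.25), params$lat_log_sd)), 3),
               persev = stats::rpois(1, params$persev_rate))
        } else {
          list(index = i, outcome = "incorrect", is_correction = correction,
               window = win, stim_dur = d_eff,
               touch_latency = NA_real_, reward_latency = NA_real_,
               persev = 0L)
        }
      }
      out[[length(out) + 1]] <- make_row(idx, if (correct) "correct" else
        "incorrect", FALSE)
      if (!correct && task %in% c("PD", "PAL")) {
        for (cc in seq_len(MAX_CORRECTION_CHAIN)) {
          idx <- idx + 1L
          corr_ok <- stats::runif(1) < pc
          out[[length(out) + 1]] <- make_row(
            idx, if (corr_ok) "correct" else "incorrect", TRUE)
          if (corr_ok) break
        }
      }
    }
    out
  })

  trials <- if (length(rows) == 0) empty_trials() else do.call(
    rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  trials$persev <- as.integer(trials$persev)
  # deterministic plausible duration: ~0.55 min per trial event
  duration <- round(min(60, 4 + 0.55 * nrow(trials)), 3)

  session_record(
    meta = meta, task = task, schedule = schedule,
    session_date = session_date, duration_min = duration,
    stim_dur_s = if (task == "5-CSRTT") stim_dur_s else NA_real_,
    trials = trials, file_ref = file_ref
  )
}

#' Cohort configuration
#'
#' Describes a simulated cohort: strains, genotypes, sexes, sites, testing
#' ages and the session plan. Defaults emulate the reference study design —
#' 2 genotypes x 2 sexes x 2 sites per strain, three testing intervals
#' (ages 4, 8 and 12 months), and for 5-CSRTT a probe plan of two sessions
#' at each of the four reduced stimulus durations with the duration order
#' counterbalanced across mice by seeded shuffle.
#'
#' @param task task simulated (default `"5-CSRTT"`).
#' @param strains strain names.
#' @param n_per_cell animals per (strain, genotype, sex, site).
#' @param sexes,sites,ages design levels (`ages` in months; each age is a
#'   separate testing interval / independent observation).
#' @param genotypes genotype levels.
#' @param baseline [trial_model_params()] of wildtype animals.
#' @param transgenic_delta named numeric vector added to the baseline
#'   parameters for transgenic animals (default: accuracy intercept lowered
#'   by 0.6 and omissions raised, a mild attention impairment).
#' @param presets optional named list of [trial_model_params()] (e.g.
#'   [performance_presets()]); when supplied, animals are assigned presets
#'   round-robin (recorded in the truth table) instead of the
#'   genotype-delta model.
#' @param n_sessions_per_duration probe sessions per stimulus duration
#'   (default 2); for PD/PAL, `n_sessions` daily sessions are generated.
#' @param n_sessions PD/PAL daily session count (defaults: PD 10 reversal
#'   sessions, PAL 45 acquisition sessions).
#' @param seed master seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(task = "5-CSRTT", strains = "3xTG-AD-line",
                          n_per_cell = 2,
                          sexes = c("female", "male"),
                          sites = c("site1", "site2"),
                          ages = c(4L, 8L, 12L),
                          genotypes = c("wildtype", "transgenic"),
                          baseline = trial_model_params(),
                          transgenic_delta = c(acc_intercept = -0.6,
                                               p_omission = 0.05),
                          presets = NULL,
                          n_sessions_per_duration = 2,
                          n_sessions = if (task == "PD") 10 else 45,
                          seed = 1) {
  stopifnot(task %in% TSCOG_TASKS, n_per_cell >= 1)
  structure(
    list(task = task, strains = strains, n_per_cell = n_per_cell,
         sexes = sexes, sites = sites, ages = as.integer(ages),
         genotypes = genotypes, baseline = baseline,
         transgenic_delta = transgenic_delta, presets = presets,
         n_sessions_per_duration = n_sessions_per_duration,
         n_sessions = n_sessions, seed = seed),
    class = "cohort_config"
  )
}

shift_params <- function(params, delta) {
  if (is.null(delta) || length(delta) == 0) return(params)
  for (nm in names(delta)) {
    params[[nm]] <- params[[nm]] + delta[[nm]]
  }
  params$p_premature <- min(max(params$p_premature, 0), 1)
  params$p_omission <- min(max(params$p_omission, 0), 1)
  params
}

#' Simulate a cohort of session files
#'
#' Emits the full session plan for every animal at every testing age and
#' returns the XML documents together with a ground-truth table recording
#' each observation's design cell, generative parameters and (when presets
#' are used) planted performance group. For 5-CSRTT the plan is the probe
#' design: `n_sessions_per_duration` sessions at each of 1.5, 1.0, 0.8 and
#' 0.6 s, duration order counterbalanced across mice by seeded shuffle. For
#' PD/PAL it is `n_sessions` consecutive daily sessions.
#'
#' @param config a [cohort_config()].
#' @return list with `files` (named character vector of XML texts), `truth`
#'   (one row per observation = animal x age) and `roster` (one
#'   [subject_meta()]-style row per animal).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  files <- character(); fnames <- character()
  truth <- list(); roster <- list()
  preset_names <- names(config$presets %||% list())
  subj_counter <- 0L

  for (strain in config$strains) for (gt in config$genotypes)
    for (sex in config$sexes) for (site in config$sites)
      for (i in seq_len(config$n_per_cell)) {
        subj_counter <- subj_counter + 1L
        animal_id <- sprintf("M%04d", subj_counter)
        if (length(preset_names)) {
          preset <- preset_names[(subj_counter - 1L) %% length(preset_names) + 1L]
          params <- config$presets[[preset]]
        } else {
          preset <- NA_character_
          params <- if (gt == "transgenic") {
            shift_params(config$baseline, config$transgenic_delta)
          } else config$baseline
        }
        roster[[length(roster) + 1]] <- data.frame(
          animal_id = animal_id, strain = strain, genotype = gt, sex = sex,
          site = site, stringsAsFactors = FALSE)

        for (age in config$ages) {
          meta <- subject_meta(animal_id, strain = strain, genotype = gt,
                               sex = sex, age_months = age, site = site)
          obs_seed <- child_seed(config$seed, subj_counter * 1000 + age)
          date0 <- as.Date("2020-01-06") + (age - min(config$ages)) * 30

          if (config$task == "5-CSRTT") {
            dur_order <- with_seed(obs_seed, sample(PROBE_DURATIONS))
            plan <- rep(dur_order, each = config$n_sessions_per_duration)
            scheds <- rep("probe", length(plan))
          } else {
            plan <- rep(NA_real_, config$n_sessions)
            scheds <- rep(if (config$task == "PD") "reversal" else "dPAL",
                          config$n_sessions)
          }
          for (s in seq_along(plan)) {
            fname <- sprintf("%s_age%02d_s%02d.xml", animal_id, age, s)
            rec <- simulate_session(
              params = params, task = config$task, schedule = scheds[s],
              stim_dur_s = plan[s],
              meta = meta, session_date = date0 + (s - 1),
              seed = child_seed(obs_seed, s), file_ref = fname)
            files <- c(files, write_session_xml(rec))
            fnames <- c(fnames, fname)
          }
          truth[[length(truth) + 1]] <- data.frame(
            observation_id = sprintf("%s_%s", animal_id, age_bin_of(age)),
            animal_id = animal_id, strain = strain, genotype = gt, sex = sex,
            site = site, age_months = age, age_bin = age_bin_of(age),
            preset = preset, p_premature = params$p_premature,
            p_omission = params$p_omission,
            acc_intercept = params$acc_intercept,
            acc_slope = params$acc_slope, stringsAsFactors = FALSE)
        }
      }

  names(files) <- fnames
  list(files = files, truth = do.call(rbind, truth),
       roster = do.call(rbind, roster))
}

#' Defect-injection specification
#'
#' Rates of the three emulated data defects: a duplicated same-day file
#' (the incomplete first attempt after a software failure and restart), a
#' wrong animal ID, and a truncated session (software failure early in the
#' session). At most one defect is applied per file so the injection truth
#' log maps one-to-one onto QC flags.
#'
#' @param rate_duplicate,rate_bad_id,rate_truncation probabilities in
#'   \[0, 1\] with sum at most 1.
#' @return object of class `defect_spec`.
#' @export
defect_spec <- function(rate_duplicate = 0.05, rate_bad_id = 0.05,
                        rate_truncation = 0.05) {
  rates <- c(rate_duplicate, rate_bad_id, rate_truncation)
  stopifnot(all(rates >= 0), all(rates <= 1), sum(rates) <= 1)
  structure(list(rate_duplicate = rate_duplicate, rate_bad_id = rate_bad_id,
                 rate_truncation = rate_truncation),
            class = "defect_spec")
}

#' Inject defects into a simulated batch
#'
#' Corrupts a batch of session XML files according to a [defect_spec()] and
#' returns the corrupted batch plus an exact truth log. A `duplicate` adds a
#' second same-day file for the same mouse with the trial list truncated to
#' under half its length; `bad_id` replaces the animal ID with an off-roster
#' token; `truncation` cuts the session below the incomplete-session
#' thresholds (under 10 trials and under 10 minutes).
#'
#' @param files named character vector of XML documents.
#' @param spec a [defect_spec()].
#' @param seed integer seed.
#' @return list with `files` (corrupted batch, duplicates appended) and
#'   `truth_log` (data frame `file_ref`, `defect`).
#' @export
inject_defects <- function(files, spec = defect_spec(), seed = 1) {
  n <- length(files)
  log <- list()
  out <- files
  with_seed(seed, {
    u <- stats::runif(n)
    for (i in seq_len(n)) {
      r1 <- spec$rate_duplicate
      r2 <- r1 + spec$rate_bad_id
      r3 <- r2 + spec$rate_truncation
      if (u[i] < r1) {
        rec <- parse_session_xml(files[[i]], file_ref = names(files)[i])
        keep <- floor(stats::runif(1, 0.1, 0.45) * nrow(rec$trials))
        rec$trials <- rec$trials[seq_len(keep), , drop = FALSE]
        rec$duration_min <- round(max(0.5, rec$duration_min *
                                        stats::runif(1, 0.1, 0.4)), 3)
        dup_name <- sub("\\.xml$", "_dup.xml", names(files)[i])
        rec$file_ref <- dup_name
        out[[dup_name]] <- write_session_xml(rec, validate = FALSE)
        log[[length(log) + 1]] <- data.frame(
          file_ref = dup_name, defect = "duplicate", stringsAsFactors = FALSE)
      } else if (u[i] < r2) {
        rec <- parse_session_xml(files[[i]], file_ref = names(files)[i])
        rec$meta$animal_id <- sprintf("X%04d", i)
        out[[i]] <- write_session_xml(rec, validate = FALSE)
        log[[length(log) + 1]] <- data.frame(
          file_ref = names(files)[i], defect = "bad_id",
          stringsAsFactors = FALSE)
      } else if (u[i] < r3) {
        rec <- parse_session_xml(files[[i]], file_ref = names(files)[i])
        keep <- sample(0:5, 1)
        rec$trials <- rec$trials[seq_len(keep), , drop = FALSE]
        rec$duration_min <- round(stats::runif(1, 2, 8), 3)
        out[[i]] <- write_session_xml(rec, validate = FALSE)
        log[[length(log) + 1]] <- data.frame(
          file_ref = names(files)[i], defect = "truncation",
          stringsAsFactors = FALSE)
      }
    }
  })
  truth_log <- if (length(log)) do.call(rbind, log) else
    data.frame(file_ref = character(), defect = character(),
               stringsAsFactors = FALSE)
  list(files = out, truth_log = truth_log)
}
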
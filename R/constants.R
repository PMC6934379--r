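# Vocabulary shared across the package: task names, schedules, enum levels
# and per-task structural limits.

TSCOG_TASKS <- c("5-CSRTT", "PD", "PAL")

TSCOG_SCHEDULES <- c(
  "habituation", "pretrain_I", "pretrain_II", "pretrain_III", "pretrain_IV",
  "train", "probe", "baseline", "reversal", "maintenance", "acquisition",
  "dPAL", "sPAL"
)

TSCOG_STRAINS <- c(
  "3xTG-AD-line", "5xFAD-line", "APP/PS1-line",
  "B6129SF2/J", "B6SJLF1/J", "C57BL6/J", "other"
)

TSCOG_OUTCOMES <- c("correct", "incorrect", "omission", "premature")
TSCOG_SEXES <- c("female", "male")
TSCOG_GENOTYPES <- c("wildtype", "transgenic")
TSCOG_HOUSING <- c("single", "group")
TSCOG_LIGHT_CYCLE <- c("standard", "reversed")
TSCOG_AGE_BINS <- c("3-6", "7-10", "11-13")

#' Probe stimulus durations (seconds) used in 5-CSRTT probe sessions
#' @keywords internal
PROBE_DURATIONS <- c(1.5, 1.0, 0.8, 0.6)

# Maximum number of non-correction trials per daily session.
task_max_trials <- function(task) {
  switch(task, "5-CSRTT" = 50L, "PD" = 30L, "PAL" = 36L,
         stop("unknown task: ", task))
}

# Number of response windows on the touchscreen mask.
task_n_windows <- function(task) {
  switch(task, "5-CSRTT" = 5L, "PD" = 2L, "PAL" = 3L,
         stop("unknown task: ", task))
}

#' Age bin containing an age in months
#'
#' Testing ages are grouped into the three longitudinal testing intervals
#' used throughout the package: 3-6, 7-10 and 11-13 months.
#'
#' @param age_months integer vector of ages in months.
#' @return character vector of bin labels (`NA` outside 3-13 months).
#' @export
#' @examples
#' age_bin_of(c(4, 8, 12))
age_bin_of <- function(age_months) {
  bins <- rep(NA_character_, length(age_months))
  bins[age_months >= 3 & age_months <= 6] <- "3-6"
  bins[age_months >= 7 & age_months <= 10] <- "7-10"
  bins[age_months >= 11 & age_months <= 13] <- "11-13"
  bins
}
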
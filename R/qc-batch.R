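# Batch QC pipeline: parse -> validate -> apply fixes -> resolve duplicates
# -> discard fatals, with IQR outlier thresholds computed over the clean set.

apply_fixes <- function(record, fixes) {
  if (is.null(fixes) || nrow(fixes) == 0) return(record)
  mine <- fixes[fixes$file_ref == record$file_ref, , drop = FALSE]
  if (nrow(mine) == 0) return(record)
  meta_fields <- c("animal_id", "strain", "genotype", "sex", "age_months",
                   "site", "housing", "light_cycle")
  for (i in seq_len(nrow(mine))) {
    field <- mine$field[i]
    value <- mine$value[i]
    if (field %in% meta_fields) {
      record$meta[[field]] <- if (field == "age_months") as.integer(value)
      else as.character(value)
      if (field == "age_months") {
        record$meta$age_bin <- age_bin_of(record$meta$age_months)
      }
    } else if (field == "task") {
      record$task <- value
    } else if (field == "schedule") {
      record$schedule <- value
    } else if (field == "date") {
      record$session_date <- as.Date(value)
    } else if (field == "duration_min") {
      record$duration_min <- as.numeric(value)
    } else {
      warnf("fix for unknown field '%s' ignored", field)
      next
    }
    field_key <- if (field %in% meta_fields) field else field
    record$annotations <- setdiff(record$annotations,
                                  paste0("missing:", field_key))
    attr(record, "fix_applied") <- TRUE
  }
  record
}

#' Run the automated QC pipeline over a batch of session files
#'
#' The pipeline mirrors the screening applied before any file enters a
#' behavioural database: each document is parsed leniently, validated against
#' the QC rule set, fixable flags with supplied corrections are repaired
#' (disposition `"fixed"`), same-day duplicates are resolved, and any record
#' retaining a fatal or unrepaired flag is discarded. Finally the one-sided
#' Q3 + k*IQR thresholds for the temporal features (correct-touch and
#' reward-collection latencies) are computed per task over the clean records
#' and attached to the report for use by [score_session()].
#'
#' @param files named character vector (or list) of XML documents or file
#'   paths; names are the file references (paths are used when unnamed).
#' @param roster data frame with unique `animal_id`s (or a character vector).
#' @param fixes optional data frame `(file_ref, field, value)` of manual
#'   corrections for fixable flags.
#' @param params an [iqr_filter_params()].
#' @param min_trials,min_duration_min incomplete-session thresholds, see
#'   [validate_session()].
#' @return `list(clean = <records>, report = <qc_report>)`. The report holds
#'   per-file dispositions, all flags, batch counts with percentages, and the
#'   per-task latency outlier thresholds.
#' @export
run_qc_batch <- function(files, roster, fixes = NULL,
                         params = iqr_filter_params(),
                         min_trials = 10, min_duration_min = 10) {
  files <- as.list(files)
  if (is.null(names(files)) || any(!nzchar(names(files)))) {
    names(files) <- vapply(seq_along(files), function(i) {
      f <- files[[i]]
      if (!grepl("<", f, fixed = TRUE)) f else sprintf("file%04d", i)
    }, character(1))
  }
  refs <- names(files)
  n_total <- length(files)

  records <- vector("list", n_total)
  flags_pre <- no_flags()   # flags before fixes (reporting)
  flags_post <- no_flags()  # flags remaining after fixes (disposition)
  fixed_refs <- character()

  for (i in seq_len(n_total)) {
    rec <- tryCatch(parse_session_xml(files[[i]], file_ref = refs[i]),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      f <- qc_flag("SCHEMA_MISSING", "fatal",
                   paste("unparseable:", conditionMessage(rec)), refs[i])
      flags_pre <- rbind(flags_pre, f)
      flags_post <- rbind(flags_post, f)
      next
    }
    pre <- validate_session(rec, roster, min_trials, min_duration_min)
    flags_pre <- rbind(flags_pre, pre)
    rec2 <- apply_fixes(rec, fixes)
    if (isTRUE(attr(rec2, "fix_applied"))) {
      post <- validate_session(rec2, roster, min_trials, min_duration_min)
      if (nrow(post) < nrow(pre)) fixed_refs <- c(fixed_refs, refs[i])
    } else {
      post <- pre
    }
    flags_post <- rbind(flags_post, post)
    records[[i]] <- rec2
  }

  parsed <- !vapply(records, is.null, logical(1))
  dup <- resolve_duplicates(records[parsed])
  flags_pre <- rbind(flags_pre, dup$flagged)
  flags_post <- rbind(flags_post, dup$flagged)

  disposition <- setNames(rep("pass", n_total), refs)
  has_post <- refs %in% flags_post$file_ref
  disposition[has_post] <- "discarded"
  disposition[refs %in% fixed_refs & !has_post] <- "fixed"

  clean <- records[parsed]
  clean_refs <- vapply(clean, function(r) r$file_ref, character(1))
  clean <- clean[disposition[clean_refs] != "discarded"]

  # Outlier thresholds on temporal features over the clean batch, per task.
  thresholds <- iqr_thresholds(clean, params)

  n_flagged_files <- length(unique(flags_pre$file_ref))
  tp <- qc_throughput(n_total, n_flagged_files)
  report <- structure(
    list(
      per_file = data.frame(
        file_ref = refs,
        n_flags = vapply(refs, function(r) sum(flags_pre$file_ref == r),
                         integer(1)),
        disposition = unname(disposition),
        stringsAsFactors = FALSE, row.names = NULL
      ),
      flags = flags_pre,
      n_total = n_total,
      n_pass = sum(disposition == "pass"),
      n_fixed = sum(disposition == "fixed"),
      n_discarded = sum(disposition == "discarded"),
      n_flagged_files = n_flagged_files,
      pct_flagged = tp$pct_flagged,
      pct_passed = tp$pct_passed,
      iqr_thresholds = thresholds,
      params = params
    ),
    class = "qc_report"
  )
  list(clean = clean, report = report)
}

# Per-task Q3 + k*IQR thresholds over pooled correct-trial latencies.
iqr_thresholds <- function(records, params = iqr_filter_params()) {
  out <- data.frame(task = character(), feature = character(),
                    q1 = double(), q3 = double(), threshold = double(),
                    n = integer(), n_outliers = integer(),
                    stringsAsFactors = FALSE)
  if (length(records) == 0) return(out)
  tasks <- unique(vapply(records, function(r) r$task, character(1)))
  for (task in tasks) {
    recs <- Filter(function(r) identical(r$task, task), records)
    for (feature in c("touch_latency", "reward_latency")) {
      vals <- unlist(lapply(recs, function(r) {
        tr <- r$trials
        tr[[feature]][tr$outcome == "correct" & !tr$is_correction]
      }))
      vals <- vals[!is.na(vals)]
      if (length(vals) < 4) next
      q1 <- compute_quartile(vals, 0.25)
      q3 <- compute_quartile(vals, 0.75)
      thr <- q3 + params$multiplier * (q3 - q1)
      out <- rbind(out, data.frame(
        task = task, feature = feature, q1 = q1, q3 = q3, threshold = thr,
        n = length(vals), n_outliers = sum(vals > thr),
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  files screened : %d\n", x$n_total))
  cat(sprintf("  pass / fixed / discarded : %d / %d / %d\n",
              x$n_pass, x$n_fixed, x$n_discarded))
  cat(sprintf("  flagged files  : %d (%.1f%%); passing %.1f%%\n",
              x$n_flagged_files, x$pct_flagged, x$pct_passed))
  if (nrow(x$iqr_thresholds)) {
    cat("  latency outlier thresholds (Q3 + k*IQR):\n")
    for (i in seq_len(nrow(x$iqr_thresholds))) {
      r <- x$iqr_thresholds[i, ]
      cat(sprintf("    %-8s %-15s %.3f s (%d/%d flagged)\n",
                  r$task, r$feature, r$threshold, r$n_outliers, r$n))
    }
  }
  invisible(x)
}

#' Write a QC report to disk
#'
#' Emits the flag table as CSV (`file_ref, rule_id, severity, disposition`)
#' and the batch counts as a JSON summary block.
#'
#' @param report a `qc_report` from [run_qc_batch()].
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the report.
#' @export
write_qc_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    fl <- report$flags
    fl$disposition <- report$per_file$disposition[
      match(fl$file_ref, report$per_file$file_ref)]
    utils::write.csv(fl[, c("file_ref", "rule_id", "severity", "disposition",
                            "message")],
                     csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_total = report$n_total, n_pass = report$n_pass,
           n_fixed = report$n_fixed, n_discarded = report$n_discarded,
           n_flagged_files = report$n_flagged_files,
           pct_flagged = report$pct_flagged, pct_passed = report$pct_passed),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
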
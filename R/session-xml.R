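# Canonical session XML dialect.
#
# One file = one session. Root <session schema_version="1"> with metadata
# children followed by <trials> holding one <trial/> per event. The reader is
# deliberately lenient: missing required fields become parse annotations
# ("missing:<field>") for the QC stage rather than errors; only malformed XML
# and wrong-kind values abort. The writer is strictly deterministic (fixed
# element order, seconds formatted with 3 decimals) so identical records
# serialise to identical bytes.

REQUIRED_FIELDS <- c(
  "animal_id", "strain", "genotype", "sex", "age_months", "site",
  "housing", "light_cycle", "task", "schedule", "date", "duration_min"
)

KNOWN_ELEMENTS <- c(REQUIRED_FIELDS, "stimulus_duration_s", "trials")

#' Parse a session XML document
#'
#' Reads one session event log in the canonical dialect into a
#' [session_record()]. Missing required fields are recorded as
#' `"missing:<field>"` annotations rather than raised, so that the QC stage
#' can flag (and possibly fix) them; unknown extra elements are preserved in
#' the record's `extra` slot. Element names of a foreign dialect can be
#' translated via `element_map`, a named character vector mapping canonical
#' names to the names used in the document.
#'
#' @param text XML document as a string, or a file path.
#' @param file_ref file reference recorded in the result (defaults to the
#'   path when `text` is a path).
#' @param element_map optional named character vector: canonical element name
#'   -> element name used by the foreign dialect.
#' @return a [session_record()].
#' @export
#' @examples
#' rec <- simulate_session(seed = 1)
#' txt <- write_session_xml(rec)
#' rec2 <- parse_session_xml(txt)
parse_session_xml <- function(text, file_ref = NA_character_,
                              element_map = NULL) {
  is_path <- length(text) == 1 && !grepl("<", text, fixed = TRUE) &&
    file.exists(text)
  if (is_path && is.na(file_ref)) file_ref <- text
  doc <- tryCatch(
    xml2::read_xml(if (is_path) text else paste(text, collapse = "\n")),
    error = function(e) {
      stopf("malformed XML%s: %s",
            if (!is.na(file_ref)) paste0(" in '", file_ref, "'") else "",
            conditionMessage(e))
    }
  )
  root <- doc

  name_of <- function(canonical) {
    if (!is.null(element_map) && canonical %in% names(element_map)) {
      element_map[[canonical]]
    } else canonical
  }

  annotations <- character()
  get_text <- function(field) {
    node <- xml2::xml_find_first(root, paste0("./", name_of(field)))
    if (inherits(node, "xml_missing")) {
      if (field %in% REQUIRED_FIELDS) {
        annotations <<- c(annotations, paste0("missing:", field))
      }
      return(NA_character_)
    }
    xml2::xml_text(node)
  }
  as_num <- function(x, path) {
    if (is.na(x)) return(NA_real_)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stopf("non-numeric value '%s' at %s", x, path)
    v
  }
  as_int <- function(x, path) {
    v <- as_num(x, path)
    if (is.na(v)) NA_integer_ else as.integer(v)
  }

  meta <- subject_meta(
    animal_id = get_text("animal_id") %||% NA_character_,
    strain = get_text("strain"),
    genotype = get_text("genotype"),
    sex = get_text("sex"),
    age_months = as_int(get_text("age_months"), "/session/age_months"),
    site = get_text("site"),
    housing = get_text("housing"),
    light_cycle = get_text("light_cycle")
  )
  if (is.na(meta$animal_id)) meta$animal_id <- NA_character_

  task <- get_text("task")
  schedule <- get_text("schedule")
  date_txt <- get_text("date")
  session_date <- if (is.na(date_txt)) as.Date(NA) else {
    d <- tryCatch(as.Date(date_txt), error = function(e) NA)
    if (is.na(d)) stopf("unparseable date '%s' at /session/date", date_txt)
    d
  }
  duration <- as_num(get_text("duration_min"), "/session/duration_min")
  stim_node <- xml2::xml_find_first(root, paste0("./", name_of("stimulus_duration_s")))
  stim_dur <- if (inherits(stim_node, "xml_missing")) NA_real_ else {
    as_num(xml2::xml_text(stim_node), "/session/stimulus_duration_s")
  }

  trial_nodes <- xml2::xml_find_all(
    root, paste0("./", name_of("trials"), "/trial"))
  n <- length(trial_nodes)
  attr_of <- function(nodes, a) xml2::xml_attr(nodes, a)
  num_attr <- function(a) {
    raw <- attr_of(trial_nodes, a)
    out <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(out))
    if (length(bad)) {
      stopf("non-numeric value '%s' at /session/trials/trial[%d]/@%s",
            raw[bad[1]], bad[1], a)
    }
    out
  }
  trials <- if (n == 0) empty_trials() else data.frame(
    index = as.integer(num_attr("index")),
    outcome = attr_of(trial_nodes, "outcome"),
    is_correction = tolower(attr_of(trial_nodes, "correction") %||%
                              rep("false", n)) %in% "true",
    window = as.integer(num_attr("window")),
    stim_dur = num_attr("stim_dur"),
    touch_latency = num_attr("touch_latency"),
    reward_latency = num_attr("reward_latency"),
    persev = as.integer(num_attr("persev")),
    stringsAsFactors = FALSE
  )
  if (n > 0) trials$persev[is.na(trials$persev)] <- 0L

  known <- vapply(KNOWN_ELEMENTS, name_of, character(1))
  kids <- xml2::xml_children(root)
  extra_idx <- which(!(xml2::xml_name(kids) %in% known))
  extra <- list()
  for (i in extra_idx) {
    extra[[xml2::xml_name(kids[[i]])]] <- xml2::xml_text(kids[[i]])
  }

  session_record(
    meta = meta, task = task, schedule = schedule,
    session_date = session_date, duration_min = duration,
    stim_dur_s = stim_dur, trials = trials,
    annotations = annotations, extra = extra, file_ref = file_ref
  )
}

#' Serialise a session record to canonical XML
#'
#' Deterministic serialisation: fixed element order, ISO-8601 dates,
#' seconds-valued numbers with exactly 3 decimals. Identical records produce
#' identical bytes, and `parse_session_xml(write_session_xml(r))` reproduces
#' `r`. Fields a lenient parse left missing are simply omitted, so a parsed
#' defective file round-trips too.
#'
#' @param record a [session_record()]; invariant violations abort unless the
#'   record carries parse annotations for exactly those fields.
#' @param validate check [validate_record()] invariants first (default TRUE).
#' @return a single string containing the XML document.
#' @export
write_session_xml <- function(record, validate = TRUE) {
  if (validate && length(record$annotations) == 0) {
    bad <- validate_record(record)
    if (length(bad)) {
      stopf("record violates invariants: %s", paste(bad, collapse = "; "))
    }
  }
  m <- record$meta
  line <- function(name, value, fmt = NULL) {
    if (is.null(value) || length(value) == 0 || is.na(value)) return(character())
    v <- if (is.null(fmt)) as.character(value) else sprintf(fmt, value)
    sprintf("  <%s>%s</%s>", name, xml_escape(v), name)
  }
  head_lines <- c(
    "<session schema_version=\"1\">",
    line("animal_id", m$animal_id),
    line("strain", m$strain),
    line("genotype", m$genotype),
    line("sex", m$sex),
    line("age_months", m$age_months, "%d"),
    line("site", m$site),
    line("housing", m$housing),
    line("light_cycle", m$light_cycle),
    line("task", record$task),
    line("schedule", record$schedule),
    line("date", if (is.na(record$session_date)) NA else
      format(record$session_date, "%Y-%m-%d")),
    line("duration_min", record$duration_min, "%.3f"),
    line("stimulus_duration_s",
         if (is.na(record$stim_dur_s)) NA else record$stim_dur_s, "%.3f")
  )

  tr <- record$trials
  trial_lines <- if (nrow(tr) == 0) "  <trials/>" else {
    rows <- vapply(seq_len(nrow(tr)), function(i) {
      at <- c(
        sprintf('index="%d"', tr$index[i]),
        sprintf('outcome="%s"', tr$outcome[i]),
        sprintf('correction="%s"', if (tr$is_correction[i]) "true" else "false"),
        if (!is.na(tr$window[i])) sprintf('window="%d"', tr$window[i]),
        if (!is.na(tr$stim_dur[i]))
          sprintf('stim_dur="%s"', fmt_secs(tr$stim_dur[i])),
        if (!is.na(tr$touch_latency[i]))
          sprintf('touch_latency="%s"', fmt_secs(tr$touch_latency[i])),
        if (!is.na(tr$reward_latency[i]))
          sprintf('reward_latency="%s"', fmt_secs(tr$reward_latency[i])),
        sprintf('persev="%d"', tr$persev[i] %||% 0L)
      )
      sprintf("    <trial %s/>", paste(at, collapse = " "))
    }, character(1))
    c("  <trials>", rows, "  </trials>")
  }

  extra_lines <- if (length(record$extra)) {
    mapply(function(nm, v) sprintf("  <%s>%s</%s>", nm, xml_escape(v), nm),
           names(record$extra), unlist(record$extra))
  } else character()

  paste(c(head_lines, trial_lines, extra_lines, "</session>", ""),
        collapse = "\n")
}

#' Export session metrics to CSV
#'
#' Writes one row per session: metadata columns first, then the behavioural
#' measures, RFC-4180-style quoting, full numeric precision. All sessions
#' must come from the same task.
#'
#' @param metrics data frame of per-session metrics (as returned by
#'   [score_session()] rows bound together, including a `task` column).
#' @param path output file path; omit to return the CSV text.
#' @return the path (invisibly), or the CSV text when `path` is missing.
#' @export
export_metrics_csv <- function(metrics, path = NULL) {
  if (nrow(metrics) > 0 && "task" %in% names(metrics)) {
    tasks <- unique(metrics$task)
    if (length(tasks) > 1) {
      stopf("mixed tasks in metrics export: %s", paste(tasks, collapse = ", "))
    }
  }
  meta_cols <- intersect(
    c("file_ref", "animal_id", "strain", "genotype", "sex", "age_months",
      "age_bin", "site", "task", "schedule", "session_date",
      "stimulus_duration_s"),
    names(metrics))
  metrics <- metrics[, c(meta_cols, setdiff(names(metrics), meta_cols)),
                     drop = FALSE]
  if (is.null(path)) {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(metrics, con, row.names = FALSE)
    close(con)
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
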
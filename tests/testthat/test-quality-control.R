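test_that("quartiles follow the (n-1)p linear-interpolation convention", {
  expect_equal(compute_quartile(c(1, 2, 3, 4), 0.75), 3.25)
  expect_equal(compute_quartile(c(5, 5, 5), 0.2), 5)
  expect_equal(compute_quartile(c(9, 1, 4), 0), 1)
  expect_equal(compute_quartile(c(9, 1, 4), 1), 9)
  expect_error(compute_quartile(numeric(), 0.5), "empty")
  set.seed(42)
  for (i in 1:100) {
    v <- rnorm(sample(4:30, 1))
    p <- runif(1)
    expect_equal(compute_quartile(v, p), oracle_quantile(v, p),
                 tolerance = 1e-12)
  }
})

test_that("outlier mask flags exactly the values above Q3 + k*IQR", {
  expect_equal(which(iqr_outlier_mask(c(1:8, 100))), 9)
  expect_equal(iqr_outlier_mask(rep(7, 10)), rep(FALSE, 10))
  expect_warning(m <- iqr_outlier_mask(c(1, 2, 3)), "fewer than 4")
  expect_equal(m, rep(FALSE, 3))
  expect_error(iqr_outlier_mask(c(1, NA, 3, 4)), "positions")
})

test_that("outlier mask agrees with brute force on random vectors", {
  set.seed(7)
  for (i in 1:500) {
    v <- rlnorm(sample(4:50, 1), sdlog = runif(1, 0.2, 1.5))
    expect_identical(iqr_outlier_mask(v), oracle_iqr_mask(v))
  }
})

test_that("an appended far-out value is always flagged itself", {
  # the fence is bounded above by 4*Q3 <= 4*max of the data (Q1 > 0 for
  # latency-like positive data), so a value beyond that is always caught
  set.seed(11)
  for (i in 1:50) {
    v <- rlnorm(20, sdlog = 1)
    v2 <- c(v, 4 * max(v) + 1)
    m2 <- iqr_outlier_mask(v2)
    expect_true(m2[length(v2)])
  }
})

test_that("validate_session implements the five QC rules", {
  roster <- data.frame(animal_id = c("M0001", "M0002"))
  rec <- make_tiny_record()
  rec$duration_min <- 30

  # clean session with enough trials
  full <- make_count_record()
  expect_equal(nrow(validate_session(full, roster)), 0)

  # off-roster animal is fixable
  bad_id <- full
  bad_id$meta$animal_id <- "M9999"
  fl <- validate_session(bad_id, roster)
  expect_equal(fl$rule_id, "BAD_ANIMAL_ID")
  expect_equal(fl$severity, "fixable")

  # few trials AND short duration: incomplete (fatal)
  inc <- make_tiny_record()
  inc$duration_min <- 4
  fl <- validate_session(inc, roster)
  expect_true("INCOMPLETE_SESSION" %in% fl$rule_id)
  expect_equal(fl$severity[fl$rule_id == "INCOMPLETE_SESSION"], "fatal")
  # few trials but a long session is not incomplete
  inc$duration_min <- 45
  expect_false("INCOMPLETE_SESSION" %in% validate_session(inc, roster)$rule_id)

  # missing-field annotations surface as SCHEMA_MISSING
  txt <- sub("  <sex>female</sex>\n", "", write_session_xml(full),
             fixed = TRUE)
  fl <- validate_session(parse_session_xml(txt), roster)
  expect_true(any(fl$rule_id == "SCHEMA_MISSING" & grepl("sex", fl$message)))

  # out-of-range values are fatal
  neg <- make_tiny_record()
  neg$trials$touch_latency[1] <- -0.5
  expect_true("VALUE_OUT_OF_RANGE" %in% validate_session(neg, roster)$rule_id)
  odd <- make_tiny_record()
  odd$stim_dur_s <- 0.7
  expect_true("VALUE_OUT_OF_RANGE" %in% validate_session(odd, roster)$rule_id)

  expect_error(validate_session(full, c("M0001", "M0001")), "unique")
})

test_that("duplicate resolution keeps the most complete same-day file", {
  mk <- function(n, dur, ref) {
    r <- make_count_record(n_correct = n, n_incorrect = 0, n_omission = 0,
                           n_premature = 0)
    r$duration_min <- dur
    r$file_ref <- ref
    r
  }
  res <- resolve_duplicates(list(mk(50, 31, "a.xml"), mk(7, 8, "b.xml")))
  expect_equal(vapply(res$kept, function(r) r$file_ref, ""), "a.xml")
  expect_equal(res$flagged$rule_id, "DUPLICATE_SESSION")
  expect_equal(res$flagged$file_ref, "b.xml")

  # no duplicates: everything kept
  two <- list(mk(50, 31, "a.xml"), mk(50, 31, "c.xml"))
  two[[2]]$session_date <- as.Date("2020-01-07")
  res <- resolve_duplicates(two)
  expect_length(res$kept, 2)
  expect_equal(nrow(res$flagged), 0)

  # three-way tie-break: trials first, then duration
  res <- resolve_duplicates(list(mk(50, 31, "x.xml"), mk(50, 20, "y.xml"),
                                 mk(20, 31, "z.xml")))
  expect_equal(vapply(res$kept, function(r) r$file_ref, ""), "x.xml")
  expect_setequal(res$flagged$file_ref, c("y.xml", "z.xml"))
})

test_that("batch QC partitions files and is idempotent on clean output", {
  cc <- cohort_config(sexes = "female", sites = "site1", ages = 4L,
                      n_per_cell = 3, seed = 5)
  sim <- simulate_cohort(cc)
  qc <- run_qc_batch(sim$files, roster = sim$roster)
  r <- qc$report
  expect_equal(r$n_total, length(sim$files))
  expect_equal(r$n_pass + r$n_fixed + r$n_discarded, r$n_total)
  expect_equal(r$n_pass, r$n_total)
  expect_equal(r$pct_flagged, 0)
  expect_equal(r$pct_passed, 100)

  # running QC again on its own clean output yields no new flags
  clean_files <- vapply(qc$clean, write_session_xml, character(1))
  names(clean_files) <- vapply(qc$clean, function(x) x$file_ref, "")
  qc2 <- run_qc_batch(clean_files, roster = sim$roster)
  expect_equal(qc2$report$n_flagged_files, 0)
  expect_equal(qc2$report$n_pass, r$n_pass)
})

test_that("injected defects are flagged, fixable IDs fixed, rest discarded", {
  cc <- cohort_config(sexes = "female", sites = "site1", ages = 4L,
                      n_per_cell = 3, seed = 6)
  sim <- simulate_cohort(cc)
  inj <- inject_defects(sim$files, defect_spec(0.08, 0.08, 0.08), seed = 9)
  tl <- inj$truth_log
  expect_gt(nrow(tl), 0)
  bad_ids <- tl$file_ref[tl$defect == "bad_id"]
  fixes <- data.frame(
    file_ref = bad_ids, field = "animal_id",
    value = sub("_age.*", "", bad_ids), stringsAsFactors = FALSE)
  qc <- run_qc_batch(inj$files, roster = sim$roster, fixes = fixes)
  r <- qc$report

  flagged <- unique(r$flags$file_ref)
  expect_setequal(flagged, tl$file_ref)
  fixed <- r$per_file$file_ref[r$per_file$disposition == "fixed"]
  expect_setequal(fixed, bad_ids)
  discarded <- r$per_file$file_ref[r$per_file$disposition == "discarded"]
  expect_setequal(discarded, setdiff(tl$file_ref, bad_ids))
  expect_equal(r$n_total, r$n_pass + r$n_fixed + r$n_discarded)
  expect_equal(r$pct_flagged,
               round(100 * length(flagged) / r$n_total, 1))
})

test_that("throughput percentages reproduce batch-count arithmetic", {
  tp <- qc_throughput(1000, 100)
  expect_equal(tp$pct_flagged, 10.0)
  expect_equal(tp$pct_passed, 90.0)
  expect_true(is.na(qc_throughput(0, 0)$pct_flagged))
})

test_that("IQR thresholds are computed per task over the clean batch", {
  cc <- cohort_config(sexes = "female", sites = "site1", ages = 4L,
                      n_per_cell = 2, seed = 8)
  sim <- simulate_cohort(cc)
  qc <- run_qc_batch(sim$files, roster = sim$roster)
  th <- qc$report$iqr_thresholds
  expect_setequal(th$feature, c("touch_latency", "reward_latency"))
  expect_true(all(th$task == "5-CSRTT"))
  # recompute one threshold by hand from the clean records
  vals <- unlist(lapply(qc$clean, function(r) {
    tr <- r$trials
    tr$touch_latency[tr$outcome == "correct" & !tr$is_correction]
  }))
  vals <- vals[!is.na(vals)]
  q1 <- oracle_quantile(vals, 0.25); q3 <- oracle_quantile(vals, 0.75)
  expect_equal(th$threshold[th$feature == "touch_latency"],
               q3 + 3 * (q3 - q1), tolerance = 1e-10)
})
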
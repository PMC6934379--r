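# Shared workflows for the planted-structure recovery and null-calibration
# checks.

# Simulate a 60-animal cohort with the three performance presets planted
# (20 animals each), run the pipeline through clustering, and return the
# adjusted Rand index between recovered labels and planted presets.
planted_recovery_ari <- function(seed) {
  out <- tempfile("recovery-")
  cfg <- list(
    simulate = list(task = "5-CSRTT", strains = "3xTG-AD-line",
                    n_per_cell = 30, sexes = "female", sites = "site1",
                    ages = 4L, presets = "performance"),
    cluster = list(restarts = 20),
    stages = c("simulate", "qc", "score", "cluster")
  )
  res <- suppressWarnings(run_pipeline(cfg, seed = seed, out_dir = out,
                                       log_level = "quiet"))
  truth <- utils::read.csv(file.path(out, "ground_truth.csv"),
                           stringsAsFactors = FALSE)
  assign <- utils::read.csv(file.path(out, "cluster_assignments.csv"),
                            stringsAsFactors = FALSE)
  unlink(out, recursive = TRUE)
  m <- merge(assign, truth[, c("observation_id", "preset")],
             by = "observation_id")
  stopifnot(nrow(m) == 60)
  mclust::adjustedRandIndex(m$label, m$preset)
}

# One genotype-balanced null simulation: random high/mid/low labels drawn
# independently of genotype in every stratum; returns the stratum-level
# adjusted p-values from the membership comparison.
null_membership_padj <- function(seed, n_per_stratum = 20) {
  sexes <- c("female", "male"); bins <- c("3-6", "7-10", "11-13")
  rows <- list(); labelled <- character(); ids <- character()
  set.seed(seed)
  counter <- 0
  for (sx in sexes) for (bn in bins) {
    for (i in seq_len(n_per_stratum)) {
      counter <- counter + 1
      id <- sprintf("o%04d", counter)
      ids <- c(ids, id)
      labelled <- c(labelled, sample(c("high", "mid", "low"), 1))
      rows[[length(rows) + 1]] <- data.frame(
        observation_id = id, strain = "3xTG-AD-line", sex = sx,
        age_bin = bn,
        genotype = if (i <= n_per_stratum / 2) "wildtype" else "transgenic",
        stringsAsFactors = FALSE)
    }
  }
  res <- structure(list(k = 3, labels = c("high", "mid", "low"),
                        assignments = setNames(
                          match(labelled, c("high", "mid", "low")), ids),
                        labelled = setNames(labelled, ids)),
                   class = "kml_result")
  compare_membership(res, do.call(rbind, rows))$p_adj
}
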
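# Independent oracles used to cross-check the package implementations.
# Each is written directly from the defining formula and shares no code
# with the implementation it checks.

# Quantile by explicit linear interpolation of order statistics.
oracle_quantile <- function(values, p) {
  x <- sort(values)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(x[n])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

# Brute-force one-sided extreme-outlier mask.
oracle_iqr_mask <- function(values, multiplier = 3) {
  q1 <- oracle_quantile(values, 0.25)
  q3 <- oracle_quantile(values, 0.75)
  values > q3 + multiplier * (q3 - q1)
}

# Two-sided Fisher p for a 2 x k table by full recursive enumeration of all
# tables with the observed margins under the multivariate hypergeometric
# null (point-probability method).
oracle_fisher <- function(tab) {
  c_sums <- colSums(tab)
  r1 <- sum(tab[1, ])
  N <- sum(tab)
  k <- length(c_sums)
  log_denom <- lchoose(N, r1)
  probs <- numeric(0)
  recurse <- function(j, rem, logp) {
    if (j > k) {
      if (rem == 0) probs[length(probs) + 1] <<- exp(logp - log_denom)
      return(invisible())
    }
    for (a in 0:min(c_sums[j], rem)) {
      recurse(j + 1, rem - a, logp + lchoose(c_sums[j], a))
    }
  }
  recurse(1, r1, 0)
  p_obs <- exp(sum(lchoose(c_sums, tab[1, ])) - log_denom)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Step-up FDR adjustment written directly from the formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, p[o] * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Minimum within-cluster SS over every partition of the rows of X into k
# non-empty parts (exhaustive; for tiny n only).
oracle_best_partition <- function(X, k) {
  n <- nrow(X)
  grids <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- list(wss = Inf, assign = NULL)
  n_parts <- 0L
  seen <- character(0)
  for (i in seq_len(nrow(grids))) {
    a <- as.integer(grids[i, ])
    if (length(unique(a)) != k) next
    # canonical form so each set partition is counted once
    canon <- paste(match(a, unique(a)), collapse = "")
    if (canon %in% seen) next
    seen <- c(seen, canon)
    n_parts <- n_parts + 1L
    wss <- 0
    for (j in seq_len(k)) {
      sub <- X[a == j, , drop = FALSE]
      ctr <- colMeans(sub)
      wss <- wss + sum(sweep(sub, 2, ctr)^2)
    }
    if (wss < best$wss) best <- list(wss = wss, assign = match(a, unique(a)))
  }
  best$n_partitions <- n_parts
  best
}

# Random balanced long-format split-plot dataset.
random_splitplot_data <- function(n_per_group = 3, a = 2, b = 3) {
  subj <- seq_len(n_per_group * a)
  grp <- rep(letters[seq_len(a)], each = n_per_group)
  d <- expand.grid(subject = subj, within = paste0("w", seq_len(b)),
                   stringsAsFactors = FALSE)
  d$between <- grp[d$subject]
  d$value <- rnorm(nrow(d))
  d
}

# A fully valid hand-built 2-trial 5-CSRTT record.
make_tiny_record <- function(file_ref = "tiny.xml") {
  trials <- data.frame(
    index = 1:2,
    outcome = c("correct", "incorrect"),
    is_correction = c(FALSE, FALSE),
    window = c(3L, 1L),
    stim_dur = c(1.0, 1.0),
    touch_latency = c(1.234, NA),
    reward_latency = c(2.0, NA),
    persev = c(1L, 0L),
    stringsAsFactors = FALSE
  )
  session_record(
    meta = subject_meta("M0001", strain = "3xTG-AD-line",
                        genotype = "transgenic", sex = "female",
                        age_months = 4L, site = "site1"),
    task = "5-CSRTT", schedule = "probe",
    session_date = "2020-01-06", duration_min = 30,
    stim_dur_s = 1.0, trials = trials, file_ref = file_ref
  )
}

# Record with given outcome counts (appended correction trials optional).
make_count_record <- function(n_correct = 30, n_incorrect = 10,
                              n_omission = 5, n_premature = 5,
                              n_correction = 0, task = "5-CSRTT",
                              schedule = "probe", persev = 0L) {
  outs <- c(rep("correct", n_correct), rep("incorrect", n_incorrect),
            rep("omission", n_omission), rep("premature", n_premature))
  n <- length(outs)
  trials <- data.frame(
    index = seq_len(n),
    outcome = outs,
    is_correction = FALSE,
    window = ifelse(outs == "premature", NA_integer_, 1L),
    stim_dur = ifelse(outs == "premature", NA_real_, 1.0),
    touch_latency = ifelse(outs == "correct", 1.0, NA_real_),
    reward_latency = ifelse(outs == "correct", 2.0, NA_real_),
    persev = ifelse(outs == "correct", as.integer(persev), 0L),
    stringsAsFactors = FALSE
  )
  if (n_correction > 0) {
    # open a correction run after a final incorrect trial
    opener <- data.frame(
      index = n + 1L, outcome = "incorrect", is_correction = FALSE,
      window = 1L, stim_dur = 1.0, touch_latency = NA_real_,
      reward_latency = NA_real_, persev = 0L, stringsAsFactors = FALSE)
    corr <- data.frame(
      index = n + 1L + seq_len(n_correction), outcome = "incorrect",
      is_correction = TRUE, window = 1L, stim_dur = 1.0,
      touch_latency = NA_real_, reward_latency = NA_real_, persev = 0L,
      stringsAsFactors = FALSE)
    trials <- rbind(trials, opener, corr)
  }
  session_record(
    meta = subject_meta("M0001"), task = task, schedule = schedule,
    session_date = "2020-01-06", duration_min = 30,
    stim_dur_s = if (task == "5-CSRTT") 1.0 else NA_real_,
    trials = trials, file_ref = "counts.xml"
  )
}

# Synthetic trajectory set straight from a matrix of flattened observations
# (already on a common scale; standardisation bypassed deliberately).
make_trajectory_set <- function(X, Tn = 2, V = ncol(X) / 2,
                                ids = sprintf("o%02d", seq_len(nrow(X)))) {
  A <- array(X, c(nrow(X), Tn, V),
             dimnames = list(ids, paste0("t", seq_len(Tn)),
                             paste0("v", seq_len(V))))
  structure(
    list(array = A, ids = ids,
         variables = paste0("v", seq_len(V)),
         timepoints = paste0("t", seq_len(Tn)),
         scaling = data.frame(variable = paste0("v", seq_len(V)),
                              mean = 0, sd = 1),
         excluded = character()),
    class = "trajectory_set")
}
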
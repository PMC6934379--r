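make_long <- function(values, ids, timepoints = c("1.5", "1.0"),
                      variables = c("accuracy_pct", "omission_pct")) {
  g <- expand.grid(timepoint = timepoints, variable = variables,
                   observation_id = ids, stringsAsFactors = FALSE)
  g$value <- values
  g
}

test_that("trajectory assembly standardises each variable globally", {
  set.seed(13)
  ids <- sprintf("o%d", 1:8)
  long <- make_long(rnorm(32, mean = 50, sd = 20), ids)
  ts <- build_trajectories(long, variables = c("accuracy_pct", "omission_pct"),
                           timepoints = c("1.5", "1.0"))
  expect_equal(dim(ts$array), c(8, 2, 2))
  for (v in 1:2) {
    cells <- as.vector(ts$array[, , v])
    expect_equal(mean(cells), 0, tolerance = 1e-10)
    expect_equal(sd(cells), 1, tolerance = 1e-10)
  }
  # de-standardising recovers the original values
  raw <- ts$array[, , 1] * ts$scaling$sd[1] + ts$scaling$mean[1]
  orig <- long$value[long$variable == "accuracy_pct" &
                       long$observation_id == ids[3]]
  expect_equal(as.numeric(raw[3, ]), orig, tolerance = 1e-10)
})

test_that("incomplete observations are excluded and listed", {
  ids <- sprintf("o%d", 1:5)
  long <- make_long(rnorm(20), ids)
  long <- long[!(long$observation_id == "o4" & long$variable == "omission_pct" &
                   long$timepoint == "1.0"), ]
  ts <- build_trajectories(long, c("accuracy_pct", "omission_pct"),
                           c("1.5", "1.0"))
  expect_equal(ts$excluded, "o4")
  expect_setequal(ts$ids, setdiff(ids, "o4"))
})

test_that("a zero-variance variable is rejected by name", {
  long <- make_long(rnorm(32), sprintf("o%d", 1:8),
                    variables = c("flat", "ok"))
  long$value[long$variable == "flat"] <- 1
  expect_error(build_trajectories(long, c("flat", "ok"), c("1.5", "1.0")),
               "flat")
})

test_that("k-means recovers planted clusters and matches the exhaustive oracle", {
  set.seed(23)
  centers <- rbind(c(0, 0, 0, 0), c(10, 10, 10, 10), c(-10, 10, -10, 10))
  X <- centers[rep(1:3, each = 2), ] + matrix(rnorm(24, sd = 0.5), 6, 4)
  ts <- make_trajectory_set(X)
  res <- kmeans_longitudinal(ts, k = 3, restarts = 10, seed = 5)

  oracle <- oracle_best_partition(X, 3)
  expect_equal(oracle$n_partitions, 90) # Stirling S(6,3)
  expect_equal(res$within_ss, oracle$wss, tolerance = 1e-8)
  # identical partitions up to label permutation
  planted <- rep(1:3, each = 2)
  expect_equal(mclust::adjustedRandIndex(res$assignments, planted), 1)
  expect_equal(mclust::adjustedRandIndex(res$assignments, oracle$assign), 1)
})

test_that("k = n gives singleton clusters with zero within-SS", {
  set.seed(29)
  X <- matrix(rnorm(12), 4, 3) * 5
  ts <- make_trajectory_set(X, Tn = 3, V = 1)
  res <- kmeans_longitudinal(ts, k = 4, restarts = 5, seed = 2)
  expect_equal(res$within_ss, 0, tolerance = 1e-12)
  expect_equal(sort(unname(res$assignments)), 1:4)
})

test_that("clustering is deterministic in the seed and stable across seeds on separated data", {
  set.seed(33)
  X <- rbind(matrix(rnorm(20, 0, 0.3), 10, 2),
             matrix(rnorm(20, 8, 0.3), 10, 2),
             matrix(rnorm(20, -8, 0.3), 10, 2))
  ts <- make_trajectory_set(X, Tn = 1, V = 2)
  a <- kmeans_longitudinal(ts, seed = 4)
  b <- kmeans_longitudinal(ts, seed = 4)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$within_ss, b$within_ss)
  for (s in c(11, 12, 13)) {
    r <- kmeans_longitudinal(ts, seed = s)
    expect_equal(mclust::adjustedRandIndex(r$assignments, a$assignments), 1)
  }
  # input-order invariance of the partition
  perm <- sample(nrow(X))
  ts2 <- make_trajectory_set(X[perm, ], Tn = 1, V = 2)
  r2 <- kmeans_longitudinal(ts2, seed = 4)
  expect_equal(mclust::adjustedRandIndex(r2$assignments,
                                         a$assignments[perm]), 1)
})

test_that("within-SS equals the best single restart and matches stats::kmeans", {
  set.seed(37)
  X <- rbind(matrix(rnorm(21, 0, 1), 7, 3),
             matrix(rnorm(21, 5, 1), 7, 3),
             matrix(rnorm(18, -5, 1), 6, 3))
  ts <- make_trajectory_set(X, Tn = 3, V = 1)
  multi <- kmeans_longitudinal(ts, k = 3, restarts = 25, seed = 6)
  # the first restart of the same seeded sequence cannot beat best-of-25
  single <- kmeans_longitudinal(ts, k = 3, restarts = 1, seed = 6)
  expect_lte(multi$within_ss, single$within_ss + 1e-9)
  # independent implementation finds the same optimum on separated data
  km <- stats::kmeans(X, centers = 3, nstart = 50,
                      algorithm = "Lloyd", iter.max = 100)
  expect_equal(multi$within_ss, km$tot.withinss, tolerance = 1e-6)
})

test_that("cluster labelling orders centroids on the primary variable", {
  # three obvious accuracy levels; omission constant-ish
  X <- rbind(matrix(c(1.2, 1.2), 2, 2, byrow = TRUE),
             matrix(c(0.1, 0.1), 2, 2, byrow = TRUE),
             matrix(c(-1.3, -1.3), 2, 2, byrow = TRUE)) +
    matrix(rnorm(12, sd = 0.01), 6, 2)
  ts <- make_trajectory_set(X, Tn = 2, V = 1)
  ts$variables <- "accuracy_pct"
  dimnames(ts$array)[[3]] <- "accuracy_pct"
  res <- kmeans_longitudinal(ts, seed = 3)
  lab <- label_clusters(res, ts, primary = "accuracy_pct")
  expect_setequal(lab$labels, c("high", "mid", "low"))
  expect_equal(unname(lab$labelled[c("o01", "o03", "o05")]),
               c("high", "mid", "low"))

  # lower-is-better reverses the ordering
  lab2 <- label_clusters(res, ts, primary = "accuracy_pct",
                         polarity = "lower-is-better")
  expect_equal(unname(lab2$labelled[c("o01", "o05")]), c("low", "high"))

  # labelling is invariant to cluster index permutation
  res_perm <- res
  perm <- c(2L, 3L, 1L)
  res_perm$assignments <- setNames(perm[res$assignments],
                                   names(res$assignments))
  res_perm$centroids <- res$centroids[order(perm), , , drop = FALSE]
  lab3 <- label_clusters(res_perm, ts, primary = "accuracy_pct")
  expect_equal(lab3$labelled, lab$labelled)

  expect_error(label_clusters(kmeans_longitudinal(ts, k = 2, seed = 1), ts),
               "k = 3")
})

test_that("membership comparison builds per-stratum tables with BH across strata", {
  set.seed(43)
  n <- 60
  ids <- sprintf("m%02d", 1:n)
  res <- structure(list(
    k = 3, labels = c("high", "mid", "low"),
    assignments = setNames(rep(1:3, each = 20), ids),
    labelled = setNames(rep(c("high", "mid", "low"), each = 20), ids)),
    class = "kml_result")
  groups <- data.frame(
    observation_id = ids,
    strain = "3xTG-AD-line",
    sex = rep(c("female", "male"), 30),
    age_bin = "3-6",
    genotype = rep(c("wildtype", "transgenic"), each = 30),
    stringsAsFactors = FALSE)
  out <- compare_membership(res, groups)
  expect_equal(nrow(out), 2) # one per sex
  expect_true(all(out$p_adj >= out$p))
  tabs <- attr(out, "tables")
  expect_equal(dim(tabs[[1]]), c(2, 3))
  expect_equal(sum(tabs[[1]]) + sum(tabs[[2]]), n)

  # perfectly separated table is significant before and after BH
  res2 <- res
  res2$labelled <- setNames(
    ifelse(groups$genotype == "wildtype", "high", "low"), ids)
  out2 <- compare_membership(res2, groups)
  expect_true(all(out2$p < 0.001))
  expect_true(all(out2$p_adj < 0.001))

  # identical genotype rows give p = 1
  res3 <- res
  res3$labelled <- setNames(rep(c("high", "mid", "low"), 20), ids)
  g3 <- groups
  g3$genotype <- rep(c("wildtype", "transgenic"), 30)
  # make label independent of genotype exactly: 10 of each label per genotype
  out3 <- compare_membership(res3, g3)
  expect_true(all(out3$p > 0.99))

  # p-values invariant to label column order is inherent to fisher_exact;
  # here check invariance to observation order
  sh <- sample(n)
  res4 <- res
  res4$assignments <- res$assignments[sh]
  res4$labelled <- res$labelled[sh]
  out4 <- compare_membership(res4, groups)
  expect_equal(out4$p, out$p, tolerance = 1e-12)

  expect_error(compare_membership(res, groups[-1, ]), "unmapped")
})

test_that("membership percentages sum to 100 within each cell", {
  ids <- sprintf("m%02d", 1:30)
  res <- structure(list(
    k = 3, labels = c("high", "mid", "low"),
    assignments = setNames(rep(1:3, 10), ids),
    labelled = setNames(rep(c("high", "mid", "low"), 10), ids)),
    class = "kml_result")
  groups <- data.frame(
    observation_id = ids, strain = "5xFAD-line",
    sex = rep(c("female", "male"), 15), age_bin = "7-10",
    genotype = rep(c("wildtype", "transgenic"), each = 15),
    stringsAsFactors = FALSE)
  pct <- membership_percent(res, groups)
  expect_true(all(abs(pct$pct_high + pct$pct_mid + pct$pct_low - 100) < 1e-9))
})
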
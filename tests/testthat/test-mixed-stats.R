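splitplot_toy <- function() {
  d <- expand.grid(subject = 1:4, within = c("w1", "w2"),
                   stringsAsFactors = FALSE)
  d$between <- ifelse(d$subject <= 2, "A", "B")
  d$value <- c(2, 4, 6, 8, 4, 4, 8, 8)
  d
}

test_that("split-plot ANOVA reproduces the hand-computed decomposition", {
  fit <- splitplot_anova(splitplot_toy())
  tb <- fit$table
  expect_equal(tb$SS, c(32, 2, 2, 0, 2))
  expect_equal(tb$df, c(1, 2, 1, 1, 2))
  expect_equal(tb$F[c(1, 3, 4)], c(32, 2, 0))
  expect_equal(tb$p[1], pf(32, 1, 2, lower.tail = FALSE))
})

test_that("SS components always sum to the total sum of squares", {
  set.seed(21)
  for (i in 1:500) {
    d <- random_splitplot_data(n_per_group = sample(2:5, 1),
                               a = sample(2:3, 1), b = sample(2:4, 1))
    fit <- splitplot_anova(d)
    expect_equal(sum(fit$table$SS), sum((d$value - mean(d$value))^2),
                 tolerance = 1e-8)
    expect_equal(sum(fit$table$df), nrow(d) - 1)
    expect_true(all(fit$table$SS > -1e-10))
  }
})

test_that("split-plot F ratios agree with aov's Error-stratum fit", {
  set.seed(31)
  for (i in 1:20) {
    d <- random_splitplot_data(n_per_group = 4, a = 2, b = 3)
    fit <- splitplot_anova(d)
    d$subject <- factor(d$subject); d$between <- factor(d$between)
    d$within <- factor(d$within)
    av <- summary(stats::aov(value ~ between * within + Error(subject),
                             data = d))
    s1 <- av[["Error: subject"]][[1]]
    s2 <- av[["Error: Within"]][[1]]
    expect_equal(fit$table$F[1], s1["between", "F value"], tolerance = 1e-8)
    expect_equal(fit$table$F[3], s2["within", "F value"], tolerance = 1e-8)
    expect_equal(fit$table$F[4], s2["between:within", "F value"],
                 tolerance = 1e-8)
    expect_equal(fit$table$p[1], s1["between", "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("design validation rejects incomplete or degenerate input", {
  d <- splitplot_toy()
  expect_error(splitplot_anova(d[-1, ]), "incomplete")
  d2 <- d
  d2$between[d2$subject == 1] <- c("A", "B")
  expect_error(splitplot_anova(d2), "more than one")
  # zero error MS -> infinite F with warning
  d3 <- d
  d3$value <- rep(c(1, 2, 3, 4), 2) + rep(c(0, 1), each = 4)
  fit <- suppressWarnings(splitplot_anova(d3))
  expect_warning(splitplot_anova(d3), "infinite")
  expect_equal(fit$table$F[3], Inf)
  expect_equal(fit$table$p[3], 0)
})

test_that("Bonferroni pairwise comparisons use the pooled error term", {
  set.seed(41)
  d <- random_splitplot_data(n_per_group = 5, a = 2, b = 4)
  fit <- splitplot_anova(d)
  cmp <- bonferroni_pairwise(fit)
  expect_equal(nrow(cmp), 4) # one pair at each of 4 within levels
  expect_equal(cmp$p_adj, pmin(1, cmp$p * 4))

  # independent recomputation at one level
  lvl <- cmp$within[1]
  g1 <- d$value[d$within == lvl & d$between == "a"]
  g2 <- d$value[d$within == lvl & d$between == "b"]
  tb <- fit$table
  ms_pool <- (tb$SS[2] + tb$SS[5]) / (tb$df[2] + tb$df[5])
  t_hand <- (mean(g1) - mean(g2)) / sqrt(ms_pool * (2 / 5))
  expect_equal(cmp$t[1], t_hand, tolerance = 1e-10)
  expect_equal(cmp$p[1], 2 * pt(-abs(t_hand), tb$df[2] + tb$df[5]),
               tolerance = 1e-10)

  # identical group means give p_adj = 1
  d0 <- d
  d0$value <- ave(d0$value, d0$within)
  f0 <- suppressWarnings(splitplot_anova(d0))
  c0 <- bonferroni_pairwise(f0)
  expect_true(all(c0$p_adj == 1))
})

test_that("Fisher p-values match hand enumeration on the worked tables", {
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2))$p, 34 / 70,
               tolerance = 1e-10)
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2))$p, 1 / 3,
               tolerance = 1e-10)
  deg <- fisher_exact(matrix(c(0, 3, 0, 2), 2, byrow = TRUE))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("Fisher matches the full-enumeration oracle on random 2x3 tables", {
  set.seed(51)
  for (i in 1:200) {
    repeat {
      tab <- matrix(rpois(6, sample(1:5, 1)), 2, 3)
      if (sum(tab) > 0 && sum(tab) <= 40 &&
          all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    expect_equal(fisher_exact(tab)$p, oracle_fisher(tab), tolerance = 1e-7,
                 label = paste("table", paste(tab, collapse = ",")))
  }
})

test_that("Fisher is invariant to row swap and column permutation", {
  set.seed(61)
  for (i in 1:25) {
    tab <- matrix(rpois(6, 4) + 1, 2, 3)
    p <- fisher_exact(tab)$p
    expect_equal(fisher_exact(tab[2:1, ])$p, p, tolerance = 1e-9)
    expect_equal(fisher_exact(tab[, sample(3)])$p, p, tolerance = 1e-9)
  }
})

test_that("Benjamini-Hochberg follows the step-up formula", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(c(0.005, 0.05, 0.5)),
               c(0.015, 0.075, 0.5))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(numeric()), numeric())
  set.seed(71)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    # adjusted values are monotone non-decreasing in rank
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("effect calls encode direction of significant genotype effects", {
  mk_fit <- function(delta, noise_sd = 0.5, seed = 1) {
    set.seed(seed)
    d <- expand.grid(subject = 1:12, within = c("w1", "w2"),
                     stringsAsFactors = FALSE)
    d$between <- ifelse(d$subject <= 6, "wildtype", "transgenic")
    d$value <- rnorm(nrow(d), sd = noise_sd) +
      ifelse(d$between == "transgenic", delta, 0)
    splitplot_anova(d)
  }
  low <- summarize_effect(mk_fit(-3), measure = "accuracy_pct",
                          polarity = "higher-is-better")
  expect_equal(low$symbol, "down")
  expect_equal(low$basis, "main effect")

  high <- summarize_effect(mk_fit(3), measure = "premature_count",
                           polarity = "lower-is-better")
  expect_equal(high$symbol, "up")

  none <- summarize_effect(mk_fit(0, noise_sd = 5), measure = "x",
                           polarity = "higher-is-better")
  expect_equal(none$symbol, "none")
  expect_equal(none$basis, "none")

  # interaction-only effect is called on the interaction basis
  set.seed(9)
  d <- expand.grid(subject = 1:12, within = c("w1", "w2"),
                   stringsAsFactors = FALSE)
  d$between <- ifelse(d$subject <= 6, "wildtype", "transgenic")
  d$value <- rnorm(nrow(d), sd = 0.3) +
    ifelse(d$between == "transgenic" & d$within == "w2", 3, 0) -
    ifelse(d$between == "transgenic" & d$within == "w1", 2.6, 0)
  fit <- splitplot_anova(d)
  call <- summarize_effect(fit, measure = "premature_count",
                           polarity = "lower-is-better")
  expect_lt(call$p_interaction, 0.05)
  expect_true(call$basis %in% c("main effect", "interaction"))
  expect_equal(call$symbol, "up")
})
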
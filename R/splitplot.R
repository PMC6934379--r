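# Split-plot (mixed-design) ANOVA: one between-subjects factor (e.g.
# genotype) crossed with one within-subjects factor (e.g. stimulus duration,
# session bin). Sums of squares follow the classical cell/level-mean
# decomposition; the between factor is tested against subjects-within-groups
# and the within factor and interaction against the within-subjects error.

#' Split-plot ANOVA (one between x one within factor)
#'
#' Fits the mixed design used to call genotype effects on repeated
#' behavioural measures: each subject belongs to exactly one between-group
#' level and is measured once at every within level. With `a` between
#' levels (group sizes `n_j`), `b` within levels and `N` subjects:
#' \deqn{SS_{between.subj} = b \sum_s (\bar y_s - \bar y)^2,\quad
#'       SS_A = b \sum_j n_j (\bar y_j - \bar y)^2,\quad
#'       SS_{subj(A)} = SS_{between.subj} - SS_A}
#' \deqn{SS_B = \sum_l N (\bar y_l - \bar y)^2,\quad
#'       SS_{AB} = SS_{cells} - SS_A - SS_B,\quad
#'       SS_{err} = SS_{tot} - SS_{between.subj} - SS_B - SS_{AB}}
#' F ratios: `F_A = MS_A / MS_subj(A)` on `(a-1, N-a)` df;
#' `F_B = MS_B / MS_err` on `(b-1, (N-a)(b-1))` df;
#' `F_AB = MS_AB / MS_err` on `((a-1)(b-1), (N-a)(b-1))` df.
#' Unequal group sizes are allowed; incomplete within-subject data is an
#' error (subjects with missing cells must be dropped beforehand — no
#' imputation). A zero error mean square yields an infinite F with p = 0 and
#' a degeneracy warning.
#'
#' @param data data frame in long format.
#' @param value,between,within,subject column names (defaults `"value"`,
#'   `"between"`, `"within"`, `"subject"`).
#' @return an object of class `splitplot_anova` with a `table` component
#'   (effect, SS, df, MS, F, p), the grand/group/level/cell means, and the
#'   design sizes.
#' @export
#' @examples
#' d <- expand.grid(subject = 1:4, within = c("w1", "w2"))
#' d$between <- ifelse(d$subject <= 2, "A", "B")
#' d$value <- c(2, 4, 6, 8, 4, 4, 8, 8)
#' splitplot_anova(d)
splitplot_anova <- function(data, value = "value", between = "between",
                            within = "within", subject = "subject") {
  y <- data[[value]]
  A <- as.character(data[[between]])
  B <- as.character(data[[within]])
  S <- as.character(data[[subject]])
  if (any(is.na(y))) stopf("missing values in '%s'", value)

  # each subject at exactly one between level
  lv <- tapply(A, S, function(x) length(unique(x)))
  if (any(lv != 1)) {
    stopf("subject(s) %s appear at more than one '%s' level",
          paste(names(lv)[lv != 1], collapse = ", "), between)
  }
  subjects <- unique(S)
  b_levels <- unique(B)
  a_levels <- unique(A)
  a <- length(a_levels); b <- length(b_levels); N <- length(subjects)
  tab <- table(S, B)
  if (any(tab != 1)) {
    stopf("incomplete within-subject data: every subject needs exactly one value per '%s' level",
          within)
  }
  n_j <- table(tapply(A, S, `[`, 1))[a_levels]
  if (a < 2 || any(n_j < 2)) {
    stopf("need at least 2 between levels with >= 2 subjects each")
  }

  grand <- mean(y)
  subj_mean <- tapply(y, S, mean)
  grp_of_subj <- tapply(A, S, `[`, 1)
  grp_mean <- tapply(y, A, mean)[a_levels]
  lvl_mean <- tapply(y, B, mean)[b_levels]
  cell_mean <- tapply(y, list(A, B), mean)

  ss_total <- sum((y - grand)^2)
  ss_between_subj <- b * sum((subj_mean - grand)^2)
  ss_A <- b * sum(as.numeric(n_j) * (grp_mean - grand)^2)
  ss_subj <- ss_between_subj - ss_A
  ss_B <- sum(N * (lvl_mean - grand)^2)
  # cell SS weighted by group size (each cell holds n_j subjects once)
  ss_cells <- sum(outer(as.numeric(n_j), rep(1, b)) *
                    (cell_mean[a_levels, b_levels, drop = FALSE] - grand)^2)
  ss_AB <- ss_cells - ss_A - ss_B
  ss_err <- ss_total - ss_between_subj - ss_B - ss_AB

  df_A <- a - 1
  df_subj <- N - a
  df_B <- b - 1
  df_AB <- (a - 1) * (b - 1)
  df_err <- (N - a) * (b - 1)

  ms <- function(ss, df) if (df > 0) ss / df else NA_real_
  ms_A <- ms(ss_A, df_A); ms_subj <- ms(ss_subj, df_subj)
  ms_B <- ms(ss_B, df_B); ms_AB <- ms(ss_AB, df_AB)
  ms_err <- ms(ss_err, df_err)

  warned <- FALSE
  fstat <- function(msn, msd, df1, df2) {
    if (is.na(msn) || is.na(msd)) return(list(F = NA_real_, p = NA_real_))
    if (msd <= 0) {
      if (!warned) warnf("zero error mean square; F reported as infinite")
      warned <<- TRUE
      return(list(F = Inf, p = 0))
    }
    f <- msn / msd
    list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
  }
  FA <- fstat(ms_A, ms_subj, df_A, df_subj)
  FB <- fstat(ms_B, ms_err, df_B, df_err)
  FAB <- fstat(ms_AB, ms_err, df_AB, df_err)

  table <- data.frame(
    effect = c(between, paste0("subject(", between, ")"), within,
               paste0(between, ":", within), "within-error"),
    SS = c(ss_A, ss_subj, ss_B, ss_AB, ss_err),
    df = c(df_A, df_subj, df_B, df_AB, df_err),
    MS = c(ms_A, ms_subj, ms_B, ms_AB, ms_err),
    F = c(FA$F, NA, FB$F, FAB$F, NA),
    p = c(FA$p, NA, FB$p, FAB$p, NA),
    stringsAsFactors = FALSE
  )
  structure(
    list(table = table, ss_total = ss_total, grand_mean = grand,
         group_means = grp_mean, level_means = lvl_mean,
         cell_means = cell_mean, group_sizes = n_j,
         a = a, b = b, N = N,
         factors = c(between = between, within = within),
         data = data.frame(subject = S, between = A, within = B, value = y,
                           stringsAsFactors = FALSE)),
    class = "splitplot_anova"
  )
}

#' @export
print.splitplot_anova <- function(x, ...) {
  cat(sprintf("Split-plot ANOVA: %s (between, %d levels) x %s (within, %d levels), N = %d subjects\n\n",
              x$factors["between"], x$a, x$factors["within"], x$b, x$N))
  tb <- x$table
  tb$SS <- signif(tb$SS, 6); tb$MS <- signif(tb$MS, 6)
  tb$F <- signif(tb$F, 5)
  tb$p <- format.pval(tb$p, digits = 4)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' @export
summary.splitplot_anova <- function(object, ...) object$table

#' Bonferroni-corrected between-group comparisons per within level
#'
#' Post-hoc follow-up of a split-plot ANOVA: at each within-factor level,
#' every pair of between-group means is compared with
#' `t = (m1 - m2) / sqrt(MS_pooled * (1/n1 + 1/n2))`, where `MS_pooled`
#' pools the subjects-within-groups and within-error terms
#' (`(SS_subj + SS_err) / (df_subj + df_err)`), the classical error term for
#' between comparisons at a fixed within level. Raw p-values are multiplied
#' by the number of comparisons and capped at 1.
#'
#' @param fit a [splitplot_anova()] object.
#' @return data frame: within level, group pair, mean difference, t, df,
#'   raw and Bonferroni-adjusted p. Empty when only one between group exists.
#' @export
bonferroni_pairwise <- function(fit) {
  d <- fit$data
  a_levels <- names(fit$group_means)
  b_levels <- names(fit$level_means)
  if (length(a_levels) < 2) {
    return(data.frame(within = character(), group1 = character(),
                      group2 = character(), diff = double(), t = double(),
                      df = double(), p = double(), p_adj = double()))
  }
  tb <- fit$table
  ss_subj <- tb$SS[2]; df_subj <- tb$df[2]
  ss_err <- tb$SS[5]; df_err <- tb$df[5]
  ms_pooled <- (ss_subj + ss_err) / (df_subj + df_err)
  df_pooled <- df_subj + df_err

  pairs <- utils::combn(a_levels, 2, simplify = FALSE)
  rows <- list()
  for (bl in b_levels) {
    for (pr in pairs) {
      g1 <- d$value[d$within == bl & d$between == pr[1]]
      g2 <- d$value[d$within == bl & d$between == pr[2]]
      delta <- mean(g1) - mean(g2)
      se <- sqrt(ms_pooled * (1 / length(g1) + 1 / length(g2)))
      tt <- if (se > 0) delta / se else ifelse(delta == 0, 0, Inf * sign(delta))
      p <- 2 * stats::pt(-abs(tt), df_pooled)
      rows[[length(rows) + 1]] <- data.frame(
        within = bl, group1 = pr[1], group2 = pr[2], diff = delta,
        t = tt, df = df_pooled, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_adj <- pmin(1, out$p * m)
  out
}

#' Impairment / facilitation call from a genotype ANOVA
#'
#' Summarises a genotype-by-condition split-plot ANOVA into the symbol used
#' in cross-strain summary tables: `"none"` when neither the genotype main
#' effect nor the interaction reaches `alpha`; otherwise the direction of the
#' transgenic-minus-wildtype marginal mean difference (`"up"` = transgenic
#' higher, `"down"` = transgenic lower). The symbol encodes direction of
#' change only; whether a higher value is better or worse is carried in the
#' `polarity` field and left to interpretation (a higher premature count and
#' a higher accuracy are both `"up"`).
#'
#' @param fit a [splitplot_anova()] whose between factor is genotype with
#'   levels `"wildtype"` and `"transgenic"`.
#' @param measure measure name carried into the call.
#' @param polarity `"higher-is-better"` or `"lower-is-better"`.
#' @param alpha significance threshold (default 0.05).
#' @return one-row data frame of class `effect_call`: measure, symbol
#'   (up/down/none), basis (main effect / interaction / none), p-values,
#'   means and polarity.
#' @export
summarize_effect <- function(fit, measure = "measure",
                             polarity = c("higher-is-better",
                                          "lower-is-better"),
                             alpha = 0.05) {
  polarity <- match.arg(polarity)
  gm <- fit$group_means
  if (!all(c("wildtype", "transgenic") %in% names(gm))) {
    stopf("between-factor levels must be 'wildtype' and 'transgenic'")
  }
  p_main <- fit$table$p[1]
  p_int <- fit$table$p[4]
  sig_main <- !is.na(p_main) && p_main < alpha
  sig_int <- !is.na(p_int) && p_int < alpha
  delta <- unname(gm["transgenic"] - gm["wildtype"])
  symbol <- if (!sig_main && !sig_int) "none" else if (delta > 0) "up" else
    if (delta < 0) "down" else "none"
  basis <- if (sig_main) "main effect" else if (sig_int) "interaction" else
    "none"
  out <- data.frame(
    measure = measure, symbol = symbol, basis = basis,
    p_genotype = p_main, p_interaction = p_int,
    mean_wildtype = unname(gm["wildtype"]),
    mean_transgenic = unname(gm["transgenic"]),
    delta = delta, polarity = polarity, alpha = alpha,
    stringsAsFactors = FALSE
  )
  class(out) <- c("effect_call", "data.frame")
  out
}

#' @export
print.effect_call <- function(x, ...) {
  arrow <- c(up = "↑", down = "↓", none = "-")[x$symbol]
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%s: %s (%s; p_genotype = %.4g, p_interaction = %.4g)\n",
                x$measure[i], arrow[i], x$basis[i], x$p_genotype[i],
                x$p_interaction[i]))
  }
  invisible(x)
}
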
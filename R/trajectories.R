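# Longitudinal multivariate k-means: subjects' behavioural measures over an
# ordered set of timepoints (probe stimulus durations, session bins, reversal
# sessions) form T x V matrices; observations are grouped by seeded Lloyd
# iterations on the Euclidean distance over all matrix cells and the three
# clusters are labelled high/mid/low post hoc.

#' Assemble standardised trajectory matrices
#'
#' Builds one T(imepoints) x V(ariables) matrix per observation (an animal
#' at one testing interval — intervals are treated as independent
#' observations) from long-format measures, then z-standardises each
#' variable by its overall mean and SD across all cells so that no measure
#' dominates the distance. Observations with any missing cell are excluded
#' and listed (complete-case policy; no imputation).
#'
#' @param data long data frame with columns `observation_id`, `timepoint`,
#'   `variable`, `value` (column names configurable).
#' @param variables variables to include, in column order.
#' @param timepoints timepoint labels, in row order.
#' @param id,timepoint,variable,value column names in `data`.
#' @return object of class `trajectory_set`: 3-d array `n x T x V`
#'   (standardised), ids, labels, the per-variable scaling used, and the
#'   excluded observation ids.
#' @export
build_trajectories <- function(data, variables, timepoints,
                               id = "observation_id", timepoint = "timepoint",
                               variable = "variable", value = "value") {
  d <- data.frame(id = as.character(data[[id]]),
                  tp = as.character(data[[timepoint]]),
                  var = as.character(data[[variable]]),
                  val = as.numeric(data[[value]]),
                  stringsAsFactors = FALSE)
  timepoints <- as.character(timepoints)
  d <- d[d$var %in% variables & d$tp %in% timepoints, , drop = FALSE]
  ids <- unique(d$id)
  Tn <- length(timepoints); V <- length(variables)

  complete <- character(); excluded <- character()
  arr_list <- list()
  for (oid in ids) {
    sub <- d[d$id == oid, , drop = FALSE]
    m <- matrix(NA_real_, Tn, V, dimnames = list(timepoints, variables))
    m[cbind(match(sub$tp, timepoints), match(sub$var, variables))] <- sub$val
    if (any(is.na(m))) {
      excluded <- c(excluded, oid)
    } else {
      complete <- c(complete, oid)
      arr_list[[oid]] <- m
    }
  }
  if (length(complete) == 0) stopf("no complete observations")
  A <- array(NA_real_, c(length(complete), Tn, V),
             dimnames = list(complete, timepoints, variables))
  for (i in seq_along(complete)) A[i, , ] <- arr_list[[complete[i]]]

  scaling <- data.frame(variable = variables, mean = NA_real_, sd = NA_real_,
                        stringsAsFactors = FALSE)
  for (v in seq_len(V)) {
    cells <- as.vector(A[, , v])
    mu <- mean(cells); sdv <- stats::sd(cells)
    if (!is.finite(sdv) || sdv == 0) {
      stopf("variable '%s' has zero variance; cannot standardise",
            variables[v])
    }
    A[, , v] <- (A[, , v] - mu) / sdv
    scaling$mean[v] <- mu; scaling$sd[v] <- sdv
  }
  structure(
    list(array = A, ids = complete, variables = variables,
         timepoints = timepoints, scaling = scaling, excluded = excluded),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d observations, %d timepoints x %d variables\n",
              length(x$ids), length(x$timepoints), length(x$variables)))
  cat("  variables:", paste(x$variables, collapse = ", "), "\n")
  if (length(x$excluded)) {
    cat(sprintf("  excluded (incomplete): %d\n", length(x$excluded)))
  }
  invisible(x)
}

# Flatten n x T x V to n x (T*V) for distance computations.
flatten_trajectories <- function(ts) {
  A <- ts$array
  n <- dim(A)[1]
  matrix(A, nrow = n)
}

lloyd_once <- function(X, centers, max_iter) {
  n <- nrow(X); k <- nrow(centers)
  assign_prev <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    cl <- max.col(-d2, ties.method = "first")
    empty <- setdiff(seq_len(k), unique(cl))
    if (length(empty)) {
      # re-seed each empty cluster with the observation currently farthest
      # from its own centroid (without re-using the same observation twice)
      own <- d2[cbind(seq_len(n), cl)]
      for (j in empty) {
        far <- which.max(own)
        cl[far] <- j
        own[far] <- -Inf
      }
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(X[cl == j, , drop = FALSE])
    }
    if (identical(cl, assign_prev)) break
    assign_prev <- cl
  }
  d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
    outer(rep(1, n), rowSums(centers^2))
  wss <- sum(pmax(d2[cbind(seq_len(n), cl)], 0))
  list(assign = cl, centers = centers, wss = wss, iter = it)
}

#' Longitudinal k-means clustering
#'
#' Lloyd's algorithm on whole trajectories: the distance between two
#' observations is the Euclidean distance over all T x V standardised cells.
#' Each restart initialises the centroids from `k` distinct observations
#' drawn under the seeded generator; an emptied cluster is re-seeded with
#' the observation farthest from its centroid; iteration stops when
#' assignments stabilise or at `max_iter`. The best of `restarts` runs by
#' total within-cluster sum of squares is returned. Fully reproducible
#' given `seed`; the caller's RNG state is untouched.
#'
#' @param ts a [build_trajectories()] result.
#' @param k number of clusters (default 3: high/mid/low performers).
#' @param restarts random restarts (default 20).
#' @param seed integer seed.
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @return object of class `kml_result`: assignments (named by observation),
#'   centroid array `k x T x V`, `within_ss`, restart bookkeeping and (after
#'   [label_clusters()]) the high/mid/low labels.
#' @export
kmeans_longitudinal <- function(ts, k = 3, restarts = 20, seed = 1,
                                max_iter = 100) {
  X <- flatten_trajectories(ts)
  n <- nrow(X)
  if (k < 2) stopf("k must be at least 2")
  if (k > n) stopf("k = %d exceeds the %d observations", k, n)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- sample.int(n, k)
      res <- lloyd_once(X, X[init, , drop = FALSE], max_iter)
      if (is.null(best) || res$wss < best$wss) best <- res
    }
  })
  Tn <- length(ts$timepoints); V <- length(ts$variables)
  centroids <- array(best$centers, c(k, Tn, V),
                     dimnames = list(NULL, ts$timepoints, ts$variables))
  structure(
    list(k = k, assignments = setNames(best$assign, ts$ids),
         centroids = centroids, within_ss = best$wss,
         n_restarts = restarts, seed = seed, labels = NULL),
    class = "kml_result"
  )
}

#' @export
print.kml_result <- function(x, ...) {
  cat(sprintf("<kml_result> k = %d, %d observations, within-SS = %.4f (%d restarts, seed %d)\n",
              x$k, length(x$assignments), x$within_ss, x$n_restarts, x$seed))
  sizes <- table(x$assignments)
  if (!is.null(x$labels)) names(sizes) <- x$labels[as.integer(names(sizes))]
  cat("  cluster sizes:",
      paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Label the three clusters high / mid / low
#'
#' Clusters are renamed post hoc by overall performance: centroids are
#' ordered on the mean (over timepoints) of a primary variable — by default
#' accuracy, where higher is better — and assigned the labels high, mid and
#' low. Ties on the primary variable are broken by the `secondary` variable
#' list (same polarity convention applied to each).
#'
#' @param result a `kml_result` with `k = 3`.
#' @param ts the [build_trajectories()] set clustered.
#' @param primary primary variable name (default `"accuracy_pct"`).
#' @param polarity `"higher-is-better"` (default) or `"lower-is-better"`.
#' @param secondary optional character vector of tie-break variables.
#' @return the `kml_result` with `labels` (cluster index -> label) and
#'   `labelled` (observation -> label) filled in.
#' @export
label_clusters <- function(result, ts, primary = "accuracy_pct",
                           polarity = c("higher-is-better",
                                        "lower-is-better"),
                           secondary = NULL) {
  polarity <- match.arg(polarity)
  if (result$k != 3) stopf("high/mid/low labelling requires k = 3")
  if (!(primary %in% ts$variables)) {
    stopf("primary variable '%s' not in the trajectory set", primary)
  }
  score_of <- function(var) {
    v <- match(var, ts$variables)
    apply(result$centroids[, , v, drop = FALSE], 1, mean)
  }
  keys <- list(score_of(primary))
  for (s in secondary %||% character()) keys <- c(keys, list(score_of(s)))
  sgn <- if (polarity == "higher-is-better") -1 else 1
  ord <- do.call(order, lapply(keys, function(kk) sgn * kk))
  labels <- character(3)
  labels[ord] <- c("high", "mid", "low")
  result$labels <- labels
  result$labelled <- setNames(labels[result$assignments],
                              names(result$assignments))
  result
}

#' Compare high/mid/low membership between genotypes
#'
#' For each (strain, sex, age bin) stratum, builds the 2 x 3 genotype-by-
#' performance-group count table and tests it with [fisher_exact()]; the raw
#' p-values across all strata are then adjusted with
#' [benjamini_hochberg()]. Sexes and testing intervals are analysed as
#' separate strata so sex effects and age effects are not conflated with
#' genotype. Strata with no observations are omitted with a note.
#'
#' @param result a labelled `kml_result` (see [label_clusters()]).
#' @param groups data frame mapping `observation_id` to `strain`, `sex`,
#'   `age_bin`, `genotype`.
#' @return data frame (strain, sex, age_bin, n, p, p_adj) of class
#'   `membership_tests`; the per-stratum count tables ride in the
#'   `"tables"` attribute.
#' @export
compare_membership <- function(result, groups) {
  if (is.null(result$labelled)) stopf("label_clusters() must be run first")
  lab <- result$labelled
  miss <- setdiff(names(lab), as.character(groups$observation_id))
  if (length(miss)) {
    stopf("unmapped observation(s): %s", paste(miss, collapse = ", "))
  }
  g <- groups[match(names(lab), as.character(groups$observation_id)), ,
              drop = FALSE]
  strata <- unique(g[, c("strain", "sex", "age_bin")])
  rows <- list(); tables <- list(); notes <- character()
  for (i in seq_len(nrow(strata))) {
    sel <- g$strain == strata$strain[i] & g$sex == strata$sex[i] &
      g$age_bin == strata$age_bin[i]
    if (!any(sel)) {
      notes <- c(notes, sprintf("stratum %s/%s/%s empty", strata$strain[i],
                                strata$sex[i], strata$age_bin[i]))
      next
    }
    tab <- table(factor(g$genotype[sel], levels = TSCOG_GENOTYPES),
                 factor(lab[sel], levels = c("high", "mid", "low")))
    ft <- fisher_exact(tab)
    key <- paste(strata$strain[i], strata$sex[i], strata$age_bin[i], sep = "/")
    tables[[key]] <- tab
    rows[[length(rows) + 1]] <- data.frame(
      strain = strata$strain[i], sex = strata$sex[i],
      age_bin = strata$age_bin[i], n = sum(sel), p = ft$p,
      degenerate = ft$degenerate, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- benjamini_hochberg(out$p)
  attr(out, "tables") <- tables
  attr(out, "notes") <- notes
  class(out) <- c("membership_tests", "data.frame")
  out
}

#' Percent membership of each genotype per performance group
#'
#' The heat-map quantity: within each (strain, sex, age bin, genotype) cell,
#' the percentage of observations labelled high, mid and low.
#'
#' @inheritParams compare_membership
#' @return data frame with one row per (strain, sex, age_bin, genotype) and
#'   `pct_high`, `pct_mid`, `pct_low` columns.
#' @export
membership_percent <- function(result, groups) {
  if (is.null(result$labelled)) stopf("label_clusters() must be run first")
  lab <- result$labelled
  g <- groups[match(names(lab), as.character(groups$observation_id)), ,
              drop = FALSE]
  cells <- unique(g[, c("strain", "sex", "age_bin", "genotype")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- g$strain == cells$strain[i] & g$sex == cells$sex[i] &
      g$age_bin == cells$age_bin[i] & g$genotype == cells$genotype[i]
    tt <- table(factor(lab[sel], levels = c("high", "mid", "low")))
    pct <- 100 * as.numeric(tt) / sum(sel)
    data.frame(cells[i, , drop = FALSE], n = sum(sel),
               pct_high = pct[1], pct_mid = pct[2], pct_low = pct[3],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
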
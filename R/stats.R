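# Brunner-Munzel comparison and group summaries ------------------------------

#' Brunner-Munzel two-sample rank test
#'
#' Tests whether `P(X < Y) + 0.5 P(X = Y) = 0.5` without assuming equal
#' variances, via midranks over the pooled sample and a studentized statistic
#' referred to a t distribution with Satterthwaite-type degrees of freedom.
#'
#' The t approximation breaks down when both within-group rank variances are
#' zero — exactly what happens when the two samples are completely separated,
#' as the pyrenoid groups are. In that degenerate case the test switches to a
#' permutation reference for the statistic `|p_hat - 0.5|`: a closed-form
#' exact count when the samples are fully separated without cross-group ties
#' (the extreme statistic is attained by exactly the two one-sided
#' assignments, so p = 2/C(n_x+n_y, n_y)), full enumeration when the number
#' of group assignments is at most 2e6, and otherwise seeded Monte Carlo.
#' All-identical samples return p = 1.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param alternative only "two.sided" is implemented.
#' @param mc_reps Monte Carlo permutations when enumeration is infeasible.
#' @param seed seed for the Monte Carlo path (ignored otherwise).
#' @return An object of class `bm_result`: `p_hat`, `statistic`, `dof`,
#'   `p_value`, `method` ("t_approx", "permutation_exact" or
#'   "permutation_mc"), `n_x`, `n_y`, `seed`.
#' @export
brunner_munzel <- function(x, y, alternative = "two.sided",
                           mc_reps = 100000L, seed = NULL) {
  alternative <- match.arg(alternative, "two.sided")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) stop("each group needs at least 2 values")
  if (any(!is.finite(c(x, y)))) stop("non-finite values")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))              # pooled midranks
  r1 <- rank(x); r2 <- rank(y)    # within-group midranks
  m1 <- mean(r[seq_len(n1)]); m2 <- mean(r[n1 + seq_len(n2)])
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  v1 <- sum((r[seq_len(n1)] - r1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r[n1 + seq_len(n2)] - r2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)

  if (v1 == 0 && v2 == 0) {
    if (length(unique(c(x, y))) == 1L) {
      return(bm_result(p_hat = 0.5, statistic = 0, dof = NA_real_,
                       p_value = 1, method = "t_approx", n1, n2, seed))
    }
    return(bm_permutation(x, y, p_hat, mc_reps, seed))
  }
  statistic <- (m2 - m1) / sqrt(N * (v1 / n2 + v2 / n1)) * sqrt(n1 * n2 / N)
  dof <- (n1 * v1 + n2 * v2)^2 /
    ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(statistic), df = dof)
  bm_result(p_hat, statistic, dof, min(1, p), "t_approx", n1, n2, seed)
}

bm_result <- function(p_hat, statistic, dof, p_value, method, n_x, n_y, seed) {
  structure(list(p_hat = p_hat, statistic = statistic, dof = dof,
                 p_value = p_value, method = method,
                 n_x = n_x, n_y = n_y, seed = seed),
            class = "bm_result")
}

# estimator of P(X<Y) + 0.5 P(X=Y) from a pooled vector and a y-membership
# index, used as the permutation statistic
p_hat_of <- function(pooled, y_idx) {
  r <- rank(pooled)
  n2 <- length(y_idx); n1 <- length(pooled) - n2
  (mean(r[y_idx]) - (n2 + 1) / 2) / n1
}

bm_permutation <- function(x, y, p_hat_obs, mc_reps, seed) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  t_obs <- abs(p_hat_obs - 0.5)
  separated <- max(x) < min(y) || max(y) < min(x)
  n_assign <- choose(N, n2)
  if (separated) {
    # the extreme value |p_hat - 0.5| = 0.5 is attained only by the two
    # one-sided assignments, so the exact permutation p has a closed form
    p <- 2 / n_assign
    return(bm_result(p_hat_obs, NA_real_, NA_real_, p, "permutation_exact",
                     n1, n2, seed))
  }
  if (n_assign <= 2e6) {
    combos <- utils::combn(N, n2)
    stats_all <- apply(combos, 2, function(idx)
      abs(p_hat_of(pooled, idx) - 0.5))
    p <- mean(stats_all >= t_obs - 1e-12)
    return(bm_result(p_hat_obs, NA_real_, NA_real_, p, "permutation_exact",
                     n1, n2, seed))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  hits <- 0L
  for (b in seq_len(mc_reps)) {
    idx <- sample.int(N, n2)
    if (abs(p_hat_of(pooled, idx) - 0.5) >= t_obs - 1e-12) hits <- hits + 1L
  }
  p <- (hits + 1) / (mc_reps + 1)   # add-one Monte Carlo estimator
  bm_result(p_hat_obs, NA_real_, NA_real_, p, "permutation_mc", n1, n2, seed)
}

#' @export
print.bm_result <- function(x, ...) {
  cat(sprintf("Brunner-Munzel: p_hat = %.4f, statistic = %s, dof = %s, p = %.3g (%s; n = %d vs %d)\n",
              x$p_hat,
              if (is.na(x$statistic)) "NA" else sprintf("%.4f", x$statistic),
              if (is.na(x$dof)) "NA" else sprintf("%.2f", x$dof),
              x$p_value, x$method, x$n_x, x$n_y))
  invisible(x)
}

#' Five-number summary of a score sample
#'
#' Quartiles use the linear-interpolation convention (R quantile type 7);
#' min and max are exact.
#'
#' @param scores numeric, length >= 1.
#' @return List with `n`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
group_summary <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) == 0) stop("empty sample")
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(n = length(scores), min = min(scores), q1 = q[1], median = q[2],
       q3 = q[3], max = max(scores))
}

#' Compare pyrenoid-present vs pyrenoid-absent scores
#'
#' Splits a score table on the `pyrenoid` column, summarizes each group and
#' runs the Brunner-Munzel comparison with x = present, y = absent.
#' Unknown-status rows are dropped with a warning.
#'
#' @param table data.frame with columns `score` and `pyrenoid`
#'   (e.g. from [score_table()] or [reticulata_scores()]).
#' @param seed forwarded to [brunner_munzel()] for the Monte Carlo path.
#' @return List of class `group_comparison`: `present` and `absent`
#'   summaries, and `test` (a `bm_result`).
#' @export
compare_groups <- function(table, seed = NULL) {
  stopifnot(all(c("score", "pyrenoid") %in% names(table)))
  unknown <- table$pyrenoid == "unknown"
  if (any(unknown)) {
    warning("dropping ", sum(unknown), " row(s) with unknown pyrenoid status")
    table <- table[!unknown, , drop = FALSE]
  }
  x <- table$score[table$pyrenoid == "present"]
  y <- table$score[table$pyrenoid == "absent"]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 scores per group (present: ", length(x),
         ", absent: ", length(y), ")")
  }
  structure(list(present = group_summary(x), absent = group_summary(y),
                 test = brunner_munzel(x, y, seed = seed)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt <- function(g, lab) {
    cat(sprintf("  %s: n = %d, range [%.1f, %.1f], median %.1f\n",
                lab, g$n, g$min, g$max, g$median))
  }
  cat("Helix hydrophobicity by pyrenoid status\n")
  fmt(x$present, "present")
  fmt(x$absent, "absent ")
  print(x$test)
  invisible(x)
}
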
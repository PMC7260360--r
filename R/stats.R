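# Statistical procedures used by the suppression pipeline: 2x2 chi-square
# (with optional Yates correction), pooled-variance and paired t tests, a
# two-stage group-by-size test, permutation-based Pearson correlation p
# values, and Bonferroni adjustment.

test_result <- function(statistic, df, p, method) {
  structure(list(statistic = statistic, df = df, p = p, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic, dfs, x$p))
  invisible(x)
}

#' Chi-square test for a 2x2 contingency table
#'
#' Pearson chi-square test of independence on a 2x2 table of counts (rows =
#' group, columns = category), with the continuity (Yates) correction
#' applied when `yates = TRUE` -- used for tables with low expected counts,
#' such as handedness. Computation is delegated to [stats::chisq.test()].
#'
#' @param table 2x2 integer matrix of counts.
#' @param yates Apply Yates's continuity correction.
#' @return A `test_result` (statistic, df = 1, p).
#' @examples
#' # demographic sex table: 18M/10F vs 21M/14F
#' chi_square_2x2(matrix(c(18, 21, 10, 14), 2), yates = FALSE)
#' @export
chi_square_2x2 <- function(table, yates = FALSE) {
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  # low expected counts are expected here -- that is what the Yates
  # correction is for -- so the approximation warning is silenced
  ct <- suppressWarnings(stats::chisq.test(table, correct = yates))
  test_result(unname(ct$statistic), unname(ct$parameter), ct$p.value,
              if (yates) "chi-square (Yates)" else "chi-square")
}

#' Pooled-variance two-sample t test
#'
#' Classical two-sample t test with pooled variance,
#' df = n1 + n2 - 2, two-tailed. If both groups are constant and equal the
#' contract t = 0, p = 1 applies; constant groups with different means are
#' an error.
#'
#' @param x,y Numeric samples for the two groups.
#' @return A `test_result`.
#' @export
two_sample_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(test_result(0, length(x) + length(y) - 2, 1,
                         "two-sample t (pooled)"))
    stop("zero variance with unequal means: t statistic undefined")
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
              "two-sample t (pooled)")
}

#' Paired t test
#'
#' Two-tailed paired t test on within-subject differences.
#'
#' @param x,y Paired numeric samples, or `y = NULL` to treat `x` as the
#'   vector of differences.
#' @return A `test_result`.
#' @export
paired_t <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  stopifnot(length(d) >= 2)
  if (stats::var(d) == 0) {
    if (mean(d) == 0)
      return(test_result(0, length(d) - 1, 1, "paired t"))
    stop("zero variance with nonzero mean difference: t undefined")
  }
  tt <- stats::t.test(d)
  test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
              "paired t")
}

#' Two-stage group and group-by-size tests
#'
#' Mixed design with participants nested in groups and stimulus size as a
#' continuous within-subject variable, implemented as a two-stage
#' summary-statistic procedure: each participant's responses are reduced to
#' an OLS slope against size (the within-subject size effect) and a mean;
#' between-group pooled t tests on the slopes and the means give the
#' group x size interaction and the group main effect respectively,
#' reported as F = t^2 with (1, n1 + n2 - 2) df. Participants with fewer
#' than two size levels are dropped (with a message).
#'
#' @param data Long-format data frame: `participant`, `group` (two levels),
#'   `size`, `value`.
#' @return List of `test_result`s: `group` (main effect) and `interaction`
#'   (group x size), plus the per-participant `slopes` data frame.
#' @export
mixed_group_by_size_test <- function(data) {
  stopifnot(all(c("participant", "group", "size", "value") %in% names(data)))
  per <- split(data, data$participant)
  rows <- lapply(per, function(d) {
    if (length(unique(d$size)) < 2) return(NULL)
    fit <- stats::lm.fit(cbind(1, d$size), d$value)
    data.frame(participant = d$participant[1], group = d$group[1],
               slope = fit$coefficients[2], mean = mean(d$value))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    message(dropped, " participant(s) dropped (fewer than 2 size levels)")
  sm <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  gs <- unique(sm$group)
  stopifnot(length(gs) == 2)
  t_int <- two_sample_t(sm$slope[sm$group == gs[1]],
                        sm$slope[sm$group == gs[2]])
  t_grp <- two_sample_t(sm$mean[sm$group == gs[1]],
                        sm$mean[sm$group == gs[2]])
  list(group = test_result(t_grp$statistic^2, c(1, t_grp$df), t_grp$p,
                           "group main effect (F = t^2)"),
       interaction = test_result(t_int$statistic^2, c(1, t_int$df), t_int$p,
                                 "group x size interaction (F = t^2)"),
       slopes = sm)
}

#' Permutation test for a Pearson correlation
#'
#' Pearson's r with a two-tailed permutation p value: one of the variables
#' is shuffled across participants without replacement `n_perm` times
#' (default 10,000) and p is the proportion of permuted |r| values at least
#' as extreme as the observed |r|, computed as `(count + 1) / (n_perm + 1)`
#' so the estimate is never exactly zero. Reproducible under [set.seed()].
#'
#' @param x,y Numeric vectors (n >= 3, finite, non-constant).
#' @param n_perm Number of permutations.
#' @return List: `r`, `p`, `n`, `n_perm`.
#' @export
permutation_correlation <- function(x, y, n_perm = 10000) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant variable")
  r_obs <- stats::cor(x, y)
  # r under permutation depends on y only through sum(x_i * y_perm_i);
  # vectorize across permutations
  n <- length(x)
  xs <- (x - mean(x)) / stats::sd(x)
  ys <- (y - mean(y)) / stats::sd(y)
  perm <- replicate(n_perm, sum(xs * ys[sample.int(n)])) / (n - 1)
  p <- (sum(abs(perm) >= abs(r_obs)) + 1) / (n_perm + 1)
  list(r = r_obs, p = p, n = n, n_perm = n_perm)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` for a family of `m` comparisons, via
#' [stats::p.adjust()].
#'
#' @param p Unadjusted p values.
#' @param m Family size (defaults to `length(p)`; must be at least that).
#' @return Adjusted p values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  stopifnot(m >= length(p))
  stats::p.adjust(p, method = "bonferroni", n = m)
}
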
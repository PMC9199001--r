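#' Two-way ANOVA mean squares of a complete ratings table
#'
#' Decomposes a complete subjects x raters table (no replication) into
#' between-subject, between-rater, and residual mean squares — the building
#' blocks of both two-way random-effects ICC forms.
#'
#' @param table Numeric matrix or data frame, rows = subjects (n >= 2),
#'   columns = raters (r >= 2), no missing cells.
#' @return A list with `ms_subjects`, `ms_raters`, `ms_error`, plus the sums of
#'   squares (`ss_*`), `n` and `r`.
#' @export
anova_mean_squares <- function(table) {
  x <- as.matrix(table)
  if (!is.numeric(x)) stop("ratings table must be numeric", call. = FALSE)
  if (anyNA(x)) stop("ratings table has missing cells; no imputation is performed", call. = FALSE)
  n <- nrow(x)
  r <- ncol(x)
  if (n < 2 || r < 2) stop("need at least 2 subjects and 2 raters", call. = FALSE)
  g <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_s <- r * sum((row_m - g)^2)
  ss_r <- n * sum((col_m - g)^2)
  ss_t <- sum((x - g)^2)
  ss_e <- ss_t - ss_s - ss_r
  # tiny negatives from cancellation are numerical zero
  if (ss_e < 0 && abs(ss_e) < 1e-9 * max(ss_t, 1)) ss_e <- 0
  list(
    ms_subjects = ss_s / (n - 1),
    ms_raters = ss_r / (r - 1),
    ms_error = ss_e / ((n - 1) * (r - 1)),
    ss_subjects = ss_s, ss_raters = ss_r, ss_error = ss_e, ss_total = ss_t,
    n = n, r = r
  )
}

new_icc_result <- function(estimate, lower, upper, model, ms, alpha) {
  structure(
    list(estimate = estimate, ci_lower = lower, ci_upper = upper,
         model = model, alpha = alpha,
         ms_subjects = ms$ms_subjects, ms_raters = ms$ms_raters,
         ms_error = ms$ms_error, n_subjects = ms$n, n_raters = ms$r),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s): %.3f (%.0f%% CI: %.3f to %.3f), %d subjects x %d raters\n",
              x$model, x$estimate, 100 * (1 - x$alpha),
              x$ci_lower, x$ci_upper, x$n_subjects, x$n_raters))
  invisible(x)
}

#' Single-rating, absolute-agreement, two-way random-effects ICC
#'
#' ICC(A,1): the correlation between single ratings of the same subject by
#' different raters, counting systematic rater offsets as disagreement.
#' Estimate: `(MS_S - MS_E) / (MS_S + (r-1) MS_E + (r/n)(MS_R - MS_E))`.
#' The confidence interval uses the conventional F-based construction with
#' Satterthwaite-approximated denominator degrees of freedom.
#'
#' @param table Subjects x raters matrix (complete).
#' @param alpha Two-sided error rate for the CI (default 0.05).
#' @return An `icc_result` with estimate, CI, model tag and mean squares.
#'   Negative estimates are reported as computed, not truncated.
#' @export
icc_single_absolute <- function(table, alpha = 0.05) {
  ms <- anova_mean_squares(table)
  n <- ms$n
  r <- ms$r
  ms_s <- ms$ms_subjects; ms_r <- ms$ms_raters; ms_e <- ms$ms_error
  denom <- ms_s + (r - 1) * ms_e + (r / n) * (ms_r - ms_e)
  if (denom == 0) {
    stop("all cells equal: absolute-agreement ICC is undefined", call. = FALSE)
  }
  est <- (ms_s - ms_e) / denom
  if (ms_e == 0 && ms_r == 0) {
    # perfect absolute agreement: interval degenerates at 1
    return(new_icc_result(1, 1, 1, "absolute-agreement, single-rating, two-way random", ms, alpha))
  }
  # Satterthwaite df for the linear combination a*MS_R + b*MS_E
  a <- (r * est) / (n * (1 - est))
  b <- 1 + (r * est * (n - 1)) / (n * (1 - est))
  v_num <- (a * ms_r + b * ms_e)^2
  v_den <- (a * ms_r)^2 / (r - 1) + (b * ms_e)^2 / ((n - 1) * (r - 1))
  v <- if (v_den > 0) v_num / v_den else Inf
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (ms_s - f_l * ms_e) /
    (f_l * (r * ms_r + (r * n - r - n) * ms_e) + n * ms_s)
  upper <- n * (f_u * ms_s - ms_e) /
    (r * ms_r + (r * n - r - n) * ms_e + n * f_u * ms_s)
  new_icc_result(est, lower, upper, "absolute-agreement, single-rating, two-way random", ms, alpha)
}

#' Single-rating, consistency, two-way random-effects ICC
#'
#' ICC(C,1): agreement up to a constant per-rater offset. Estimate:
#' `(MS_S - MS_E) / (MS_S + (r-1) MS_E)`. The CI comes from
#' `F = MS_S / MS_E` with `(n-1)` and `(n-1)(r-1)` degrees of freedom:
#' `lower = (F/F_u - 1) / (F/F_u + r - 1)` with
#' `F_u = qf(1 - alpha/2, n-1, (n-1)(r-1))`, and the analogous upper bound
#' using the reciprocal quantile.
#'
#' @inheritParams icc_single_absolute
#' @return An `icc_result`.
#' @export
icc_single_consistency <- function(table, alpha = 0.05) {
  ms <- anova_mean_squares(table)
  n <- ms$n
  r <- ms$r
  ms_s <- ms$ms_subjects; ms_e <- ms$ms_error
  denom <- ms_s + (r - 1) * ms_e
  if (denom == 0) {
    stop("no variance in the ratings: consistency ICC is undefined", call. = FALSE)
  }
  if (ms_e == 0) {
    # perfect consistency: F is infinite and the interval degenerates at 1
    return(new_icc_result(1, 1, 1, "consistency, single-rating, two-way random", ms, alpha))
  }
  est <- (ms_s - ms_e) / denom
  f_obs <- ms_s / ms_e
  df1 <- n - 1
  df2 <- (n - 1) * (r - 1)
  fl <- f_obs / stats::qf(1 - alpha / 2, df1, df2)
  fu <- f_obs * stats::qf(1 - alpha / 2, df2, df1)
  lower <- (fl - 1) / (fl + r - 1)
  upper <- (fu - 1) / (fu + r - 1)
  new_icc_result(est, lower, upper, "consistency, single-rating, two-way random", ms, alpha)
}

#' Qualitative reliability label for an ICC estimate
#'
#' Conventional cut-offs: below 0.50 poor, 0.50 to below 0.75 moderate, 0.75 to
#' 0.90 good, above 0.90 excellent. Negative estimates are poor.
#'
#' @param estimate ICC estimate(s).
#' @return Character vector of labels.
#' @export
#' @examples
#' classify_reliability(c(-0.21, 0.17, 0.5, 0.91))
classify_reliability <- function(estimate) {
  vapply(estimate, function(e) {
    if (e < 0.50) "poor"
    else if (e < 0.75) "moderate"
    else if (e <= 0.90) "good"
    else "excellent"
  }, character(1))
}
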
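#' Per-participant mean ratios for observer-selected images
#'
#' For each observer, participant and region, averages the densities of the
#' selected images and divides by the participant's reference mean, mirroring
#' the "three representative images" estimate.
#'
#' @param selections Tibble with `observer_id`, `participant_id`, `region`,
#'   `image_id` (see [simulate_selections()] or the selections CSV).
#' @param counts The count table the selections refer to.
#' @return A tibble with `observer_id`, `participant_id`, `region`, `ratio`.
#' @export
observer_ratios <- function(selections, counts) {
  dens <- add_density(counts)
  joined <- dplyr::left_join(
    selections, dens,
    by = c("participant_id", "region", "image_id")
  )
  if (anyNA(joined$density)) {
    bad <- joined[is.na(joined$density), ]
    stop(sprintf("selection references unknown image(s), e.g. %s/%s/%s",
                 bad$participant_id[1], bad$region[1], bad$image_id[1]),
         call. = FALSE)
  }
  tm <- true_mean_table(counts)
  if (any(tm$true_mean <= 0)) {
    bad <- tm[tm$true_mean <= 0, ]
    warning(sprintf("excluding %d participant-region(s) with zero true mean from observer ratios",
                    nrow(bad)), call. = FALSE)
    tm <- tm[tm$true_mean > 0, ]
  }
  est <- dplyr::summarise(
    dplyr::group_by(joined, .data$observer_id, .data$participant_id, .data$region),
    est_mean = mean(.data$density), .groups = "drop"
  )
  out <- dplyr::inner_join(est, tm, by = c("participant_id", "region"))
  out$ratio <- out$est_mean / out$true_mean
  out[c("observer_id", "participant_id", "region", "ratio")]
}

#' Student's t comparison of observer vs random-subset mean ratios
#'
#' Two-sample pooled-variance (Student's) t-test of the observer's
#' per-participant mean ratios against the exhaustive random k-subset ratio
#' pool, with Bonferroni adjustment over `m` comparisons. A Welch test is
#' available via `welch = TRUE` but the pooled-variance form is the default.
#'
#' @param observer_ratios Numeric vector of the observer's per-participant
#'   ratios.
#' @param random_ratios Numeric vector of pooled random-subset ratios (e.g. the
#'   full k = 3 enumeration across participants).
#' @param m Number of comparisons in the Bonferroni family (default 3 raters).
#' @param welch Use Welch's unequal-variance t-test instead (default `FALSE`).
#' @return A one-row tibble: `statistic`, `p_value`, `p_adjusted`, `m`,
#'   `mean_observer`, `mean_random`, `degenerate`.
#' @export
compare_mean_to_random <- function(observer_ratios, random_ratios, m = 3,
                                   welch = FALSE) {
  if (length(observer_ratios) < 2 || length(random_ratios) < 2) {
    stop("both samples need at least 2 values", call. = FALSE)
  }
  degenerate <- stats::var(observer_ratios) == 0 && stats::var(random_ratios) == 0
  if (degenerate) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          p_adjusted = NA_real_, m = m,
                          mean_observer = mean(observer_ratios),
                          mean_random = mean(random_ratios), degenerate = TRUE))
  }
  tt <- stats::t.test(observer_ratios, random_ratios, var.equal = !welch)
  tibble::tibble(
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    p_adjusted = min(1, tt$p.value * m),
    m = m,
    mean_observer = mean(observer_ratios),
    mean_random = mean(random_ratios),
    degenerate = FALSE
  )
}

#' F comparison of observer vs random-subset ratio variances
#'
#' Tests whether the observer's ratio spread differs from the random-subset
#' reference: `F = var(observer) / var(random)` with `(n1 - 1, n2 - 1)`
#' degrees of freedom and two-sided p-value `2 * min(P(F <= f), P(F >= f))`,
#' Bonferroni-adjusted over `m` comparisons.
#'
#' @inheritParams compare_mean_to_random
#' @return A one-row tibble: `statistic`, `p_value`, `p_adjusted`, `m`,
#'   `var_observer`, `var_random`, `degenerate`.
#' @export
compare_variance_to_random <- function(observer_ratios, random_ratios, m = 3) {
  if (length(observer_ratios) < 2 || length(random_ratios) < 2) {
    stop("both samples need at least 2 values", call. = FALSE)
  }
  v1 <- stats::var(observer_ratios)
  v2 <- stats::var(random_ratios)
  if (v1 == 0 || v2 == 0) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          p_adjusted = NA_real_, m = m,
                          var_observer = v1, var_random = v2, degenerate = TRUE))
  }
  f <- v1 / v2
  df1 <- length(observer_ratios) - 1
  df2 <- length(random_ratios) - 1
  p_lo <- stats::pf(f, df1, df2)
  p <- min(1, 2 * min(p_lo, 1 - p_lo))
  tibble::tibble(statistic = f, p_value = p, p_adjusted = min(1, p * m), m = m,
                 var_observer = v1, var_random = v2, degenerate = FALSE)
}

#' Inter-observer consistency of representative-image ratios
#'
#' Pivots per-observer, per-participant mean ratios into a participants x
#' observers table and computes the single-rating, consistency, two-way
#' random-effects ICC.
#'
#' @param ratios Tibble with `observer_id`, `participant_id`, `ratio` (single
#'   region).
#' @param alpha Two-sided error rate for the CI (default 0.05).
#' @return An `icc_result` (see [icc_single_consistency()]).
#' @export
representative_consistency <- function(ratios, alpha = 0.05) {
  wide <- tidyr::pivot_wider(
    ratios[c("participant_id", "observer_id", "ratio")],
    names_from = "observer_id", values_from = "ratio"
  )
  mat <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(mat)) stop("incomplete participant x observer ratio table", call. = FALSE)
  icc_single_consistency(mat, alpha = alpha)
}

#' Full observer-vs-random comparison report for one region
#'
#' For each observer: the mean ratio of their selected-image estimates, a
#' Student's t comparison of means and an F comparison of variances against the
#' pooled exhaustive k-image random reference, with Bonferroni adjustment over
#' the observers; plus the inter-observer consistency ICC.
#'
#' @param counts A count table.
#' @param selections Selections tibble (`observer_id`, `participant_id`,
#'   `region`, `image_id`).
#' @param region Region label to report on.
#' @param k Random-reference subset size (default 3, the representative-image
#'   count).
#' @param m Bonferroni family size (default: number of observers).
#' @param welch Use Welch's t-test (default `FALSE`).
#' @return A list of class `ic_comparison`: `region`, `k`, tibble `tests` (one
#'   row per observer with both tests), `icc` (consistency `icc_result`),
#'   `random_summary` (mean/var/n of the reference pool).
#' @export
comparison_report <- function(counts, selections, region, k = 3, m = NULL,
                              welch = FALSE) {
  sel <- selections[selections$region == region, ]
  if (nrow(sel) == 0) stop(sprintf("no selections for region '%s'", region), call. = FALSE)
  obs <- observer_ratios(sel, counts[counts$region == region, ])
  observers <- sort(unique(obs$observer_id))
  if (is.null(m)) m <- length(observers)
  pool <- pooled_distribution(counts, region, k)$ratio
  rows <- lapply(observers, function(o) {
    x <- obs$ratio[obs$observer_id == o]
    tt <- compare_mean_to_random(x, pool, m = m, welch = welch)
    ft <- compare_variance_to_random(x, pool, m = m)
    tibble::tibble(
      observer_id = o, region = region, n_participants = length(x),
      mean_ratio = mean(x),
      t_statistic = tt$statistic, t_p = tt$p_value, t_p_adjusted = tt$p_adjusted,
      f_statistic = ft$statistic, f_p = ft$p_value, f_p_adjusted = ft$p_adjusted,
      degenerate = tt$degenerate | ft$degenerate
    )
  })
  icc <- representative_consistency(obs)
  structure(
    list(region = region, k = k, m = m,
         tests = dplyr::bind_rows(rows),
         icc = icc,
         observer_ratios = obs,
         random_summary = tibble::tibble(mean = mean(pool), var = stats::var(pool),
                                         n = length(pool))),
    class = "ic_comparison"
  )
}

#' @export
print.ic_comparison <- function(x, ...) {
  cat(sprintf("<ic_comparison> region %s, random reference: all %d-image subsets (n = %d)\n",
              x$region, x$k, x$random_summary$n))
  print(as.data.frame(x$tests[c("observer_id", "mean_ratio", "t_p_adjusted", "f_p_adjusted")]),
        row.names = FALSE)
  cat(sprintf("representative-image consistency ICC: %.3f (%s)\n",
              x$icc$estimate, classify_reliability(x$icc$estimate)))
  invisible(x)
}
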
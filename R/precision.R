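#' Precision criterion for a density estimate
#'
#' An estimate is acceptable when it differs from the participant's true mean
#' by less than `delta` (relative), with confidence `level` — i.e. the
#' mean-ratio band at that level lies within `[1 - delta, 1 + delta]`.
#'
#' @param delta Relative tolerance in (0, 1); default 0.30.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return An object of class `ic_criterion`.
#' @export
precision_criterion <- function(delta = 0.30, level = 0.95) {
  if (delta <= 0 || delta >= 1) stop("`delta` must lie in (0, 1)", call. = FALSE)
  if (level <= 0 || level >= 1) stop("`level` must lie in (0, 1)", call. = FALSE)
  structure(list(delta = delta, level = level), class = "ic_criterion")
}

# population-SD (divisor N): the enumeration IS the full population of
# estimates, so no n-1 correction is applied
sd_pop <- function(x) {
  mu <- mean(x)
  sqrt(mean((x - mu)^2))
}

#' Tolerance-style confidence band of a ratio distribution
#'
#' Computes `mu +/- t * SD` of the pooled mean ratios, where `t` is the
#' two-sided t quantile at the requested level with `n - 1` degrees of freedom
#' (indistinguishable from the normal quantile at the pooled sizes involved).
#' This is a spread band on the distribution of estimates — "within the band,
#' `level` of the time" — not a standard-error band on the mean.
#'
#' @param ratios Numeric vector of pooled mean ratios (length >= 2).
#' @param level Confidence level in (0, 1).
#' @return A one-row tibble: `level`, `mu`, `sd`, `lower`, `upper`, `n`.
#' @export
ratio_ci <- function(ratios, level = 0.95) {
  n <- length(ratios)
  if (n < 2) stop("need at least 2 ratios for a band", call. = FALSE)
  mu <- mean(ratios)
  s <- sd_pop(ratios)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  tibble::tibble(level = level, mu = mu, sd = s,
                 lower = mu - tq * s, upper = mu + tq * s, n = n)
}

#' Confidence-band table across subset sizes
#'
#' Enumerates the pooled ratio distribution for each `k` and computes the
#' band at each confidence level.
#'
#' @param counts A count table.
#' @param region Region label.
#' @param k_range Integer vector of subset sizes (default `2:(n_images - 1)`,
#'   taken from the data).
#' @param levels Confidence levels (default 0.80, 0.85, 0.90, 0.95).
#' @return A tibble with columns `region`, `k`, `level`, `mu`, `sd`, `lower`,
#'   `upper`, `n`.
#' @export
ci_bands <- function(counts, region, k_range = NULL,
                     levels = c(0.80, 0.85, 0.90, 0.95)) {
  sub <- counts[counts$region == region, ]
  if (nrow(sub) == 0) stop(sprintf("region '%s' absent from dataset", region), call. = FALSE)
  n_img <- min(table(sub$participant_id))
  if (is.null(k_range)) k_range <- 2:(n_img - 1)
  rows <- lapply(k_range, function(k) {
    pooled <- pooled_distribution(counts, region, k)
    bands <- dplyr::bind_rows(lapply(levels, function(l) ratio_ci(pooled$ratio, l)))
    dplyr::bind_cols(tibble::tibble(region = region, k = k), bands)
  })
  dplyr::bind_rows(rows)
}

#' Minimal image sample size from a band table
#'
#' Returns the smallest `k` whose band at the criterion's level lies entirely
#' within `[1 - delta, 1 + delta]`.
#'
#' @param bands A band table from [ci_bands()] (single region).
#' @param criterion An [precision_criterion()].
#' @return An object of class `ic_sample_size`: a list with `region`,
#'   `criterion`, `k_min` (integer, or `NA` with `achieved = FALSE` when no
#'   `k` qualifies), and the band rows at the criterion level.
#' @export
minimal_sample_size <- function(bands, criterion = precision_criterion()) {
  stopifnot(inherits(criterion, "ic_criterion"))
  if (nrow(bands) == 0) stop("empty band table", call. = FALSE)
  at_level <- bands[abs(bands$level - criterion$level) < 1e-12, ]
  if (nrow(at_level) == 0) {
    stop(sprintf("band table has no level %g rows", criterion$level), call. = FALSE)
  }
  at_level <- at_level[order(at_level$k), ]
  ok <- at_level$upper <= 1 + criterion$delta & at_level$lower >= 1 - criterion$delta
  k_min <- if (any(ok)) at_level$k[which(ok)[1]] else NA_integer_
  structure(
    list(region = unique(at_level$region), criterion = criterion,
         k_min = k_min, achieved = !is.na(k_min), bands = at_level),
    class = "ic_sample_size"
  )
}

#' @export
print.ic_sample_size <- function(x, ...) {
  cat("<ic_sample_size>\n")
  cat(sprintf("  region: %s, criterion: within %.0f%% of true mean, %.0f%% of the time\n",
              paste(x$region, collapse = ","),
              100 * x$criterion$delta, 100 * x$criterion$level))
  cat(sprintf("  k_min: %s\n", if (x$achieved) x$k_min else "not achieved"))
  invisible(x)
}

#' Closed-form minimal sample size (analytic oracle)
#'
#' Every participant's enumerated ratio distribution is centred at exactly 1,
#' so the pooled (population-SD) band SD at subset size `k` is the root mean
#' square of the per-participant [exact_ratio_sd()] values, weighted equally
#' because each participant contributes the same number of combinations. The
#' minimal `k` is the smallest with `t * sd <= delta`. Agrees with the
#' enumeration path ([ci_bands()] + [minimal_sample_size()]) to numerical
#' precision without enumerating anything.
#'
#' @param counts A count table.
#' @param region Region label.
#' @param criterion An [precision_criterion()].
#' @param k_range Integer vector of subset sizes (default `2:(n_images - 1)`).
#' @return An `ic_sample_size` object, as [minimal_sample_size()].
#' @export
analytic_minimal_sample_size <- function(counts, region,
                                         criterion = precision_criterion(),
                                         k_range = NULL) {
  stopifnot(inherits(criterion, "ic_criterion"))
  sub <- counts[counts$region == region, ]
  if (nrow(sub) == 0) stop(sprintf("region '%s' absent from dataset", region), call. = FALSE)
  dens <- add_density(sub)
  groups <- split(dens$density, dens$participant_id)
  tm <- vapply(groups, mean, numeric(1))
  if (any(tm <= 0)) {
    warning("participants with zero true mean excluded from analytic bands", call. = FALSE)
    groups <- groups[tm > 0]
  }
  n_img <- min(lengths(groups))
  if (is.null(k_range)) k_range <- 2:(n_img - 1)
  rows <- lapply(k_range, function(k) {
    v <- vapply(groups, function(d) exact_ratio_sd(d, k)^2, numeric(1))
    s <- sqrt(mean(v))
    n_pool <- length(groups) * count_combinations(n_img, k)
    tq <- stats::qt(1 - (1 - criterion$level) / 2, df = n_pool - 1)
    tibble::tibble(region = region, k = k, level = criterion$level,
                   mu = 1, sd = s, lower = 1 - tq * s, upper = 1 + tq * s,
                   n = n_pool)
  })
  minimal_sample_size(dplyr::bind_rows(rows), criterion)
}
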
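#' Number of unordered k-subsets of n items
#'
#' @param n Set size (non-negative integer).
#' @param k Subset size, `0 <= k <= n`.
#' @return The binomial coefficient as an exact whole number.
#' @export
#' @examples
#' count_combinations(16, 3)  # 560
#' count_combinations(16, 8)  # 12870
count_combinations <- function(n, k) {
  if (n < 0 || k < 0) stop("`n` and `k` must be non-negative", call. = FALSE)
  if (k > n) stop("`k` must not exceed `n`", call. = FALSE)
  round(choose(n, k))
}

# cache of combn index matrices, keyed "n:k" -- the enumeration for a given
# (n, k) is reused across participants, replicates and k-scans
.combn_cache <- new.env(parent = emptyenv())

combination_indices <- function(n, k) {
  key <- paste(n, k, sep = ":")
  if (!is.null(.combn_cache[[key]])) return(.combn_cache[[key]])
  m <- utils::combn(n, k)
  .combn_cache[[key]] <- m
  m
}

#' Mean ratios of all k-subsets for one participant
#'
#' Enumerates every k-subset of the participant's image densities (in
#' lexicographic order of index subsets) and returns, for each, the subset mean
#' divided by the full-set ("true") mean.
#'
#' @param densities Numeric vector of the participant's per-image densities.
#' @param k Subset size, `1 <= k <= length(densities)`.
#' @return Numeric vector of `choose(n, k)` mean ratios.
#' @export
participant_mean_ratios <- function(densities, k) {
  n <- length(densities)
  if (k < 1 || k > n) stop("`k` must lie in 1..length(densities)", call. = FALSE)
  m <- mean(densities)
  if (m <= 0) stop("true mean must be positive for ratio analysis", call. = FALSE)
  if (k == n) return(1)
  idx <- combination_indices(n, k)
  subset_means <- if (k == 1) densities else .colMeans(densities[idx], k, ncol(idx))
  subset_means / m
}

#' Exact SD of the k-subset mean ratio
#'
#' Closed form for the spread of the enumerated ratio distribution: the subset
#' mean of k items drawn without replacement from n has variance
#' `S^2 * (1/k - 1/n)` (finite-population correction), with `S^2` the sample
#' variance (divisor n-1) of the n densities. Dividing by the true mean `m`
#' gives the ratio SD `(S/m) * sqrt(1/k - 1/n)`. This equals the population SD
#' (divisor N = number of combinations) of [participant_mean_ratios()] exactly.
#'
#' @inheritParams participant_mean_ratios
#' @return The exact ratio SD; 0 when `k == n` or the densities are constant.
#' @export
exact_ratio_sd <- function(densities, k) {
  n <- length(densities)
  if (n < 2) stop("need at least 2 densities", call. = FALSE)
  if (k < 1 || k > n) stop("`k` must lie in 1..length(densities)", call. = FALSE)
  m <- mean(densities)
  if (m <= 0) stop("true mean must be positive for ratio analysis", call. = FALSE)
  if (k == n) return(0)
  (stats::sd(densities) / m) * sqrt(1 / k - 1 / n)
}

#' Pooled mean-ratio distribution for one region and subset size
#'
#' Concatenates [participant_mean_ratios()] across all participants of a
#' region. Participant-regions with a zero true mean are excluded with a
#' warning (the ratio is undefined there). For reference sets larger than the
#' study design, a seeded uniform subsample of combinations can be requested
#' via `max_combinations`; by default the enumeration is exhaustive.
#'
#' @param counts A count table.
#' @param region Region label to pool over.
#' @param k Subset size.
#' @param max_combinations Optional cap on combinations per participant; when
#'   the full enumeration exceeds it, a uniform random subsample of that size
#'   is used (requires a seeded RNG state for reproducibility).
#' @return A tibble with columns `participant_id`, `region`, `k`,
#'   `combination_index`, `ratio`.
#' @export
pooled_distribution <- function(counts, region, k, max_combinations = NULL) {
  sub <- counts[counts$region == region, ]
  if (nrow(sub) == 0) stop(sprintf("region '%s' absent from dataset", region), call. = FALSE)
  dens <- add_density(sub)
  groups <- split(dens$density, dens$participant_id)
  pieces <- lapply(names(groups), function(pid) {
    d <- groups[[pid]]
    if (mean(d) <= 0) {
      warning(sprintf("participant %s (%s) has zero true mean; excluded", pid, region),
              call. = FALSE)
      return(NULL)
    }
    r <- participant_mean_ratios(d, k)
    if (!is.null(max_combinations) && length(r) > max_combinations) {
      keep <- sort(sample.int(length(r), max_combinations))
      tibble::tibble(participant_id = pid, region = region, k = k,
                     combination_index = keep, ratio = r[keep])
    } else {
      tibble::tibble(participant_id = pid, region = region, k = k,
                     combination_index = seq_along(r), ratio = r)
    }
  })
  dplyr::bind_rows(pieces)
}
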
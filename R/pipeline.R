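#' Write a provenance sidecar for a pipeline run
#'
#' Records everything needed to regenerate the outputs byte-identically: the
#' generator or run configuration, the seed, and the package version.
#'
#' @param path Output JSON path.
#' @param config A list-like configuration (e.g. [generator_config()]).
#' @param seed Integer seed used for the run.
#' @param extra Optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config, seed, extra = list()) {
  payload <- c(
    list(
      package = "icdensity",
      version = as.character(utils::packageVersion("icdensity")),
      seed = as.integer(seed),
      config = unclass(config)
    ),
    extra
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Generate and persist a synthetic dataset
#'
#' @param config An [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Seed (defaults to `config$seed`).
#' @return The generated `ic_counts` tibble, invisibly. Writes `counts.csv` and
#'   `provenance.json` under `out_dir`.
#' @export
run_simulation <- function(config, out_dir, seed = config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- generate_counts(config, seed = seed)
  write_image_counts(counts, file.path(out_dir, "counts.csv"))
  write_provenance(file.path(out_dir, "provenance.json"), config, seed,
                   extra = list(n_records = nrow(counts)))
  invisible(counts)
}

#' Scatterplot of pooled mean ratios against subset size
#'
#' @param pooled A tibble of pooled ratios over several `k` (rows from
#'   [pooled_distribution()]).
#' @return A ggplot object.
#' @export
plot_ratio_scatter <- function(pooled) {
  ggplot2::ggplot(pooled, ggplot2::aes(x = .data$k, y = .data$ratio)) +
    ggplot2::geom_point(alpha = 0.08, size = 0.4,
                        position = ggplot2::position_jitter(width = 0.18, height = 0)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "number of images (k)", y = "mean ratio (estimate / true mean)") +
    ggplot2::theme_minimal()
}

#' Confidence-band plot with the precision criterion
#'
#' Band endpoints against `k` for each confidence level, with horizontal lines
#' at `1 +/- delta` and, when achieved, a vertical line at `k_min`.
#'
#' @param bands A band table from [ci_bands()].
#' @param criterion An [precision_criterion()].
#' @param k_min Optional integer to mark.
#' @return A ggplot object.
#' @export
plot_ci_bands <- function(bands, criterion = precision_criterion(), k_min = NULL) {
  bands$level_lab <- sprintf("%.0f%%", 100 * bands$level)
  p <- ggplot2::ggplot(bands, ggplot2::aes(x = .data$k, colour = .data$level_lab)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper)) +
    ggplot2::geom_hline(yintercept = c(1 - criterion$delta, 1 + criterion$delta),
                        linetype = "dotted") +
    ggplot2::labs(x = "number of images (k)", y = "mean ratio band",
                  colour = "confidence") +
    ggplot2::theme_minimal()
  if (!is.null(k_min) && !is.na(k_min)) {
    p <- p + ggplot2::geom_vline(xintercept = k_min, linetype = "dashed")
  }
  p
}

#' Observer-vs-random interval plot
#'
#' Mean ratio with a `+/- t * SD` spread interval for the random reference and
#' each observer, mirroring the bar-and-interval presentation of the
#' representative-image comparison.
#'
#' @param report An `ic_comparison` from [comparison_report()].
#' @param level Interval confidence level (default 0.95).
#' @return A ggplot object.
#' @export
plot_observer_comparison <- function(report, level = 0.95) {
  obs <- report$observer_ratios
  per_obs <- dplyr::bind_rows(lapply(split(obs$ratio, obs$observer_id), function(x) {
    ratio_ci(x, level)
  }), .id = "group")
  rand <- tibble::tibble(
    group = "random", level = level,
    mu = report$random_summary$mean,
    sd = sqrt(report$random_summary$var),
    lower = report$random_summary$mean -
      stats::qt(1 - (1 - level) / 2, report$random_summary$n - 1) * sqrt(report$random_summary$var),
    upper = report$random_summary$mean +
      stats::qt(1 - (1 - level) / 2, report$random_summary$n - 1) * sqrt(report$random_summary$var),
    n = report$random_summary$n
  )
  df <- dplyr::bind_rows(rand, per_obs)
  df$group <- factor(df$group, levels = df$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mu)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "mean ratio (+/- spread interval)",
                  title = sprintf("%s cornea", report$region)) +
    ggplot2::theme_minimal()
}

#' Run the sample-size analysis for one region and persist outputs
#'
#' Computes the pooled ratio distributions, band table and minimal sample size,
#' writes `bands_<region>.csv` and `sample_size_<region>.json`, and saves the
#' ratio scatter and band figures as PNG.
#'
#' @param counts A count table.
#' @param region Region label.
#' @param out_dir Output directory.
#' @param criterion An [precision_criterion()].
#' @param levels Confidence levels for the band table.
#' @param k_range Optional subset-size range.
#' @return The `ic_sample_size` result, invisibly.
#' @export
run_sample_size_analysis <- function(counts, region, out_dir,
                                     criterion = precision_criterion(),
                                     levels = c(0.80, 0.85, 0.90, 0.95),
                                     k_range = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bands <- ci_bands(counts, region, k_range = k_range, levels = levels)
  res <- minimal_sample_size(bands, criterion)
  utils::write.csv(as.data.frame(bands[c("region", "k", "level", "mu", "sd",
                                         "lower", "upper", "n")]),
                   file.path(out_dir, sprintf("bands_%s.csv", region)),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(region = region, delta = criterion$delta, level = criterion$level,
         k_min = if (res$achieved) res$k_min else "not achieved",
         achieved = res$achieved),
    file.path(out_dir, sprintf("sample_size_%s.json", region)),
    auto_unbox = TRUE, digits = NA
  )
  pooled <- dplyr::bind_rows(lapply(sort(unique(bands$k)), function(k) {
    pooled_distribution(counts, region, k)
  }))
  ggplot2::ggsave(file.path(out_dir, sprintf("ratio_scatter_%s.png", region)),
                  plot_ratio_scatter(pooled), width = 7, height = 4.5, dpi = 150)
  ggplot2::ggsave(file.path(out_dir, sprintf("ci_bands_%s.png", region)),
                  plot_ci_bands(bands, criterion, res$k_min),
                  width = 7, height = 4.5, dpi = 150)
  invisible(res)
}

#' Run the observer comparison for one region and persist outputs
#'
#' @param counts A count table.
#' @param selections Selections tibble.
#' @param region Region label.
#' @param out_dir Output directory.
#' @param k Random-reference subset size (default 3).
#' @param m Bonferroni family size (default: number of observers).
#' @return The `ic_comparison` report, invisibly. Writes
#'   `comparison_<region>.json` and the interval figure.
#' @export
run_observer_analysis <- function(counts, selections, region, out_dir,
                                  k = 3, m = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- comparison_report(counts, selections, region, k = k, m = m)
  jsonlite::write_json(
    list(
      region = region, k = k, m = report$m,
      tests = report$tests,
      icc = list(estimate = report$icc$estimate,
                 ci_lower = report$icc$ci_lower,
                 ci_upper = report$icc$ci_upper,
                 model = report$icc$model,
                 reliability = classify_reliability(report$icc$estimate)),
      random = report$random_summary
    ),
    file.path(out_dir, sprintf("comparison_%s.json", region)),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  ggplot2::ggsave(file.path(out_dir, sprintf("observer_comparison_%s.png", region)),
                  plot_observer_comparison(report), width = 6, height = 4, dpi = 150)
  invisible(report)
}
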
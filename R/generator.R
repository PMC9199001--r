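#' Configuration for the synthetic IVCM count generator
#'
#' Bundles the study-design parameters the generator emulates: the number of
#' participants, the number of non-overlapping images per corneal region, the
#' per-image quantified area, and the per-region participant-level density
#' distribution (mean and SD in cells/mm^2). Defaults reproduce the design of
#' the healthy-cornea study the pipeline targets: 20 participants, 16 images of
#' 400 um x 400 um (0.16 mm^2) per region, central density 21.7 +/- 17.7 and
#' peripheral density 62.0 +/- 26.1 cells/mm^2.
#'
#' @param n_participants Number of participants (default 20).
#' @param n_images Number of non-overlapping images per participant and region
#'   (default 16; must be at least 2).
#' @param image_area Quantified area per image in mm^2 (default 0.16).
#' @param density_mean Named numeric vector of per-region mean true densities
#'   in cells/mm^2; names are the region labels.
#' @param density_sd Named numeric vector of per-region between-participant
#'   density SDs (cells/mm^2), same names as `density_mean`.
#' @param dispersion Negative-binomial size parameter for image-level counting
#'   noise. `Inf` (the default) gives Poisson counts; finite values add
#'   overdispersion (variance `mu + mu^2 / dispersion`).
#' @param seed Integer seed; the same config and seed reproduce the dataset
#'   exactly.
#'
#' @return An object of class `ic_config` (a validated list).
#' @seealso [generate_counts()]
#' @export
#' @examples
#' cfg <- generator_config(seed = 1)
#' cfg$density_mean
generator_config <- function(n_participants = 20,
                             n_images = 16,
                             image_area = 0.16,
                             density_mean = c(central = 21.7, peripheral = 62.0),
                             density_sd = c(central = 17.7, peripheral = 26.1),
                             dispersion = Inf,
                             seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 1) {
    stop("`n_participants` must be a positive count", call. = FALSE)
  }
  if (!is.numeric(n_images) || n_images < 2) {
    stop("`n_images` must be at least 2", call. = FALSE)
  }
  if (!is.numeric(image_area) || image_area <= 0) {
    stop("`image_area` must be positive (mm^2)", call. = FALSE)
  }
  if (is.null(names(density_mean)) || is.null(names(density_sd)) ||
      !identical(sort(names(density_mean)), sort(names(density_sd)))) {
    stop("`density_mean` and `density_sd` must share region names", call. = FALSE)
  }
  if (any(density_mean <= 0)) {
    stop("all `density_mean` values must be positive", call. = FALSE)
  }
  if (any(density_sd < 0)) {
    stop("`density_sd` values must be non-negative", call. = FALSE)
  }
  if (!is.numeric(dispersion) || length(dispersion) != 1 || dispersion <= 0) {
    stop("`dispersion` must be a positive number or Inf", call. = FALSE)
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_images = as.integer(n_images),
      image_area = as.numeric(image_area),
      density_mean = density_mean,
      density_sd = density_sd[names(density_mean)],
      dispersion = dispersion,
      seed = as.integer(seed)
    ),
    class = "ic_config"
  )
}

#' @export
print.ic_config <- function(x, ...) {
  cat("<ic_config>\n")
  cat(sprintf("  participants: %d, images/region: %d, area: %g mm^2\n",
              x$n_participants, x$n_images, x$image_area))
  for (r in names(x$density_mean)) {
    cat(sprintf("  %s: %g +/- %g cells/mm^2\n",
                r, x$density_mean[[r]], x$density_sd[[r]]))
  }
  cat(sprintf("  dispersion: %s, seed: %d\n",
              if (is.infinite(x$dispersion)) "Inf (Poisson)" else format(x$dispersion),
              x$seed))
  invisible(x)
}

#' Draw participant-level true densities for one region
#'
#' Participant heterogeneity is modelled as a gamma distribution moment-matched
#' to the configured regional mean and SD (shape = mean^2/sd^2, scale =
#' sd^2/mean), giving strictly positive densities. With `sd = 0` all
#' participants share the mean exactly. Draws below 1e-6 cells/mm^2 are redrawn
#' so downstream ratio analyses never see a numerically zero true mean.
#'
#' Consumes the current RNG state; wrap in [withr::with_seed()] (or call via
#' [generate_counts()]) for reproducibility.
#'
#' @param config An [generator_config()] object.
#' @param region Region name present in `config$density_mean`.
#' @param n Number of draws (defaults to `config$n_participants`).
#' @return Numeric vector of `n` true densities (cells/mm^2).
#' @export
draw_participant_densities <- function(config, region, n = config$n_participants) {
  stopifnot(inherits(config, "ic_config"))
  if (!region %in% names(config$density_mean)) {
    stop(sprintf("unknown region '%s'", region), call. = FALSE)
  }
  m <- config$density_mean[[region]]
  s <- config$density_sd[[region]]
  if (m <= 0) stop("density mean must be positive", call. = FALSE)
  if (s == 0) return(rep(m, n))
  shape <- m^2 / s^2
  scale <- s^2 / m
  d <- stats::rgamma(n, shape = shape, scale = scale)
  while (any(d < 1e-6)) {
    idx <- which(d < 1e-6)
    d[idx] <- stats::rgamma(length(idx), shape = shape, scale = scale)
  }
  d
}

# image-level counts for one participant-region; lambda = density * area
draw_image_counts <- function(density, n_images, image_area, dispersion) {
  lambda <- density * image_area
  if (is.infinite(dispersion)) {
    stats::rpois(n_images, lambda)
  } else {
    stats::rnbinom(n_images, size = dispersion, mu = lambda)
  }
}

#' Generate a synthetic per-image count dataset
#'
#' Emits one row per participant x region x image with an integer immune-cell
#' count and the image area. For each region, participant true densities are
#' drawn by [draw_participant_densities()]; image counts are then Poisson (or
#' negative-binomial when `config$dispersion` is finite) with mean
#' `density * image_area`. Regions are generated independently.
#'
#' @param config An [generator_config()] object.
#' @param seed Integer seed (defaults to `config$seed`). Identical config and
#'   seed give byte-identical output.
#' @return A tibble of class `ic_counts` with columns `participant_id`,
#'   `region`, `image_id`, `count`, `area_mm2`, and the true participant
#'   density in `true_density` (generator-only ground truth, dropped on CSV
#'   write). The config and seed are attached as attributes `config` / `seed`.
#' @export
#' @examples
#' counts <- generate_counts(generator_config(seed = 42))
#' nrow(counts)  # 20 participants x 2 regions x 16 images = 640
generate_counts <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "ic_config"))
  out <- withr::with_seed(seed, {
    regions <- names(config$density_mean)
    pieces <- lapply(regions, function(r) {
      d <- draw_participant_densities(config, r)
      per_part <- lapply(seq_len(config$n_participants), function(i) {
        counts <- draw_image_counts(d[i], config$n_images,
                                    config$image_area, config$dispersion)
        tibble::tibble(
          participant_id = sprintf("P%02d", i),
          region = r,
          image_id = sprintf("img%02d", seq_len(config$n_images)),
          count = as.integer(counts),
          area_mm2 = config$image_area,
          true_density = d[i]
        )
      })
      dplyr::bind_rows(per_part)
    })
    dplyr::bind_rows(pieces)
  })
  attr(out, "config") <- config
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("ic_counts", class(out))
  out
}

#' Observer counting-error model
#'
#' The simplest mechanism able to emulate imperfect recounts: each true cell is
#' detected independently with probability `detection_probability` (binomial
#' thinning) and an independent Poisson number of spurious cells with mean
#' `false_positive_rate` is added per image. With detection 1 and false-positive
#' rate 0 the recounts reproduce the reference counts exactly.
#'
#' @param detection_probability Per-cell detection probability in (0, 1].
#' @param false_positive_rate Expected spurious cells per image (>= 0).
#' @return An object of class `ic_observer_model`.
#' @export
observer_model <- function(detection_probability = 1, false_positive_rate = 0) {
  if (detection_probability <= 0 || detection_probability > 1) {
    stop("`detection_probability` must lie in (0, 1]", call. = FALSE)
  }
  if (false_positive_rate < 0) {
    stop("`false_positive_rate` must be non-negative", call. = FALSE)
  }
  structure(
    list(detection_probability = detection_probability,
         false_positive_rate = false_positive_rate),
    class = "ic_observer_model"
  )
}

#' Simulate one observer's recounts
#'
#' Applies the [observer_model()] error mechanism to a vector of reference
#' counts. Consumes the current RNG state.
#'
#' @param counts Non-negative integer vector of reference counts.
#' @param model An [observer_model()].
#' @return Integer vector of recounts, same length as `counts`.
#' @export
simulate_observer_counts <- function(counts, model) {
  stopifnot(inherits(model, "ic_observer_model"))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  n <- length(counts)
  detected <- stats::rbinom(n, size = as.integer(round(counts)),
                            prob = model$detection_probability)
  fp <- if (model$false_positive_rate > 0) {
    stats::rpois(n, model$false_positive_rate)
  } else {
    integer(n)
  }
  as.integer(detected + fp)
}

#' Observer image-selection model
#'
#' Emulates an observer choosing `n_selected` "representative" images from a
#' participant's image set. Selection is without replacement with probability
#' weights proportional to `exp(bias_strength * z)`, where `z` is the image
#' density standardised within the participant (z is defined as 0 for all
#' images when the within-participant SD is 0). `bias_strength = 0` gives
#' uniform random selection; large positive values concentrate selection on the
#' densest images, mimicking an observer drawn to cell-rich fields.
#'
#' @param bias_strength Real selection-bias coefficient (beta).
#' @param n_selected Number of images selected per participant-region
#'   (default 3).
#' @return An object of class `ic_selection_model`.
#' @export
selection_model <- function(bias_strength = 0, n_selected = 3) {
  if (!is.numeric(bias_strength) || length(bias_strength) != 1) {
    stop("`bias_strength` must be a single number", call. = FALSE)
  }
  if (n_selected < 1) stop("`n_selected` must be at least 1", call. = FALSE)
  structure(
    list(bias_strength = as.numeric(bias_strength),
         n_selected = as.integer(n_selected)),
    class = "ic_selection_model"
  )
}

#' Select images for one participant-region under a bias model
#'
#' @param image_densities Numeric vector of per-image densities for one
#'   participant-region.
#' @param model An [selection_model()].
#' @return Integer vector of `n_selected` distinct image indices.
#' @export
simulate_image_selection <- function(image_densities, model) {
  stopifnot(inherits(model, "ic_selection_model"))
  n <- length(image_densities)
  if (model$n_selected > n) {
    stop("cannot select more images than are available", call. = FALSE)
  }
  s <- stats::sd(image_densities)
  z <- if (is.na(s) || s == 0) rep(0, n) else (image_densities - mean(image_densities)) / s
  w <- exp(model$bias_strength * z)
  sample.int(n, size = model$n_selected, prob = w)
}

#' Simulate representative-image selections for a panel of observers
#'
#' Applies [simulate_image_selection()] independently for each observer,
#' participant and region of a count dataset.
#'
#' @param counts An `ic_counts` dataset (see [generate_counts()]).
#' @param model An [selection_model()] shared by all observers.
#' @param n_observers Number of observers (default 3).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `observer_id`, `participant_id`, `region`,
#'   `image_id` (`model$n_selected` rows per observer-participant-region).
#' @export
simulate_selections <- function(counts, model, n_observers = 3, seed = NULL) {
  stopifnot(inherits(model, "ic_selection_model"))
  run <- function() {
    dens <- add_density(counts)
    groups <- dplyr::group_split(dplyr::group_by(dens, .data$participant_id, .data$region))
    rows <- lapply(seq_len(n_observers), function(o) {
      sel <- lapply(groups, function(g) {
        idx <- simulate_image_selection(g$density, model)
        tibble::tibble(
          observer_id = sprintf("rater%d", o),
          participant_id = g$participant_id[1],
          region = g$region[1],
          image_id = g$image_id[idx]
        )
      })
      dplyr::bind_rows(sel)
    })
    dplyr::bind_rows(rows)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a recount experiment for several observers
#'
#' Draws a random subset of images from a count dataset and produces one
#' recount column per observer under a shared [observer_model()], yielding the
#' wide subjects x raters table used for inter-observer agreement analysis.
#'
#' @param counts An `ic_counts` dataset.
#' @param model An [observer_model()].
#' @param n_images Number of images to recount (default 100).
#' @param n_observers Number of observers (default 3).
#' @param seed Optional integer seed.
#' @return A matrix with `n_images` rows (subjects = images) and
#'   `n_observers` columns of recounts.
#' @export
simulate_recount_table <- function(counts, model, n_images = 100,
                                   n_observers = 3, seed = NULL) {
  run <- function() {
    if (n_images > nrow(counts)) {
      stop("`n_images` exceeds the number of available images", call. = FALSE)
    }
    picked <- counts$count[sample.int(nrow(counts), n_images)]
    m <- vapply(seq_len(n_observers), function(o) {
      simulate_observer_counts(picked, model)
    }, numeric(n_images))
    colnames(m) <- sprintf("rater%d", seq_len(n_observers))
    m
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
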
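#' Convert a cell count to a density
#'
#' @param count Non-negative integer cell count(s).
#' @param area Image area in mm^2 (> 0), recycled against `count`.
#' @return Density in cells/mm^2 (`count / area`).
#' @export
#' @examples
#' density_from_count(4, 0.16)   # 25
#' density_from_count(10, 0.16)  # 62.5
density_from_count <- function(count, area) {
  if (any(area <= 0)) stop("`area` must be positive", call. = FALSE)
  if (any(count < 0)) stop("`count` must be non-negative", call. = FALSE)
  count / area
}

#' Add a per-image density column to a count table
#'
#' @param counts A count table with `count` and `area_mm2` columns.
#' @return The table with a `density` column (cells/mm^2) appended.
#' @export
add_density <- function(counts) {
  dplyr::mutate(counts, density = density_from_count(.data$count, .data$area_mm2))
}

#' Reference ("true") mean density of one image set
#'
#' The participant-region reference standard is the arithmetic mean density
#' over the full non-overlapping image set (16 images, 2.56 mm^2 quantified
#' area, at the default design).
#'
#' @param densities Numeric vector of per-image densities.
#' @param n_ref Expected reference-set size (default 16).
#' @param strict If `TRUE` (default), a vector of the wrong length is an error;
#'   otherwise a warning is emitted and the mean of whatever was supplied is
#'   returned.
#' @return The arithmetic mean density. A zero mean is returned as 0 with a
#'   warning, since downstream ratio analyses are undefined for it.
#' @export
true_mean_density <- function(densities, n_ref = 16, strict = TRUE) {
  if (length(densities) != n_ref) {
    msg <- sprintf("expected %d reference images, got %d", n_ref, length(densities))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  m <- mean(densities)
  if (m == 0) warning("zero true mean: ratio analyses undefined for this set", call. = FALSE)
  m
}

#' Per participant-region reference means
#'
#' @param counts A count table (`participant_id`, `region`, `image_id`,
#'   `count`, `area_mm2`).
#' @return A tibble with one row per participant-region: `true_mean`
#'   (cells/mm^2), `n_images`, `total_area_mm2`.
#' @export
true_mean_table <- function(counts) {
  dens <- add_density(counts)
  dplyr::summarise(
    dplyr::group_by(dens, .data$participant_id, .data$region),
    true_mean = mean(.data$density),
    n_images = dplyr::n(),
    total_area_mm2 = sum(.data$area_mm2),
    .groups = "drop"
  )
}

#' Validate the structure of a count dataset
#'
#' Checks the structural assumptions the pipeline relies on: unique
#' (participant, region, image) keys, integer non-negative counts, a single
#' image area within each participant-region, and complete reference sets.
#'
#' @param counts A count table.
#' @param n_ref Expected images per participant-region (default 16).
#' @return A tibble of findings with columns `type`, `participant_id`,
#'   `region`, `detail`; zero rows when the dataset is clean.
#' @export
validate_image_set <- function(counts, n_ref = 16) {
  findings <- list()
  key <- paste(counts$participant_id, counts$region, counts$image_id, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    parts <- do.call(rbind, strsplit(dup, "\r", fixed = TRUE))
    findings$dup <- tibble::tibble(
      type = "duplicate_key",
      participant_id = parts[, 1], region = parts[, 2],
      detail = sprintf("image '%s' duplicated", parts[, 3])
    )
  }
  bad <- counts$count < 0 | counts$count != round(counts$count)
  if (any(bad)) {
    findings$bad <- tibble::tibble(
      type = "invalid_count",
      participant_id = counts$participant_id[bad],
      region = counts$region[bad],
      detail = sprintf("count %s is not a non-negative integer",
                       format(counts$count[bad]))
    )
  }
  by_set <- dplyr::summarise(
    dplyr::group_by(counts, .data$participant_id, .data$region),
    n_areas = dplyr::n_distinct(.data$area_mm2),
    n_img = dplyr::n(),
    .groups = "drop"
  )
  mixed <- by_set[by_set$n_areas > 1, ]
  if (nrow(mixed) > 0) {
    findings$mixed <- tibble::tibble(
      type = "inconsistent_area",
      participant_id = mixed$participant_id, region = mixed$region,
      detail = sprintf("%d distinct image areas", mixed$n_areas)
    )
  }
  short <- by_set[by_set$n_img < n_ref, ]
  if (nrow(short) > 0) {
    findings$short <- tibble::tibble(
      type = "short_set",
      participant_id = short$participant_id, region = short$region,
      detail = sprintf("only %d of %d reference images", short$n_img, n_ref)
    )
  }
  if (length(findings) == 0) {
    return(tibble::tibble(type = character(), participant_id = character(),
                          region = character(), detail = character()))
  }
  dplyr::bind_rows(findings)
}

#' Read a per-image count table from CSV
#'
#' Expected header: `participant_id,region,image_id,count,area_mm2`. Region
#' tokens are matched case-insensitively and canonicalised to lower case.
#'
#' @param path Path to the CSV file.
#' @return A tibble count table.
#' @export
read_image_counts <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "region", "image_id", "count", "area_mm2")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("count CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  raw$participant_id <- as.character(raw$participant_id)
  raw$image_id <- as.character(raw$image_id)
  raw$region <- tolower(as.character(raw$region))
  raw$count <- as.integer(raw$count)
  raw$area_mm2 <- as.numeric(raw$area_mm2)
  tibble::as_tibble(raw[needed])
}

#' Write a per-image count table to CSV
#'
#' Writes the canonical columns only (generator-internal columns such as
#' `true_density` are dropped).
#'
#' @param counts A count table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_image_counts <- function(counts, path) {
  cols <- c("participant_id", "region", "image_id", "count", "area_mm2")
  utils::write.csv(as.data.frame(counts)[cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
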
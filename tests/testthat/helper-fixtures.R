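# shared fixture builders -- all data is generated in code, no files

# tiny count table with a constant density per participant-region
constant_counts <- function(n_participants = 2, n_images = 16,
                            count = 4, area = 0.16,
                            regions = c("central", "peripheral")) {
  grid <- expand.grid(
    image_id = sprintf("img%02d", seq_len(n_images)),
    participant_id = sprintf("P%02d", seq_len(n_participants)),
    region = regions,
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    participant_id = grid$participant_id,
    region = grid$region,
    image_id = grid$image_id,
    count = as.integer(count),
    area_mm2 = area
  )
}

# subjects x raters table under the two-way random-effects model:
# x_ij = subject_i + rater_j + error, population ICC = var_s / (var_s + var_e)
# (consistency form; rater_sd = 0 makes absolute agreement match too)
icc_table <- function(n, r, icc, rater_sd = 0, total_var = 1) {
  var_s <- icc * total_var
  var_e <- total_var - var_s
  subj <- stats::rnorm(n, 0, sqrt(var_s))
  rater <- stats::rnorm(r, 0, rater_sd)
  matrix(subj, n, r) + matrix(rater, n, r, byrow = TRUE) +
    matrix(stats::rnorm(n * r, 0, sqrt(var_e)), n, r)
}

# independent ANOVA route via stats::aov, used as the oracle for the
# hand-computed mean squares and ICC estimates
aov_mean_squares <- function(table) {
  x <- as.matrix(table)
  df <- data.frame(
    value = as.vector(x),
    subject = factor(rep(seq_len(nrow(x)), ncol(x))),
    rater = factor(rep(seq_len(ncol(x)), each = nrow(x)))
  )
  tab <- summary(stats::aov(value ~ subject + rater, data = df))[[1]]
  list(
    ms_subjects = tab["subject", "Mean Sq"],
    ms_raters = tab["rater", "Mean Sq"],
    ms_error = tab["Residuals", "Mean Sq"],
    ss_subjects = tab["subject", "Sum Sq"],
    ss_raters = tab["rater", "Sum Sq"],
    ss_error = tab["Residuals", "Sum Sq"]
  )
}

# population-SD helper mirroring the divisor-N convention
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
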
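make_selection <- function(observer, participant, region, images) {
  tibble::tibble(observer_id = observer, participant_id = participant,
                 region = region, image_id = images)
}

test_that("observer ratios divide selected-image means by the true mean", {
  counts <- constant_counts(n_participants = 2, regions = "central")
  sel <- dplyr::bind_rows(
    make_selection("rater1", "P01", "central", c("img01", "img02", "img03")),
    make_selection("rater1", "P02", "central", c("img04", "img08", "img16"))
  )
  r <- observer_ratios(sel, counts)
  expect_equal(r$ratio, c(1, 1))

  # a selection whose mean equals the true mean by construction
  counts2 <- constant_counts(n_participants = 1, regions = "central")
  counts2$count <- as.integer(c(2, 4, 6, rep(4, 13)))  # mean 4 overall; {2,4,6} mean 4
  sel2 <- make_selection("rater1", "P01", "central", c("img01", "img02", "img03"))
  expect_equal(observer_ratios(sel2, counts2)$ratio, 1)

  bad <- make_selection("rater1", "P01", "central", c("img01", "img02", "nope"))
  expect_error(observer_ratios(bad, counts), "unknown image")
})

test_that("biased selections push the observer mean ratio above 1", {
  withr::with_seed(61, {
    cfg <- generator_config(density_mean = c(central = 21.7),
                            density_sd = c(central = 17.7), seed = 1)
    above <- replicate(25, {
      counts <- generate_counts(cfg, seed = sample.int(2^31 - 1, 1))
      sel <- simulate_selections(counts, selection_model(1), n_observers = 1)
      mean(suppressWarnings(observer_ratios(sel, counts))$ratio) > 1
    })
    expect_gt(mean(above), 0.5)
  })
})

test_that("the t comparison is null-stable, directional and Bonferroni-adjusted", {
  withr::with_seed(62, {
    pool <- rnorm(5000, 1, 0.2)
    x <- pool[1:20]
    res <- compare_mean_to_random(x, pool, m = 3)
    expect_gt(res$p_value, 0.05)
    expect_equal(res$p_adjusted, min(1, res$p_value * 3))

    biased <- pool[1:20] + 1
    res2 <- compare_mean_to_random(biased, pool, m = 3)
    expect_lt(res2$p_adjusted, 0.001)
    # adjustment preserves ordering
    expect_lt(res2$p_value, res$p_value)
    expect_lt(res2$p_adjusted, res$p_adjusted)
  })
  # both samples constant: degenerate, signalled
  res <- compare_mean_to_random(rep(1, 5), rep(1, 100))
  expect_true(res$degenerate)
  expect_true(is.na(res$statistic))
  expect_error(compare_mean_to_random(1, rnorm(10)), "at least 2")
})

test_that("the F comparison matches var.test and flags zero variance", {
  withr::with_seed(63, {
    x <- rnorm(20, 1, 0.3)
    y <- rnorm(2000, 1, 0.3)
    res <- compare_variance_to_random(x, y, m = 3)
    ref <- stats::var.test(x, y)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(res$p_adjusted, min(1, res$p_value * 3))

    # identical samples: F exactly 1
    expect_equal(compare_variance_to_random(x, x)$statistic, 1)

    res0 <- compare_variance_to_random(rep(1, 5), y)
    expect_true(res0$degenerate)
  })
})

test_that("representative-image consistency reflects observer agreement", {
  # identical per-participant ratios across observers (non-constant across
  # participants): perfect consistency
  ratios <- tidyr::expand_grid(observer_id = c("r1", "r2", "r3"),
                               participant_id = sprintf("P%02d", 1:10))
  ratios$ratio <- rep(seq(0.5, 1.5, length.out = 10), times = 3)
  expect_equal(representative_consistency(ratios)$estimate, 1)

  # deterministic top-3 selectors: identical selections, ICC 1
  counts <- generate_counts(generator_config(n_participants = 6, seed = 64))
  dens <- add_density(counts[counts$region == "central", ])
  top3 <- dplyr::slice_max(dplyr::group_by(dens, participant_id), density,
                           n = 3, with_ties = FALSE)
  sel <- dplyr::bind_rows(lapply(c("r1", "r2", "r3"), function(o) {
    tibble::tibble(observer_id = o, participant_id = top3$participant_id,
                   region = "central", image_id = top3$image_id)
  }))
  rep <- comparison_report(counts, sel, "central")
  expect_equal(rep$icc$estimate, 1)

  # incomplete table errors
  expect_error(representative_consistency(ratios[-1, ]), "incomplete")
})

test_that("independent unbiased observers on noisy data agree poorly", {
  withr::with_seed(65, {
    cfg <- generator_config(density_mean = c(central = 21.7),
                            density_sd = c(central = 17.7), seed = 1)
    est <- replicate(20, {
      counts <- generate_counts(cfg, seed = sample.int(2^31 - 1, 1))
      sel <- simulate_selections(counts, selection_model(0))
      suppressWarnings(comparison_report(counts, sel, "central")$icc$estimate)
    })
    expect_lt(abs(mean(est)), 0.2)
  })
})

test_that("a full comparison report is coherent on unbiased selections", {
  withr::with_seed(66, {
    counts <- generate_counts(generator_config(seed = 67))
    sel <- simulate_selections(counts, selection_model(0))
    rep <- comparison_report(counts, sel, "peripheral")
    expect_equal(nrow(rep$tests), 3)
    expect_false(any(rep$tests$degenerate))
    expect_true(all(rep$tests$f_statistic > 0))
    expect_equal(rep$random_summary$n, 20 * 560)
    expect_true(all(rep$tests$t_p_adjusted >= rep$tests$t_p))
  })
})
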
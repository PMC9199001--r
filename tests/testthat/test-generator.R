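test_that("generator config validates its inputs", {
  expect_s3_class(generator_config(), "ic_config")
  expect_error(generator_config(n_images = 1), "at least 2")
  expect_error(generator_config(image_area = 0), "positive")
  expect_error(generator_config(density_mean = c(central = -1),
                                density_sd = c(central = 1)), "positive")
  expect_error(generator_config(density_sd = c(central = -1, peripheral = 1)),
               "non-negative|region names")
  expect_error(generator_config(dispersion = 0), "positive")
})

test_that("identical config and seed reproduce the dataset exactly", {
  cfg <- generator_config(seed = 33)
  a <- generate_counts(cfg)
  b <- generate_counts(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_counts(cfg, seed = 34)
  expect_false(identical(a$count, c2$count))
})

test_that("participant densities are gamma moment-matched to the regional summaries", {
  cfg <- generator_config(n_participants = 1e5, seed = 1)
  withr::with_seed(5, {
    d <- draw_participant_densities(cfg, "central")
    expect_true(all(d > 0))
    expect_lt(abs(mean(d) - 21.7) / 21.7, 0.01)
    expect_lt(abs(sd(d) - 17.7) / 17.7, 0.02)
    dp <- draw_participant_densities(cfg, "peripheral", n = 1000)
    expect_true(all(dp > 0))
  })
  # degenerate sd: every participant at the mean
  cfg0 <- generator_config(density_sd = c(central = 0, peripheral = 0))
  expect_identical(draw_participant_densities(cfg0, "central"), rep(21.7, 20))
})

test_that("image counts are Poisson at infinite dispersion (index of dispersion ~ 1)", {
  cfg <- generator_config(n_participants = 1, n_images = 1e5,
                          density_mean = c(central = 25),
                          density_sd = c(central = 0), seed = 2)
  counts <- generate_counts(cfg)
  expect_true(all(counts$count >= 0))
  expect_lt(abs(mean(counts$count) - 4) / 4, 0.02)
  iod <- var(counts$count) / mean(counts$count)
  expect_gt(iod, 0.97)
  expect_lt(iod, 1.03)
})

test_that("finite dispersion gives the negative-binomial variance", {
  s <- 2
  cfg <- generator_config(n_participants = 1, n_images = 1e5,
                          density_mean = c(central = 25),
                          density_sd = c(central = 0),
                          dispersion = s, seed = 3)
  counts <- generate_counts(cfg)
  lambda <- 4
  expect_lt(abs(var(counts$count) - (lambda + lambda^2 / s)) / (lambda + lambda^2 / s), 0.05)
})

test_that("dispersion limit: huge NB size is indistinguishable from Poisson", {
  cfg <- generator_config(n_participants = 1, n_images = 1e5,
                          density_mean = c(central = 25),
                          density_sd = c(central = 0),
                          dispersion = 1e6, seed = 4)
  counts <- generate_counts(cfg)
  iod <- var(counts$count) / mean(counts$count)
  expect_lt(abs(iod - 1), 0.01)
})

test_that("a perfect observer reproduces the reference counts", {
  withr::with_seed(6, {
    x <- rpois(200, 5)
    expect_identical(simulate_observer_counts(x, observer_model(1, 0)), as.integer(x))
  })
})

test_that("binomial thinning has the expected mean recount", {
  withr::with_seed(7, {
    rec <- simulate_observer_counts(rep(10L, 1e5), observer_model(0.9, 0))
    expect_lt(abs(mean(rec) - 9), 0.05)
  })
})

test_that("imperfect recounts on a synthetic panel still agree strongly (ICC > 0.8)", {
  counts <- generate_counts(generator_config(seed = 8))
  tab <- simulate_recount_table(counts, observer_model(0.95, 0.2),
                                n_images = 100, n_observers = 3, seed = 9)
  expect_equal(dim(tab), c(100, 3))
  expect_gt(icc_single_absolute(tab)$estimate, 0.8)
})

test_that("unbiased selection is uniform over images", {
  withr::with_seed(10, {
    d <- rgamma(16, 2, 0.1)
    freq <- tabulate(replicate(1e5, simulate_image_selection(d, selection_model(0))),
                     nbins = 16) / 1e5
    expect_true(all(abs(freq - 3 / 16) < 0.01))
  })
})

test_that("extreme bias selects the densest images almost surely", {
  withr::with_seed(11, {
    d <- sample(seq(1, 80, 5))
    top3 <- order(d, decreasing = TRUE)[1:3]
    sel <- replicate(200, sort(simulate_image_selection(d, selection_model(50))))
    expect_true(all(apply(sel, 2, function(s) setequal(s, top3))))
  })
})

test_that("constant within-participant densities make selection uniform at any beta", {
  withr::with_seed(12, {
    freq <- tabulate(replicate(2e4, simulate_image_selection(rep(5, 16), selection_model(50))),
                     nbins = 16) / 2e4
    expect_true(all(abs(freq - 3 / 16) < 0.02))
  })
})

test_that("mean selected density is non-decreasing in the bias strength", {
  withr::with_seed(13, {
    d <- rgamma(16, 2, 0.1)
    mean_sel <- vapply(c(0, 0.5, 1, 2), function(b) {
      mean(replicate(1e4, mean(d[simulate_image_selection(d, selection_model(b))])))
    }, numeric(1))
    expect_true(all(diff(mean_sel) > 0))
  })
})

test_that("selection rejects asking for more images than exist", {
  expect_error(simulate_image_selection(1:3, selection_model(0, n_selected = 4)),
               "more images")
})

test_that("simulated selections cover every observer-participant-region with 3 distinct images", {
  counts <- generate_counts(generator_config(n_participants = 3, seed = 14))
  sel <- simulate_selections(counts, selection_model(0.5), n_observers = 3, seed = 15)
  expect_equal(nrow(sel), 3 * 3 * 2 * 3)
  per <- dplyr::count(sel, observer_id, participant_id, region)
  expect_true(all(per$n == 3))
  dup <- dplyr::count(sel, observer_id, participant_id, region, image_id)
  expect_true(all(dup$n == 1))
})
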
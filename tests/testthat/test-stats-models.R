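test_that("with zero random-effect variance the LMM slope matches OLS", {
  set.seed(17)
  tab <- expand.grid(colony_id = "c1", penguin_id = paste0("p", 1:6),
                     song_id = paste0("s", 1:5), obs = 1:8,
                     stringsAsFactors = FALSE)
  tab$x <- runif(nrow(tab))
  tab$y <- 2 - 0.7 * tab$x + rnorm(nrow(tab), 0, 0.3)
  fit <- suppressWarnings(
    fit_lmm_lrt(tab, "y", "x", c("colony_id", "penguin_id", "song_id")))
  ols <- unname(coef(lm(y ~ x, data = tab))[2])
  expect_lt(abs(fit$estimate - ols), 1e-2)
  expect_lt(abs(fit$estimate - (-0.7)), 3 * fit$se)
  expect_gte(fit$chi_square, 0)
  expect_equal(fit$df, 1L)
})

test_that("LR statistics are nonnegative even for null responses", {
  set.seed(30)
  for (i in 1:5) {
    tab <- expand.grid(colony_id = c("c1", "c2"),
                       penguin_id = paste0("p", 1:4),
                       song_id = paste0("s", 1:4), obs = 1:3,
                       stringsAsFactors = FALSE)
    tab$x <- runif(nrow(tab))
    tab$y <- rnorm(nrow(tab))
    fit <- suppressWarnings(
      fit_lmm_lrt(tab, "y", "x", c("colony_id", "penguin_id", "song_id")))
    expect_gte(fit$chi_square, 0)
    expect_true(fit$p_value >= 0 && fit$p_value <= 1)
  }
})

test_that("grouping factors below 2 levels are dropped with a message", {
  set.seed(5)
  tab <- expand.grid(colony_id = "only", penguin_id = paste0("p", 1:8),
                     song_id = paste0("s", 1:6), obs = 1:3,
                     stringsAsFactors = FALSE)
  tab$x <- runif(nrow(tab))
  tab$y <- 1 + tab$x + rnorm(nrow(tab), 0, 0.2)
  expect_message(
    fit <- suppressWarnings(
      fit_lmm_lrt(tab, "y", "x", c("colony_id", "penguin_id", "song_id"))),
    "fewer than 2 levels")
  expect_false(grepl("colony_id\\)", fit$random_structure))
})

test_that("accelerando slope converts exactly to the end-of-song IOI ratio", {
  d <- generate_dataset(small_config(seed = 31))
  fit <- suppressWarnings(model_accelerando(dataset_intervals(d)))
  # exp(slope) is the model-predicted IOI at position 1 over position 0
  expect_equal(fit$percent_change, 100 * (exp(fit$estimate) - 1))
  expect_lt(fit$estimate, 0)
  expect_lt(fit$p_value, 0.001)
})

test_that("constant per-step decay gives a flat acceleration-ratio trend", {
  # geometric IOIs have identical ratios, so the constancy model is null
  cfg <- small_config(seed = 41, jitter_sd_start = 0.02,
                      jitter_sd_end = 0.02, ioi1_coupling = 0)
  fit <- suppressWarnings(model_acceleration_constancy(generate_dataset(cfg)))
  expect_lt(abs(fit$estimate), 2 * fit$se)
})

test_that("an isochronous generator behaves as a null for the accelerando", {
  cfg <- small_config(seed = 42, ioi_decay = 0, ioi1_coupling = 0,
                      jitter_sd_start = 0.05, jitter_sd_end = 0.05)
  fit <- suppressWarnings(
    model_accelerando(dataset_intervals(generate_dataset(cfg))))
  expect_lt(abs(fit$estimate), 3 * fit$se)
})

test_that("per-penguin regressions mirror the pooled OLS for one penguin", {
  cfg <- synthetic_song_config(n_colonies = 1, n_penguins = 1,
                               songs_per_penguin = 8, seed = 12)
  d <- generate_dataset(cfg)
  pp <- per_penguin_regressions(d, "accelerando")
  expect_equal(nrow(pp), 1L)
  iv <- dataset_intervals(d)
  pooled <- unname(coef(lm(log(ioi) ~ relative_position, data = iv))[2])
  expect_equal(pp$slope, pooled, tolerance = 1e-10)
})

test_that("per-penguin accelerando slopes are negative for all penguins", {
  d <- generate_dataset(synthetic_song_config(seed = 19,
                                              songs_per_penguin = 10))
  pp <- per_penguin_regressions(d, "accelerando")
  expect_equal(nrow(pp), 26L)
  expect_true(all(pp$slope < 0))
  expect_equal(attr(pp, "n_significant"), 26L)
})

test_that("per-penguin crescendo regressions show nominal false positives on flat data", {
  # flat intensities: about alpha of penguins significant by chance
  cfg <- synthetic_song_config(seed = 77, crescendo_rise = 0,
                               n_penguins = 40, songs_per_penguin = 8,
                               syllable_count_range = c(6, 10))
  pp <- per_penguin_regressions(generate_dataset(cfg), "crescendo")
  frac <- attr(pp, "n_significant") / nrow(pp)
  expect_lt(frac, 0.2)
})

test_that("crescendo model downgrades gracefully and keeps the B point at zero", {
  d <- generate_dataset(small_config(seed = 55))
  fit <- suppressWarnings(suppressMessages(model_crescendo(d)))
  expect_gt(fit$estimate, 0)
  expect_lt(fit$p_value, 0.001)
  # excluding the B syllable still detects the crescendo
  fit_a <- suppressWarnings(suppressMessages(model_crescendo(d,
                                                             include_b = FALSE)))
  expect_gt(fit_a$estimate, 0)
})

test_that("the binned-CV trend model sees shrinking jitter", {
  d <- generate_dataset(synthetic_song_config(seed = 61, n_penguins = 12,
                                              songs_per_penguin = 10))
  fit <- suppressWarnings(model_cv_trend(bin_iois(dataset_intervals(d))))
  expect_lt(fit$estimate, 0)
  expect_lt(fit$p_value, 0.05)
  # constant jitter: null behavior
  d0 <- generate_dataset(synthetic_song_config(seed = 62, n_penguins = 12,
                                               songs_per_penguin = 10,
                                               jitter_sd_start = 0.05,
                                               jitter_sd_end = 0.05,
                                               ioi1_coupling = 0))
  fit0 <- suppressWarnings(model_cv_trend(bin_iois(dataset_intervals(d0))))
  expect_gt(fit0$p_value, 0.001)
})

test_that("tempo plasticity needs the coupling to be detected", {
  cfg0 <- small_config(seed = 71, ioi1_coupling = 0, songs_per_penguin = 10)
  fit0 <- suppressWarnings(model_ioi1_plasticity(generate_dataset(cfg0)))
  expect_lt(abs(fit0$estimate), 3 * fit0$se)
})
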
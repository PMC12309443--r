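test_that("interval computation decomposes IOIs into syllable and silence", {
  iv <- compute_intervals(aab_song())
  expect_equal(iv$ioi, c(0.50, 0.40))
  expect_equal(iv$syllable_duration, c(0.10, 0.12))
  expect_equal(iv$silence, c(0.40, 0.28))
  expect_equal(iv$relative_position, c(0, 1))

  # a C syllable is invisible when include_c = FALSE ...
  iv_c <- compute_intervals(aacb_song(), include_c = FALSE)
  expect_equal(iv_c$ioi, iv$ioi)
  # ... and contributes its onset when include_c = TRUE
  iv_all <- compute_intervals(aacb_song(), include_c = TRUE)
  expect_equal(iv_all$ioi, c(0.20, 0.30, 0.40))

  # conservation holds for every record
  expect_equal(iv_all$ioi, iv_all$syllable_duration + iv_all$silence)
})

test_that("too-short and overlapping songs are interval errors", {
  short <- make_song(c(0, 0.5), c(0.1, 0.8), c("A", "B"))
  expect_error(compute_intervals(short), "too short")
  # C-only padding does not rescue an egressive-stream computation
  padded <- make_song(c(0, 0.2, 0.5), c(0.1, 0.3, 0.8), c("A", "C", "B"))
  expect_error(compute_intervals(padded, include_c = FALSE), "too short")
  expect_equal(nrow(compute_intervals(padded, include_c = TRUE)), 2L)
})

test_that("acceleration ratios follow their closed forms", {
  # isochrony is the 0.5 fixed point
  expect_equal(acceleration_ratios(c(1, 1, 1)), c(0.5, 0.5))
  # geometric decay r: every ratio is 1/(1+r)
  expect_equal(acceleration_ratios(c(1.0, 0.8, 0.64)),
               rep(1 / 1.8, 2), tolerance = 1e-12)
  expect_equal(round(acceleration_ratios(c(1.0, 0.8, 0.64)), 4),
               c(0.5556, 0.5556))
  # a lengthening pair decelerates: ratio below 0.5
  expect_equal(acceleration_ratios(c(0.5, 1.0)), 1 / 3, tolerance = 1e-12)
  expect_error(acceleration_ratios(c(1, 0)), "positive")
  expect_error(acceleration_ratios(0.5), "at least 2")
})

test_that("ratios are invariant to uniform time rescaling", {
  set.seed(21)
  for (i in 1:10) {
    iois <- runif(8, 0.2, 0.8)
    k <- runif(1, 0.1, 10)
    expect_equal(acceleration_ratios(iois * k), acceleration_ratios(iois))
  }
})

test_that("the song-level average excludes the first acceleration ratio", {
  expect_equal(average_acceleration(c(0.5263, 0.5294, 0.5333)),
               mean(c(0.5294, 0.5333)))
  expect_equal(round(average_acceleration(c(0.5263, 0.5294, 0.5333)), 4),
               0.5314)
  expect_equal(average_acceleration(c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(average_acceleration(c(0.9, 0.6, 0.6)), 0.6)
  # one ratio (a 4-syllable song) has no defined average
  expect_error(average_acceleration(0.55), "undefined")
})

test_that("relative positions scale 0..1 with the right denominators", {
  expect_equal(relative_positions(5), c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(relative_positions(2), c(0, 1))
  expect_error(relative_positions(1), "at least 2")
  # a 6-syllable song: 6 syllable positions, 5 IOI positions, 4 ratio ones
  song <- make_song(seq(0, 2.5, by = 0.5), seq(0.2, 2.7, by = 0.5),
                    c(rep("A", 5), "B"))
  iv <- compute_intervals(song)
  expect_equal(nrow(iv), 5L)
  expect_length(acceleration_ratios(iv$ioi), 4L)
})

test_that("corrected CV applies the small-sample factor and is scale-free", {
  expect_equal(corrected_cv(c(1, 1, 1, 1)), 0)
  expect_equal(corrected_cv(c(1, 2)), (1 + 1 / 8) * sd(c(1, 2)) / 1.5)
  expect_equal(round(corrected_cv(c(1, 2)), 4), 0.5303)
  set.seed(3)
  x <- rlnorm(30)
  expect_equal(corrected_cv(10 * x), corrected_cv(x))
  expect_error(corrected_cv(1), "at least 2")
  expect_error(corrected_cv(c(-2, 1)), "positive mean")
})

test_that("IOI binning partitions [0,1] with a closed final bin", {
  iv <- data.frame(colony_id = "c1", penguin_id = "p1", song_id = "s",
                   ioi = rep(0.4, 6), syllable_duration = 0.1, silence = 0.3,
                   relative_position = c(0, 0.2, 0.4, 0.6, 0.8, 1.0))
  b <- bin_iois(iv)
  expect_equal(nrow(b), 5L)
  # exact edges fall in the upper bin; 1.0 falls in bin 5
  expect_equal(b$n, c(1, 1, 1, 1, 2))
  expect_true(is.na(b$cv[1]))      # singleton bins have undefined CV
  expect_equal(b$cv[5], 0)         # equal IOIs: zero variability
  expect_error(bin_iois(iv[0, ]), "no interval records")
})

test_that("interval records conserve ioi = syllable + silence on synthetic data", {
  d <- generate_dataset(small_config(seed = 9))
  iv <- dataset_intervals(d)
  expect_true(all(abs(iv$ioi - iv$syllable_duration - iv$silence) < 1e-9))
  expect_true(all(iv$silence > 0))
  # per-song position bookkeeping: first 0, last 1
  per_song <- split(iv, iv$song_id)
  expect_true(all(vapply(per_song, function(s)
    s$relative_position[1] == 0 && s$relative_position[nrow(s)] == 1,
    logical(1))))
})
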
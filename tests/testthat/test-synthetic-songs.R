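test_that("generation is byte-identical given a seed", {
  cfg <- small_config(seed = 1)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_csv_table(generate_dataset(cfg), f1)
  write_csv_table(generate_dataset(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed changes the data
  f3 <- tempfile(fileext = ".csv")
  write_csv_table(generate_dataset(small_config(seed = 2)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("generated songs honor the configured population structure", {
  cfg <- synthetic_song_config(seed = 8, songs_per_penguin = 6)
  s <- summarize_dataset(generate_dataset(cfg))
  expect_equal(s$n_colonies, 3L)
  expect_equal(s$n_penguins, 26L)
  expect_equal(unname(s$songs_per_penguin["min"]), 6)
  expect_equal(s$n_songs, 26L * 6L)
})

test_that("the noise-free limit reproduces the geometric closed form", {
  cfg <- synthetic_song_config(seed = 13, n_penguins = 2,
                               songs_per_penguin = 3,
                               jitter_sd_start = 0, jitter_sd_end = 0,
                               syllable_jitter_sd = 0,
                               ioi1_coupling = 0, re_sd_colony = 0,
                               re_sd_penguin = 0, re_sd_song = 0)
  d <- generate_dataset(cfg)
  for (song in split_songs(d)) {
    iv <- compute_intervals(song)
    m <- nrow(iv)
    r_step <- exp(log(0.75) / (m - 1))   # per-step decay over m IOIs
    ratios <- acceleration_ratios(iv$ioi)
    expect_equal(ratios, rep(1 / (1 + r_step), m - 1), tolerance = 1e-9)
    expect_gt(average_acceleration(ratios), 0.5)
  }
})

test_that("rhythmic-mode C syllables occupy beat slots", {
  cfg <- small_config(seed = 22, c_mode = "rhythmic", c_penguin_fraction = 1,
                      c_probability = 0.3)
  d <- generate_dataset(cfg)
  expect_gt(sum(d$label == "C"), 0)
  # the all-syllable onset chain equals the same-seed C-free chain
  d0 <- generate_dataset(small_config(seed = 22, c_mode = "none"))
  expect_equal(d$onset_s, d0$onset_s)
  # but the egressive stream has merged IOIs where Cs sit
  expect_lt(length(d$onset_s[d$label != "C"]), length(d0$onset_s))
})

test_that("impossible silence configurations are rejected up front", {
  expect_error(synthetic_song_config(initial_syllable_fraction = 0.7,
                                     syllable_growth = log(1.5)),
               "impossible")
  expect_error(synthetic_song_config(jitter_sd_start = -0.1), "nonnegative")
})

test_that("implied end-of-song silence decrease sits in the published band", {
  sl <- implied_slopes(synthetic_song_config())
  expect_gt(sl$silence_percent_change, -45)
  expect_lt(sl$silence_percent_change, -44)
})

test_that("rendered audio realizes the intensity targets", {
  cfg <- synthetic_song_config(seed = 5, n_colonies = 1, n_penguins = 1,
                               songs_per_penguin = 2)
  d <- generate_dataset(cfg)
  song <- split_songs(d)[[1]]
  au <- synthesize_song_audio(song)
  got <- vapply(seq_len(nrow(song)), function(i)
    extract_intensity(au$samples, au$rate, song$onset_s[i],
                      song$offset_s[i]), numeric(1))
  norm_target <- song$intensity_db - song$intensity_db[song$label == "B"]
  norm_got <- got - got[song$label == "B"]
  expect_gt(cor(norm_got, norm_target), 0.95)
  # equal targets yield equal rendered intensities
  flat <- song
  flat$intensity_db <- 60
  au_flat <- synthesize_song_audio(flat)
  flat_got <- vapply(seq_len(nrow(flat)), function(i)
    extract_intensity(au_flat$samples, au_flat$rate, flat$onset_s[i],
                      flat$offset_s[i]), numeric(1))
  expect_lt(diff(range(flat_got)), 1)
})

test_that("WAV files round-trip synthesized audio", {
  cfg <- synthetic_song_config(seed = 2, n_colonies = 1, n_penguins = 1,
                               songs_per_penguin = 1,
                               syllable_count_range = c(6, 6))
  au <- synthesize_song_audio(split_songs(generate_dataset(cfg))[[1]])
  path <- tempfile(fileext = ".wav")
  write_wav(au$samples, au$rate, path)
  back <- read_wav(path)
  expect_equal(back$rate, au$rate)
  expect_lt(max(abs(back$samples - au$samples)), 1e-4)
})
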
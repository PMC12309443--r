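test_that("TextGrid reading truncates at the first B and keeps C syllables", {
  # truncation: everything after the first B is dropped
  tg <- textgrid_long(c(0.0, 0.5, 0.9, 2.5), c(0.1, 0.62, 2.0, 2.6),
                      c("A", "A", "B", "A"))
  song <- read_textgrid(tg)
  expect_equal(song$label, c("A", "A", "B"))
  expect_equal(song$onset_s, c(0.0, 0.5, 0.9))

  # C syllables are retained for the downstream inclusion choice
  tg2 <- textgrid_long(c(0.0, 0.2, 0.5, 0.9), c(0.1, 0.3, 0.62, 2.0),
                       c("A", "C", "A", "B"))
  expect_equal(read_textgrid(tg2)$label, c("A", "C", "A", "B"))

  # a song with no B cannot be analysed
  tg3 <- textgrid_long(c(0.0, 0.5), c(0.1, 0.62), c("A", "A"))
  expect_error(read_textgrid(tg3), class = "truncation_error")

  # labels outside A/B/C are annotation errors, reported with their time
  tg4 <- textgrid_long(c(0.0, 0.5), c(0.1, 0.62), c("A", "X"))
  expect_error(read_textgrid(tg4), "X")
})

test_that("long and short TextGrid forms parse identically", {
  xmin <- c(0.0, 0.5, 0.9)
  xmax <- c(0.1, 0.62, 2.0)
  lab <- c("A", "A", "B")
  long <- read_textgrid(textgrid_long(xmin, xmax, lab))
  short <- read_textgrid(textgrid_short(xmin, xmax, lab))
  expect_equal(long$onset_s, short$onset_s)
  expect_equal(long$offset_s, short$offset_s)
  expect_equal(long$label, short$label)
})

test_that("empty intervals are ignored and named tiers are selectable", {
  tg <- textgrid_long(c(0.0, 0.1, 0.5, 0.9), c(0.1, 0.5, 0.62, 2.0),
                      c("A", "", "A", "B"), tier = "syll")
  song <- read_textgrid(tg, tier_name = "syll")
  expect_equal(song$label, c("A", "A", "B"))
  expect_error(read_textgrid(tg, tier_name = "nope"), "no interval tier named")
})

test_that("TextGrid writer round-trips through the reader", {
  song <- aacb_song()
  path <- tempfile(fileext = ".TextGrid")
  write_textgrid(song, path)
  back <- read_textgrid(path, colony_id = "c1", penguin_id = "p1",
                        song_id = "s1")
  expect_equal(back$label, song$label)
  expect_equal(back$onset_s, song$onset_s, tolerance = 1e-7)
  expect_equal(back$offset_s, song$offset_s, tolerance = 1e-7)
})

test_that("a song expressed as TextGrid or CSV yields identical fields", {
  song <- aab_song()
  csv <- tempfile(fileext = ".csv")
  write_csv_table(as_song_dataset(song), csv)
  from_csv <- split_songs(read_csv_table(csv))[[1]]
  tg <- textgrid_long(song$onset_s, song$offset_s, song$label)
  from_tg <- read_textgrid(tg, colony_id = "c1", penguin_id = "p1",
                           song_id = "s1")
  expect_equal(from_csv$onset_s, from_tg$onset_s)
  expect_equal(from_csv$offset_s, from_tg$offset_s)
  expect_equal(from_csv$label, from_tg$label)
})

test_that("CSV round-trip reproduces generator output field-identically", {
  d <- generate_dataset(small_config(seed = 4))
  path <- tempfile(fileext = ".csv")
  write_csv_table(d, path)
  back <- read_csv_table(path)
  expect_equal(as.data.frame(back), as.data.frame(d),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("CSV reader enforces its contract", {
  # missing column
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(colony_id = "c", penguin_id = "p",
                              label = "A"), path, row.names = FALSE)
  expect_error(read_csv_table(path), "missing column")

  # the (colony, penguin, song) triple identifies songs: a shared song_id
  # under different penguins is two songs
  two <- rbind(aab_song(penguin = "p1", song = "shared"),
               aab_song(penguin = "p2", song = "shared"))
  utils::write.csv(two[setdiff(names(two), "intensity_db")], path,
                   row.names = FALSE)
  expect_length(split_songs(read_csv_table(path)), 2L)

  # header-only file: empty dataset with a warning
  utils::write.csv(aab_song()[0L, ], path, row.names = FALSE)
  expect_warning(empty <- read_csv_table(path), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("datasets without intensity omit the column on write", {
  d <- as_song_dataset(aab_song())
  path <- tempfile(fileext = ".csv")
  write_csv_table(d, path)
  expect_false("intensity_db" %in% names(utils::read.csv(path)))
})

test_that("truncation is idempotent and songs lacking B can be skipped", {
  song <- aab_song()
  expect_identical(truncate_at_first_b(truncate_at_first_b(song)),
                   truncate_at_first_b(song))
  no_b <- make_song(c(0, 0.5), c(0.1, 0.6), c("A", "A"), song = "bad")
  both <- rbind(aab_song(), no_b)
  expect_warning(d <- as_song_dataset(both, on_no_b = "skip"), "skipped")
  expect_length(split_songs(d), 1L)
  expect_error(as_song_dataset(both, on_no_b = "error"),
               class = "truncation_error")
})

test_that("overlapping or disordered annotations are rejected", {
  overlap <- make_song(c(0, 0.05), c(0.1, 0.6), c("A", "B"))
  expect_error(as_song_dataset(overlap), "overlapping")
  backwards <- make_song(c(0.5, 0.0), c(0.6, 0.1), c("A", "B"))
  expect_error(as_song_dataset(backwards), "increasing")
})

test_that("intensity normalization subtracts the first B syllable", {
  song <- aab_song(intensity = c(58, 61, 65))
  out <- normalize_intensity(song)
  expect_equal(out$norm_intensity_db, c(-7, -4, 0))
  expect_equal(out$relative_position, c(0, 0.5, 1))

  # all-equal intensities map to zeros; order is preserved by the shift
  flat <- aab_song(intensity = c(60, 60, 60))
  expect_equal(normalize_intensity(flat)$norm_intensity_db, c(0, 0, 0))

  # C syllables carry no crescendo information and are dropped
  with_c <- aacb_song(intensity = c(58, NA, 61, 65))
  expect_equal(normalize_intensity(with_c)$norm_intensity_db, c(-7, -4, 0))

  # a missing egressive intensity is an error
  song$intensity_db[2] <- NA
  expect_error(normalize_intensity(song), "intensity")
})
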
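# Small in-code fixtures shared across test files.

make_song <- function(onsets, offsets, labels,
                      colony = "c1", penguin = "p1", song = "s1",
                      intensity = NA_real_) {
  data.frame(colony_id = colony, penguin_id = penguin, song_id = song,
             label = labels, onset_s = onsets, offset_s = offsets,
             intensity_db = intensity, stringsAsFactors = FALSE)
}

# The worked three-syllable song used in several interval tests:
# A:(0.00,0.10) A:(0.50,0.62) B:(0.90,2.00)
aab_song <- function(...) {
  make_song(c(0.00, 0.50, 0.90), c(0.10, 0.62, 2.00), c("A", "A", "B"), ...)
}

# Same song with a C syllable inside the first silence.
aacb_song <- function(...) {
  make_song(c(0.00, 0.20, 0.50, 0.90), c(0.10, 0.30, 0.62, 2.00),
            c("A", "C", "A", "B"), ...)
}

# A long-form TextGrid with the given labelled intervals on one tier.
textgrid_long <- function(xmin, xmax, labels, tier = "syllables",
                          total = max(xmax) + 0.5) {
  n <- length(labels)
  lines <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
             "xmin = 0", paste0("xmax = ", total), "tiers? <exists>",
             "size = 1", "item []:", "    item [1]:",
             '        class = "IntervalTier"',
             paste0('        name = "', tier, '"'),
             "        xmin = 0", paste0("        xmax = ", total),
             paste0("        intervals: size = ", n))
  for (i in seq_len(n)) {
    lines <- c(lines,
               paste0("        intervals [", i, "]:"),
               paste0("            xmin = ", xmin[i]),
               paste0("            xmax = ", xmax[i]),
               paste0('            text = "', labels[i], '"'))
  }
  path <- tempfile(fileext = ".TextGrid")
  writeLines(lines, path)
  path
}

# Same content in the short form.
textgrid_short <- function(xmin, xmax, labels, tier = "syllables",
                           total = max(xmax) + 0.5) {
  lines <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
             "0", as.character(total), "<exists>", "1",
             '"IntervalTier"', paste0('"', tier, '"'),
             "0", as.character(total), as.character(length(labels)))
  for (i in seq_along(labels)) {
    lines <- c(lines, as.character(xmin[i]), as.character(xmax[i]),
               paste0('"', labels[i], '"'))
  }
  path <- tempfile(fileext = ".TextGrid")
  writeLines(lines, path)
  path
}

small_config <- function(n_penguins = 6L, songs_per_penguin = 6L,
                         syllable_count_range = c(6L, 10L), ...) {
  synthetic_song_config(n_penguins = n_penguins,
                        songs_per_penguin = songs_per_penguin,
                        syllable_count_range = syllable_count_range, ...)
}
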
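#' Relative positions within a song
#'
#' Positions an ordered sequence of `count` elements on `[0, 1]`:
#' `(i - 1) / (count - 1)`, so the first element sits at 0 and the last at 1.
#' The same rule serves syllables, IOIs and acceleration ratios; for a song
#' with n retained syllables the denominators are n-1, n-2 and n-3
#' respectively, because n syllables give n-1 IOIs and n-2 ratios.
#'
#' @param count number of elements, at least 2.
#' @return numeric vector of length `count` from 0 to 1.
#' @export
relative_positions <- function(count) {
  if (count < 2L) stop("relative positions need at least 2 elements",
                       call. = FALSE)
  (seq_len(count) - 1) / (count - 1)
}

#' Inter-onset intervals of a song
#'
#' Computes the onset-to-onset intervals (IOIs) between consecutive retained
#' syllables of a truncated song, together with each IOI's components: the
#' earlier syllable's duration and the silent interval
#' (`silence = ioi - syllable_duration`). The terminal B syllable contributes
#' only its onset — it ends the last IOI and its duration never enters the
#' series. With `include_c = FALSE` (the default, following the C-syllable
#' analysis) ingressive C syllables are dropped before computing IOIs; with
#' `include_c = TRUE` every syllable's onset counts.
#'
#' @param song per-song data frame, truncated at the first B.
#' @param include_c logical: count C-syllable onsets as beats?
#' @return data frame with one row per IOI: `colony_id`, `penguin_id`,
#'   `song_id`, `index`, `ioi`, `syllable_duration`, `silence`,
#'   `relative_position`.
#' @export
compute_intervals <- function(song, include_c = FALSE) {
  keep <- if (include_c) rep(TRUE, nrow(song)) else song$label != "C"
  syl <- song[keep, , drop = FALSE]
  n <- nrow(syl)
  if (n < 3L) {
    stop("song ", song_label(song), " too short: needs at least 3 retained ",
         "syllables, has ", n, call. = FALSE)
  }
  ioi <- diff(syl$onset_s)
  dur <- (syl$offset_s - syl$onset_s)[-n]
  silence <- ioi - dur
  if (any(silence < -1e-9)) {
    stop("song ", song_label(song), ": overlapping annotations give a ",
         "negative silence", call. = FALSE)
  }
  silence[silence < 0] <- 0
  data.frame(colony_id = syl$colony_id[1L], penguin_id = syl$penguin_id[1L],
             song_id = syl$song_id[1L], index = seq_len(n - 1L),
             ioi = ioi, syllable_duration = dur, silence = silence,
             relative_position = relative_positions(n - 1L),
             stringsAsFactors = FALSE)
}

#' Acceleration ratios between successive IOIs
#'
#' `a_i = IOI_i / (IOI_i + IOI_{i+1})`: 0.5 for an isochronous pair, above
#' 0.5 when the next interval is shorter (accelerating), below 0.5 when it is
#' longer (decelerating). A sequence of m IOIs yields m - 1 ratios.
#'
#' @param iois positive numeric vector of at least 2 IOIs (seconds).
#' @return numeric vector of ratios in (0, 1).
#' @export
acceleration_ratios <- function(iois) {
  if (length(iois) < 2L) stop("need at least 2 IOIs", call. = FALSE)
  if (any(!is.finite(iois)) || any(iois <= 0)) {
    stop("IOIs must be positive and finite", call. = FALSE)
  }
  m <- length(iois)
  iois[-m] / (iois[-m] + iois[-1L])
}

#' Average acceleration ratio of a song, excluding the first IOI
#'
#' The song-level acceleration summary is the mean of the ratios
#' `a_2, ..., a_{n-2}`; `a_1` — the only ratio involving the first IOI — is
#' excluded so that the summary can be regressed on the first IOI without
#' sharing data with it. Defined only for songs with at least 5 retained
#' syllables (at least 2 ratios).
#'
#' @param ratios ordered acceleration ratios of one song.
#' @return the mean of `ratios[-1]`.
#' @export
average_acceleration <- function(ratios) {
  if (length(ratios) < 2L) {
    stop("average acceleration undefined: needs at least 2 ratios ",
         "(a song of at least 5 retained syllables)", call. = FALSE)
  }
  mean(ratios[-1L])
}

#' Coefficient of variation, corrected for small samples
#'
#' `(1 + 1/(4n)) * sd(x) / mean(x)` with the usual n-1 sample SD.
#'
#' @param values positive-mean numeric sample, n >= 2.
#' @return corrected CV (dimensionless).
#' @export
corrected_cv <- function(values) {
  n <- length(values)
  if (n < 2L) stop("CV needs at least 2 values", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("CV needs a positive mean", call. = FALSE)
  (1 + 1 / (4 * n)) * stats::sd(values) / m
}

#' Interval table for a whole dataset
#'
#' Applies [compute_intervals()] to every song; songs with fewer than 3
#' retained syllables are skipped with a message.
#'
#' @param dataset a `song_dataset`.
#' @inheritParams compute_intervals
#' @return row-bound interval table.
#' @export
dataset_intervals <- function(dataset, include_c = FALSE) {
  songs <- split_songs(dataset)
  skipped <- 0L
  out <- lapply(songs, function(s) {
    tryCatch(compute_intervals(s, include_c = include_c),
             error = function(e) { skipped <<- skipped + 1L; NULL })
  })
  if (skipped > 0L) {
    message(skipped, " song(s) skipped as too short for interval analysis")
  }
  do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                   list(make.row.names = FALSE)))
}

#' Binned IOI variability per penguin
#'
#' Pools each penguin's IOI durations across songs, bins them by relative
#' position into five equal bins (`[0,0.2) [0.2,0.4) [0.4,0.6) [0.6,0.8)
#' [0.8,1]`; the last bin is closed so the final IOI is always binned), and
#' returns per-bin mean, SD and corrected CV. Bins with fewer than 2 IOIs get
#' `NA` statistics.
#'
#' @param intervals an interval table from [dataset_intervals()] (may span
#'   many penguins).
#' @return data frame with one row per penguin per bin: `colony_id`,
#'   `penguin_id`, `bin` (1-5), `bin_position` (midpoint), `mean_ioi`,
#'   `sd_ioi`, `cv`, `n`.
#' @export
bin_iois <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    stop("no interval records to bin", call. = FALSE)
  }
  edges <- c(0.2, 0.4, 0.6, 0.8)
  intervals$bin <- pmin(findInterval(intervals$relative_position, edges) + 1L,
                        5L)
  groups <- split(intervals,
                  interaction(intervals$colony_id, intervals$penguin_id,
                              drop = TRUE, sep = "\r"))
  rows <- lapply(groups, function(g) {
    per_bin <- lapply(1:5, function(b) {
      x <- g$ioi[g$bin == b]
      if (length(x) >= 2L) {
        c(mean_ioi = mean(x), sd_ioi = stats::sd(x),
          cv = corrected_cv(x), n = length(x))
      } else {
        c(mean_ioi = if (length(x)) mean(x) else NA_real_,
          sd_ioi = NA_real_, cv = NA_real_, n = length(x))
      }
    })
    stats_mat <- do.call(rbind, per_bin)
    data.frame(colony_id = g$colony_id[1L], penguin_id = g$penguin_id[1L],
               bin = 1:5, bin_position = seq(0.1, 0.9, by = 0.2),
               stats_mat, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
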
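#' Syllable tables and song datasets
#'
#' The package's canonical container is a tidy *syllable table*: one row per
#' annotated syllable, ordered by onset within song, with columns
#' `colony_id`, `penguin_id`, `song_id`, `label` (one of `"A"`, `"B"`, `"C"`),
#' `onset_s`, `offset_s` and (optionally) `intensity_db`. A dataset is such a
#' table carrying the class `"song_dataset"` and a `provenance` attribute.
#' Every song is stored already truncated at its first B syllable, which is
#' the unit of analysis throughout: the run of short egressive A syllables
#' (with possible ingressive C syllables interspersed) up to and including
#' the terminal long B syllable.
#'
#' @name song_dataset
NULL

SYLLABLE_COLUMNS <- c("colony_id", "penguin_id", "song_id",
                      "label", "onset_s", "offset_s")

#' Build a song dataset from a syllable table
#'
#' Validates a syllable data frame, truncates each song at its first B
#' syllable, and returns a `song_dataset`. Songs without a B syllable are an
#' error unless `on_no_b = "skip"`, in which case they are dropped with a
#' warning (batch mode).
#'
#' @param df data frame with the syllable-table columns (see
#'   [song_dataset]); `intensity_db` is optional.
#' @param provenance character scalar recorded on the result.
#' @param on_no_b `"error"` or `"skip"`: what to do with songs lacking a B.
#' @return a `song_dataset` data frame.
#' @export
as_song_dataset <- function(df, provenance = "in-memory table",
                            on_no_b = c("error", "skip")) {
  on_no_b <- match.arg(on_no_b)
  missing_cols <- setdiff(SYLLABLE_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("syllable table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"intensity_db" %in% names(df)) df$intensity_db <- NA_real_
  df <- df[c(SYLLABLE_COLUMNS, "intensity_db")]
  for (col in c("colony_id", "penguin_id", "song_id", "label")) {
    df[[col]] <- as.character(df[[col]])
  }
  if (nrow(df) == 0L) {
    warning("empty syllable table: dataset contains no songs")
    return(structure(df, class = c("song_dataset", "data.frame"),
                     provenance = provenance))
  }
  bad <- setdiff(unique(df$label), c("A", "B", "C"))
  if (length(bad) > 0L) {
    stop("invalid syllable label(s): ", paste(bad, collapse = ", "),
         " (labels must be A, B or C)", call. = FALSE)
  }
  key <- song_key(df)
  pieces <- lapply(split(df, key), function(song) {
    validate_song_rows(song)
    tryCatch(truncate_at_first_b(song),
             truncation_error = function(e) {
               if (on_no_b == "skip") {
                 warning(conditionMessage(e), ": song skipped", call. = FALSE)
                 NULL
               } else stop(e)
             })
  })
  out <- do.call(rbind, c(pieces[!vapply(pieces, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  if (is.null(out)) out <- df[0L, ]
  structure(out, class = c("song_dataset", "data.frame"),
            provenance = provenance)
}

song_key <- function(df) {
  interaction(df$colony_id, df$penguin_id, df$song_id,
              drop = TRUE, lex.order = TRUE, sep = "\r")
}

#' Split a dataset into per-song data frames
#'
#' @param dataset a `song_dataset` (or compatible data frame).
#' @return named list of per-song data frames, rows in onset order.
#' @export
split_songs <- function(dataset) {
  split(as.data.frame(dataset), song_key(dataset))
}

validate_song_rows <- function(song) {
  id <- song_label(song)
  if (any(song$offset_s <= song$onset_s)) {
    stop("song ", id, ": syllable offset must exceed onset", call. = FALSE)
  }
  if (is.unsorted(song$onset_s, strictly = TRUE)) {
    stop("song ", id, ": syllable onsets must be strictly increasing",
         call. = FALSE)
  }
  overlap <- song$onset_s[-1L] < song$offset_s[-nrow(song)] - 1e-9
  if (any(overlap)) {
    stop("song ", id, ": overlapping syllables at onset ",
         format(song$onset_s[-1L][overlap][1L]), " s", call. = FALSE)
  }
  invisible(song)
}

song_label <- function(song) {
  paste(song$colony_id[1L], song$penguin_id[1L], song$song_id[1L], sep = "/")
}

#' Truncate a song at its first B syllable
#'
#' Keeps syllables up to and including the first B; later syllables are
#' dropped. Idempotent on already-truncated songs. A song with no B syllable
#' raises a condition of class `"truncation_error"` naming the song.
#'
#' @param song per-song data frame (syllable-table columns).
#' @return the truncated data frame.
#' @export
truncate_at_first_b <- function(song) {
  b <- which(song$label == "B")
  if (length(b) == 0L) {
    stop(structure(class = c("truncation_error", "error", "condition"),
                   list(message = paste0("song ", song_label(song),
                                         " has no B syllable"),
                        call = NULL)))
  }
  song[seq_len(b[1L]), , drop = FALSE]
}

#' Summarize a song dataset
#'
#' Counts colonies, penguins and songs, the per-penguin song count range, and
#' syllables by type.
#'
#' @param dataset a `song_dataset`.
#' @return list with components `n_colonies`, `n_penguins`, `n_songs`,
#'   `songs_per_penguin` (min/median/max), `syllable_counts`.
#' @export
summarize_dataset <- function(dataset) {
  df <- as.data.frame(dataset)
  if (nrow(df) == 0L) {
    return(list(n_colonies = 0L, n_penguins = 0L, n_songs = 0L,
                songs_per_penguin = c(min = NA, median = NA, max = NA),
                syllable_counts = table(factor(character(),
                                               levels = c("A", "B", "C")))))
  }
  song_of <- unique(df[c("colony_id", "penguin_id", "song_id")])
  per_penguin <- table(paste(song_of$colony_id, song_of$penguin_id))
  list(
    n_colonies = length(unique(df$colony_id)),
    n_penguins = nrow(unique(df[c("colony_id", "penguin_id")])),
    n_songs = nrow(song_of),
    songs_per_penguin = c(min = min(per_penguin),
                          median = stats::median(per_penguin),
                          max = max(per_penguin)),
    syllable_counts = table(factor(df$label, levels = c("A", "B", "C")))
  )
}
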
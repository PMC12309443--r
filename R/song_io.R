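#' Read a song from a Praat TextGrid
#'
#' Parses a Praat `ooTextFile` TextGrid (long or short form), takes the
#' non-empty intervals of one interval tier as syllables, and truncates the
#' song at the first B syllable. Point (TextTier) tiers are ignored.
#'
#' @param path path to the TextGrid file.
#' @param tier_name name of the interval tier holding the syllable labels;
#'   default uses the first interval tier in the file.
#' @param colony_id,penguin_id,song_id identifiers attached to the song
#'   (TextGrids carry none); defaults derive the song id from the file name.
#' @return a per-song data frame with the syllable-table columns.
#' @export
read_textgrid <- function(path, tier_name = NULL,
                          colony_id = "unknown", penguin_id = "unknown",
                          song_id = sub("\\.[Tt]ext[Gg]rid$", "",
                                        basename(path))) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) < 3L || !grepl("ooTextFile", lines[1L]) ||
      !grepl("TextGrid", lines[2L])) {
    stop("not a Praat ooTextFile TextGrid: ", path, call. = FALSE)
  }
  body <- lines[-(1:2)]
  tiers <- if (any(grepl("^\\s*xmin\\s*=", body))) {
    parse_textgrid_long(body)
  } else {
    parse_textgrid_short(body)
  }
  tiers <- Filter(function(t) t$class == "IntervalTier", tiers)
  if (length(tiers) == 0L) {
    stop("TextGrid has no interval tier: ", path, call. = FALSE)
  }
  if (!is.null(tier_name)) {
    hit <- which(vapply(tiers, function(t) t$name, "") == tier_name)
    if (length(hit) == 0L) {
      stop("TextGrid has no interval tier named '", tier_name, "': ", path,
           call. = FALSE)
    }
    tier <- tiers[[hit[1L]]]
  } else {
    tier <- tiers[[1L]]
  }
  iv <- tier$intervals
  iv$text <- trimws(iv$text)
  iv <- iv[nzchar(iv$text), , drop = FALSE]
  bad <- !iv$text %in% c("A", "B", "C")
  if (any(bad)) {
    stop("invalid syllable label '", iv$text[bad][1L], "' at ",
         format(iv$xmin[bad][1L]), " s in ", path, call. = FALSE)
  }
  song <- data.frame(colony_id = colony_id, penguin_id = penguin_id,
                     song_id = song_id, label = iv$text,
                     onset_s = iv$xmin, offset_s = iv$xmax,
                     intensity_db = NA_real_,
                     stringsAsFactors = FALSE)
  song <- song[order(song$onset_s), , drop = FALSE]
  rownames(song) <- NULL
  validate_song_rows(song)
  truncate_at_first_b(song)
}

# Long ("text") form: labelled "item [k]:" blocks with xmin/xmax/text fields.
parse_textgrid_long <- function(body) {
  num_field <- function(line) as.numeric(sub("^[^=]*=\\s*", "", line))
  str_field <- function(line) {
    m <- regmatches(line, regexpr('"(?:[^"]|"")*"', line))
    if (length(m) == 0L) return("")
    gsub('""', '"', substr(m, 2L, nchar(m) - 1L))
  }
  item_at <- grep("^\\s*item\\s*\\[[0-9]+\\]\\s*:", body)
  tiers <- vector("list", length(item_at))
  bounds <- c(item_at, length(body) + 1L)
  for (k in seq_along(item_at)) {
    blk <- body[item_at[k]:(bounds[k + 1L] - 1L)]
    cls <- str_field(blk[grep("^\\s*class\\s*=", blk)[1L]])
    nm <- str_field(blk[grep("^\\s*name\\s*=", blk)[1L]])
    ivl <- grep("^\\s*intervals\\s*\\[[0-9]+\\]\\s*:", blk)
    xmins <- xmaxs <- numeric(length(ivl))
    texts <- character(length(ivl))
    for (j in seq_along(ivl)) {
      sub_blk <- blk[ivl[j]:min(ivl[j] + 3L, length(blk))]
      xmins[j] <- num_field(sub_blk[grep("^\\s*xmin\\s*=", sub_blk)[1L]])
      xmaxs[j] <- num_field(sub_blk[grep("^\\s*xmax\\s*=", sub_blk)[1L]])
      texts[j] <- str_field(sub_blk[grep("^\\s*text\\s*=", sub_blk)[1L]])
    }
    tiers[[k]] <- list(class = cls, name = nm,
                       intervals = data.frame(xmin = xmins, xmax = xmaxs,
                                              text = texts,
                                              stringsAsFactors = FALSE))
  }
  tiers
}

# Short form: bare values in fixed order (tier class, name, xmin, xmax, n,
# then n (xmin, xmax, text) triples for interval tiers).
parse_textgrid_short <- function(body) {
  toks <- trimws(body)
  toks <- toks[nzchar(toks)]
  unquote <- function(x) gsub('""', '"', sub('^"(.*)"$', "\\1", x))
  pos <- 1L
  take <- function() {
    v <- toks[pos]; pos <<- pos + 1L; v
  }
  take()  # global xmin
  take()  # global xmax
  take()  # tiers? flag
  n_tiers <- as.integer(take())
  tiers <- vector("list", n_tiers)
  for (k in seq_len(n_tiers)) {
    cls <- unquote(take())
    nm <- unquote(take())
    take(); take()  # tier xmin, xmax
    n <- as.integer(take())
    if (cls == "IntervalTier") {
      xmins <- xmaxs <- numeric(n)
      texts <- character(n)
      for (j in seq_len(n)) {
        xmins[j] <- as.numeric(take())
        xmaxs[j] <- as.numeric(take())
        texts[j] <- unquote(take())
      }
      tiers[[k]] <- list(class = cls, name = nm,
                         intervals = data.frame(xmin = xmins, xmax = xmaxs,
                                                text = texts,
                                                stringsAsFactors = FALSE))
    } else {
      for (j in seq_len(n)) { take(); take() }  # points: time, mark
      tiers[[k]] <- list(class = cls, name = nm, intervals = NULL)
    }
  }
  tiers
}

#' Write a song as a Praat TextGrid (long form)
#'
#' One interval tier named `tier_name`; gaps between syllables become empty
#' intervals so the tier tiles `[0, xmax]`.
#'
#' @param song per-song data frame.
#' @param path output path.
#' @param tier_name tier name, default `"syllables"`.
#' @export
write_textgrid <- function(song, path, tier_name = "syllables") {
  xmax <- max(song$offset_s)
  edges <- data.frame(xmin = song$onset_s, xmax = song$offset_s,
                      text = song$label, stringsAsFactors = FALSE)
  full <- list()
  cursor <- 0
  for (i in seq_len(nrow(edges))) {
    if (edges$xmin[i] > cursor + 1e-12) {
      full[[length(full) + 1L]] <- data.frame(xmin = cursor,
                                              xmax = edges$xmin[i], text = "")
    }
    full[[length(full) + 1L]] <- edges[i, ]
    cursor <- edges$xmax[i]
  }
  iv <- do.call(rbind, full)
  fmt <- function(x) formatC(x, format = "f", digits = 8)
  out <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
           "xmin = 0", paste0("xmax = ", fmt(xmax)), "tiers? <exists>",
           "size = 1", "item []:", "    item [1]:",
           '        class = "IntervalTier"',
           paste0('        name = "', tier_name, '"'),
           "        xmin = 0", paste0("        xmax = ", fmt(xmax)),
           paste0("        intervals: size = ", nrow(iv)))
  for (i in seq_len(nrow(iv))) {
    out <- c(out,
             paste0("        intervals [", i, "]:"),
             paste0("            xmin = ", fmt(iv$xmin[i])),
             paste0("            xmax = ", fmt(iv$xmax[i])),
             paste0('            text = "', iv$text[i], '"'))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a song dataset from a CSV syllable table
#'
#' Expects columns `colony_id, penguin_id, song_id, label, onset_s, offset_s`
#' and optionally `intensity_db`; rows are grouped by the (colony, penguin,
#' song) triple, ordered by onset within each song, and each song is
#' truncated at its first B syllable.
#'
#' @param path CSV path (UTF-8, header row, `.` decimal separator).
#' @param on_no_b passed to [as_song_dataset()].
#' @return a `song_dataset`.
#' @export
read_csv_table <- function(path, on_no_b = "error") {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   warning("empty or unreadable CSV '", path,
                           "': returning an empty dataset", call. = FALSE)
                   empty_syllable_table()
                 })
  as_song_dataset(df, provenance = path, on_no_b = on_no_b)
}

empty_syllable_table <- function() {
  data.frame(colony_id = character(), penguin_id = character(),
             song_id = character(), label = character(),
             onset_s = numeric(), offset_s = numeric(),
             intensity_db = numeric(), stringsAsFactors = FALSE)
}

#' Write a song dataset to CSV
#'
#' Round-trips through [read_csv_table()] with all fields identical (times
#' written with enough digits for at least 1e-6 s precision). A dataset with
#' no intensities omits the `intensity_db` column.
#'
#' @param dataset a `song_dataset`.
#' @param path output path.
#' @export
write_csv_table <- function(dataset, path) {
  df <- as.data.frame(dataset)
  if (all(is.na(df$intensity_db))) df$intensity_db <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Intensity differences relative to the first B syllable
#'
#' Returns, for each egressive (A or B) syllable, its relative position in
#' the song and its intensity minus the first B syllable's intensity, so the
#' B syllable maps to 0 dB by construction. Ingressive C syllables are not
#' part of the crescendo and are dropped.
#'
#' @param song per-song data frame, truncated, with `intensity_db` set on
#'   every egressive syllable.
#' @return data frame with columns `relative_position` ((i-1)/(n-1) over the
#'   n egressive syllables), `label`, and `norm_intensity_db`.
#' @export
normalize_intensity <- function(song) {
  eg <- song[song$label != "C", , drop = FALSE]
  if (!any(eg$label == "B")) {
    stop("song ", song_label(song), " has no B syllable", call. = FALSE)
  }
  if (any(is.na(eg$intensity_db))) {
    stop("song ", song_label(song),
         ": every egressive syllable needs an intensity for normalization",
         call. = FALSE)
  }
  ref <- eg$intensity_db[which(eg$label == "B")[1L]]
  n <- nrow(eg)
  data.frame(relative_position = relative_positions(n),
             label = eg$label,
             norm_intensity_db = eg$intensity_db - ref,
             stringsAsFactors = FALSE)
}
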
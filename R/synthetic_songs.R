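#' Configuration for the synthetic song generator
#'
#' Defaults emulate the study population the analysis targets: 3 colonies,
#' 26 male penguins with at least six songs each, songs made of 6-20 short A
#' syllables ending in one long B syllable, IOIs shortening exponentially by
#' about 25% over a song while A syllables lengthen by about 20% (so
#' silences shrink by almost 45%), timing jitter that shrinks along the
#' song, a 12 dB intensity crescendo peaking at the B syllable, and a
#' per-song coupling that makes songs starting with a long first IOI
#' accelerate more strongly.
#'
#' @param n_colonies,n_penguins,songs_per_penguin population sizes.
#' @param syllable_count_range integer range of A syllables per song.
#' @param ioi1_meanlog,ioi1_sdlog lognormal parameters of the first IOI
#'   (seconds; default median 0.5 s).
#' @param ioi_decay total log-IOI slope over the song (default `log(0.75)`,
#'   i.e. 25% shortening).
#' @param syllable_growth total log A-syllable-duration slope (default
#'   `log(1.2)`, i.e. 20% lengthening).
#' @param initial_syllable_fraction A-syllable duration as a fraction of the
#'   first IOI, at the song's start (default 0.3).
#' @param jitter_sd_start,jitter_sd_end lognormal SD of the multiplicative
#'   IOI jitter at the start and end of a song (decreasing by default, which
#'   produces the falling CV).
#' @param syllable_jitter_sd lognormal SD of per-syllable duration noise.
#' @param ioi1_coupling coupling `k` (log-slope units per second) between a
#'   song's first-IOI deviation from its penguin-level expectation and the
#'   song's log-IOI slope; negative values make slow-starting songs
#'   accelerate harder. The deviation is within-penguin (a penguin's
#'   habitual tempo, carried by the random intercepts, does not change its
#'   acceleration), matching how the plasticity model's random structure
#'   isolates within-penguin variation.
#' @param crescendo_rise total intensity rise over a song (dB, default 12).
#' @param intensity_noise_sd per-syllable intensity noise (dB).
#' @param base_intensity_db mean B-syllable intensity (dB).
#' @param c_mode `"none"`, `"breath"` (C syllables sit wholly inside a
#'   silence and do not displace the next egressive onset) or `"rhythmic"`
#'   (a C occupies a genuine beat slot: the onset chain is unchanged but the
#'   slot is ingressive, so omitting it merges two IOIs).
#' @param c_probability per-silence (breath) or per-slot (rhythmic)
#'   probability of a C syllable, for C-producing penguins.
#' @param c_penguin_fraction fraction of penguins that produce C syllables
#'   (default 0.5, i.e. 13 of 26).
#' @param re_sd_colony,re_sd_penguin,re_sd_song random-intercept SDs (log-IOI
#'   units) at each nesting level.
#' @param seed integer master seed; all per-song randomness derives from it.
#' @return list of class `"song_generator_config"`.
#' @export
synthetic_song_config <- function(n_colonies = 3L, n_penguins = 26L,
                                  songs_per_penguin = 20L,
                                  syllable_count_range = c(6L, 20L),
                                  ioi1_meanlog = log(0.5), ioi1_sdlog = 0.15,
                                  ioi_decay = log(0.75),
                                  syllable_growth = log(1.2),
                                  initial_syllable_fraction = 0.3,
                                  jitter_sd_start = 0.08,
                                  jitter_sd_end = 0.03,
                                  syllable_jitter_sd = 0.05,
                                  ioi1_coupling = -0.6,
                                  crescendo_rise = 12,
                                  intensity_noise_sd = 1.5,
                                  base_intensity_db = 65,
                                  c_mode = c("none", "breath", "rhythmic"),
                                  c_probability = 0.2,
                                  c_penguin_fraction = 0.5,
                                  re_sd_colony = 0.05, re_sd_penguin = 0.05,
                                  re_sd_song = 0.05,
                                  seed = 1L) {
  c_mode <- match.arg(c_mode)
  cfg <- as.list(environment())
  if (cfg$initial_syllable_fraction <= 0 || cfg$initial_syllable_fraction >= 1) {
    stop("initial_syllable_fraction must be in (0, 1)", call. = FALSE)
  }
  sds <- c(cfg$jitter_sd_start, cfg$jitter_sd_end, cfg$re_sd_colony,
           cfg$re_sd_penguin, cfg$re_sd_song, cfg$ioi1_sdlog,
           cfg$intensity_noise_sd, cfg$syllable_jitter_sd)
  if (any(sds < 0)) stop("all SDs must be nonnegative", call. = FALSE)
  # deterministic part of the end-of-song silence must stay positive
  if (exp(cfg$ioi_decay) - cfg$initial_syllable_fraction *
        exp(cfg$syllable_growth) <= 0) {
    stop("impossible configuration: syllables outgrow the IOI ",
         "(every end-of-song silence would be negative)", call. = FALSE)
  }
  structure(cfg, class = "song_generator_config")
}

# Deterministic per-song substream seed below 2^31. Songs draw their core
# timing and their C-syllable decoration from distinct substreams, so a
# breath-mode run has the same egressive onsets as the same-seed C-free run.
substream_seed <- function(seed, penguin_idx, song_idx, purpose) {
  tag <- switch(purpose, core = 1, c = 2, audio = 3)
  v <- (as.double(seed) %% 2147483647) * 48271 +
    penguin_idx * 69621 + song_idx * 16807 + tag * 75091
  as.integer(v %% 2147483629) + 1L
}

#' Generate a synthetic song dataset
#'
#' Draws songs from the generative process the inference suite assumes: log
#' IOI linear in relative position (slope `ioi_decay`, perturbed by the
#' first-IOI coupling) with multiplicative lognormal jitter shrinking along
#' the song, A-syllable durations growing exponentially, silences as the
#' remainder, intensities rising linearly to the B syllable, and optional C
#' syllables in breath or rhythmic mode. Random intercepts at the colony,
#' penguin and song levels act on the log first-IOI level, so the fitted
#' nested-intercept models match the generating process exactly. Fully
#' reproducible from the config seed; per-song substreams mean adding
#' penguins or songs does not perturb existing ones.
#'
#' @param config a [synthetic_song_config()].
#' @return a `song_dataset`.
#' @export
generate_dataset <- function(config = synthetic_song_config()) {
  stopifnot(inherits(config, "song_generator_config"))
  cfg <- config
  colony_of <- rep(seq_len(cfg$n_colonies), length.out = cfg$n_penguins)
  colony_of <- sort(colony_of)
  # penguin-level draws from the master seed
  set.seed(cfg$seed %% 2147483647)
  u_colony <- stats::rnorm(cfg$n_colonies, 0, cfg$re_sd_colony)
  u_penguin <- stats::rnorm(cfg$n_penguins, 0, cfg$re_sd_penguin)
  base_int_penguin <- stats::rnorm(cfg$n_penguins, cfg$base_intensity_db, 2)
  makes_c <- seq_len(cfg$n_penguins) <=
    round(cfg$c_penguin_fraction * cfg$n_penguins)
  songs <- list()
  for (p in seq_len(cfg$n_penguins)) {
    for (s in seq_len(cfg$songs_per_penguin)) {
      song <- generate_song(cfg, p, s, u_colony[colony_of[p]], u_penguin[p],
                            base_int_penguin[p], makes_c[p])
      song$colony_id <- sprintf("col%d", colony_of[p])
      song$penguin_id <- sprintf("peng%02d", p)
      song$song_id <- sprintf("song%03d", s)
      songs[[length(songs) + 1L]] <- song
    }
  }
  df <- do.call(rbind, c(songs, list(make.row.names = FALSE)))
  df <- df[c(SYLLABLE_COLUMNS, "intensity_db")]
  as_song_dataset(df, provenance = sprintf("synthetic (seed %d)", cfg$seed))
}

generate_song <- function(cfg, p, s, u_col, u_pen, base_int, makes_c) {
  set.seed(substream_seed(cfg$seed, p, s, "core"))
  for (attempt in 1:100) {
    n_a <- sample(cfg$syllable_count_range[1L]:cfg$syllable_count_range[2L], 1L)
    n <- n_a + 1L                       # syllables including the B
    m <- n - 1L                         # IOIs
    relpos <- relative_positions(m)
    u_song <- stats::rnorm(1, 0, cfg$re_sd_song)
    ioi1_level <- exp(cfg$ioi1_meanlog + stats::rnorm(1, 0, cfg$ioi1_sdlog) +
                        u_col + u_pen + u_song)
    # penguin-conditional expectation: coupling acts on within-penguin
    # tempo deviations only
    ioi1_penguin_expected <- exp(cfg$ioi1_meanlog + u_col + u_pen +
                                   (cfg$ioi1_sdlog^2 + cfg$re_sd_song^2) / 2)
    beta_song <- cfg$ioi_decay +
      cfg$ioi1_coupling * (ioi1_level - ioi1_penguin_expected)
    jitter_sd <- cfg$jitter_sd_start +
      (cfg$jitter_sd_end - cfg$jitter_sd_start) * relpos
    ioi <- ioi1_level * exp(beta_song * relpos +
                              stats::rnorm(m, 0, jitter_sd))
    dur <- cfg$initial_syllable_fraction * ioi1_level *
      exp(cfg$syllable_growth * relpos +
            stats::rnorm(m, 0, cfg$syllable_jitter_sd))
    silence <- ioi - dur
    if (all(silence > 1e-3)) break
    if (attempt == 100) stop("generator cannot satisfy silence > 0; ",
                             "relax the configuration", call. = FALSE)
  }
  onsets <- c(0, cumsum(ioi))
  b_dur <- max(dur) * stats::runif(1, 1.8, 2.5)
  offsets <- c(onsets[-n] + dur, onsets[n] + b_dur)
  syl_pos <- relative_positions(n)
  intensity <- base_int + cfg$crescendo_rise * (syl_pos - 1) +
    stats::rnorm(n, 0, cfg$intensity_noise_sd)
  song <- data.frame(colony_id = "", penguin_id = "", song_id = "",
                     label = c(rep("A", n_a), "B"),
                     onset_s = onsets, offset_s = offsets,
                     intensity_db = intensity, stringsAsFactors = FALSE)
  if (cfg$c_mode != "none" && makes_c) {
    set.seed(substream_seed(cfg$seed, p, s, "c"))
    song <- insert_c_syllables(song, cfg)
  }
  song
}

# Breath mode: a C sits in the middle 40% of a silent gap, leaving every
# egressive onset untouched. Rhythmic mode: an interior A slot turns
# ingressive (label C, shortened) while the onset chain is untouched.
insert_c_syllables <- function(song, cfg) {
  n <- nrow(song)
  if (cfg$c_mode == "breath") {
    extra <- list()
    for (i in seq_len(n - 1L)) {
      gap_start <- song$offset_s[i]
      gap_end <- song$onset_s[i + 1L]
      if (gap_end - gap_start < 0.02) next
      if (stats::runif(1) < cfg$c_probability) {
        gap <- gap_end - gap_start
        extra[[length(extra) + 1L]] <-
          data.frame(colony_id = "", penguin_id = "", song_id = "",
                     label = "C", onset_s = gap_start + 0.3 * gap,
                     offset_s = gap_start + 0.7 * gap,
                     intensity_db = NA_real_, stringsAsFactors = FALSE)
      }
    }
    if (length(extra) > 0L) {
      song <- rbind(song, do.call(rbind, extra))
      song <- song[order(song$onset_s), , drop = FALSE]
      rownames(song) <- NULL
    }
  } else {  # rhythmic
    interior <- 2:(n - 2L)  # never the first A, never the last A or the B
    flip <- interior[stats::runif(length(interior)) < cfg$c_probability]
    if (length(flip) > 0L) {
      song$label[flip] <- "C"
      song$offset_s[flip] <- song$onset_s[flip] +
        0.5 * (song$offset_s[flip] - song$onset_s[flip])
      song$intensity_db[flip] <- NA_real_
    }
  }
  song
}

#' Population-level slopes implied by a generator configuration
#'
#' Closed-form / numerically projected "truths" for parameter-recovery
#' checks. The log-IOI and log-syllable trends are linear by construction,
#' so their implied slopes are `ioi_decay` and `syllable_growth`. The
#' silence trend `log(exp(ioi_decay * p) - f * exp(syllable_growth * p))`
#' is smooth but not exactly linear; its implied slope is the least-squares
#' projection onto relative position, computed on a fine grid. The implied
#' first-IOI/average-acceleration slope is obtained the same way, by
#' differentiating the noise-free average acceleration with respect to the
#' first IOI around its expectation (numerically, at the median song
#' length).
#'
#' @param config a [synthetic_song_config()].
#' @return list with `ioi_slope`, `syllable_slope`, `silence_slope`,
#'   `silence_percent_change` (end-to-end, from the exact curve),
#'   `crescendo_slope`, `ioi1_slope`.
#' @export
implied_slopes <- function(config) {
  cfg <- config
  f <- cfg$initial_syllable_fraction
  p <- seq(0, 1, length.out = 401L)
  sil <- exp(cfg$ioi_decay * p) - f * exp(cfg$syllable_growth * p)
  silence_slope <- unname(stats::coef(stats::lm(log(sil) ~ p))[2L])
  ioi1_expected <- exp(cfg$ioi1_meanlog +
                         (cfg$ioi1_sdlog^2 + cfg$re_sd_song^2) / 2)
  n_med <- round(mean(cfg$syllable_count_range)) + 1L
  avg_acc <- function(ioi1) {
    beta <- cfg$ioi_decay + cfg$ioi1_coupling * (ioi1 - ioi1_expected)
    iois <- ioi1 * exp(beta * relative_positions(n_med - 1L))
    average_acceleration(acceleration_ratios(iois))
  }
  h <- 0.01 * ioi1_expected
  ioi1_slope <- (avg_acc(ioi1_expected + h) - avg_acc(ioi1_expected - h)) /
    (2 * h)
  list(ioi_slope = cfg$ioi_decay,
       syllable_slope = cfg$syllable_growth,
       silence_slope = silence_slope,
       silence_percent_change = 100 * (sil[length(sil)] / sil[1L] - 1),
       crescendo_slope = cfg$crescendo_rise,
       ioi1_slope = ioi1_slope)
}
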
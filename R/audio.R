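#' Energy-based syllable intensity
#'
#' Praat-style intensity of one syllable: the waveform around the syllable
#' is band-stop filtered below 100 Hz (spectral-domain mask with a
#' Hann-shaped 10 Hz transition, removing low-frequency rumble), an
#' intensity contour is computed from Hann-windowed frames (32 ms window,
#' 8 ms step by default), and the syllable's intensity is the energy-based
#' average of the contour: `10*log10(mean(10^(I/10)))` over frames, i.e. the
#' dB of the mean frame power. The dB reference is the standard auditory
#' reference power 4e-10 (amplitude 2e-5), so unit-amplitude signals land
#' near 91 dB; only intensity *differences* matter downstream.
#'
#' @param samples numeric waveform, mono, nominally in `[-1, 1]`.
#' @param rate sampling rate in Hz (>= 8000).
#' @param onset,offset syllable bounds in seconds within the waveform.
#' @param window_s,step_s analysis window and step (seconds). These are not
#'   fixed by the method and are exposed as arguments.
#' @param stop_high,stop_smooth band-stop upper edge and transition width
#'   (Hz): energy below `stop_high` is removed, with a half-Hann ramp of
#'   width `stop_smooth` above it.
#' @return intensity in dB, or `NA` with attribute `undefined = TRUE` for a
#'   silent (all-zero) segment.
#' @export
extract_intensity <- function(samples, rate, onset, offset,
                              window_s = 0.032, step_s = 0.008,
                              stop_high = 100, stop_smooth = 10) {
  if (rate < 8000) stop("sampling rate must be at least 8 kHz", call. = FALSE)
  if (onset < 0 || offset * rate > length(samples) + 1e-6 || offset <= onset) {
    stop("syllable bounds [", onset, ", ", offset,
         "] outside waveform extent", call. = FALSE)
  }
  pad <- 0.05
  i0 <- max(1L, floor((onset - pad) * rate) + 1L)
  i1 <- min(length(samples), ceiling((offset + pad) * rate))
  seg <- bandstop_low(samples[i0:i1], rate, stop_high, stop_smooth)
  seg_start <- (i0 - 1L) / rate
  win <- max(3L, round(window_s * rate))
  step <- max(1L, round(step_s * rate))
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))
  first_center <- onset + window_s / 2
  last_center <- offset - window_s / 2
  centers <- if (last_center >= first_center) {
    seq(first_center, last_center, by = step / rate)
  } else {
    (onset + offset) / 2  # syllable shorter than one window
  }
  powers <- vapply(centers, function(tc) {
    j0 <- round((tc - seg_start) * rate - win / 2) + 1L
    j1 <- j0 + win - 1L
    if (j0 < 1L || j1 > length(seg)) return(NA_real_)
    frame <- seg[j0:j1]
    sum(frame^2 * hann) / sum(hann)
  }, numeric(1))
  powers <- powers[is.finite(powers)]
  mean_power <- mean(powers)
  if (!is.finite(mean_power) || mean_power <= 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  10 * log10(mean_power / 4e-10)
}

# Remove energy below `edge` Hz via an FFT mask: 0 up to `edge`, half-Hann
# rise over [edge, edge + width], 1 above.
bandstop_low <- function(x, rate, edge = 100, width = 10) {
  n <- length(x)
  freqs <- (seq_len(n) - 1L) / n * rate
  freqs <- pmin(freqs, rate - freqs)  # fold to [0, rate/2]
  mask <- ifelse(freqs <= edge, 0,
                 ifelse(freqs >= edge + width, 1,
                        0.5 - 0.5 * cos(pi * (freqs - edge) / width)))
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE) / n)
}

#' Render a song as audio
#'
#' Synthesizes each syllable as a harmonic tone burst (fundamental plus two
#' harmonics, 5 ms cosine on/off ramps) whose amplitude realizes the
#' syllable's `intensity_db` relative to the loudest syllable; silences are
#' zeros. Syllables without an intensity are rendered at the quietest
#' syllable's level minus 6 dB. Intended for testing the intensity
#' extractor, not for spectral realism.
#'
#' @param song per-song data frame with `intensity_db` on egressive
#'   syllables.
#' @param rate sampling rate (Hz).
#' @param base_frequency fundamental frequency (Hz).
#' @param peak_amplitude amplitude of the loudest syllable (linear, < 1).
#' @return list with `samples` and `rate`.
#' @export
synthesize_song_audio <- function(song, rate = 16000, base_frequency = 400,
                                  peak_amplitude = 0.5) {
  validate_song_rows(song)
  total <- max(song$offset_s) + 0.1
  samples <- numeric(ceiling(total * rate))
  ints <- song$intensity_db
  ref_db <- max(ints, na.rm = TRUE)
  ints[is.na(ints)] <- min(ints, na.rm = TRUE) - 6
  for (i in seq_len(nrow(song))) {
    t0 <- song$onset_s[i]
    t1 <- song$offset_s[i]
    idx <- (floor(t0 * rate) + 1L):min(length(samples), ceiling(t1 * rate))
    t <- (idx - 1L) / rate - t0
    amp <- peak_amplitude * 10^((ints[i] - ref_db) / 20)
    wave <- sin(2 * pi * base_frequency * t) +
      0.4 * sin(2 * pi * 2 * base_frequency * t) +
      0.2 * sin(2 * pi * 3 * base_frequency * t)
    wave <- wave / sqrt(1 + 0.4^2 + 0.2^2) * amp  # keep RMS tied to amp
    ramp_n <- min(length(t) %/% 2, round(0.005 * rate))
    if (ramp_n > 0L) {
      ramp <- 0.5 - 0.5 * cos(pi * seq_len(ramp_n) / ramp_n)
      wave[seq_len(ramp_n)] <- wave[seq_len(ramp_n)] * ramp
      wave[(length(wave) - ramp_n + 1L):length(wave)] <-
        wave[(length(wave) - ramp_n + 1L):length(wave)] * rev(ramp)
    }
    samples[idx] <- samples[idx] + wave
  }
  list(samples = samples, rate = rate)
}

#' Minimal mono 16-bit PCM WAV I/O
#'
#' Reads or writes a single-channel 16-bit PCM RIFF/WAVE file, returning or
#' taking samples scaled to `[-1, 1]`.
#'
#' @param path file path.
#' @return `read_wav`: list with `samples` and `rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4L, useBytes = TRUE)
  if (hdr != "RIFF") stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (readChar(con, 4L, useBytes = TRUE) != "WAVE") {
    stop("not a WAVE file: ", path, call. = FALSE)
  }
  rate <- NULL
  repeat {
    chunk <- readChar(con, 4L, useBytes = TRUE)
    if (length(chunk) == 0L || nchar(chunk) < 4L) {
      stop("no data chunk in ", path, call. = FALSE)
    }
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (chunk == "fmt ") {
      fmt <- readBin(con, "integer", 2L, size = 2L, endian = "little")
      if (fmt[1L] != 1L || fmt[2L] != 1L) {
        stop("only mono PCM WAV is supported", call. = FALSE)
      }
      rate <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      bits <- readBin(con, "integer", size - 8L, size = 1L)
      if (bits[7L] != 16L) stop("only 16-bit WAV is supported", call. = FALSE)
    } else if (chunk == "data") {
      raw_samples <- readBin(con, "integer", size %/% 2L, size = 2L,
                             signed = TRUE, endian = "little")
      return(list(samples = raw_samples / 32767, rate = rate))
    } else {
      readBin(con, "raw", size)
    }
  }
}

#' @rdname read_wav
#' @param samples numeric vector in `[-1, 1]`.
#' @param rate sampling rate (Hz).
#' @export
write_wav <- function(samples, rate, path) {
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16L), con, size = 4L, endian = "little")
  writeBin(c(1L, 1L), con, size = 2L, endian = "little")       # PCM, mono
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")               # block align
  writeBin(16L, con, size = 2L, endian = "little")              # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
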
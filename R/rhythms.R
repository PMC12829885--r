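# Rhythm stimulus set and audio synthesis.
#
# Rhythms are ordered sequences of inter-onset interval multipliers of a
# 250-ms base unit. Strong- and weak-beat rhythms use integer multipliers
# (1:2:3:4) summing to 12 units (3 s per pattern); non-beat rhythms use
# non-integer ratios (1:1.4:3.6:4) that abolish the regular beat.

#' Construct a rhythm specification
#'
#' A rhythm is an ordered sequence of inter-onset-interval multipliers of a
#' base unit (250 ms by default). Strong- and weak-beat rhythms are built
#' from integer multipliers in \{1, 2, 3, 4\}; non-beat rhythms from the
#' non-integer ratio set \{1, 1.4, 3.6, 4\}.
#'
#' @param intervals Numeric vector of 6 or 7 interval multipliers.
#' @param condition One of \code{"strong"}, \code{"weak"}, \code{"non"}.
#' @param set_ids Integer vector, which counterbalanced stimulus sets
#'   (subset of 1:4) the rhythm belongs to.
#' @param unit_ms Base unit duration in milliseconds.
#' @return An object of class \code{"rhythm_spec"}.
#' @examples
#' rhythm_spec(c(1, 1, 2, 3, 1, 4), "strong", set_ids = c(1, 3))
#' @export
rhythm_spec <- function(intervals, condition = c("strong", "weak", "non"),
                        set_ids = integer(), unit_ms = 250) {
  condition <- match.arg(condition)
  if (!length(intervals) %in% c(6L, 7L))
    stop("a rhythm has six or seven intervals, got ", length(intervals))
  allowed <- if (condition == "non") c(1, 1.4, 3.6, 4) else c(1, 2, 3, 4)
  if (!all(intervals %in% allowed))
    stop(sprintf("'%s' rhythms may only use multipliers {%s}",
                 condition, paste(allowed, collapse = ", ")))
  if (condition != "non" && sum(intervals) != 12)
    stop("strong/weak rhythm multipliers must sum to 12 units, got ",
         sum(intervals))
  structure(
    list(intervals = as.numeric(intervals), condition = condition,
         set_ids = sort(as.integer(set_ids)), unit_ms = unit_ms),
    class = "rhythm_spec")
}

#' @export
print.rhythm_spec <- function(x, ...) {
  cat(sprintf("<rhythm_spec> %s-beat  [%s]  (%g units = %g ms; sets %s)\n",
              x$condition, paste(x$intervals, collapse = " "),
              sum(x$intervals), sum(x$intervals) * x$unit_ms,
              if (length(x$set_ids)) paste(x$set_ids, collapse = ",") else "-"))
  invisible(x)
}

#' @export
format.rhythm_spec <- function(x, ...) paste(x$intervals, collapse = " ")

# The full experimental stimulus table: 24 unique rhythms, 8 per beat
# strength condition, arranged in four counterbalanced sets so that each
# set holds 4 rhythms per condition and every rhythm appears in exactly
# two sets.
.rhythm_rows <- list(
  strong = list(
    list(c(1, 1, 1, 1, 4, 3, 1), c(1L, 3L)),
    list(c(2, 1, 1, 2, 2, 3, 1), c(1L, 4L)),
    list(c(1, 1, 2, 3, 1, 4),    c(1L, 3L)),
    list(c(2, 2, 1, 3, 3, 1),    c(1L, 4L)),
    list(c(2, 1, 1, 3, 1, 1, 3), c(2L, 3L)),
    list(c(3, 1, 4, 1, 1, 1, 1), c(2L, 4L)),
    list(c(3, 1, 2, 2, 1, 3),    c(2L, 4L)),
    list(c(3, 1, 1, 3, 2, 2),    c(2L, 3L))),
  weak = list(
    list(c(1, 4, 1, 1, 3, 1, 1), c(1L, 4L)),
    list(c(1, 1, 3, 2, 2, 1, 2), c(1L, 3L)),
    list(c(1, 2, 2, 1, 4, 2),    c(1L, 3L)),
    list(c(2, 3, 1, 1, 2, 3),    c(1L, 4L)),
    list(c(2, 3, 3, 1, 1, 1, 1), c(2L, 4L)),
    list(c(2, 1, 4, 1, 2, 1, 1), c(2L, 3L)),
    list(c(3, 2, 3, 2, 1, 1),    c(2L, 3L)),
    list(c(4, 1, 2, 2, 1, 2),    c(2L, 4L))),
  non = list(
    list(c(1, 3.6, 1, 4, 1, 1, 1),       c(1L, 3L)),
    list(c(1.4, 1, 1.4, 3.6, 1.4, 1, 1), c(1L, 4L)),
    list(c(1.4, 1, 4, 1.4, 1.4, 1),      c(1L, 4L)),
    list(c(1, 3.6, 1.4, 3.6, 1.4, 1),    c(1L, 3L)),
    list(c(3.6, 1, 1, 3.6, 1, 1.4, 1),   c(2L, 3L)),
    list(c(3.6, 1.4, 1.4, 1, 1, 1, 1.4), c(2L, 4L)),
    list(c(1.4, 1.4, 1, 1.4, 4, 1),      c(2L, 3L)),
    list(c(4, 1.4, 1, 3.6, 1, 1),        c(2L, 4L))))

#' The built-in rhythm stimulus table
#'
#' Returns the complete experimental stimulus set: 24 unique rhythms (8 per
#' beat strength condition) organized into four counterbalanced sets such
#' that each set contains four rhythms per condition and each rhythm belongs
#' to exactly two sets. Rhythms shared between sets are represented once,
#' with both set ids recorded.
#'
#' @param condition Optional filter, one or more of
#'   \code{c("strong", "weak", "non")}.
#' @param set_id Optional filter, keep rhythms belonging to this set.
#' @param unit_ms Base unit duration in milliseconds.
#' @return A list of \code{\link{rhythm_spec}} objects, class
#'   \code{"rhythm_table"}.
#' @examples
#' length(rhythm_table())                       # 24 unique rhythms
#' length(rhythm_table("strong", set_id = 1))   # 4 per condition per set
#' @export
rhythm_table <- function(condition = NULL, set_id = NULL, unit_ms = 250) {
  out <- list()
  for (cond in names(.rhythm_rows))
    for (row in .rhythm_rows[[cond]])
      out[[length(out) + 1L]] <-
        rhythm_spec(row[[1]], cond, set_ids = row[[2]], unit_ms = unit_ms)
  if (!is.null(condition))
    out <- Filter(function(r) r$condition %in% condition, out)
  if (!is.null(set_id))
    out <- Filter(function(r) set_id %in% r$set_ids, out)
  structure(out, class = "rhythm_table")
}

#' @export
print.rhythm_table <- function(x, ...) {
  cat(sprintf("<rhythm_table> %d rhythms\n", length(x)))
  for (r in x) print(r)
  invisible(x)
}

#' @export
as.data.frame.rhythm_table <- function(x, ...) {
  data.frame(
    condition = vapply(x, function(r) r$condition, character(1)),
    sets      = vapply(x, function(r) paste(r$set_ids, collapse = " "),
                       character(1)),
    intervals = vapply(x, format, character(1)),
    n_intervals = vapply(x, function(r) length(r$intervals), integer(1)),
    total_units = vapply(x, function(r) sum(r$intervals), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Write / read a stimulus table as delimited text
#'
#' @param x A \code{"rhythm_table"}.
#' @param path File path for the tab-separated table.
#' @return \code{read_stimulus_table} returns a \code{"rhythm_table"}.
#' @export
write_stimulus_table <- function(x, path) {
  utils::write.table(as.data.frame(x)[, c("sets", "condition", "intervals")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_table
#' @export
read_stimulus_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  out <- lapply(seq_len(nrow(df)), function(i)
    rhythm_spec(as.numeric(strsplit(df$intervals[i], " ")[[1]]),
                df$condition[i],
                set_ids = as.integer(strsplit(df$sets[i], " ")[[1]])))
  structure(out, class = "rhythm_table")
}

# ---- audio synthesis ---------------------------------------------------

ramp_envelope <- function(n, n_ramp) {
  env <- rep(1, n)
  n_ramp <- min(n_ramp, floor(n / 2))
  if (n_ramp > 1) {
    env[seq_len(n_ramp)] <- seq(0, 1, length.out = n_ramp)
    env[(n - n_ramp + 1):n] <- seq(1, 0, length.out = n_ramp)
  }
  env
}

new_audio_stimulus <- function(samples, sample_rate, onset_times_ms,
                               tone_durations_ms, duration_ms,
                               target_tone_indices = integer()) {
  structure(
    list(samples = samples, sample_rate = sample_rate,
         onset_times_ms = onset_times_ms,
         tone_durations_ms = tone_durations_ms,
         duration_ms = duration_ms,
         target_tone_indices = target_tone_indices),
    class = "audio_stimulus")
}

#' @export
print.audio_stimulus <- function(x, ...) {
  cat(sprintf(
    "<audio_stimulus> %.0f ms, %d tones, %g Hz sample rate%s\n",
    x$duration_ms, length(x$onset_times_ms), x$sample_rate,
    if (length(x$target_tone_indices))
      sprintf(", AM targets at tones %s",
              paste(x$target_tone_indices, collapse = ",")) else ""))
  invisible(x)
}

# Render a tone train: 500-Hz sine tones with linear on/off ramps, each tone
# filling its interval minus a constant silent gap that demarcates onsets.
render_tones <- function(onsets_ms, durs_ms, sample_rate, tone_hz, ramp_ms) {
  total_ms <- onsets_ms[length(onsets_ms)] + durs_ms[length(durs_ms)]
  n <- round(total_ms / 1000 * sample_rate)
  x <- numeric(n)
  n_ramp <- round(ramp_ms / 1000 * sample_rate)
  for (k in seq_along(onsets_ms)) {
    i0 <- round(onsets_ms[k] / 1000 * sample_rate)
    nd <- round(durs_ms[k] / 1000 * sample_rate)
    t <- (seq_len(nd) - 1) / sample_rate
    x[i0 + seq_len(nd)] <- sin(2 * pi * tone_hz * t) * ramp_envelope(nd, n_ramp)
  }
  list(samples = x, total_ms = total_ms)
}

#' Synthesize a short auditory rhythm
#'
#' One 500-Hz sine tone per interval: tone k starts at the k-th cumulative
#' onset and fills the interval minus a 40-ms silent gap that demarcates the
#' next onset. Tones carry linear on/off amplitude ramps. A closing tone of
#' the rhythm's shortest interval length (minus the gap) is appended after
#' the last interval so its onset marks the end of the final interval.
#'
#' @param spec A \code{\link{rhythm_spec}}.
#' @param tone_hz Carrier frequency of the tones, Hz.
#' @param ramp_ms Linear onset/offset ramp duration, ms.
#' @param gap_ms Silent gap ending each interval, ms.
#' @param sample_rate Audio sample rate in Hz (must exceed 2 * tone_hz).
#' @param append_final_tone Append the closing downbeat tone?
#' @return An \code{"audio_stimulus"}: waveform in [-1, 1] plus tone onset
#'   times (ms).
#' @examples
#' stim <- synthesize(rhythm_spec(c(1, 1, 2, 3, 1, 4), "strong"),
#'                    sample_rate = 11025)
#' tail(stim$onset_times_ms, 1)  # appended downbeat at 3000 ms
#' @export
synthesize <- function(spec, tone_hz = 500, ramp_ms = 8, gap_ms = 40,
                       sample_rate = 44100, append_final_tone = TRUE) {
  stopifnot(inherits(spec, "rhythm_spec"))
  if (sample_rate < 2 * tone_hz)
    stop("sample_rate must be at least twice the tone frequency")
  iv_ms <- spec$intervals * spec$unit_ms
  if (any(iv_ms <= gap_ms))
    stop("every interval must exceed the silent gap (", gap_ms, " ms)")
  if (append_final_tone) {
    final_ms <- min(spec$intervals) * spec$unit_ms
    onsets <- c(0, cumsum(iv_ms))
    durs <- c(iv_ms, final_ms) - gap_ms
  } else {
    onsets <- c(0, cumsum(iv_ms))[seq_along(iv_ms)]
    durs <- iv_ms - gap_ms
  }
  r <- render_tones(onsets, durs, sample_rate, tone_hz, ramp_ms)
  new_audio_stimulus(r$samples, sample_rate, onsets, durs, r$total_ms)
}

#' Synthesize a long (looped) rhythm
#'
#' Concatenates \code{n_loops} repetitions of the short rhythm seamlessly:
#' the closing downbeat tone is omitted between repetitions (the first tone
#' of the next repetition serves as the previous repetition's downbeat) and
#' appended only once, after the final repetition. Six loops of a 3-s
#' integer-ratio rhythm give the ~18-s stimuli used for EEG.
#'
#' @inheritParams synthesize
#' @param n_loops Number of repetitions (>= 1).
#' @return An \code{"audio_stimulus"}.
#' @export
synthesize_long <- function(spec, n_loops = 6, tone_hz = 500, ramp_ms = 8,
                            gap_ms = 40, sample_rate = 44100) {
  stopifnot(inherits(spec, "rhythm_spec"), n_loops >= 1)
  looped <- spec
  looped$intervals <- rep(spec$intervals, n_loops)
  # bypass the 6/7-interval and 12-unit checks for the concatenated pattern
  iv_ms <- looped$intervals * spec$unit_ms
  if (any(iv_ms <= gap_ms))
    stop("every interval must exceed the silent gap (", gap_ms, " ms)")
  if (sample_rate < 2 * tone_hz)
    stop("sample_rate must be at least twice the tone frequency")
  final_ms <- min(spec$intervals) * spec$unit_ms
  onsets <- c(0, cumsum(iv_ms))
  durs <- c(iv_ms, final_ms) - gap_ms
  r <- render_tones(onsets, durs, sample_rate, tone_hz, ramp_ms)
  new_audio_stimulus(r$samples, sample_rate, onsets, durs, r$total_ms)
}

#' Amplitude-modulate target tones
#'
#' Marks \code{n_targets} distinct tones as detection targets by multiplying
#' them with a raised-cosine amplitude modulation
#' \code{1 - depth/2 + depth/2 * cos(2*pi*am_hz*t)} measured from each
#' tone's onset (100\% depth at \code{depth = 1}). Gaps are untouched.
#'
#' @param stim An \code{"audio_stimulus"}.
#' @param n_targets Number of target tones, between 1 and 4.
#' @param am_hz Modulation frequency, Hz.
#' @param depth Modulation depth in [0, 1].
#' @param seed Optional integer seed making target selection reproducible.
#' @return The stimulus with modulated tones and
#'   \code{target_tone_indices} recording which tones were chosen.
#' @export
add_am_targets <- function(stim, n_targets, am_hz = 40, depth = 1.0,
                           seed = NULL) {
  stopifnot(inherits(stim, "audio_stimulus"))
  if (n_targets < 1 || n_targets > 4)
    stop("n_targets must lie in [1, 4]")
  n_tones <- length(stim$onset_times_ms)
  if (n_targets > n_tones)
    stop("stimulus has fewer tones than requested targets")
  idx <- with_seed(seed, sort(sample.int(n_tones, n_targets)))
  sr <- stim$sample_rate
  for (k in idx) {
    i0 <- round(stim$onset_times_ms[k] / 1000 * sr)
    nd <- round(stim$tone_durations_ms[k] / 1000 * sr)
    t <- (seq_len(nd) - 1) / sr
    am <- 1 - depth / 2 + depth / 2 * cos(2 * pi * am_hz * t)
    stim$samples[i0 + seq_len(nd)] <- stim$samples[i0 + seq_len(nd)] * am
  }
  stim$target_tone_indices <- idx
  stim
}

# ---- WAV I/O -----------------------------------------------------------

#' Write a mono 16-bit PCM WAV file
#'
#' @param stim An \code{"audio_stimulus"} (or numeric vector via
#'   \code{samples}/\code{sample_rate}).
#' @param path Output file path.
#' @param sidecar Also write \code{<path>.csv} with tone onset times and
#'   target flags?
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(stim, path, sidecar = FALSE) {
  samples <- stim$samples
  sr <- as.integer(stim$sample_rate)
  pcm <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_bytes, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(c(16L, 1L + 65536L), con, size = 4, endian = "little") # fmt len; PCM, mono
  writeBin(c(sr, sr * 2L), con, size = 4, endian = "little")      # rate, byte rate
  writeBin(c(2L + 16L * 65536L), con, size = 4, endian = "little") # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  if (sidecar) {
    df <- data.frame(tone = seq_along(stim$onset_times_ms),
                     onset_ms = stim$onset_times_ms,
                     duration_ms = stim$tone_durations_ms,
                     is_target = seq_along(stim$onset_times_ms) %in%
                       stim$target_tone_indices)
    utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Minimal reader for files produced by \code{\link{write_wav}}.
#'
#' @param path WAV file path.
#' @return List with \code{samples} (numeric in [-1, 1]) and
#'   \code{sample_rate}.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) stop("not a RIFF/WAVE file")
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a RIFF/WAVE file")
  sr <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    len <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, raw(), len)
      sr <- readBin(fmt_raw[5:8], integer(), 1, size = 4, endian = "little")
    } else if (identical(id, "data")) {
      pcm <- readBin(con, integer(), len / 2, size = 2, endian = "little")
      return(list(samples = pcm / 32767, sample_rate = sr))
    } else {
      invisible(readBin(con, raw(), len))
    }
  }
}
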
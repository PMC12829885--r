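# Amplitude spectra: the common container for stimulus-envelope spectra and
# EEG spectra, plus the zero-padded FFT that realizes a fixed frequency
# resolution (0.0125 Hz by default, i.e. an 80-s analysis window) from
# shorter epochs.

new_spectrum <- function(freqs, amplitude, resolution, n_signal,
                         sample_rate, source = NA_character_,
                         denoised = FALSE, aperiodic_a = NA_real_,
                         aperiodic_b = NA_real_) {
  structure(
    list(freqs = freqs, amplitude = amplitude, resolution = resolution,
         n_signal = n_signal, sample_rate = sample_rate, source = source,
         denoised = denoised, aperiodic_a = aperiodic_a,
         aperiodic_b = aperiodic_b),
    class = "amplitude_spectrum")
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  nch <- if (is.matrix(x$amplitude)) ncol(x$amplitude) else 1L
  cat(sprintf(
    "<amplitude_spectrum> %d bins (%g-%g Hz, res %g Hz), %d channel%s%s%s\n",
    NROW(x$amplitude), min(x$freqs), max(x$freqs), x$resolution, nch,
    if (nch > 1) "s" else "",
    if (!is.na(x$source)) paste0(", source: ", x$source) else "",
    if (isTRUE(x$denoised))
      sprintf(", denoised (a=%.4g, b=%.4g)", x$aperiodic_a, x$aperiodic_b)
    else ""))
  invisible(x)
}

#' Zero-padded FFT amplitude spectrum at fixed frequency resolution
#'
#' The mean-removed series is zero-padded to an effective analysis window of
#' \code{1/resolution} seconds (80 s at the 0.0125-Hz default) and Fourier
#' transformed. Amplitudes are scaled by \code{2/N} with \code{N} the
#' unpadded signal length, so a sinusoid of unit amplitude whose frequency
#' lies on the grid reads ~1 at its bin.
#'
#' @param x Numeric vector (one series) or a channels x samples matrix.
#' @param sample_rate Sampling rate, Hz.
#' @param resolution Frequency-grid spacing in Hz; must divide the sample
#'   rate and 1 Hz exactly so the grid contains the integer frequencies of
#'   interest. \code{NULL} requests the native (unpadded) grid with spacing
#'   \code{sample_rate / length(x)}: its bins are mutually orthogonal, so a
#'   sinusoid completing an integer number of cycles leaks nothing into the
#'   other native bins (used for the aperiodic background fit).
#' @param fmax Highest frequency retained, Hz.
#' @param source Optional label carried in the result.
#' @return An \code{"amplitude_spectrum"}; \code{amplitude} is a vector, or
#'   a bins x channels matrix for matrix input.
#' @examples
#' t <- seq(0, 6 - 1/256, by = 1/256)
#' sp <- amplitude_spectrum(cos(2 * pi * t), sample_rate = 256)
#' sp$amplitude[sp$freqs == 1]  # ~1
#' @export
amplitude_spectrum <- function(x, sample_rate, resolution = 0.0125,
                               fmax = 30, source = NA_character_) {
  xm <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  n <- ncol(xm)
  if (is.null(resolution)) {
    resolution <- sample_rate / n
    n_pad <- n
  } else {
    n_pad <- resolution_nfft(sample_rate, resolution)
  }
  if (n > n_pad)
    stop("signal longer than the analysis window implied by the resolution")
  fmax <- min(fmax, sample_rate / 2)
  n_bins <- floor(fmax / resolution + 1e-9) + 1L
  freqs <- (seq_len(n_bins) - 1) * resolution
  xm <- xm - rowMeans(xm)
  padded <- rbind(t(xm), matrix(0, n_pad - n, nrow(xm)))
  amp <- 2 / n * Mod(stats::mvfft(padded)[seq_len(n_bins), , drop = FALSE])
  if (!is.matrix(x)) amp <- drop(amp)
  new_spectrum(freqs, amp, resolution, n, sample_rate, source = source)
}

#' Hilbert envelope of a waveform
#'
#' Magnitude of the analytic signal, computed with the FFT method (positive
#' frequencies doubled, negative zeroed). The transform length is padded to
#' the next 2-3-5-smooth number for speed and truncated back.
#'
#' @param x Numeric waveform.
#' @return Nonnegative envelope, same length as \code{x}.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  nf <- stats::nextn(n, c(2, 3, 5))
  X <- padded_fft(x, nf)
  h <- numeric(nf)
  h[1] <- 1
  h[nf / 2 + 1] <- 1
  h[2:(nf / 2)] <- 2
  Mod(stats::fft(X * h, inverse = TRUE) / nf)[seq_len(n)]
}

#' Envelope amplitude spectrum of an auditory stimulus
#'
#' FFT amplitude of the mean-removed Hilbert envelope of the waveform --
#' the slow amplitude modulation whose spectral peaks define the
#' stimulus-driven frequencies of interest.
#'
#' @param stim An \code{"audio_stimulus"} (or numeric waveform).
#' @param sample_rate Required when \code{stim} is a bare vector.
#' @param resolution Frequency-grid spacing, Hz.
#' @param fmax Highest frequency retained, Hz.
#' @return An \code{"amplitude_spectrum"} over [0, fmax].
#' @export
envelope_spectrum <- function(stim, sample_rate = NULL, resolution = 0.0125,
                              fmax = 10) {
  if (inherits(stim, "audio_stimulus")) {
    x <- stim$samples
    sample_rate <- stim$sample_rate
  } else {
    x <- as.numeric(stim)
    if (is.null(sample_rate)) stop("sample_rate required for a bare waveform")
  }
  if (!length(x)) stop("empty stimulus")
  amplitude_spectrum(hilbert_envelope(x), sample_rate, resolution,
                     fmax = fmax, source = "envelope")
}

#' Average amplitude spectra on a common grid
#'
#' Pointwise mean of amplitude spectra after linear interpolation onto a
#' common frequency grid (needed when inputs differ in native grid, e.g.
#' looped rhythms of unequal duration analysed at their own resolution).
#' Spectra already sharing \code{grid} are averaged directly.
#'
#' @param spectra List of \code{"amplitude_spectrum"} objects.
#' @param grid Target frequency grid; defaults to the first spectrum's grid.
#' @return An \code{"amplitude_spectrum"} on \code{grid}.
#' @export
average_spectra <- function(spectra, grid = NULL) {
  stopifnot(length(spectra) >= 1)
  if (is.null(grid)) grid <- spectra[[1]]$freqs
  vals <- vapply(spectra, function(sp) {
    a <- if (is.matrix(sp$amplitude)) rowMeans(sp$amplitude) else sp$amplitude
    if (length(sp$freqs) == length(grid) &&
        isTRUE(all.equal(sp$freqs, grid, tolerance = 1e-9))) return(a)
    if (min(grid) < min(sp$freqs) - 1e-9 || max(grid) > max(sp$freqs) + 1e-9)
      stop("grid extends outside a spectrum's frequency support")
    stats::approx(sp$freqs, a, xout = grid)$y
  }, numeric(length(grid)))
  new_spectrum(grid, rowMeans(vals), spectra[[1]]$resolution,
               NA_integer_, spectra[[1]]$sample_rate,
               source = spectra[[1]]$source)
}

#' Frequency of the largest spectral peak within a band
#'
#' Returns the grid frequency of the maximal amplitude inside \code{band}
#' (DC excluded by the default lower edge). Ties break toward the lower
#' frequency.
#'
#' @param spectrum An \code{"amplitude_spectrum"}.
#' @param band Frequency interval searched, Hz.
#' @return Peak frequency in Hz.
#' @export
peak_frequency <- function(spectrum, band = c(0.5, 8)) {
  a <- if (is.matrix(spectrum$amplitude)) rowMeans(spectrum$amplitude)
       else spectrum$amplitude
  sel <- spectrum$freqs >= band[1] - 1e-9 & spectrum$freqs <= band[2] + 1e-9
  if (!any(sel)) stop("band contains no frequency bins")
  spectrum$freqs[sel][which.max(a[sel])]
}

#' Stimulus-driven frequencies of interest per condition
#'
#' Synthesizes the long looped stimuli for each beat strength condition,
#' averages their envelope amplitude spectra, and reads the peak frequency
#' in \code{band}; the 1-Hz beat frequency is common to all conditions.
#'
#' @param sample_rate Audio sample rate used for synthesis, Hz.
#' @param resolution Spectral grid spacing, Hz.
#' @param band Peak-search band, Hz.
#' @param n_loops Loop count for the long stimuli.
#' @return Data frame with condition, beat and stimulus frequencies (Hz);
#'   stimulus peaks are reported to two decimals.
#' @examples
#' \donttest{derive_foi(sample_rate = 11025)}
#' @export
derive_foi <- function(sample_rate = 44100, resolution = 0.0125,
                       band = c(0.5, 8), n_loops = 6) {
  conds <- c("strong", "weak", "non")
  peaks <- vapply(conds, function(cond) {
    specs <- lapply(rhythm_table(condition = cond), function(r)
      envelope_spectrum(synthesize_long(r, n_loops = n_loops,
                                        sample_rate = sample_rate),
                        resolution = resolution))
    peak_frequency(average_spectra(specs), band = band)
  }, numeric(1))
  data.frame(condition = conds, beat_hz = 1,
             stimulus_hz = round(peaks, 2), row.names = NULL)
}
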
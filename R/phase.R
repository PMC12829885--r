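# Intertrial phase coherence: per-trial complex spectra at a frequency of
# interest, averaged across channels as complex values (amplitude-weighted),
# then the resultant vector length of the per-trial phase angles.

#' Per-trial phase at a frequency of interest
#'
#' For each trial the complex spectrum is evaluated per channel with the
#' same convention as the amplitude pipeline (mean removal, zero-padded
#' grid, so phase is referenced to a cosine at trial start), channels are
#' averaged as complex values, and the phase angle at the grid bin nearest
#' \code{foi} is returned. Trials whose channel-averaged complex value is
#' numerically zero (antiphase cancellation across channels) have no
#' defined phase and are flagged.
#'
#' @param epochs An \code{"epoched_eeg"}.
#' @param foi Frequency of interest, Hz (below Nyquist).
#' @param resolution Frequency-grid spacing, Hz.
#' @return List with \code{phase} (radians, NA where undefined),
#'   \code{magnitude} (modulus of the channel-averaged complex spectrum,
#'   2/N-scaled), \code{defined} (logical), and \code{foi_grid} (the grid
#'   frequency actually evaluated).
#' @export
single_trial_phase <- function(epochs, foi, resolution = 0.0125) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  d <- dim(epochs$data)
  if (d[1] == 0) stop("no trials")
  if (foi >= epochs$sample_rate / 2) stop("foi must be below Nyquist")
  n_pad <- resolution_nfft(epochs$sample_rate, resolution)
  n <- d[3]
  if (n > n_pad)
    stop("trials longer than the analysis window implied by the resolution")
  k <- foi / resolution
  klo <- floor(k + 1e-9)
  kbin <- if (k - klo <= (klo + 1) - k + 1e-12) klo else klo + 1  # ties lower
  foi_grid <- kbin * resolution
  # evaluating the padded-FFT bin directly: zeros contribute nothing
  w <- exp(-2i * pi * foi_grid * (0:(n - 1)) / epochs$sample_rate)
  phase <- magnitude <- numeric(d[1])
  for (i in seq_len(d[1])) {
    x <- epochs$data[i, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    z <- (x - rowMeans(x)) %*% w        # per-channel complex spectrum at foi
    zbar <- mean(z) * 2 / n             # complex channel average
    magnitude[i] <- Mod(zbar)
    phase[i] <- Arg(zbar)
  }
  rms <- sqrt(mean(epochs$data^2))
  defined <- magnitude >= 1e-12 * max(rms, .Machine$double.eps)
  phase[!defined] <- NA_real_
  list(phase = phase, magnitude = magnitude, defined = defined,
       foi_grid = foi_grid)
}

#' Intertrial phase coherence (resultant vector length)
#'
#' The modulus of the mean unit phasor across trials: 1 when all phases
#' coincide, near 0 for uniformly scattered phases. Undefined (NA) phases
#' are dropped with a count.
#'
#' @param phases Numeric vector of per-trial phase angles, radians (or the
#'   list returned by \code{\link{single_trial_phase}}).
#' @param foi Optional frequency carried in the result, Hz.
#' @return An object of class \code{"itpc_result"}: \code{r} in [0, 1],
#'   \code{mean_angle} in (-pi, pi], \code{n_trials},
#'   \code{n_undefined}, \code{foi}.
#' @examples
#' itpc(rep(0.3, 10))$r                    # 1: identical phases
#' itpc(c(0, pi/2, pi, 3*pi/2))$r          # 0: symmetric cancellation
#' @export
itpc <- function(phases, foi = NA_real_) {
  if (is.list(phases)) {
    if (!is.na(phases$foi_grid) && is.na(foi)) foi <- phases$foi_grid
    phases <- phases$phase
  }
  n_undefined <- sum(is.na(phases))
  phases <- phases[!is.na(phases)]
  if (length(phases) < 2)
    stop("at least two defined phases are required")
  zbar <- mean(exp(1i * phases))
  structure(list(r = Mod(zbar), mean_angle = Arg(zbar),
                 n_trials = length(phases), n_undefined = n_undefined,
                 foi = foi),
            class = "itpc_result")
}

#' @export
print.itpc_result <- function(x, ...) {
  cat(sprintf(
    "<itpc> r = %.4f, mean angle = %.3f rad, n = %d%s%s\n",
    x$r, x$mean_angle, x$n_trials,
    if (x$n_undefined > 0) sprintf(" (%d undefined dropped)", x$n_undefined)
    else "",
    if (!is.na(x$foi)) sprintf(", foi = %g Hz", x$foi) else ""))
  invisible(x)
}

#' Intertrial phase coherence per analysis cell
#'
#' Applies the same trial rejection as the amplitude pipeline, computes
#' per-trial channel-averaged phases at \code{foi}, and returns the
#' resultant vector length per cell of the label crossing.
#'
#' @inheritParams freqtag
#' @param foi Frequency of interest, Hz.
#' @return Data frame with one row per cell: labels, \code{foi_hz},
#'   \code{n_trials_itpc}, \code{n_undefined}, \code{r},
#'   \code{mean_angle}.
#' @export
itpc_by_cell <- function(epochs, foi = 1, resolution = 0.0125,
                         reject_uv = 300,
                         by = c("condition", "session", "set")) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  by <- intersect(by, names(epochs$labels))
  if (!length(by)) stop("no grouping labels found in the epochs")
  key <- epochs$labels[, by, drop = FALSE]
  cells <- unique(key)
  rownames(cells) <- NULL
  trial_labels <- cell_label(key)
  labels <- cell_label(cells)
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    cell_epochs <- subset_trials(epochs, trial_labels == labels[r])
    if (is.finite(reject_uv)) cell_epochs <- reject_trials(cell_epochs, reject_uv)
    if (dim(cell_epochs)[1] < 2)
      return(data.frame(cells[r, , drop = FALSE], foi_hz = foi,
                        n_trials_itpc = dim(cell_epochs)[1],
                        n_undefined = NA_integer_, r = NA_real_,
                        mean_angle = NA_real_, row.names = NULL))
    res <- itpc(single_trial_phase(cell_epochs, foi, resolution), foi = foi)
    data.frame(cells[r, , drop = FALSE], foi_hz = foi,
               n_trials_itpc = res$n_trials, n_undefined = res$n_undefined,
               r = res$r, mean_angle = res$mean_angle, row.names = NULL)
  })
  do.call(rbind, rows)
}
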
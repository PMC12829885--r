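# The frequency-tagging pipeline. Per condition/session/set cell:
# amplitude-based trial rejection -> time-domain averaging (isolates
# phase-locked activity) -> per-channel zero-padded FFT amplitude spectra at
# 0.0125-Hz resolution -> channel averaging -> exponential aperiodic fit
# a * b^f over 0.5-6 Hz (frequencies of interest and their harmonics
# excluded) -> subtraction -> amplitude read-out at the frequencies of
# interest. `freqtag()` wraps the whole pipeline as a model fit.

#' Reject high-amplitude trials
#'
#' Removes every trial in which any channel's within-trial peak-to-peak
#' range exceeds \code{threshold} microvolts (the conventional reading of a
#' channel "fluctuating more than" the threshold).
#'
#' @param epochs An \code{"epoched_eeg"}.
#' @param threshold Peak-to-peak rejection threshold, microvolts.
#' @return The retained trials, with attributes \code{retained_fraction}
#'   and \code{n_rejected}. May contain zero trials; downstream averaging
#'   refuses empty input.
#' @export
reject_trials <- function(epochs, threshold = 300) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  d <- dim(epochs$data)
  if (d[1] == 0) stop("no trials to screen")
  p2p <- apply(epochs$data, c(1, 2), function(v) max(v) - min(v))
  keep <- apply(p2p <= threshold, 1, all)
  out <- subset_trials(epochs, keep)
  attr(out, "retained_fraction") <- mean(keep)
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Average trials in the time domain
#'
#' Pointwise mean across trials, per channel. Time-domain averaging before
#' the FFT isolates activity phase-locked to the stimulus from
#' non-phase-locked activity.
#'
#' @param epochs An \code{"epoched_eeg"}.
#' @param which Optional trial subset (indices or logical); default all.
#' @return channels x samples matrix.
#' @export
average_trials <- function(epochs, which = NULL) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  if (!is.null(which)) epochs <- subset_trials(epochs, which)
  if (dim(epochs$data)[1] == 0) stop("no trials to average")
  colMeans(epochs$data)  # mean over the trial dimension -> channels x samples
}

#' Average an amplitude spectrum across channels
#'
#' Pointwise mean of the per-channel amplitude (not complex) spectra.
#'
#' @param spectrum An \code{"amplitude_spectrum"} whose amplitude is a
#'   bins x channels matrix (or a list of single-channel spectra sharing
#'   one grid).
#' @return A single-channel \code{"amplitude_spectrum"}.
#' @export
average_channels <- function(spectrum) {
  if (is.list(spectrum) && !inherits(spectrum, "amplitude_spectrum")) {
    ref <- spectrum[[1]]
    for (sp in spectrum)
      if (!isTRUE(all.equal(sp$freqs, ref$freqs, tolerance = 1e-12)))
        stop("channel spectra must share one frequency grid")
    amp <- rowMeans(vapply(spectrum, function(sp) sp$amplitude,
                           numeric(length(ref$freqs))))
    out <- ref
    out$amplitude <- amp
    return(out)
  }
  stopifnot(inherits(spectrum, "amplitude_spectrum"))
  if (is.matrix(spectrum$amplitude))
    spectrum$amplitude <- rowMeans(spectrum$amplitude)
  spectrum
}

# Frequencies excluded from the aperiodic fit: each frequency of interest
# and its harmonics up to the top of the band.
foi_exclusions <- function(foi, band) {
  ex <- unlist(lapply(foi, function(f0) f0 * seq_len(floor(band[2] / f0))))
  sort(unique(ex[ex >= band[1] & ex <= band[2]]))
}

#' Fit the exponential aperiodic background
#'
#' Least-squares fit of \code{amplitude(f) ~ a * b^f} in linear amplitude
#' space over \code{band}, excluding bins within \code{exclude_halfwidth}
#' of each frequency of interest and its harmonics so periodic peaks do not
#' bias the fit. The fit is started from a log-linear regression on the
#' positive amplitudes and refined with bound-constrained
#' quasi-Newton least squares (\code{b} constrained to (0, 1]).
#'
#' The fit is performed on whatever grid the supplied spectrum carries.
#' \code{\link{freqtag}} fits on the native (unpadded) grid, whose bins are
#' orthogonal: phase-locked sinusoids completing whole cycles in the epoch
#' contribute exactly zero there, so their zero-padding leakage skirt
#' cannot inflate the background estimate. The fitted curve is then
#' subtracted from the padded fine-grid spectrum.
#'
#' @param spectrum A channel-averaged, not yet denoised
#'   \code{"amplitude_spectrum"}.
#' @param band Fit interval, Hz.
#' @param foi Frequencies of interest whose neighbourhoods are excluded.
#' @param exclude_halfwidth Half-width of each exclusion window, Hz.
#' @return Named numeric vector \code{c(a = , b = )}: amplitude intercept
#'   (microvolts) and decay factor per Hz.
#' @export
fit_aperiodic <- function(spectrum, band = c(0.5, 6), foi = c(1, 4, 3.34),
                          exclude_halfwidth = 0.05) {
  stopifnot(inherits(spectrum, "amplitude_spectrum"))
  if (isTRUE(spectrum$denoised)) stop("spectrum is already denoised")
  if (is.matrix(spectrum$amplitude))
    stop("average across channels before fitting the background")
  f <- spectrum$freqs
  if (band[1] < min(f) - 1e-9 || band[2] > max(f) + 1e-9)
    stop("fit band extends outside the frequency grid")
  sel <- f >= band[1] - 1e-9 & f <= band[2] + 1e-9
  for (f0 in foi_exclusions(foi, band))
    sel <- sel & abs(f - f0) > exclude_halfwidth + 1e-9
  x <- f[sel]
  y <- spectrum$amplitude[sel]
  if (all(y <= 0))
    stop("no positive amplitudes in the fit band; cannot fit a decaying background")
  pos <- y > 0
  cf <- stats::coef(stats::lm(log(y[pos]) ~ x[pos]))
  start <- c(a = unname(exp(cf[1])),
             b = unname(min(max(exp(cf[2]), 1e-6), 1)))
  obj <- function(p) sum((y - p[1] * p[2]^x)^2)
  grad <- function(p) {
    r <- y - p[1] * p[2]^x
    c(-2 * sum(r * p[2]^x), -2 * sum(r * p[1] * x * p[2]^(x - 1)))
  }
  fit <- stats::optim(start, obj, grad, method = "L-BFGS-B",
                      lower = c(0, 1e-8), upper = c(Inf, 1),
                      control = list(maxit = 500, factr = 10))
  c(a = unname(fit$par[1]), b = unname(fit$par[2]))
}

#' Subtract the fitted aperiodic background
#'
#' Removes \code{a * b^f} from every bin, flattening the spectrum so that
#' periodic signals remain as peaks above 0 microvolts. Negative residual
#' amplitudes are retained (mild overcorrection away from periodic peaks is
#' expected and diagnostic).
#'
#' @param spectrum A channel-averaged \code{"amplitude_spectrum"}.
#' @param a,b Aperiodic coefficients from \code{\link{fit_aperiodic}}.
#' @return The denoised spectrum, with \code{denoised = TRUE} and the
#'   coefficients stored.
#' @export
subtract_aperiodic <- function(spectrum, a, b) {
  stopifnot(inherits(spectrum, "amplitude_spectrum"),
            is_scalar_number(a), is_scalar_number(b))
  spectrum$amplitude <- spectrum$amplitude - a * b^spectrum$freqs
  spectrum$denoised <- TRUE
  spectrum$aperiodic_a <- a
  spectrum$aperiodic_b <- b
  spectrum
}

#' Amplitude at a frequency of interest
#'
#' Reads the amplitude at the grid bin nearest \code{foi} (exact bin for
#' on-grid frequencies such as 1 and 4 Hz; nearest bin, ties toward the
#' lower frequency, for off-grid frequencies such as 3.34 Hz on a 0.0125-Hz
#' grid).
#'
#' @param spectrum An \code{"amplitude_spectrum"} (typically denoised).
#' @param foi Frequency of interest, Hz.
#' @return Amplitude in microvolts.
#' @export
foi_amplitude <- function(spectrum, foi) {
  stopifnot(inherits(spectrum, "amplitude_spectrum"), is_scalar_number(foi))
  if (!is.na(spectrum$sample_rate) && foi > spectrum$sample_rate / 2)
    stop("frequency of interest above the Nyquist frequency")
  if (foi > max(spectrum$freqs) + 1e-9 || foi < min(spectrum$freqs) - 1e-9)
    stop("frequency of interest outside the spectral grid")
  a <- if (is.matrix(spectrum$amplitude)) rowMeans(spectrum$amplitude)
       else spectrum$amplitude
  a[which.min(abs(spectrum$freqs - foi))]
}

# ---- the model-fitting wrapper ----------------------------------------

cell_label <- function(df)
  do.call(paste, c(as.list(df), sep = "/"))

#' Fit the frequency-tagging model to epoched EEG
#'
#' Runs the full spectral pipeline per cell of the crossing of the label
#' columns in \code{by}: trial rejection, time-domain averaging, per-channel
#' zero-padded FFT amplitude spectra, channel averaging, exponential
#' aperiodic fit and subtraction, and amplitude extraction at each
#' frequency of interest. The aperiodic model \code{a * b^f} is the fitted
#' component: \code{coef} returns its coefficients per cell,
#' \code{predict} evaluates it, and \code{residuals} are the denoised
#' spectra.
#'
#' @param epochs An \code{"epoched_eeg"} of cleaned trials.
#' @param foi Frequencies of interest, Hz (default: 1-Hz beat frequency and
#'   the stimulus-driven 4 and 3.34 Hz).
#' @param resolution Spectral grid spacing, Hz.
#' @param band Aperiodic fit band, Hz.
#' @param reject_uv Peak-to-peak trial-rejection threshold, microvolts;
#'   \code{Inf} disables rejection.
#' @param denoise Subtract the fitted aperiodic background before the FOI
#'   read-out?
#' @param exclude_halfwidth Exclusion half-width around each FOI and its
#'   harmonics in the aperiodic fit, Hz.
#' @param fmax Highest frequency retained in the spectra, Hz.
#' @param by Label columns defining the analysis cells (missing columns are
#'   ignored).
#' @return An object of class \code{"freqtag"}; see
#'   \code{\link{condition_table}} for a tidy export.
#' @examples
#' eeg <- generate_dataset(synth_config(n_trials = 4, seed = 42))
#' fit <- freqtag(eeg, foi = c(1, 4))
#' coef(fit)
#' summary(fit)
#' @export
freqtag <- function(epochs, foi = c(1, 4, 3.34), resolution = 0.0125,
                    band = c(0.5, 6), reject_uv = 300, denoise = TRUE,
                    exclude_halfwidth = 0.05, fmax = 30,
                    by = c("condition", "session", "set")) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  by <- intersect(by, names(epochs$labels))
  if (!length(by)) stop("no grouping labels found in the epochs")
  key <- epochs$labels[, by, drop = FALSE]
  cells <- unique(key)
  rownames(cells) <- NULL
  n_cells <- nrow(cells)
  labels <- cell_label(cells)
  amp <- matrix(NA_real_, n_cells, length(foi),
                dimnames = list(labels, paste0(foi, "Hz")))
  ab <- matrix(NA_real_, n_cells, 2, dimnames = list(labels, c("a", "b")))
  n_trials <- n_rejected <- integer(n_cells)
  spectra <- vector("list", n_cells)
  names(spectra) <- labels
  trial_labels <- cell_label(key)
  for (r in seq_len(n_cells)) {
    cell_epochs <- subset_trials(epochs, trial_labels == labels[r])
    if (is.finite(reject_uv)) {
      cell_epochs <- reject_trials(cell_epochs, reject_uv)
      n_rejected[r] <- attr(cell_epochs, "n_rejected")
    }
    n_trials[r] <- dim(cell_epochs)[1]
    if (n_trials[r] == 0) next  # explicit empty cell: NA amplitudes
    avg <- average_trials(cell_epochs)
    raw <- average_channels(
      amplitude_spectrum(avg, epochs$sample_rate, resolution, fmax = fmax,
                         source = labels[r]))
    if (denoise) {
      native <- average_channels(
        amplitude_spectrum(avg, epochs$sample_rate, resolution = NULL,
                           fmax = fmax, source = labels[r]))
      co <- fit_aperiodic(native, band = band, foi = foi,
                          exclude_halfwidth = exclude_halfwidth)
      den <- subtract_aperiodic(raw, co["a"], co["b"])
      ab[r, ] <- co
    } else {
      den <- raw
    }
    amp[r, ] <- vapply(foi, function(f0) foi_amplitude(den, f0), numeric(1))
    spectra[[r]] <- list(raw = raw, denoised = if (denoise) den else NULL)
  }
  structure(
    list(cells = cbind(cells,
                       data.frame(n_trials = n_trials,
                                  n_rejected = n_rejected,
                                  a = ab[, "a"], b = ab[, "b"],
                                  row.names = NULL)),
         amplitude = amp, spectra = spectra, foi = foi, band = band,
         resolution = resolution, by = by,
         settings = list(reject_uv = reject_uv, denoise = denoise,
                         exclude_halfwidth = exclude_halfwidth, fmax = fmax),
         call = match.call()),
    class = "freqtag")
}

#' @export
print.freqtag <- function(x, ...) {
  cat("Frequency-tagging fit\n\nCall:\n  ")
  print(x$call)
  cat(sprintf("\n%d cell(s) by %s; FOI: %s Hz; aperiodic band %g-%g Hz%s\n",
              nrow(x$cells), paste(x$by, collapse = " x "),
              paste(x$foi, collapse = ", "), x$band[1], x$band[2],
              if (x$settings$denoise) " (denoised)" else ""))
  invisible(x)
}

#' @export
summary.freqtag <- function(object, ...) {
  out <- cbind(object$cells, object$amplitude)
  class(out) <- c("summary.freqtag", "data.frame")
  out
}

#' @export
print.summary.freqtag <- function(x, digits = 4, ...) {
  cat("Frequency-tagging summary (amplitudes in microvolts)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
coef.freqtag <- function(object, ...) {
  cbind(a = object$cells$a, b = object$cells$b) |>
    `rownames<-`(cell_label(object$cells[, object$by, drop = FALSE]))
}

#' Evaluate the fitted aperiodic background
#'
#' @param object A \code{"freqtag"} fit.
#' @param freq Frequencies (Hz) at which to evaluate \code{a * b^f};
#'   defaults to the spectral grid.
#' @param ... Unused.
#' @return freq x cells matrix of aperiodic amplitudes.
#' @export
predict.freqtag <- function(object, freq = NULL, ...) {
  if (is.null(freq)) {
    sp <- Filter(Negate(is.null), object$spectra)
    if (!length(sp)) stop("fit contains no spectra")
    freq <- sp[[1]]$raw$freqs
  }
  co <- coef(object)
  out <- vapply(seq_len(nrow(co)),
                function(r) co[r, "a"] * co[r, "b"]^freq,
                numeric(length(freq)))
  dimnames(out) <- list(NULL, rownames(co))
  attr(out, "freq") <- freq
  out
}

#' @export
fitted.freqtag <- function(object, ...) predict(object)

#' Denoised spectra of a frequency-tagging fit
#'
#' The residuals of the aperiodic model: observed channel-averaged
#' amplitude minus the fitted \code{a * b^f}, per cell.
#'
#' @param object A \code{"freqtag"} fit (with \code{denoise = TRUE}).
#' @param ... Unused.
#' @return bins x cells matrix with frequency grid in attribute
#'   \code{"freq"}.
#' @export
residuals.freqtag <- function(object, ...) {
  sp <- object$spectra
  keep <- !vapply(sp, is.null, logical(1))
  if (!any(keep)) stop("fit contains no spectra")
  first <- sp[[which(keep)[1]]]
  grid <- first$raw$freqs
  out <- vapply(sp[keep], function(s) {
    if (!is.null(s$denoised)) s$denoised$amplitude
    else s$raw$amplitude
  }, numeric(length(grid)))
  attr(out, "freq") <- grid
  out
}

#' Plot a frequency-tagging fit
#'
#' Raw channel-averaged amplitude spectrum with the fitted aperiodic curve
#' (top) and the denoised spectrum (bottom) for selected cells.
#'
#' @param x A \code{"freqtag"} fit.
#' @param cells Cell indices or labels to draw (default: first cell).
#' @param xlim Frequency range shown, Hz.
#' @param ... Passed to \code{matplot}.
#' @export
plot.freqtag <- function(x, cells = 1, xlim = NULL, ...) {
  if (is.character(cells)) cells <- match(cells, names(x$spectra))
  if (is.null(xlim)) xlim <- c(max(0.25, x$band[1] / 2), x$band[2] + 2)
  op <- graphics::par(mfrow = c(length(cells), if (x$settings$denoise) 2 else 1),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (r in cells) {
    s <- x$spectra[[r]]
    if (is.null(s)) next
    f <- s$raw$freqs
    sel <- f >= xlim[1] & f <= xlim[2]
    graphics::plot(f[sel], s$raw$amplitude[sel], type = "l",
                   xlab = "Frequency (Hz)", ylab = "Amplitude (µV)",
                   main = paste("raw:", names(x$spectra)[r]), ...)
    graphics::lines(f[sel],
                    x$cells$a[r] * x$cells$b[r]^f[sel], col = 2, lwd = 2)
    if (x$settings$denoise) {
      graphics::plot(f[sel], s$denoised$amplitude[sel], type = "l",
                     xlab = "Frequency (Hz)", ylab = "Amplitude (µV)",
                     main = paste("denoised:", names(x$spectra)[r]), ...)
      graphics::abline(h = 0, col = "grey60")
      graphics::abline(v = x$foi, col = 4, lty = 3)
    }
  }
  invisible(x)
}

#' Tidy per-cell results table
#'
#' One record per cell and frequency of interest: labels, FOI, denoised
#' amplitude, trial counts and aperiodic coefficients, optionally joined
#' with intertrial phase coherence results. Cells with no retained trials
#' appear with NA amplitudes rather than being dropped.
#'
#' @param fit A \code{"freqtag"} fit.
#' @param itpc Optional data frame from \code{\link{itpc_by_cell}}.
#' @return A data frame.
#' @export
condition_table <- function(fit, itpc = NULL) {
  stopifnot(inherits(fit, "freqtag"))
  cells <- fit$cells
  out <- do.call(rbind, lapply(seq_along(fit$foi), function(j) {
    data.frame(cells[, fit$by, drop = FALSE],
               foi_hz = fit$foi[j],
               amplitude = fit$amplitude[, j],
               n_trials = cells$n_trials, n_rejected = cells$n_rejected,
               aperiodic_a = cells$a, aperiodic_b = cells$b,
               row.names = NULL)
  }))
  if (!is.null(itpc))
    out <- merge(out, itpc[, c(fit$by, "foi_hz", "n_trials_itpc", "r",
                               "mean_angle")],
                 by = c(fit$by, "foi_hz"), all.x = TRUE, sort = FALSE)
  out[order(out$foi_hz, cell_label(out[, fit$by, drop = FALSE])), ,
      drop = FALSE] |> `rownames<-`(NULL)
}
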
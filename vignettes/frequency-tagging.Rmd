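---
title: "Frequency tagging of neural entrainment to rhythm: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency tagging of neural entrainment to rhythm: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatfreq)
```

## The scientific problem

When people listen to rhythmic sound they perceive a regular underlying
pulse — the beat — and neural activity synchronizes to it. Frequency
tagging indexes this entrainment: epochs of EEG recorded during rhythm
listening are averaged in the time domain (so only stimulus-phase-locked
activity survives), Fourier transformed, and read out at known
*frequencies of interest* (FOIs): the 1-Hz beat rate, and the stimulus
rate given by the largest peak of the stimulus's own envelope spectrum.
Entrainment shows up as EEG amplitude peaks at those frequencies above the
smooth aperiodic background of the spectrum, and as consistent spectral
phase across trials (intertrial phase coherence, ITPC).

`beatfreq` implements this pipeline end to end for a three-condition
rhythm design — strong-beat, weak-beat and non-beat rhythms built from a
fixed interval table — together with a synthetic-EEG generator that
provides ground truth for validating every analysis stage.

## Stimuli

Rhythms are sequences of 6 or 7 inter-onset intervals, multiples of a
250-ms unit. Strong- and weak-beat rhythms use integer multipliers
(1:2:3:4) and always sum to 12 units, i.e. 3 s; strong-beat rhythms place
perceptual accents at evenly spaced points (every 4 units), weak-beat
rhythms do not. Non-beat rhythms replace the 2- and 3-unit intervals by
non-integer multiples (1:1.4:3.6:4), abolishing the regular beat. The
built-in table (`rhythm_table()`) holds 24 unique rhythms, 8 per
condition, arranged in four counterbalanced sets of 12 with each rhythm
in exactly two sets.

Synthesis (`synthesize()`, `synthesize_long()`) renders each interval as
a 500-Hz sine tone that fills the interval up to a 40-ms silent gap, with
8-ms amplitude ramps; a closing downbeat tone (the rhythm's shortest
interval, likewise gap-trimmed) is appended so its onset marks the end of
the last interval. Long versions loop the pattern six times seamlessly —
the downbeat is appended only after the last loop, since the first tone
of each repetition serves as the previous repetition's downbeat — giving
the ~18-s trials needed for fine spectral resolution. For the target
detection task, `add_am_targets()` imposes 40-Hz, 100%-depth amplitude
modulation on one to four tones.

Two choices here were genuinely open and are package decisions: the audio
sample rate (44.1 kHz by default; envelope spectra below 10 Hz are
insensitive to it, and the test suite uses 11.025 kHz) and the ramp shape
(linear, the simplest monotone ramp; at FOI scale the ramp contributes
nothing distinguishable). All timing is rounded to the nearest audio
sample.

## Frequencies of interest

`envelope_spectrum()` takes the magnitude of the analytic signal (Hilbert
envelope) of the waveform, removes its mean, and computes a zero-padded
FFT amplitude spectrum; `average_spectra()` averages conditions on a
common 0.0125-Hz grid, and `peak_frequency()` reads the largest non-DC
peak in 0.5–8 Hz (ties toward the lower frequency). Run on the synthesized
long stimuli (`derive_foi()`), the strong- and weak-beat condition
averages peak at exactly 4 Hz — the 250-ms unit rate. The non-beat
average peaks at 3.325 Hz on the 0.0125-Hz grid (3.33 to two decimals).
The non-beat spectrum is a plateau there: 3.3250 and 3.3375 Hz differ by
under half a percent in amplitude, because three of the four non-beat
loop durations (2.7, 3.0 s) place a common harmonic at 3.3333 Hz while
the others (2.55, 3.15 s) straddle it. A reading of 3.34 at two decimals
corresponds to the adjacent bin of this plateau on a slightly different
analysis grid; since the downstream FOI read-out takes the nearest bin
(3.3375 for either reading), the distinction has no effect on the EEG
analysis. The package reports what its own grid computes.

## The EEG spectral pipeline

`freqtag()` fits, per condition × session × set cell:

1. **Trial rejection** (`reject_trials()`): drop any trial in which any
   channel's peak-to-peak range exceeds 300 µV (the conventional reading
   of a channel "fluctuating more than" a threshold).
2. **Time-domain averaging** (`average_trials()`): pointwise mean across
   the cell's trials, per channel.
3. **Amplitude spectra** (`amplitude_spectrum()`): each channel's
   mean-removed series is zero-padded to an 80-s effective window,
   realizing a 0.0125-Hz grid from an 18-s epoch; amplitude is scaled by
   2/N (N the unpadded length) so a sinusoid of amplitude *A* µV whose
   frequency lies on the grid reads *A* at its bin. Zero-padding, not
   trial concatenation, supplies the grid: only padding reconciles a
   single epoch with a window longer than the epoch. Epochs within a cell
   must share one length (the generator guarantees it; real data should
   be truncated to the shortest common length first).
4. **Channel averaging** (`average_channels()`): pointwise mean of the
   amplitude (not complex) spectra.
5. **Aperiodic fit** (`fit_aperiodic()`): least squares of
   $y(f) \approx a\,b^{f}$ in linear amplitude space over 0.5–6 Hz,
   excluding ±0.05 Hz around every FOI and its harmonics up to 6 Hz so
   periodic peaks do not bias the background. The optimizer (L-BFGS-B,
   $a \ge 0$, $0 < b \le 1$) is started from a log-linear regression,
   which is already exact for noiseless exponential input.
6. **Subtraction** (`subtract_aperiodic()`): $y(f) - a\,b^{f}$ per bin.
   Negative residuals are retained — mild overcorrection away from peaks
   is expected and is itself a useful diagnostic.
7. **FOI read-out** (`foi_amplitude()`): the bin nearest each FOI (exact
   for 1 and 4 Hz; 3.3375 Hz for the off-grid 3.34, ties toward lower).

The aperiodic model is the "fit" in the S3 sense: `coef()` returns
$(a, b)$ per cell, `predict()` evaluates the background, `residuals()`
are the denoised spectra, and `plot()` shows raw spectrum, fitted curve
and residual side by side. `condition_table()` exports one tidy record
per cell × FOI for external statistics software (the repeated-measures
and Bayesian ANOVAs of the original design are deliberately out of
scope).

### Why the background is fitted on the native grid

The padded 0.0125-Hz grid *interpolates* the underlying discrete Fourier
transform: between native bins, a phase-locked sinusoid contributes its
rectangular-window leakage skirt. For short epochs this skirt is large —
for a 6-s epoch the first sidelobe of a 1-µV component is ~0.2 µV — and
because it is phase-locked it does not average away over trials. Fitting
$a\,b^f$ through it inflates the background estimate and depresses the
denoised FOI amplitudes by 10–20% at the validation scale. The native
(unpadded) grid has orthogonal bins: a sinusoid completing a whole number
of cycles in the epoch contributes *exactly zero* off its own bin, and
the synthetic background's native-bin amplitudes are exact draws of
$a\,b^f$. `freqtag()` therefore fits the background on the native-grid
spectrum of the averaged epoch and subtracts the fitted curve from the
padded fine-grid spectrum. With this choice the noiseless single-sinusoid
case is recovered to machine precision (the test suite asserts ≤1%), and
the exclusion windows still function: integer FOIs are themselves native
bins for integer-second epochs, and 3.34 Hz falls within ±0.05 Hz of a
native bin for the epoch lengths used. Whether the original analysis
excluded FOI bins from its fit is unknowable from the outside; the
exclusion half-width is exposed as a parameter.

## Intertrial phase coherence

`single_trial_phase()` evaluates each trial's complex spectrum per
channel under the same convention as the amplitude pipeline (mean
removal, padded-grid bin — evaluated directly as a discrete-time Fourier
sum, to which padding zeros contribute nothing), averages channels *as
complex values* (amplitude-weighted, matching the procedure of averaging
complex spectra across channels rather than averaging angles), and takes
the angle at the bin nearest the FOI. Phase is referenced to a cosine at
trial start, so all trials must share stimulus-locked time zero — the
generator guarantees this; for real data it is a documented requirement.
A trial whose channel-averaged complex value is numerically zero
(antiphase cancellation; below 10⁻¹² of the data RMS) has no defined
phase and is excluded with a count. `itpc()` returns the resultant vector
length $r = |\,\mathrm{mean}(e^{i\varphi})\,|$ and mean angle; `itpc_by_cell()`
applies the same trial rejection as the amplitude pipeline and tabulates
per cell. No circular significance tests are provided. Note the
small-sample bias of $r$: for uniform phases $E[r] \approx \sqrt{\pi}/(2\sqrt{n})$,
not 0 — compare cells at matched trial counts.

## The synthetic-EEG generator

`generate_dataset()` builds trials × channels × samples arrays with known
ground truth:

* **Aperiodic background** — white noise shaped in the frequency domain:
  each native bin gets magnitude $a\,b^{f}$ (deterministic) and an
  independent uniform phase, per channel. The single-trial amplitude
  spectrum therefore equals $a\,b^f$ *exactly* at native bins, which
  makes the generator its own oracle for the fitting stage. Defaults
  $a = 0.25$ µV, $b = 0.75$ per Hz match the sub-microvolt scale of the
  averaged, cleaned spectra this pipeline consumes (the raw-EEG scale is
  orders of magnitude larger, but the pipeline's inputs are cleaned
  epochs and its outputs trial averages).
* **Phase-locked components** — per condition, sinusoids at given
  frequency, amplitude and von Mises phase concentration κ; the phase is
  drawn once per trial and shared across channels (volume-conduction-like),
  then scaled by per-channel gains (`channel_gain_sd`). Defaults inject a
  1-Hz beat component ordered strong > weak > non (1.0/0.75/0.5 µV,
  κ = 50/30/15) plus the stimulus-rate component (4 Hz for strong/weak,
  3.34 Hz for non-beat, with the weak-beat 4-Hz response largest). The
  sampler is the Best–Fisher rejection algorithm; `expected_itpc()`
  supplies the analytic resultant length $I_1(\kappa)/I_0(\kappa)$.
* **Optional onset-evoked kernel** — a damped oscillation convolved with
  a tone-onset train; its shape is a free parameter, not calibrated to
  any recording.

Default κ values are far above the human regime (group ITPC near 0.2–0.3
corresponds to κ ≈ 0.5): they were fixed a priori from a signal-to-noise
budget so that a 72-trials-per-cell simulation recovers injected
amplitudes within 10% — after averaging $n$ trials the residual
background at a bin is $\approx 0.886\,a\,b^f/\sqrt{n}$ and the locked
amplitude is attenuated by $I_1(\kappa)/I_0(\kappa)$, so the budget at
$n = 72$ demands small $a$ and large κ. The human regime remains
reachable through configuration. What passing validation shows is that
the *bookkeeping and estimators* are correct at realistic geometry; it
does not show that real EEG (with non-stationary backgrounds, artifacts,
imperfect phase locking and evoked transients) would yield unbiased
amplitudes.

The `"fast"` profile (16 channels, 256 Hz, 6-s trials) is used throughout
the test suite; the `"full"` profile (64 channels, 1024 Hz, 18-s trials)
mirrors the emulated acquisition. Validation problem sizes, all fixed in
the tests: 72 trials/cell for parameter recovery; 10 replicates × 20
simulated subjects × 8 trials/session for the null-training check (sign
test of post − pre at α = 0.05); 2 trials for the noiseless oracle case.
All randomness flows from a single recorded seed, and identical
configuration + seed reproduces every output byte-identically.

## Behavioural scoring

`proportional_error()` is the mean over intervals of
$|\text{reproduced} - \text{target}|/\text{target}$, with reproduced
intervals the successive tap-time differences; 0 is perfect. A rhythm of
$n$ intervals must be demarcated by exactly $n + 1$ taps (the final tap
standing in for the appended downbeat; the appended tone's own interval
is not scored) — other tap counts are excluded from error averaging and
scored incorrect, since tap-to-interval correspondence is then undefined.
This $n+1$ convention is a documented, configurable choice; the
correctness rule (`is_correct()`) requires every interval within 15% of
its target (20% for the first block of the first training session, the
conventional easing), e.g. a 500-ms interval demarcated by taps 425–575 ms
apart. `learning_slope()` is the OLS slope of the four session-mean
errors in chronological order; a missing session is refused with an
explicit gap report rather than silently fitted on three points.

## Degenerate inputs and numerical conventions

* Spectral grids must contain 1 Hz exactly (and hence 4 Hz); other
  resolutions are refused rather than silently shifted.
* Cells whose trials are all rejected stay in `condition_table()` as
  explicit NA rows with zero trial counts.
* `fit_aperiodic()` refuses spectra with no positive amplitude in the
  band, and already-denoised spectra.
* Peak picking and FOI bin selection break ties toward the lower
  frequency, deterministically.
* A flat spectrum fits at the $b = 1$ boundary, $(c, 1)$.

## Known limitations

* The generator does not simulate head-model mixing, artifacts, or
  non-stationary backgrounds; ICA/filtering/interpolation are out of
  scope (the pipeline takes cleaned epochs).
* Group-level inferential statistics (repeated-measures and Bayesian
  ANOVAs, correlations with musicianship) are out of scope; the package
  exports tidy tables for external tools.
* The non-beat stimulus-rate FOI is grid-limited to two decimals, as
  discussed above.
* ITPC per-trial FFT parameters follow the amplitude pipeline's
  convention; other conventions (windowing, native-grid phases) would
  change absolute $r$ slightly.
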
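# Shared fixture builders: everything is generated in code at test time.

# One phase-locked sinusoid on a clean (or aperiodic) background.
single_tone_cfg <- function(freq = 1, amplitude = 0.8, kappa = Inf, mu = 0,
                            n_trials = 2, aperiodic_a = 0, seed = 11, ...) {
  synth_config("fast", n_trials = n_trials,
               conditions = list(strong = data.frame(
                 freq = freq, amplitude = amplitude, kappa = kappa, mu = mu)),
               aperiodic_a = aperiodic_a, seed = seed, ...)
}

# Bare amplitude-spectrum object with arbitrary values, for unit tests of
# the aperiodic fit.
make_spectrum <- function(freqs, amplitude, sample_rate = 256) {
  beatfreq:::new_spectrum(freqs, amplitude,
                          resolution = freqs[2] - freqs[1],
                          n_signal = NA_integer_, sample_rate = sample_rate)
}

# Tone train built independently of the package's synthesis code: n_tones
# rectangular 210-ms tones at a fixed onset period.
tone_train <- function(n_tones, period_ms = 250, tone_ms = 210,
                       sample_rate = 2000, tone_hz = 100) {
  n <- round(n_tones * period_ms / 1000 * sample_rate)
  x <- numeric(n)
  for (k in 0:(n_tones - 1)) {
    i0 <- round(k * period_ms / 1000 * sample_rate)
    nd <- round(tone_ms / 1000 * sample_rate)
    x[i0 + seq_len(nd)] <- sin(2 * pi * tone_hz * (seq_len(nd) - 1) / sample_rate)
  }
  x
}
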
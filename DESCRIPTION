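Package: beatfreq
Title: Frequency-Tagging Analysis of Neural Entrainment to Rhythmic Auditory Stimuli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying neural entrainment to the beat with EEG
    frequency tagging. Synthesizes strong-beat, weak-beat and non-beat
    auditory rhythm stimuli from a built-in interval table, derives
    stimulus-driven frequencies of interest from Hilbert-envelope amplitude
    spectra, and analyses epoched EEG with the steady-state evoked response
    pipeline: amplitude-based trial rejection, time-domain averaging,
    zero-padded FFT amplitude spectra at fixed frequency resolution, channel
    averaging, exponential (a * b^f) aperiodic-background fitting and
    subtraction, amplitude extraction at frequencies of interest, and
    intertrial phase coherence (resultant vector length). A synthetic-EEG
    generator with known aperiodic background and phase-locked components
    provides ground truth for validation, and rhythm-reproduction tap logs
    can be scored with proportional-error and correctness-window rules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
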
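# The built-in stimulus set and audio synthesis rules.

test_that("built-in table matches the experimental design", {
  tab <- rhythm_table()
  expect_length(tab, 24)
  expect_length(unique(vapply(tab, format, character(1))), 24)
  for (cond in c("strong", "weak", "non"))
    expect_length(rhythm_table(condition = cond), 8)
  for (s in 1:4)
    for (cond in c("strong", "weak", "non"))
      expect_length(rhythm_table(condition = cond, set_id = s), 4)
  # every rhythm belongs to exactly two sets; each set holds 12 rhythms
  expect_true(all(vapply(tab, function(r) length(r$set_ids), integer(1)) == 2))
  for (s in 1:4) expect_length(rhythm_table(set_id = s), 12)
  # the shared strong-beat rhythm sits in sets 1 and 3
  shared <- Filter(function(r) format(r) == "1 1 1 1 4 3 1", tab)
  expect_length(shared, 1)
  expect_identical(shared[[1]]$set_ids, c(1L, 3L))
  # integer-ratio rhythms sum to 12 units (3 s); lengths are 6 or 7
  for (r in tab) {
    expect_true(length(r$intervals) %in% c(6L, 7L))
    if (r$condition != "non") {
      expect_identical(sum(r$intervals), 12)
      expect_true(all(r$intervals %in% 1:4))
    } else {
      expect_true(all(r$intervals %in% c(1, 1.4, 3.6, 4)))
    }
  }
})

test_that("rhythm_spec validates its inputs", {
  expect_error(rhythm_spec(c(1, 1, 1), "strong"), "six or seven")
  expect_error(rhythm_spec(c(1, 1, 1, 1, 4, 3, 2), "strong"), "sum to 12")
  expect_error(rhythm_spec(c(1, 1.4, 1, 1, 4, 3), "strong"), "multipliers")
  expect_error(rhythm_spec(c(1, 2, 1, 1, 4, 3), "non"), "multipliers")
})

test_that("short synthesis follows the tone/gap/ramp rules", {
  spec <- rhythm_spec(c(1, 1, 2, 3, 1, 4), "strong")
  sr <- 11025
  stim <- synthesize(spec, sample_rate = sr)
  expect_identical(stim$onset_times_ms,
                   c(0, 250, 500, 1000, 1750, 2000, 3000))
  expect_identical(stim$onset_times_ms[1], 0)
  expect_identical(stim$tone_durations_ms,
                   c(c(1, 1, 2, 3, 1, 4) * 250, 250) - 40)
  expect_lte(max(abs(stim$samples)), 1)
  # waveform silent during every 40-ms inter-tone gap
  for (k in seq_len(length(stim$onset_times_ms) - 1)) {
    g0 <- round((stim$onset_times_ms[k] + stim$tone_durations_ms[k]) / 1000 * sr)
    g1 <- g0 + round(0.040 * sr)
    expect_identical(max(abs(stim$samples[(g0 + 2):(g1 - 1)])), 0)
  }
  # without the closing downbeat: one tone per interval
  bare <- synthesize(spec, sample_rate = sr, append_final_tone = FALSE)
  expect_length(bare$onset_times_ms, 6)
  expect_error(synthesize(spec, sample_rate = 800), "twice the tone")
  tiny <- rhythm_spec(c(1, 1, 2, 3, 1, 4), "strong", unit_ms = 30)
  expect_error(synthesize(tiny, sample_rate = sr), "exceed the silent gap")
})

test_that("looped synthesis appends the downbeat only once", {
  sr <- 11025
  spec <- rhythm_spec(c(3, 1, 2, 2, 1, 3), "strong")
  one <- synthesize_long(spec, n_loops = 1, sample_rate = sr)
  short <- synthesize(spec, sample_rate = sr)
  expect_identical(one$samples, short$samples)
  expect_identical(one$onset_times_ms, short$onset_times_ms)
  six <- synthesize_long(spec, n_loops = 6, sample_rate = sr)
  expect_identical(six$duration_ms, 6 * 3000 + 210)   # ~18-s version
  expect_length(six$onset_times_ms, 6 * 6 + 1)
  # looped interval pattern: 3 1 2 2 1 3 repeated, closed by a "1" tone
  expect_identical(diff(six$onset_times_ms), rep(c(3, 1, 2, 2, 1, 3) * 250, 6))
  nb <- rhythm_spec(c(1.4, 1, 4, 1.4, 1.4, 1), "non")    # 10.2 units
  long_nb <- synthesize_long(nb, n_loops = 6, sample_rate = sr)
  expect_identical(long_nb$duration_ms, 6 * 2550 + 210)
})

test_that("AM target tones are selected reproducibly and modulated in place", {
  spec <- rhythm_spec(c(1, 1, 2, 3, 1, 4), "strong")
  stim <- synthesize(spec, sample_rate = 11025)
  t1 <- add_am_targets(stim, n_targets = 2, seed = 99)
  t2 <- add_am_targets(stim, n_targets = 2, seed = 99)
  expect_identical(t1$target_tone_indices, t2$target_tone_indices)
  expect_identical(t1$samples, t2$samples)
  expect_length(t1$target_tone_indices, 2)
  # zero depth leaves the waveform untouched
  t0 <- add_am_targets(stim, n_targets = 3, depth = 0, seed = 1)
  expect_equal(t0$samples, stim$samples)
  # modulation confined to the selected tones
  sr <- stim$sample_rate
  changed <- which(t1$samples != stim$samples)
  in_targets <- unlist(lapply(t1$target_tone_indices, function(k) {
    i0 <- round(stim$onset_times_ms[k] / 1000 * sr)
    i0 + seq_len(round(stim$tone_durations_ms[k] / 1000 * sr))
  }))
  expect_true(all(changed %in% in_targets))
  expect_error(add_am_targets(stim, n_targets = 0), "\\[1, 4\\]")
  expect_error(add_am_targets(stim, n_targets = 5), "\\[1, 4\\]")
})

test_that("WAV files and the stimulus table round-trip", {
  stim <- synthesize(rhythm_spec(c(1, 2, 2, 1, 4, 2), "weak"),
                     sample_rate = 11025)
  wav <- tempfile(fileext = ".wav")
  write_wav(stim, wav, sidecar = TRUE)
  back <- read_wav(wav)
  expect_identical(back$sample_rate, 11025L)
  expect_lt(max(abs(back$samples - stim$samples)), 1 / 32766)
  expect_true(file.exists(paste0(wav, ".csv")))

  tab <- rhythm_table()
  tsv <- tempfile(fileext = ".tsv")
  write_stimulus_table(tab, tsv)
  back_tab <- read_stimulus_table(tsv)
  expect_length(back_tab, 24)
  expect_identical(vapply(back_tab, format, character(1)),
                   vapply(tab, format, character(1)))
  expect_identical(lapply(back_tab, `[[`, "set_ids"),
                   lapply(tab, `[[`, "set_ids"))
})
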
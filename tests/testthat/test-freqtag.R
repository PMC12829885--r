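# The spectral pipeline: rejection, averaging, aperiodic fit/subtraction,
# FOI read-out, and the freqtag model object.

test_that("trials are rejected on peak-to-peak range", {
  dat <- array(0, dim = c(20, 2, 100))
  dat[3, 2, 5] <- 350                      # one channel spans 350 uV
  dat[11, 1, ] <- seq(0, 400, length.out = 100)
  labs <- data.frame(condition = "strong")[rep(1, 20), , drop = FALSE]
  e <- epoched_eeg(dat, 256, labs)
  kept <- reject_trials(e, 300)
  expect_identical(dim(kept)[1], 18L)
  expect_equal(attr(kept, "retained_fraction"), 0.9)
  expect_identical(attr(kept, "n_rejected"), 2L)
  # all-zero data all retained; exactly-threshold spans are kept
  expect_identical(dim(reject_trials(epoched_eeg(array(0, c(4, 2, 10)), 256,
    data.frame(condition = rep("a", 4))), 300))[1], 4L)
})

test_that("time-domain averaging isolates phase-locked activity", {
  t <- (0:99) / 100
  s <- sin(2 * pi * 5 * t)
  dat <- array(0, dim = c(2, 1, 100))
  dat[1, 1, ] <- s
  dat[2, 1, ] <- s
  e <- epoched_eeg(dat, 100, data.frame(condition = c("a", "a")))
  expect_equal(drop(average_trials(e)), s)
  dat[2, 1, ] <- -s                          # antiphase pair cancels
  e2 <- epoched_eeg(dat, 100, data.frame(condition = c("a", "a")))
  expect_equal(max(abs(average_trials(e2))), 0)
  expect_error(average_trials(subset_trials(e, integer())), "no trials")
})

test_that("aperiodic fit recovers exponential backgrounds", {
  f <- seq(0.5, 6, by = 0.0125)
  co <- fit_aperiodic(make_spectrum(f, 2 * 0.7^f), foi = c(1, 4, 3.34))
  expect_equal(unname(co), c(2, 0.7), tolerance = 1e-6)
  # a narrow peak at a frequency of interest does not bias the fit
  peaky <- 2 * 0.7^f + ifelse(abs(f - 1) <= 0.05, 0.5, 0)
  co2 <- fit_aperiodic(make_spectrum(f, peaky), foi = c(1, 4, 3.34))
  expect_equal(unname(co2), c(2, 0.7), tolerance = 1e-6)
  # flat spectra sit at the b = 1 boundary
  co3 <- fit_aperiodic(make_spectrum(f, rep(0.8, length(f))),
                       foi = c(1, 4, 3.34))
  expect_equal(unname(co3), c(0.8, 1), tolerance = 1e-6)
  expect_error(fit_aperiodic(make_spectrum(f, rep(-1, length(f)))),
               "positive")
  expect_error(fit_aperiodic(make_spectrum(seq(2, 6, 0.0125),
                                           rep(1, 321)), band = c(0.5, 6)),
               "outside")
})

test_that("subtraction flattens the background and keeps peaks", {
  f <- seq(0, 10, by = 0.0125)
  bg <- 1.5 * 0.8^f
  peak <- ifelse(abs(f - 1) < 0.02, 0.5, 0)
  den <- subtract_aperiodic(make_spectrum(f, bg + peak), a = 1.5, b = 0.8)
  expect_true(den$denoised)
  expect_equal(den$aperiodic_a, 1.5)
  expect_equal(foi_amplitude(den, 1), 0.5, tolerance = 1e-9)
  off_peak <- abs(f - 1) > 0.05
  expect_lt(max(abs(den$amplitude[off_peak])), 1e-12)
  expect_identical(which.max(den$amplitude), which.max(peak))
  expect_error(fit_aperiodic(den), "already denoised")
})

test_that("FOI read-out picks the nearest grid bin, ties toward lower", {
  f <- seq(0, 10, by = 0.0125)
  amp <- numeric(length(f))
  idx334 <- which.min(abs(f - 3.3375))      # bin 267 (267 * 0.0125)
  expect_identical(idx334, 268L)
  amp[idx334] <- 7
  amp[which.min(abs(f - 4))] <- 9
  sp <- make_spectrum(f, amp)
  expect_identical(foi_amplitude(sp, 3.34), 7)
  expect_identical(foi_amplitude(sp, 4), 9)
  expect_error(foi_amplitude(sp, 200), "Nyquist")
  expect_error(foi_amplitude(sp, 20), "outside")
})

test_that("the pipeline is linear in signal scale", {
  e <- generate_dataset(synth_config("fast", n_trials = 4, seed = 77))
  f1 <- freqtag(e, foi = c(1, 4))
  e3 <- e
  e3$data <- 3 * e$data
  f3 <- freqtag(e3, foi = c(1, 4))
  expect_equal(f3$amplitude, 3 * f1$amplitude, tolerance = 1e-8)
  expect_equal(f3$cells$a, 3 * f1$cells$a, tolerance = 1e-6)
  expect_equal(f3$cells$b, f1$cells$b, tolerance = 1e-6)
})

test_that("freqtag model methods are coherent", {
  e <- generate_dataset(synth_config("fast", n_trials = 3, seed = 15))
  fit <- freqtag(e, foi = c(1, 4, 3.34))
  expect_s3_class(fit, "freqtag")
  expect_identical(dim(coef(fit)), c(3L, 2L))
  pr <- predict(fit, freq = c(1, 2, 4))
  expect_equal(unname(pr[1, 1]),
               unname(coef(fit)[1, "a"] * coef(fit)[1, "b"]^1))
  res <- residuals(fit)
  grid <- attr(res, "freq")
  # residuals are the denoised spectra: raw minus fitted aperiodic
  raw1 <- fit$spectra[[1]]$raw$amplitude
  expect_equal(res[, 1], raw1 - coef(fit)[1, "a"] * coef(fit)[1, "b"]^grid,
               tolerance = 1e-10)
  expect_output(print(fit), "Frequency-tagging fit")
  expect_output(print(summary(fit)), "microvolts")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit, cells = 1))
})

test_that("condition tables are complete, explicit about empty cells, and round-trip", {
  cfg <- synth_config("fast", n_trials = 2, sessions = c("pre", "post"),
                      sets = c("trained", "untrained"), seed = 31)
  e <- generate_dataset(cfg)
  fit <- freqtag(e, foi = c(1, 4, 3.34))
  tab <- condition_table(fit, itpc = itpc_by_cell(e, foi = 1))
  expect_identical(nrow(tab), 3L * 2L * 2L * 3L)     # cells x FOIs
  expect_true(all(is.finite(tab$amplitude)))
  expect_true(all(is.finite(tab$r[tab$foi_hz == 1])))
  expect_true(all(is.na(tab$r[tab$foi_hz != 1])))
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  back <- utils::read.csv(csv)
  expect_equal(back$amplitude, tab$amplitude, tolerance = 1e-12)
  expect_identical(back$condition, tab$condition)
  # a cell whose trials are all rejected stays in the table as NA
  e$data[e$labels$condition == "non" & e$labels$session == "pre" &
           e$labels$set == "trained", 1, 1] <- 1e4
  fit2 <- freqtag(e, foi = 1)
  tab2 <- condition_table(fit2)
  gone <- tab2$condition == "non" & tab2$session == "pre" &
    tab2$set == "trained"
  expect_identical(sum(gone), 1L)
  expect_true(is.na(tab2$amplitude[gone]))
  expect_identical(tab2$n_trials[gone], 0L)
})
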
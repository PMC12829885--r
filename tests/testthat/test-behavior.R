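# Rhythm-reproduction scoring.

test_that("proportional error implements the printed formula", {
  expect_identical(proportional_error(c(250, 500, 750), c(0, 250, 750, 1500)), 0)
  # 10% off on both intervals averages to 0.10
  expect_equal(proportional_error(c(250, 500), c(0, 275, 725)), 0.10)
  # wrong tap counts are excluded, not scored
  expect_true(is.na(proportional_error(rep(250, 7), cumsum(rep(250, 6)))))
  expect_true(is.na(proportional_error(c(250, 500), c(0))))
  expect_error(proportional_error(c(250, 500), c(0, 300, 200)),
               "strictly increasing")
  # jointly rescaling targets and taps leaves the score unchanged
  set.seed(4)
  for (i in 1:20) {
    tgt <- sample(c(250, 500, 750, 1000), 6, replace = TRUE)
    taps <- c(0, cumsum(tgt * stats::runif(6, 0.8, 1.2)))
    for (c_scale in c(0.5, 2, 7.3))
      expect_equal(proportional_error(tgt, taps),
                   proportional_error(c_scale * tgt, c_scale * taps),
                   tolerance = 1e-12)
  }
})

test_that("correctness windows match the stated tolerance", {
  # a 500-ms interval is demarcated correctly by taps 425-575 ms apart
  expect_true(is_correct(500, c(0, 430)))
  expect_true(is_correct(500, c(0, 425)))
  expect_true(is_correct(500, c(0, 575)))
  expect_false(is_correct(500, c(0, 424.9)))
  expect_false(is_correct(500, c(0, 580)))
  expect_true(is_correct(500, c(0, 590), tolerance = 0.20))
  # tap-count mismatch is simply incorrect
  expect_false(is_correct(c(500, 250), c(0, 500)))
  # correctness implies a proportional error no larger than the tolerance
  set.seed(11)
  for (i in 1:50) {
    tgt <- sample(c(250, 500, 750, 1000), 6, replace = TRUE)
    taps <- c(0, cumsum(tgt * stats::runif(6, 0.7, 1.3)))
    if (is_correct(tgt, taps))
      expect_lte(proportional_error(tgt, taps), 0.15 + 1e-9)
  }
})

test_that("learning slopes are ordinary least squares over sessions", {
  expect_equal(learning_slope(c(0.4, 0.3, 0.2, 0.1)), -0.1, tolerance = 1e-12)
  expect_equal(learning_slope(rep(0.25, 4)), 0, tolerance = 1e-12)
  # closed-form check on an uneven profile
  y <- c(0.23, 0.20, 0.18, 0.16)
  x <- 1:4
  by_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(learning_slope(y), by_hand, tolerance = 1e-12)
  expect_lt(learning_slope(y), 0)
  expect_error(learning_slope(c(0.4, NA, 0.2, 0.1)), "session\\(s\\) 2")
  expect_error(learning_slope(c(0.3, 0.2)), "four")
})

# Simulated tap logs: timing noise shrinking across sessions, as training
# would produce.
simulate_tap_log <- function(seed = 2) {
  set.seed(seed)
  targets <- list(r1 = c(250, 250, 500, 750, 250, 1000),
                  r2 = c(500, 750, 250, 250, 500, 750))
  rows <- list()
  id <- 0
  for (session in 1:4)
    for (block in 1:2)
      for (rid in names(targets))
        for (rep in 1:4) {
          id <- id + 1
          tgt <- targets[[rid]]
          sd_ms <- c(70, 50, 35, 25)[session]    # improvement with practice
          taps <- c(0, cumsum(tgt + stats::rnorm(length(tgt), 0, sd_ms)))
          rows[[id]] <- data.frame(
            trial_id = id, session = session, block = block,
            condition = if (rid == "r1") "strong" else "weak",
            rhythm_id = rid, tap_time_ms = sort(taps))
        }
  list(taps = do.call(rbind, rows), targets = targets)
}

test_that("tap logs are scored trial-wise and summarised by session", {
  sim <- simulate_tap_log()
  scores <- score_tap_log(sim$taps, sim$targets)
  expect_identical(nrow(scores), 4L * 2L * 2L * 4L)
  expect_true(all(scores$error[!scores$excluded] >= 0))
  smry <- session_summary(scores)
  expect_identical(nrow(smry$session_means), 8L)     # 2 conditions x 4 sessions
  expect_true(all(smry$slopes < 0))                  # practice reduces error
})

test_that("the first block of session 1 uses the liberal window", {
  targets <- list(r = c(500, 500, 500, 500, 500, 500))
  taps18 <- c(0, cumsum(rep(590, 6)))                # 18% off every interval
  log <- rbind(
    data.frame(trial_id = 1, session = 1, block = 1, condition = "strong",
               rhythm_id = "r", tap_time_ms = taps18),
    data.frame(trial_id = 2, session = 1, block = 2, condition = "strong",
               rhythm_id = "r", tap_time_ms = taps18))
  scores <- score_tap_log(log, targets)
  expect_true(scores$correct[scores$block == 1])
  expect_false(scores$correct[scores$block == 2])
})
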
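# Rhythm-reproduction scoring: proportional error, correctness windows,
# wrong-tap-count exclusion, and learning slopes across training sessions.
#
# Reproduced intervals are the successive differences of the tap times; the
# absolute time of the first tap carries no information (the reproduction
# happens in a silent response window with no external anchor). A rhythm of
# n intervals is demarcated by n + 1 taps, the final tap playing the role
# of the appended closing downbeat; the appended tone's own interval is not
# scored.

#' Proportional reproduction error
#'
#' Mean over intervals of |reproduced - target| / target, where reproduced
#' intervals are successive tap-time differences. Perfect reproduction
#' scores 0. Trials whose tap count does not demarcate the target intervals
#' exactly (taps != intervals + 1) are excluded: it is not clear which tap
#' corresponds to which stimulus interval.
#'
#' @param target_intervals_ms Stimulus inter-onset intervals, ms.
#' @param tap_times_ms Strictly increasing tap timestamps, ms.
#' @return Nonnegative error fraction, or \code{NA} (the exclusion marker)
#'   when the tap count is wrong.
#' @examples
#' proportional_error(c(250, 500), c(0, 275, 725))  # (0.1 + 0.1)/2
#' @export
proportional_error <- function(target_intervals_ms, tap_times_ms) {
  check_taps(tap_times_ms)
  reproduced <- diff(tap_times_ms)
  if (length(reproduced) != length(target_intervals_ms))
    return(NA_real_)
  mean(abs(reproduced - target_intervals_ms) / target_intervals_ms)
}

#' Is a reproduction trial correct?
#'
#' TRUE iff the tap count matches (intervals + 1 taps) and every reproduced
#' interval lies within \code{tolerance} of its target duration (a 500-ms
#' interval at the default 15\% window must be demarcated by taps separated
#' by 425-575 ms). The first reproduction block of the first training
#' session conventionally uses a more liberal 20\% window.
#'
#' @inheritParams proportional_error
#' @param tolerance Allowed fractional deviation per interval.
#' @return Logical.
#' @export
is_correct <- function(target_intervals_ms, tap_times_ms, tolerance = 0.15) {
  check_taps(tap_times_ms)
  reproduced <- diff(tap_times_ms)
  if (length(reproduced) != length(target_intervals_ms)) return(FALSE)
  all(abs(reproduced - target_intervals_ms) <=
        tolerance * target_intervals_ms + 1e-9)
}

check_taps <- function(tap_times_ms) {
  if (length(tap_times_ms) >= 2 && any(diff(tap_times_ms) <= 0))
    stop("tap times must be strictly increasing")
  invisible(tap_times_ms)
}

#' Learning slope across training sessions
#'
#' Ordinary least-squares slope of the four session-mean error scores
#' against chronological session number: negative slopes indicate
#' improvement.
#'
#' @param session_errors Four mean proportional errors, sessions 1-4 in
#'   order.
#' @param sessions Session codes (default 1:4).
#' @return Slope in error units per session.
#' @examples
#' learning_slope(c(0.4, 0.3, 0.2, 0.1))  # -0.1
#' @export
learning_slope <- function(session_errors, sessions = seq_along(session_errors)) {
  if (length(session_errors) != 4 || length(sessions) != 4)
    stop("exactly four session values are required")
  if (anyNA(session_errors))
    stop("missing session mean(s) at session(s) ",
         paste(sessions[is.na(session_errors)], collapse = ", "),
         "; cannot fit a learning slope")
  unname(stats::coef(stats::lm(session_errors ~ sessions))[2])
}

#' Score a tap log
#'
#' Scores every trial of a tap log against its target intervals: the
#' proportional error (NA = excluded for wrong tap count) and the
#' correctness window (15\%, or 20\% for block 1 of session 1 when
#' \code{liberal_first_block}).
#'
#' @param taps Data frame of individual taps with columns \code{trial_id},
#'   \code{session}, \code{block}, \code{condition}, \code{rhythm_id},
#'   \code{tap_time_ms}; one row per tap. Readable from delimited text via
#'   \code{utils::read.csv}.
#' @param targets Named list mapping \code{rhythm_id} to the target
#'   interval vector in ms (e.g. built from \code{\link{rhythm_table}}).
#' @param tolerance Correctness window, fraction.
#' @param liberal_tolerance Window used for session 1 / block 1.
#' @param liberal_first_block Apply the liberal window there?
#' @return Data frame with one row per trial: labels, \code{n_taps},
#'   \code{error}, \code{correct}, \code{excluded}.
#' @export
score_tap_log <- function(taps, targets, tolerance = 0.15,
                          liberal_tolerance = 0.20,
                          liberal_first_block = TRUE) {
  need <- c("trial_id", "session", "block", "condition", "rhythm_id",
            "tap_time_ms")
  if (!all(need %in% names(taps)))
    stop("tap log must have columns: ", paste(need, collapse = ", "))
  rows <- lapply(split(taps, taps$trial_id), function(tr) {
    tr <- tr[order(tr$tap_time_ms), ]
    tgt <- targets[[as.character(tr$rhythm_id[1])]]
    if (is.null(tgt)) stop("no target intervals for rhythm ", tr$rhythm_id[1])
    tol <- if (liberal_first_block && tr$session[1] == 1 && tr$block[1] == 1)
      liberal_tolerance else tolerance
    err <- proportional_error(tgt, tr$tap_time_ms)
    data.frame(trial_id = tr$trial_id[1], session = tr$session[1],
               block = tr$block[1], condition = tr$condition[1],
               rhythm_id = tr$rhythm_id[1], n_taps = nrow(tr),
               error = err,
               correct = is_correct(tgt, tr$tap_time_ms, tol),
               excluded = is.na(err), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$session, out$block, out$trial_id), , drop = FALSE]
}

#' Session-level reproduction summary
#'
#' Mean proportional error per condition and session (excluded trials
#' dropped), plus the per-condition learning slope across the four
#' sessions.
#'
#' @param scores Trial-level data frame from \code{\link{score_tap_log}}.
#' @return List with \code{session_means} (condition x session data frame)
#'   and \code{slopes} (named per-condition vector).
#' @export
session_summary <- function(scores) {
  ok <- scores[!scores$excluded, , drop = FALSE]
  agg <- stats::aggregate(error ~ condition + session, data = ok, FUN = mean)
  slopes <- vapply(split(agg, agg$condition), function(d) {
    d <- d[order(d$session), ]
    learning_slope(d$error, d$session)
  }, numeric(1))
  list(session_means = agg[order(agg$condition, agg$session), ],
       slopes = slopes)
}
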
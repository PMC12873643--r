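#' Score one trial's outcome from its licks
#'
#' A change trial is a hit if at least one lick falls in the response window
#' (300-800 ms after change onset, half-open), otherwise a miss. A no-change
#' trial is a false alarm if the mouse licks during the equivalent window
#' after the fourth-epoch onset, otherwise a correct reject. Under the
#' change-detection task rules (`task = "change_detect"`), any lick between
#' trial start and the opening of the response window is anticipatory (too
#' early to be a response to the change) and aborts the trial.
#'
#' @param trial one row of a trial timeline.
#' @param licks lick times in seconds from session start.
#' @param task `"passive"`, `"stim_reward"` or `"change_detect"`; only the
#'   last one enforces the anticipatory-abort rule.
#' @param window_ms response window relative to change onset, default
#'   `c(300, 800)`.
#' @return one of `"hit"`, `"miss"`, `"correct_reject"`, `"false_alarm"`,
#'   `"aborted"`.
#' @export
score_trial <- function(trial, licks, task = "change_detect",
                        window_ms = c(300, 800)) {
  stopifnot(nrow(trial) == 1L)
  task <- match.arg(task, c("passive", "stim_reward", "change_detect"))
  # round to sub-microsecond so window boundaries are stable against
  # floating-point representation of event times
  rel <- round((licks - trial$t_change_on) * 1000, 6)
  in_window <- any(rel >= window_ms[1] & rel < window_ms[2])
  if (task == "change_detect" && isTRUE(trial$is_change)) {
    anticipatory <- any(licks > trial$t_noise_on &
                          rel < window_ms[1])
    if (anticipatory) return("aborted")
  }
  if (isTRUE(trial$is_change)) {
    if (in_window) "hit" else "miss"
  } else {
    if (in_window) "false_alarm" else "correct_reject"
  }
}

#' Score all trials of a session
#'
#' Vectorized wrapper around [score_trial()].
#'
#' @param events trial timeline data.frame.
#' @param licks data.frame with columns `trial_id`, `lick_time_s` (may be
#'   empty).
#' @param task,window_ms see [score_trial()].
#' @return character vector of outcomes, one per trial.
#' @export
score_trials <- function(events, licks, task = "change_detect",
                         window_ms = c(300, 800)) {
  by_trial <- split(licks$lick_time_s, factor(licks$trial_id,
                                              levels = events$trial_id))
  vapply(seq_len(nrow(events)), function(i) {
    score_trial(events[i, ], by_trial[[i]], task = task,
                window_ms = window_ms)
  }, character(1))
}

#' Signal-detection sensitivity d-prime
#'
#' `qnorm(HR) - qnorm(FAR)`. By default the log-linear correction is applied
#' (0.5 added to hit and false-alarm counts, 1 to the trial counts) so the
#' value is finite at rates of 0 or 1; this requires the trial counts. With
#' `correction = "none"` the rates are used as given.
#'
#' @param hit_rate,false_alarm_rate proportions in `[0, 1]`.
#' @param n_change,n_nochange trial counts (required for the log-linear
#'   correction).
#' @param correction `"loglinear"` (default) or `"none"`.
#' @return d-prime value.
#' @export
dprime <- function(hit_rate, false_alarm_rate,
                   n_change = NULL, n_nochange = NULL,
                   correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  stopifnot(hit_rate >= 0, hit_rate <= 1,
            false_alarm_rate >= 0, false_alarm_rate <= 1)
  if (correction == "loglinear") {
    if (is.null(n_change) || is.null(n_nochange)) {
      stop("loglinear correction needs n_change and n_nochange trial counts")
    }
    hit_rate <- (hit_rate * n_change + 0.5) / (n_change + 1)
    false_alarm_rate <- (false_alarm_rate * n_nochange + 0.5) / (n_nochange + 1)
  }
  stats::qnorm(hit_rate) - stats::qnorm(false_alarm_rate)
}

#' Behavioral summary of one session
#'
#' Hit rate over scored change trials (aborted trials excluded), false-alarm
#' rate over no-change trials, d-prime (log-linear corrected; `NA` when the
#' session has no no-change trials, as for the stimulus-reward cohort, where
#' false alarms are undefined), and the median reaction time (first lick in
#' the response window) on hit trials.
#'
#' @param events scored trial timeline for one session.
#' @param licks lick table for the same session.
#' @param window_ms response window, ms after change onset.
#' @return one-row data.frame: `session_id, n_change, n_nochange, n_aborted,
#'   hit_rate, false_alarm_rate, dprime, median_rt_ms`.
#' @export
behavior_summary <- function(events, licks, window_ms = c(300, 800)) {
  stopifnot(length(unique(events$session_id)) == 1L)
  ch <- events[events$is_change & events$outcome != "aborted", ]
  nc <- events[!events$is_change, ]
  n_aborted <- sum(events$outcome == "aborted")
  hit_rate <- if (nrow(ch)) mean(ch$outcome == "hit") else NA_real_
  far <- if (nrow(nc)) mean(nc$outcome == "false_alarm") else NA_real_
  dp <- if (nrow(nc) && nrow(ch)) {
    dprime(hit_rate, far, n_change = nrow(ch), n_nochange = nrow(nc))
  } else NA_real_
  hits <- ch[ch$outcome == "hit", ]
  rts <- vapply(seq_len(nrow(hits)), function(i) {
    rel <- (licks$lick_time_s[licks$trial_id == hits$trial_id[i]] -
              hits$t_change_on[i]) * 1000
    min(rel[rel >= window_ms[1] & rel < window_ms[2]])
  }, numeric(1))
  data.frame(session_id = events$session_id[1],
             n_change = nrow(ch), n_nochange = nrow(nc),
             n_aborted = n_aborted,
             hit_rate = hit_rate, false_alarm_rate = far, dprime = dp,
             median_rt_ms = if (length(rts)) stats::median(rts) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Paired cued-versus-probe comparison across sessions
#'
#' Two-sided Wilcoxon signed-rank test on paired per-session metrics (e.g.
#' hit rate on cued versus probe trials). For up to 16 non-zero differences
#' the p-value is exact by enumerating all sign assignments of the midranked
#' absolute differences (which keeps the test exact under ties); larger
#' samples use `stats::wilcox.test`.
#'
#' @param cued,probe numeric vectors of equal length, one value per session.
#' @return list with `p`, `statistic` (signed-rank sum W+), `n` (non-zero
#'   pairs used).
#' @export
compare_cued_vs_probe <- function(cued, probe) {
  stopifnot(length(cued) == length(probe), length(cued) >= 2)
  d <- cued - probe
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(p = 1, statistic = NA_real_, n = 0L))
  }
  n <- length(d)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  if (n <= 16) {
    s_obs <- sum(sign(d) * r)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    s_null <- signs %*% r
    p <- mean(abs(s_null) >= abs(s_obs) - 1e-12)
  } else {
    p <- suppressWarnings(stats::wilcox.test(cued, probe,
                                             paired = TRUE))$p.value
  }
  list(p = p, statistic = w_plus, n = n)
}
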
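#' Count spikes in an event-relative window
#'
#' Number of spikes whose time relative to `event_time` lies in the
#' half-open window `[a, b)` milliseconds. Half-open bins make adjacent
#' windows a partition with no double counting. Works vectorized over
#' multiple event times.
#'
#' @param spikes sorted spike times (seconds).
#' @param event_time one or more event times (seconds).
#' @param window_ms length-2 numeric `c(a, b)`, ms relative to the event,
#'   `a < b`.
#' @return integer count per event time.
#' @export
count_in_window <- function(spikes, event_time, window_ms) {
  stopifnot(length(window_ms) == 2L, window_ms[1] < window_ms[2])
  if (is.unsorted(spikes)) stop("spike times must be sorted")
  lo <- event_time + window_ms[1] / 1000
  hi <- event_time + window_ms[2] / 1000
  # findInterval with left-open=FALSE gives counts of spikes < x; use
  # half-open [lo, hi): spikes >= lo and < hi
  n_lo <- findInterval(lo, spikes, left.open = TRUE)
  n_hi <- findInterval(hi, spikes, left.open = TRUE)
  as.integer(n_hi - n_lo)
}

#' Firing rates in an event-relative window
#'
#' Per-trial spike count divided by the window duration, in Hz.
#'
#' @inheritParams count_in_window
#' @return numeric rate (Hz) per event time.
#' @export
rate_in_window <- function(spikes, event_time, window_ms) {
  count_in_window(spikes, event_time, window_ms) /
    ((window_ms[2] - window_ms[1]) / 1000)
}

#' Peristimulus time histogram
#'
#' Mean firing rate across trials in non-overlapping bins (default 20 ms)
#' aligned to a trial event. Bins are half-open `[k*bin, (k+1)*bin)`
#' anchored at 0. Trials lacking the alignment event (e.g. no-change trials
#' aligned on change onset) are skipped with a message.
#'
#' @param spikes sorted spike times (seconds).
#' @param trials trial timeline data.frame.
#' @param event `"cue_on"`, `"twopatch_on"` or `"change_on"`.
#' @param range_ms length-2 window, ms relative to the event; must be an
#'   integer number of bins.
#' @param bin_ms bin width in ms.
#' @return data.frame with `bin_start_ms`, `rate_hz` (mean across trials),
#'   attribute `n_trials`.
#' @export
compute_psth <- function(spikes, trials, event = "cue_on",
                         range_ms = c(-200, 400), bin_ms = 20) {
  event <- match.arg(event, c("cue_on", "twopatch_on", "change_on"))
  trials <- .trials_with_event(trials, event)
  if (nrow(trials) == 0) stop("no trials with the alignment event")
  n_bins <- (range_ms[2] - range_ms[1]) / bin_ms
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("bin_ms must divide the range evenly")
  }
  n_bins <- as.integer(round(n_bins))
  edges <- range_ms[1] + bin_ms * (0:n_bins)
  ev <- trials[[paste0("t_", event)]]
  counts <- matrix(0, nrow(trials), n_bins)
  for (b in seq_len(n_bins)) {
    counts[, b] <- count_in_window(spikes, ev, c(edges[b], edges[b + 1]))
  }
  data.frame(bin_start_ms = edges[-length(edges)],
             rate_hz = colMeans(counts) / (bin_ms / 1000))
}

# Keep only trials for which the alignment event exists (change alignment is
# undefined on no-change trials: the fourth epoch starts but nothing changes).
.trials_with_event <- function(trials, event) {
  if (event == "change_on" && "is_change" %in% names(trials)) {
    dropped <- sum(!trials$is_change)
    if (dropped > 0) {
      message(dropped, " no-change trial(s) skipped for change alignment")
    }
    trials <- trials[trials$is_change, , drop = FALSE]
  }
  trials
}

#' z-scored response for heat-map ordering
#'
#' (mean response-window rate - mean baseline-window rate) divided by the SD
#' of baseline rates across trials. Used only to order units in population
#' heat maps. With zero baseline SD the value is signed infinity (ordered
#' after all finite values).
#'
#' @param spikes sorted spike times (seconds).
#' @param trials trial timeline data.frame.
#' @param event alignment event, as in [compute_psth()].
#' @param baseline_window_ms,response_window_ms half-open windows, ms.
#' @return scalar z value (possibly `Inf`/`-Inf`/`NaN`).
#' @export
zscore_response <- function(spikes, trials, event = "cue_on",
                            baseline_window_ms = c(-100, 0),
                            response_window_ms = c(40, 140)) {
  trials <- .trials_with_event(trials, event)
  if (nrow(trials) < 2) stop("need at least 2 trials")
  ev <- trials[[paste0("t_", event)]]
  base <- rate_in_window(spikes, ev, baseline_window_ms)
  resp <- rate_in_window(spikes, ev, response_window_ms)
  diff <- mean(resp) - mean(base)
  s <- stats::sd(base)
  if (s == 0) {
    message("zero baseline SD; z reported as signed infinity")
    return(sign(diff) * Inf)
  }
  diff / s
}
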
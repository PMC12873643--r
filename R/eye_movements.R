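#' Detect saccades in a 240 Hz eye-position trace
#'
#' Candidate epochs are maximal runs of samples whose 2-D eye speed (central
#' differences; 3-sample median prefilter on each axis when the trace is
#' noisy) exceeds `speed_thresh_dps`. Each run is extended outward to where
#' speed falls below `onset_thresh_dps` so that onset and offset sit at the
#' flanks of the movement, then kept if its duration exceeds
#' `min_duration_ms` and its net displacement (straight-line distance
#' between epoch endpoints) exceeds `min_amplitude_deg`. All three
#' thresholds are strict inequalities.
#'
#' @param trace data.frame with columns `t`, `x_deg`, `y_deg`, uniformly
#'   sampled (default 240 Hz assumed from `t`).
#' @param speed_thresh_dps core speed criterion, degrees/s (default 50).
#' @param min_amplitude_deg amplitude criterion, degrees (default 2).
#' @param min_duration_ms duration criterion on the suprathreshold run, ms
#'   (default 15).
#' @param onset_thresh_dps lower speed bound used to refine epoch edges.
#' @param median_filter apply the 3-sample median prefilter (default: only
#'   when the trace looks noisy, i.e. median absolute sample-to-sample step
#'   > 0).
#' @return data.frame of saccade events: `onset_s, offset_s, duration_ms,
#'   amplitude_deg, peak_speed_dps` (zero rows if none).
#' @export
detect_saccades <- function(trace, speed_thresh_dps = 50,
                            min_amplitude_deg = 2, min_duration_ms = 15,
                            onset_thresh_dps = 10, median_filter = NULL) {
  n <- nrow(trace)
  if (n < 3) stop("trace must have at least 3 samples")
  dt <- stats::median(diff(trace$t))
  x <- trace$x_deg; y <- trace$y_deg
  if (is.null(median_filter)) {
    median_filter <- stats::median(abs(diff(x))) > 1e-6
  }
  if (median_filter) {
    x <- stats::runmed(x, 3); y <- stats::runmed(y, 3)
  }
  # central-difference speed; endpoints get one-sided differences
  vx <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / dt
  vy <- c(y[2] - y[1], (y[3:n] - y[1:(n - 2)]) / 2, y[n] - y[n - 1]) / dt
  speed <- sqrt(vx^2 + vy^2)
  fast <- speed > speed_thresh_dps
  if (!any(fast)) {
    return(.empty_saccades())
  }
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  slow <- speed <= onset_thresh_dps
  out <- list()
  for (k in seq_len(nrow(runs))) {
    i0 <- runs[k, 1]; i1 <- runs[k, 2]
    dur_ms <- (trace$t[i1] - trace$t[i0] + dt) * 1000
    if (!(dur_ms > min_duration_ms)) next
    # extend to the surrounding low-speed flanks; measure the displacement
    # between the bounding stationary samples so the flanks are included
    e0 <- i0; while (e0 > 1 && !slow[e0 - 1]) e0 <- e0 - 1
    e1 <- i1; while (e1 < n && !slow[e1 + 1]) e1 <- e1 + 1
    a0 <- max(e0 - 1, 1); a1 <- min(e1 + 1, n)
    amp <- sqrt((x[a1] - x[a0])^2 + (y[a1] - y[a0])^2)
    if (!(amp > min_amplitude_deg)) next
    out[[length(out) + 1]] <- data.frame(
      onset_s = trace$t[e0], offset_s = trace$t[e1],
      duration_ms = dur_ms, amplitude_deg = amp,
      peak_speed_dps = max(speed[e0:e1]))
  }
  if (!length(out)) return(.empty_saccades())
  res <- do.call(rbind, out)
  # merge detections that share an extended epoch (can happen with noise)
  res <- res[!duplicated(res$onset_s), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.empty_saccades <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0),
             duration_ms = numeric(0), amplitude_deg = numeric(0),
             peak_speed_dps = numeric(0))
}

#' Event-aligned saccade probability time course
#'
#' Per bin, the fraction of trials containing at least one saccade onset in
#' that bin (a saccade is assigned to a bin by its onset sample).
#'
#' @param saccades saccade table from [detect_saccades()].
#' @param trials trial timeline data.frame.
#' @param align_event `"cue_on"`, `"twopatch_on"` or `"change_on"`.
#' @param range_ms analysis range, ms relative to the event.
#' @param bin_ms bin width, ms.
#' @return data.frame with `bin_start_ms`, `probability`.
#' @export
saccade_probability_timecourse <- function(saccades, trials,
                                           align_event = "change_on",
                                           range_ms = c(-400, 400),
                                           bin_ms = 20) {
  align_event <- match.arg(align_event, c("cue_on", "twopatch_on", "change_on"))
  trials <- .trials_with_event(trials, align_event)
  stopifnot(nrow(trials) >= 1)
  n_bins <- as.integer(round((range_ms[2] - range_ms[1]) / bin_ms))
  edges <- range_ms[1] + bin_ms * (0:n_bins)
  ev <- trials[[paste0("t_", align_event)]]
  hit <- matrix(FALSE, nrow(trials), n_bins)
  for (i in seq_len(nrow(trials))) {
    rel <- (saccades$onset_s - ev[i]) * 1000
    rel <- rel[rel >= range_ms[1] & rel < range_ms[2]]
    if (length(rel)) {
      hit[i, unique(floor((rel - range_ms[1]) / bin_ms) + 1)] <- TRUE
    }
  }
  data.frame(bin_start_ms = edges[-length(edges)],
             probability = colMeans(hit))
}

#' Saccade probability within an event-relative interval
#'
#' Fraction of trials with at least one saccade onset inside the window;
#' the interval summary quoted alongside the baseline/response bars of the
#' probability plots.
#'
#' @param saccades saccade table.
#' @param trials trial timeline.
#' @param align_event alignment event.
#' @param window_ms half-open window, ms relative to the event.
#' @return scalar probability.
#' @export
saccade_interval_probability <- function(saccades, trials,
                                         align_event = "change_on",
                                         window_ms = c(40, 140)) {
  align_event <- match.arg(align_event, c("cue_on", "twopatch_on", "change_on"))
  trials <- .trials_with_event(trials, align_event)
  ev <- trials[[paste0("t_", align_event)]]
  mean(vapply(ev, function(e) {
    rel <- (saccades$onset_s - e) * 1000
    any(rel >= window_ms[1] & rel < window_ms[2])
  }, logical(1)))
}

#' Saccade-free trial mask for one epoch definition
#'
#' Flags each trial `TRUE` when no saccade onset falls inside the union of
#' the epoch's baseline and response windows, so analyses can be repeated on
#' saccade-free trials only.
#'
#' @param saccades saccade table.
#' @param trials trial timeline.
#' @param spec an [epoch_spec()] giving the event and windows.
#' @return logical vector, one flag per trial (`TRUE` = saccade-free).
#' @export
saccade_free_mask <- function(saccades, trials, spec) {
  stopifnot(inherits(spec, "epoch_spec"))
  ev <- trials[[paste0("t_", spec$event)]]
  windows <- unique(list(spec$noise_window, spec$signal_window))
  vapply(ev, function(e) {
    rel <- (saccades$onset_s - e) * 1000
    !any(vapply(windows, function(w) {
      any(rel >= w[1] & rel < w[2])
    }, logical(1)))
  }, logical(1))
}
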
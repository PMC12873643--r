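#' Area under the ROC curve for two sets of spike counts
#'
#' Probability that a randomly drawn signal count exceeds a randomly drawn
#' noise count, with ties given half credit:
#' `sum over pairs (s > n) + 0.5 * (s == n), divided by n_s * n_n`.
#' Computed via the rank form of the Mann-Whitney U statistic (midranks make
#' the two forms identical). 0.5 means indistinguishable sets; values above
#' 0.5 mean signal counts tend to be larger.
#'
#' @param signal,noise non-empty numeric vectors (spike counts or rates).
#' @return AROC value in `[0, 1]`.
#' @export
auroc <- function(signal, noise) {
  ns <- length(signal); nn <- length(noise)
  if (ns == 0 || nn == 0) stop("both count sets must be non-empty")
  r <- rank(c(signal, noise))
  u <- sum(r[seq_len(ns)]) - ns * (ns + 1) / 2
  u / (ns * nn)
}

#' Bootstrap percentile confidence interval for an AROC
#'
#' Resamples the signal and noise sets independently with replacement
#' (preserving their sizes), recomputes the AROC for each replicate, and
#' returns the 2.5 and 97.5 percentiles of the replicate distribution.
#'
#' @param signal,noise non-empty numeric vectors.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param rng_seed integer seed.
#' @param probs percentiles to return.
#' @return numeric `c(lo, hi)`.
#' @export
bootstrap_auroc_ci <- function(signal, noise, n_boot = 1000, rng_seed = 1,
                               probs = c(0.025, 0.975)) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  ns <- length(signal); nn <- length(noise)
  if (ns == 0 || nn == 0) stop("both count sets must be non-empty")
  reps <- with_seed(rng_seed, {
    vapply(seq_len(n_boot), function(i) {
      auroc(signal[sample.int(ns, ns, replace = TRUE)],
            noise[sample.int(nn, nn, replace = TRUE)])
    }, numeric(1))
  })
  unname(stats::quantile(reps, probs))
}

# Classify a unit's AROC by whether its 95% CI excludes 0.5.
.significance_class <- function(ci_lo, ci_hi) {
  if (ci_lo > 0.5) "positive" else if (ci_hi < 0.5) "negative" else "ns"
}

#' Epoch specification for the three discriminability measures
#'
#' The three epoch-windowed AROC definitions used throughout:
#' * `cue_onset`: response `[40, 140)` ms after cue onset vs baseline
#'   `[-100, 0)` ms before cue onset, on contralateral-cue change trials.
#' * `delay_spatial`: end-of-delay rates `[-200, 0)` ms before change onset,
#'   contralateral-cue trials (signal) vs ipsilateral-cue trials (noise).
#' * `change_onset`: response `[40, 140)` ms after change onset vs baseline
#'   `[-100, 0)` ms before change onset, on contralateral-cue change trials,
#'   optionally restricted to one tilt category.
#'
#' No-change trials are excluded everywhere. Whether the cue/change measures
#' are restricted to contralateral-cue trials is configurable
#' (`cue_side_filter`); contra-only is the default.
#'
#' @param kind `"cue_onset"`, `"delay_spatial"` or `"change_onset"`.
#' @param tilt `"small"`, `"medium"`, `"large"` or `NULL` (no tilt filter);
#'   only meaningful for `change_onset`.
#' @param cue_side_filter cue side used for the within-trial epochs
#'   (`"contra"` or `"both"`); ignored for `delay_spatial`, which always
#'   contrasts the two sides.
#' @return an `epoch_spec` list with the event, windows and trial filters.
#' @export
epoch_spec <- function(kind, tilt = NULL, cue_side_filter = "contra") {
  kind <- match.arg(kind, c("cue_onset", "delay_spatial", "change_onset"))
  cue_side_filter <- match.arg(cue_side_filter, c("contra", "both"))
  if (!is.null(tilt)) {
    tilt <- match.arg(tilt, c("small", "medium", "large"))
    if (kind != "change_onset") stop("tilt filter applies to change_onset only")
  }
  def <- switch(kind,
    cue_onset = list(event = "cue_on",
                     signal_window = c(40, 140), noise_window = c(-100, 0)),
    change_onset = list(event = "change_on",
                        signal_window = c(40, 140), noise_window = c(-100, 0)),
    delay_spatial = list(event = "change_on",
                         signal_window = c(-200, 0), noise_window = c(-200, 0)))
  structure(c(def, list(kind = kind, tilt = tilt,
                        cue_side_filter = cue_side_filter)),
            class = "epoch_spec")
}

# Trial sets (row indices) for the signal and noise rate distributions.
.epoch_trial_sets <- function(trials, spec) {
  keep <- trials$is_change          # no-change trials excluded everywhere
  if (spec$kind == "delay_spatial") {
    list(signal = which(keep & trials$cue_side == "contra"),
         noise = which(keep & trials$cue_side == "ipsi"))
  } else {
    if (spec$cue_side_filter == "contra") keep <- keep & trials$cue_side == "contra"
    if (!is.null(spec$tilt)) keep <- keep & trials$tilt_category %in% spec$tilt
    idx <- which(keep)
    list(signal = idx, noise = idx)
  }
}

#' Epoch-windowed discriminability of one unit
#'
#' Computes the AROC for one unit and one [epoch_spec()], with a bootstrap
#' 95% CI and the CI-versus-0.5 significance class. Units with fewer than
#' `min_trials` trials in either set are excluded (`NULL` return with a
#' message).
#'
#' @param spikes the unit's sorted spike times (seconds).
#' @param trials trial timeline of the unit's session.
#' @param spec an [epoch_spec()].
#' @param n_boot bootstrap replicates for the CI; 0 skips the CI (the
#'   significance class is then `NA`).
#' @param rng_seed integer seed for the bootstrap.
#' @param min_trials minimum trials per set (default 5).
#' @return one-row data.frame: `epoch, tilt_category, auroc, ci_lo, ci_hi,
#'   significance, n_signal, n_noise`, or `NULL` if excluded.
#' @export
epoch_discriminability <- function(spikes, trials, spec, n_boot = 1000,
                                   rng_seed = 1, min_trials = 5) {
  stopifnot(inherits(spec, "epoch_spec"))
  sets <- .epoch_trial_sets(trials, spec)
  if (length(sets$signal) < min_trials || length(sets$noise) < min_trials) {
    message("unit excluded for epoch ", spec$kind,
            ": fewer than ", min_trials, " trials per set")
    return(NULL)
  }
  ev <- trials[[paste0("t_", spec$event)]]
  sig <- rate_in_window(spikes, ev[sets$signal], spec$signal_window)
  noi <- rate_in_window(spikes, ev[sets$noise], spec$noise_window)
  a <- auroc(sig, noi)
  if (n_boot > 0) {
    ci <- bootstrap_auroc_ci(sig, noi, n_boot = n_boot, rng_seed = rng_seed)
    signif <- .significance_class(ci[1], ci[2])
  } else {
    ci <- c(NA_real_, NA_real_); signif <- NA_character_
  }
  data.frame(epoch = spec$kind,
             tilt_category = if (is.null(spec$tilt)) NA_character_ else spec$tilt,
             auroc = a, ci_lo = ci[1], ci_hi = ci[2],
             significance = signif,
             n_signal = length(sets$signal), n_noise = length(sets$noise),
             stringsAsFactors = FALSE)
}

#' Population summary of unit AROC values
#'
#' Median AROC with a bootstrap CI (resampling units with replacement) and
#' the prevalence of units with significant positive / negative
#' discriminability.
#'
#' @param results data.frame with columns `auroc` and `significance` (one
#'   row per unit), e.g. from stacking [epoch_discriminability()] outputs.
#' @param n_boot bootstrap replicates (default 1000).
#' @param rng_seed integer seed.
#' @return list: `median`, `median_ci` (length 2), `pct_positive`,
#'   `pct_negative` (percentages), `n_units`.
#' @export
population_summary <- function(results, n_boot = 1000, rng_seed = 1) {
  if (nrow(results) == 0) stop("no unit results to summarize")
  x <- results$auroc
  med <- stats::median(x)
  ci <- if (length(x) == 1) {
    c(x, x)
  } else {
    reps <- with_seed(rng_seed, {
      vapply(seq_len(n_boot), function(i) {
        stats::median(x[sample.int(length(x), replace = TRUE)])
      }, numeric(1))
    })
    unname(stats::quantile(reps, c(0.025, 0.975)))
  }
  list(median = med, median_ci = ci,
       pct_positive = 100 * mean(results$significance == "positive"),
       pct_negative = 100 * mean(results$significance == "negative"),
       n_units = nrow(results))
}

#' Binwise AROC time course (contra vs ipsi)
#'
#' AROC per non-overlapping bin (default 20 ms) comparing spike counts on
#' contralateral-cue versus ipsilateral-cue change trials, for delay-period
#' visualization. Values above 0.5 indicate preference for the contralateral
#' cue.
#'
#' @param spikes sorted spike times (seconds).
#' @param trials trial timeline data.frame.
#' @param event alignment event (default `"change_on"`).
#' @param range_ms analysis range, ms relative to the event.
#' @param bin_ms bin width, ms.
#' @return data.frame with `bin_start_ms`, `auroc`.
#' @export
auroc_timecourse <- function(spikes, trials, event = "change_on",
                             range_ms = c(-800, 0), bin_ms = 20) {
  event <- match.arg(event, c("cue_on", "twopatch_on", "change_on"))
  trials <- trials[trials$is_change, , drop = FALSE]
  contra <- trials[trials$cue_side == "contra", ]
  ipsi <- trials[trials$cue_side == "ipsi", ]
  if (nrow(contra) == 0 || nrow(ipsi) == 0) {
    stop("need change trials with both cue sides")
  }
  n_bins <- (range_ms[2] - range_ms[1]) / bin_ms
  stopifnot(abs(n_bins - round(n_bins)) < 1e-9)
  n_bins <- as.integer(round(n_bins))
  edges <- range_ms[1] + bin_ms * (0:n_bins)
  ev_c <- contra[[paste0("t_", event)]]
  ev_i <- ipsi[[paste0("t_", event)]]
  vals <- vapply(seq_len(n_bins), function(b) {
    w <- c(edges[b], edges[b + 1])
    auroc(count_in_window(spikes, ev_c, w), count_in_window(spikes, ev_i, w))
  }, numeric(1))
  data.frame(bin_start_ms = edges[-length(edges)], auroc = vals)
}
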
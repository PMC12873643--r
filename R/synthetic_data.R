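#' Cohort specification for synthetic sessions
#'
#' Describes one training cohort of the change-detection task family:
#' the assigned performance level, how many sessions and trials to simulate,
#' whether no-change catch trials are interleaved, and which lick archetype
#' the cohort expresses. The stimulus-reward association cohort
#' (`intermediate`) is never given catch trials, matching its task rules.
#'
#' @param level `"naive"`, `"intermediate"` or `"expert"`.
#' @param n_sessions number of sessions (>= 1).
#' @param trials_per_session trials per session (>= 1).
#' @param has_no_change_trials interleave an equal number of no-change catch
#'   trials? Defaults to `TRUE` except for the intermediate cohort, where it
#'   must be `FALSE`.
#' @param lick_archetype `"early_peak"`, `"ramping"` or `"change_locked"`;
#'   defaults to the archetype characteristic of `level`.
#' @param tilt_set orientation-change amplitudes (degrees) sampled on change
#'   trials; subset of `c(9, 12, 15, 20, 30)`.
#' @param probe_frac fraction of change trials presented without the spatial
#'   cue (probe trials); 0 disables probes.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(level,
                        n_sessions = 1L,
                        trials_per_session = 200L,
                        has_no_change_trials = NULL,
                        lick_archetype = NULL,
                        tilt_set = c(9, 12, 15, 20, 30),
                        probe_frac = 0) {
  level <- match.arg(level, c("naive", "intermediate", "expert"))
  if (is.null(has_no_change_trials)) {
    has_no_change_trials <- level != "intermediate"
  }
  if (level == "intermediate" && has_no_change_trials) {
    stop("the intermediate cohort is not exposed to no-change catch trials")
  }
  if (is.null(lick_archetype)) {
    lick_archetype <- switch(level,
      naive = "early_peak", intermediate = "ramping", expert = "change_locked")
  }
  lick_archetype <- match.arg(lick_archetype,
                              c("early_peak", "ramping", "change_locked"))
  n_sessions <- as.integer(n_sessions)
  trials_per_session <- as.integer(trials_per_session)
  if (is.na(n_sessions) || n_sessions < 1L) {
    stop("n_sessions must be a positive count")
  }
  if (is.na(trials_per_session) || trials_per_session < 1L) {
    stop("trials_per_session must be a positive count")
  }
  if (!all(tilt_set %in% c(9, 12, 15, 20, 30))) {
    stop("tilt_set must be a subset of {9, 12, 15, 20, 30} degrees")
  }
  stopifnot(probe_frac >= 0, probe_frac <= 1)
  structure(list(level = level,
                 n_sessions = n_sessions,
                 trials_per_session = trials_per_session,
                 has_no_change_trials = has_no_change_trials,
                 lick_archetype = lick_archetype,
                 tilt_set = tilt_set,
                 probe_frac = probe_frac),
            class = "cohort_spec")
}

#' Map a tilt amplitude to its category
#'
#' Large = 30 degrees, medium = 15 or 20, small = 9 or 12.
#'
#' @param tilt_deg numeric vector of orientation-change amplitudes.
#' @return character vector (`"small"`, `"medium"`, `"large"`), `NA` for
#'   no-change trials (`tilt_deg` 0 or `NA`).
#' @export
tilt_category <- function(tilt_deg) {
  out <- rep(NA_character_, length(tilt_deg))
  out[tilt_deg %in% c(9, 12)] <- "small"
  out[tilt_deg %in% c(15, 20)] <- "medium"
  out[tilt_deg %in% 30] <- "large"
  bad <- !is.na(tilt_deg) & tilt_deg != 0 & is.na(out)
  if (any(bad)) stop("unknown tilt amplitude: ", tilt_deg[bad][1])
  out
}

# Printed epoch duration ranges (seconds): noise, cue, 2-patch.
.epoch_ranges <- list(noise = c(0.2, 0.3),
                      cue = c(0.36, 1.55),
                      twopatch = c(0.84, 3.6))

#' Simulate the trial timeline of one session
#'
#' Draws the four-epoch trial sequence (noise, cue, 2-patch, change) with
#' epoch durations uniform in the task's ranges (noise 0.2-0.3 s, cue
#' 0.36-1.55 s, 2-patch 0.84-3.6 s). Cue side alternates in interleaved
#' blocks so the two sides are balanced. For cohorts with catch trials a
#' random half of trials is no-change; the intermediate cohort has a change
#' on every trial. `outcome` is left `NA`; it is filled in by behavioral
#' scoring once licks exist (see [score_trial()]).
#'
#' @param spec a [cohort_spec()].
#' @param rng_seed integer seed.
#' @param session_id session identifier string.
#' @param block_size trials per cue-side block.
#' @param iti_range_s inter-trial interval range (uniform), seconds.
#' @return a data.frame of trial events, one row per trial, with columns
#'   `session_id, trial_id, cue_side, t_noise_on, t_cue_on, t_twopatch_on,
#'   t_change_on, tilt_deg, tilt_category, is_change, is_probe, outcome`.
#' @export
simulate_trial_timeline <- function(spec, rng_seed, session_id = "s1",
                                    block_size = 8L,
                                    iti_range_s = c(1, 2)) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$trials_per_session
  with_seed(rng_seed, {
    # interleaved cue-side blocks, balanced up to the final partial block
    n_blocks <- ceiling(n / block_size)
    first <- sample(c("contra", "ipsi"), 1L)
    sides <- rep(rep(c(first, setdiff(c("contra", "ipsi"), first)),
                     length.out = n_blocks), each = block_size)[seq_len(n)]
    d_noise <- stats::runif(n, .epoch_ranges$noise[1], .epoch_ranges$noise[2])
    d_cue <- stats::runif(n, .epoch_ranges$cue[1], .epoch_ranges$cue[2])
    d_two <- stats::runif(n, .epoch_ranges$twopatch[1], .epoch_ranges$twopatch[2])
    iti <- stats::runif(n, iti_range_s[1], iti_range_s[2])
    trial_len <- d_noise + d_cue + d_two + 1.5   # 1.5 s change/response epoch
    t_noise <- cumsum(iti + c(0, trial_len[-n]))
    is_change <- if (spec$has_no_change_trials) {
      half <- sample(n) <= round(n / 2)
      half
    } else {
      rep(TRUE, n)
    }
    tilt <- ifelse(is_change,
                   sample(spec$tilt_set, n, replace = TRUE), 0)
    is_probe <- rep(FALSE, n)
    if (spec$probe_frac > 0) {
      idx <- which(is_change)
      is_probe[sample(idx, round(spec$probe_frac * length(idx)))] <- TRUE
    }
    data.frame(
      session_id = session_id,
      trial_id = seq_len(n),
      cue_side = sides,
      t_noise_on = t_noise,
      t_cue_on = t_noise + d_noise,
      t_twopatch_on = t_noise + d_noise + d_cue,
      t_change_on = t_noise + d_noise + d_cue + d_two,
      tilt_deg = tilt,
      tilt_category = tilt_category(tilt),
      is_change = is_change,
      is_probe = is_probe,
      outcome = NA_character_,
      stringsAsFactors = FALSE
    )
  })
}

#' Response-kernel parameters for a simulated unit
#'
#' The transient kernel is a peak-normalized difference of exponentials
#' (causal: zero before `latency_ms`, rising with `rise_ms`, decaying with
#' `decay_ms`), so amplitudes are peak rates in Hz. Defaults place the
#' transient inside the 40-140 ms analysis response window.
#'
#' @param baseline_hz tonic rate.
#' @param cue_amp_hz peak rate added by the cue-onset transient.
#' @param change_amp_hz peak rate added by the change-onset transient at the
#'   largest tilt (30 degrees); smaller tilts scale linearly with tilt/30.
#' @param delay_contra_bias_hz sustained rate added from 2-patch onset to
#'   change onset on contralateral-cue trials.
#' @param latency_ms,rise_ms,decay_ms kernel timing, ms; `decay_ms` must
#'   exceed `rise_ms`.
#' @return a `rate_kernel_params` list.
#' @export
rate_kernel_params <- function(baseline_hz = 8,
                               cue_amp_hz = 0,
                               change_amp_hz = 0,
                               delay_contra_bias_hz = 0,
                               latency_ms = 40,
                               rise_ms = 10,
                               decay_ms = 60) {
  stopifnot(baseline_hz >= 0, cue_amp_hz >= 0, change_amp_hz >= 0,
            delay_contra_bias_hz >= 0, latency_ms >= 0,
            rise_ms > 0, decay_ms > rise_ms)
  structure(list(baseline_hz = baseline_hz,
                 cue_amp_hz = cue_amp_hz,
                 change_amp_hz = change_amp_hz,
                 delay_contra_bias_hz = delay_contra_bias_hz,
                 latency_ms = latency_ms,
                 rise_ms = rise_ms,
                 decay_ms = decay_ms),
            class = "rate_kernel_params")
}

# Peak-normalized difference-of-exponentials kernel, t in seconds.
.transient_kernel <- function(t, latency_ms, rise_ms, decay_ms) {
  lat <- latency_ms / 1000; tr <- rise_ms / 1000; td <- decay_ms / 1000
  u <- t - lat
  k <- numeric(length(t))
  pos <- !is.na(u) & u > 0
  g <- exp(-u[pos] / td) - exp(-u[pos] / tr)
  u_peak <- tr * td / (td - tr) * log(td / tr)
  peak <- exp(-u_peak / td) - exp(-u_peak / tr)
  k[pos] <- g / peak
  k
}

#' Closed-form time integral of the unit-peak transient kernel
#'
#' Area (in seconds) under the peak-normalized difference-of-exponentials
#' kernel; multiplying by an amplitude in Hz gives the expected number of
#' extra spikes per event.
#'
#' @param params a [rate_kernel_params()].
#' @return scalar area in seconds.
#' @export
kernel_area <- function(params) {
  tr <- params$rise_ms / 1000; td <- params$decay_ms / 1000
  u_peak <- tr * td / (td - tr) * log(td / tr)
  peak <- exp(-u_peak / td) - exp(-u_peak / tr)
  (td - tr) / peak
}

#' Event-locked firing rate of a simulated unit at given times
#'
#' Rate = baseline + cue-onset transient + change-onset transient (change
#' trials only, scaled by tilt/30) + sustained contralateral delay bias
#' active from 2-patch onset to change onset on contralateral-cue trials.
#' Any negative value (impossible with non-negative amplitudes, but possible
#' for user-supplied modified kernels) is clamped to zero with a warning.
#'
#' @param t times in seconds from session start (vector).
#' @param trial a single trial's events (one row of a timeline data.frame).
#' @param params a [rate_kernel_params()].
#' @return rate in Hz at each `t`.
#' @export
event_locked_rate <- function(t, trial, params) {
  stopifnot(inherits(params, "rate_kernel_params"), nrow(trial) == 1L)
  r <- rep(params$baseline_hz, length(t))
  if (params$cue_amp_hz > 0) {
    r <- r + params$cue_amp_hz *
      .transient_kernel(t - trial$t_cue_on, params$latency_ms,
                        params$rise_ms, params$decay_ms)
  }
  if (params$change_amp_hz > 0 && isTRUE(trial$is_change)) {
    amp <- params$change_amp_hz * trial$tilt_deg / 30
    r <- r + amp * .transient_kernel(t - trial$t_change_on, params$latency_ms,
                                     params$rise_ms, params$decay_ms)
  }
  if (params$delay_contra_bias_hz > 0 && trial$cue_side == "contra") {
    in_delay <- t >= trial$t_twopatch_on & t < trial$t_change_on
    r[in_delay] <- r[in_delay] + params$delay_contra_bias_hz
  }
  if (any(r < 0)) {
    warning("negative rate clamped to 0")
    r[r < 0] <- 0
  }
  r
}

#' Sample an inhomogeneous Poisson process by thinning
#'
#' Homogeneous candidates at `rate_max` on `[t0, t1)` are thinned by the
#' ratio `rate_fn(t) / rate_max`. `rate_fn` must be bounded by `rate_max`
#' on the interval.
#'
#' @param rate_fn vectorized function of time (seconds) returning Hz.
#' @param t0,t1 interval bounds in seconds; `t1 <= t0` yields no spikes.
#' @param rate_max known upper bound on `rate_fn` over the interval.
#' @param rng_seed integer seed.
#' @return sorted spike times strictly within `[t0, t1)`.
#' @export
sample_inhomogeneous_poisson <- function(rate_fn, t0, t1, rate_max, rng_seed) {
  stopifnot(rate_max >= 0)
  if (t1 <= t0 || rate_max == 0) return(numeric(0))
  with_seed(rng_seed, {
    n_cand <- stats::rpois(1, rate_max * (t1 - t0))
    if (n_cand == 0) return(numeric(0))
    cand <- sort(stats::runif(n_cand, t0, t1))
    rates <- rate_fn(cand)
    if (any(rates > rate_max * (1 + 1e-9))) {
      stop("rate_fn exceeds the stated rate_max bound")
    }
    cand[stats::runif(n_cand) < rates / rate_max]
  })
}

# Lick-intensity archetypes (Hz) as a function of absolute time for a trial.
# early_peak: burst at trial start decaying fast, low tonic baseline.
# ramping:    linear climb through the trial, sustained past the change with a
#             reward-locked bump ~0.95 s after the change.
# change_locked: near-silent until the change, then a transient centered
#             ~450 ms after change onset (expert reaction-time scale).
.lick_intensity <- function(t, archetype, trial, scale = 1) {
  t0 <- trial$t_noise_on; tc <- trial$t_change_on
  base <- switch(archetype,
    early_peak = 0.05 + 10 * exp(-pmax(t - t0, 0) / 0.3),
    ramping = {
      ramp <- 0.2 + 1.6 * pmin(pmax((t - t0) / (tc - t0), 0), 1)
      bump <- if (isTRUE(trial$is_change)) {
        6 * exp(-((t - tc - 0.95) / 0.12)^2 / 2)
      } else 0
      ramp + bump
    },
    change_locked = {
      amp <- if (isTRUE(trial$is_change)) 9.2 else 0
      if (isTRUE(trial$is_probe)) amp <- amp * 0.84
      0.01 + amp * exp(-((t - tc - 0.45) / 0.08)^2 / 2)
    },
    stop("unknown lick archetype: ", archetype))
  scale * base
}

#' Simulate lick times for one trial
#'
#' Licks are an inhomogeneous Poisson process whose intensity follows one of
#' three archetypes: `early_peak` (burst after trial start, then decay),
#' `ramping` (steady climb through the trial peaking after the change), or
#' `change_locked` (near-zero before the change, transient ~450 ms after it).
#'
#' @param archetype one of `"early_peak"`, `"ramping"`, `"change_locked"`.
#' @param trial one row of a trial timeline.
#' @param rng_seed integer seed.
#' @param intensity_scale multiplier on the archetype intensity (0 = no licks).
#' @param t_end_rel_change end of the simulated lick window, seconds after
#'   change onset.
#' @return sorted lick times in seconds from session start.
#' @export
simulate_licks <- function(archetype, trial, rng_seed, intensity_scale = 1,
                           t_end_rel_change = 1.5) {
  archetype <- match.arg(archetype,
                         c("early_peak", "ramping", "change_locked"))
  stopifnot(nrow(trial) == 1L, intensity_scale >= 0)
  rate_max <- intensity_scale * 12  # bounds all archetype intensities
  sample_inhomogeneous_poisson(
    function(t) .lick_intensity(t, archetype, trial, intensity_scale),
    trial$t_noise_on, trial$t_change_on + t_end_rel_change,
    rate_max, rng_seed)
}

#' Simulate a 240 Hz eye-position trace with scheduled saccades
#'
#' Each saccade is a smoothstep (cubic sigmoidal) horizontal displacement of
#' the scheduled amplitude and duration, on top of i.i.d. Gaussian position
#' noise. Saccade direction alternates sign so the trace does not drift far.
#'
#' @param duration_s trace duration in seconds.
#' @param saccade_schedule data.frame with columns `onset_s`, `amplitude_deg`,
#'   `duration_ms`; may have zero rows. Saccades must lie within the trace
#'   and not overlap.
#' @param noise_sd_deg SD of additive Gaussian position noise per axis.
#' @param rng_seed integer seed.
#' @param sample_rate_hz sampling rate (240 Hz camera).
#' @param session_id identifier stored with the trace.
#' @return data.frame with columns `session_id, t, x_deg, y_deg, pupil`.
#' @export
simulate_eye_trace <- function(duration_s, saccade_schedule = NULL,
                               noise_sd_deg = 0, rng_seed = 1,
                               sample_rate_hz = 240, session_id = "s1") {
  n <- floor(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  x <- numeric(n)
  if (!is.null(saccade_schedule) && nrow(saccade_schedule) > 0) {
    ss <- saccade_schedule[order(saccade_schedule$onset_s), , drop = FALSE]
    ends <- ss$onset_s + ss$duration_ms / 1000
    if (any(ends > duration_s) || any(ss$onset_s < 0)) {
      stop("scheduled saccades must lie within [0, duration]")
    }
    if (nrow(ss) > 1 && any(ss$onset_s[-1] < ends[-nrow(ss)])) {
      stop("scheduled saccades overlap")
    }
    sign <- 1
    for (i in seq_len(nrow(ss))) {
      u <- (t - ss$onset_s[i]) / (ss$duration_ms[i] / 1000)
      u <- pmin(pmax(u, 0), 1)
      x <- x + sign * ss$amplitude_deg[i] * (3 * u^2 - 2 * u^3)
      sign <- -sign
    }
  }
  with_seed(rng_seed, {
    data.frame(session_id = session_id,
               t = t,
               x_deg = x + stats::rnorm(n, 0, noise_sd_deg),
               y_deg = stats::rnorm(n, 0, noise_sd_deg),
               pupil = 1 + 0.05 * sin(2 * pi * t / 7) +
                 stats::rnorm(n, 0, noise_sd_deg * 0.01),
               stringsAsFactors = FALSE)
  })
}

#' Default level-by-layer gain table for the generator
#'
#' Synthetic ground truth encoding the qualitative pattern of the study:
#' superficial cue responses present at all levels and growing with training;
#' deep cue responses, delay-period contralateral bias, and change responses
#' absent in the naive state and present after training. The values are
#' multipliers on the base kernel amplitudes, not estimates from data.
#'
#' @return data.frame with columns `level, layer, cue_gain, delay_gain,
#'   change_gain`.
#' @export
default_gain_table <- function() {
  data.frame(
    level = rep(c("naive", "intermediate", "expert"), each = 2),
    layer = rep(c("superficial", "deep"), 3),
    cue_gain = c(1.0, 0.0, 1.5, 0.6, 2.0, 1.0),
    delay_gain = c(0.0, 0.0, 0.0, 0.5, 0.0, 1.0),
    change_gain = c(0.1, 0.0, 0.5, 0.8, 0.8, 1.2),
    stringsAsFactors = FALSE
  )
}

# Look up one row of a gain table.
.gain_row <- function(gain_table, level, layer) {
  row <- gain_table[gain_table$level == level & gain_table$layer == layer, ]
  if (nrow(row) != 1L) stop("gain table has no row for ", level, "/", layer)
  row
}

#' Simulate one complete session
#'
#' Chains the timeline, lick, spike and eye generators for one session of a
#' cohort and scores trial outcomes from the simulated licks. Units are split
#' between superficial and deep layers; each unit's kernel amplitudes are the
#' base amplitudes scaled by the level-by-layer gain table, a per-session
#' gain factor, and per-unit log-normal jitter. The per-unit realized
#' amplitudes are returned as ground truth for recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @param session_id identifier.
#' @param seed global integer seed for this session; sub-streams (timeline,
#'   licks, spikes, eye) derive independent seeds from it.
#' @param n_units units to simulate.
#' @param base_params a [rate_kernel_params()] giving base amplitudes before
#'   gain scaling.
#' @param gain_table level-by-layer gains, see [default_gain_table()].
#' @param session_gain_sd SD of the log-normal session-level gain factor
#'   (shared by all units in the session; creates realistic between-session
#'   variance).
#' @param unit_jitter_sd SD of per-unit log-normal amplitude jitter.
#' @param simulate_eye generate the 240 Hz eye trace? (Skipping it speeds up
#'   large simulation studies that do not use eye data.)
#' @param saccade_rate_hz mean rate of spontaneous saccades in the eye trace.
#' @return list with elements `session` (1-row data.frame: session_id, level,
#'   archetype), `events`, `units`, `spikes`, `licks`, `eye` (or `NULL`),
#'   `ground_truth`.
#' @export
simulate_session <- function(spec, session_id, seed,
                             n_units = 8L,
                             base_params = rate_kernel_params(
                               baseline_hz = 8, cue_amp_hz = 20,
                               change_amp_hz = 20, delay_contra_bias_hz = 4),
                             gain_table = default_gain_table(),
                             session_gain_sd = 0.1,
                             unit_jitter_sd = 0.15,
                             simulate_eye = TRUE,
                             saccade_rate_hz = 0.08) {
  events <- simulate_trial_timeline(spec, derive_seed(seed, "timeline"),
                                    session_id = session_id)
  # licks + behavioral scoring
  licks <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    lt <- simulate_licks(spec$lick_archetype, events[i, ],
                         derive_seed(seed, "licks", i))
    licks[[i]] <- if (length(lt)) {
      data.frame(session_id = session_id, trial_id = events$trial_id[i],
                 lick_time_s = lt, stringsAsFactors = FALSE)
    } else NULL
  }
  licks <- if (any(!vapply(licks, is.null, logical(1)))) {
    do.call(rbind, licks)
  } else {
    data.frame(session_id = character(0), trial_id = integer(0),
               lick_time_s = numeric(0), stringsAsFactors = FALSE)
  }
  events$outcome <- score_trials(events, licks,
                                 task = switch(spec$level,
                                               naive = "passive",
                                               intermediate = "stim_reward",
                                               expert = "change_detect"))

  # units: half superficial, half deep
  layers <- rep(c("superficial", "deep"), length.out = n_units)
  unit_ids <- sprintf("%s_u%02d", session_id, seq_len(n_units))
  depth <- with_seed(derive_seed(seed, "depth"), {
    ifelse(layers == "superficial",
           -round(stats::runif(n_units, 50, 380)),
           round(stats::runif(n_units, 100, 1800)))
  })
  units <- data.frame(unit_id = unit_ids, session_id = session_id,
                      layer = layers, depth_um = depth,
                      stringsAsFactors = FALSE)

  sess_gain <- with_seed(derive_seed(seed, "sessgain"),
                         exp(stats::rnorm(1, 0, session_gain_sd)))
  spikes <- vector("list", n_units)
  gt <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    g <- .gain_row(gain_table, spec$level, layers[u])
    jit <- with_seed(derive_seed(seed, "jitter", u),
                     exp(stats::rnorm(4, 0, unit_jitter_sd)))
    p <- rate_kernel_params(
      baseline_hz = base_params$baseline_hz * jit[1],
      cue_amp_hz = base_params$cue_amp_hz * g$cue_gain * sess_gain * jit[2],
      change_amp_hz = base_params$change_amp_hz * g$change_gain * sess_gain * jit[3],
      delay_contra_bias_hz =
        base_params$delay_contra_bias_hz * g$delay_gain * sess_gain * jit[4],
      latency_ms = base_params$latency_ms,
      rise_ms = base_params$rise_ms,
      decay_ms = base_params$decay_ms)
    st <- simulate_unit_spikes(p, events, derive_seed(seed, "spikes", u))
    spikes[[u]] <- data.frame(session_id = session_id, unit_id = unit_ids[u],
                              spike_time_s = st, stringsAsFactors = FALSE)
    gt[[u]] <- data.frame(unit_id = unit_ids[u], session_id = session_id,
                          layer = layers[u], level = spec$level,
                          baseline_hz = p$baseline_hz,
                          cue_amp_hz = p$cue_amp_hz,
                          change_amp_hz = p$change_amp_hz,
                          delay_contra_bias_hz = p$delay_contra_bias_hz,
                          stringsAsFactors = FALSE)
  }
  spikes <- do.call(rbind, spikes)
  ground_truth <- do.call(rbind, gt)

  eye <- NULL
  if (simulate_eye) {
    dur <- max(events$t_change_on) + 2
    sched <- with_seed(derive_seed(seed, "eyesched"), {
      n_sacc <- stats::rpois(1, saccade_rate_hz * dur)
      if (n_sacc > 0) {
        onset <- sort(stats::runif(n_sacc, 0, dur - 0.2))
        d <- data.frame(onset_s = onset,
                        amplitude_deg = stats::runif(n_sacc, 2.5, 8),
                        duration_ms = stats::runif(n_sacc, 20, 50))
        # drop overlapping saccades (keep earlier)
        keep <- rep(TRUE, n_sacc)
        if (n_sacc > 1) {
          last_end <- d$onset_s[1] + d$duration_ms[1] / 1000
          for (i in 2:n_sacc) {
            if (d$onset_s[i] < last_end + 0.05) keep[i] <- FALSE
            else last_end <- d$onset_s[i] + d$duration_ms[i] / 1000
          }
        }
        d[keep, , drop = FALSE]
      } else NULL
    })
    eye <- simulate_eye_trace(dur, sched, noise_sd_deg = 0.05,
                              rng_seed = derive_seed(seed, "eye"),
                              session_id = session_id)
  }

  list(session = data.frame(session_id = session_id, level = spec$level,
                            archetype = spec$lick_archetype,
                            stringsAsFactors = FALSE),
       events = events, units = units, spikes = spikes, licks = licks,
       eye = eye, ground_truth = ground_truth)
}

#' Simulate spike times of one unit across a session's trials
#'
#' Thinning-based inhomogeneous Poisson sampling of the unit's
#' [event_locked_rate()] over each trial span (0.5 s before noise onset to
#' 1 s after change onset); there is no spiking between trials.
#'
#' @param params a [rate_kernel_params()].
#' @param events trial timeline data.frame.
#' @param seed integer seed (one per-trial sub-seed is derived from it).
#' @return sorted spike times in seconds from session start.
#' @export
simulate_unit_spikes <- function(params, events, seed) {
  rate_max <- params$baseline_hz * 1.001 + params$cue_amp_hz +
    params$change_amp_hz + params$delay_contra_bias_hz + 0.01
  out <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    tr <- events[i, ]
    out[[i]] <- sample_inhomogeneous_poisson(
      function(t) event_locked_rate(t, tr, params),
      tr$t_noise_on - 0.5, tr$t_change_on + 1.0,
      rate_max, derive_seed(seed, i))
  }
  sort(unlist(out))
}

#' Simulate a multi-cohort study
#'
#' Runs [simulate_session()] for every session of every cohort and binds the
#' results into one session bundle (the in-memory analogue of the fixture
#' files written by [write_session_bundle()]).
#'
#' @param cohorts list of [cohort_spec()]s.
#' @param seed global integer seed.
#' @param ... passed on to [simulate_session()].
#' @return list with `sessions`, `events`, `units`, `spikes`, `licks`,
#'   `eye` (possibly `NULL`), `ground_truth` data.frames.
#' @export
simulate_cohorts <- function(cohorts, seed, ...) {
  bundles <- list()
  k <- 0
  for (ci in seq_along(cohorts)) {
    spec <- cohorts[[ci]]
    for (si in seq_len(spec$n_sessions)) {
      k <- k + 1
      sid <- sprintf("%s_%02d", spec$level, si)
      bundles[[k]] <- simulate_session(spec, sid,
                                       derive_seed(seed, "session", ci, si),
                                       ...)
    }
  }
  bind <- function(field) {
    parts <- lapply(bundles, `[[`, field)
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts)) do.call(rbind, parts) else NULL
  }
  list(sessions = bind("session"), events = bind("events"),
       units = bind("units"), spikes = bind("spikes"), licks = bind("licks"),
       eye = bind("eye"), ground_truth = bind("ground_truth"))
}
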
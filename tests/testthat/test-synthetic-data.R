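test_that("trial timelines respect epoch duration ranges and ordering", {
  spec <- cohort_spec("expert", trials_per_session = 100)
  ev <- simulate_trial_timeline(spec, rng_seed = 11)
  expect_equal(nrow(ev), 100)
  expect_true(all(ev$t_noise_on < ev$t_cue_on))
  expect_true(all(ev$t_cue_on < ev$t_twopatch_on))
  expect_true(all(ev$t_twopatch_on < ev$t_change_on))
  d_noise <- ev$t_cue_on - ev$t_noise_on
  d_cue <- ev$t_twopatch_on - ev$t_cue_on
  d_two <- ev$t_change_on - ev$t_twopatch_on
  expect_true(all(d_noise >= 0.2 & d_noise <= 0.3))
  expect_true(all(d_cue >= 0.36 & d_cue <= 1.55))
  expect_true(all(d_two >= 0.84 & d_two <= 3.6))
  # random half change trials for a catch-trial cohort
  expect_equal(sum(ev$is_change), 50)
  # tilt categories consistent with tilt amplitudes
  expect_true(all(ev$tilt_category[ev$tilt_deg == 30] == "large", na.rm = TRUE))
  expect_true(all(ev$tilt_category[ev$tilt_deg %in% c(15, 20)] == "medium"))
  expect_true(all(ev$tilt_category[ev$tilt_deg %in% c(9, 12)] == "small"))
})

test_that("single-trial timeline has strictly ordered onsets", {
  ev <- simulate_trial_timeline(cohort_spec("naive", trials_per_session = 1),
                                rng_seed = 3)
  expect_equal(nrow(ev), 1)
  expect_true(ev$t_noise_on < ev$t_cue_on &&
                ev$t_cue_on < ev$t_twopatch_on &&
                ev$t_twopatch_on < ev$t_change_on)
})

test_that("intermediate cohort has a change on every trial and no catch trials", {
  spec <- cohort_spec("intermediate", trials_per_session = 60)
  expect_false(spec$has_no_change_trials)
  ev <- simulate_trial_timeline(spec, rng_seed = 5)
  expect_true(all(ev$is_change))
  expect_error(cohort_spec("intermediate", has_no_change_trials = TRUE),
               "catch trials")
})

test_that("generator is deterministic in the seed", {
  spec <- cohort_spec("expert", trials_per_session = 30)
  expect_identical(simulate_trial_timeline(spec, 42),
                   simulate_trial_timeline(spec, 42))
  expect_false(identical(simulate_trial_timeline(spec, 42),
                         simulate_trial_timeline(spec, 43)))
  tr <- simulate_trial_timeline(spec, 42)[1, ]
  expect_identical(simulate_licks("change_locked", tr, 7),
                   simulate_licks("change_locked", tr, 7))
  b1 <- simulate_session(cohort_spec("expert", trials_per_session = 10),
                         "sX", 99, n_units = 2, simulate_eye = TRUE)
  b2 <- simulate_session(cohort_spec("expert", trials_per_session = 10),
                         "sX", 99, n_units = 2, simulate_eye = TRUE)
  expect_identical(b1, b2)
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec("expert", n_sessions = 0), "positive")
  expect_error(cohort_spec("expert", trials_per_session = -5), "positive")
  expect_error(cohort_spec("wizard"), "arg")
})

test_that("event-locked rate is causal and reduces to baseline", {
  tr <- make_trials(1)
  p0 <- rate_kernel_params(baseline_hz = 7)
  tt <- seq(tr$t_noise_on, tr$t_change_on + 0.5, by = 0.001)
  expect_equal(event_locked_rate(tt, tr, p0), rep(7, length(tt)))
  p <- rate_kernel_params(baseline_hz = 7, cue_amp_hz = 25,
                          change_amp_hz = 15, delay_contra_bias_hz = 0)
  # strictly before cue latency the rate is exactly baseline
  before <- tt[tt <= tr$t_cue_on + 0.040]
  expect_equal(event_locked_rate(before, tr, p), rep(7, length(before)))
  after <- tt[tt > tr$t_cue_on + 0.045 & tt < tr$t_cue_on + 0.3]
  expect_true(all(event_locked_rate(after, tr, p) > 7))
})

test_that("closed-form kernel area matches numerical quadrature", {
  for (pars in list(rate_kernel_params(cue_amp_hz = 1),
                    rate_kernel_params(cue_amp_hz = 1, rise_ms = 5,
                                       decay_ms = 120, latency_ms = 20))) {
    tr <- make_trials(1)
    f <- function(t) event_locked_rate(tr$t_cue_on + t, tr, pars) -
      pars$baseline_hz
    q <- integrate(f, 0, 5, rel.tol = 1e-10, subdivisions = 500L)
    expect_equal(q$value, kernel_area(pars), tolerance = 1e-6)
  }
})

test_that("delay bias is contralateral-only and confined to the delay", {
  p <- rate_kernel_params(baseline_hz = 5, delay_contra_bias_hz = 3)
  tr_c <- make_trials(1, cue_side = "contra")
  tr_i <- make_trials(1, cue_side = "ipsi")
  t_mid <- (tr_c$t_twopatch_on + tr_c$t_change_on) / 2
  expect_equal(event_locked_rate(t_mid, tr_c, p), 8)
  expect_equal(event_locked_rate(t_mid, tr_i, p), 5)
  expect_equal(event_locked_rate(tr_c$t_cue_on + 0.1, tr_c, p), 5)
  expect_equal(event_locked_rate(tr_c$t_change_on + 0.1, tr_c, p), 5)
})

test_that("thinning sampler matches Poisson count statistics", {
  expect_length(sample_inhomogeneous_poisson(function(t) 0 * t, 0, 10,
                                             rate_max = 0, rng_seed = 1), 0)
  expect_length(sample_inhomogeneous_poisson(function(t) rep(5, length(t)),
                                             5, 5, 5, 1), 0)
  st <- sample_inhomogeneous_poisson(function(t) rep(10, length(t)),
                                     0, 1000, rate_max = 12, rng_seed = 21)
  expect_false(is.unsorted(st))
  expect_true(all(st >= 0 & st < 1000))
  expect_lt(abs(length(st) - 10000), 5 * sqrt(10000))
})

test_that("thinning recovers a time-varying ramp rate in the PSTH sense", {
  rate_fn <- function(t) 40 * t          # 0 -> 40 Hz over one second
  n_rep <- 10000
  edges <- seq(0, 1, by = 0.1)
  counts <- matrix(0, n_rep, 10)
  for (r in seq_len(n_rep)) {
    st <- sample_inhomogeneous_poisson(rate_fn, 0, 1, 40, rng_seed = 50000 + r)
    counts[r, ] <- tabulate(findInterval(st, edges), nbins = 10)
  }
  expected <- diff(20 * edges^2)         # integral of the ramp per bin
  got <- colMeans(counts)
  se <- sqrt(expected / n_rep)
  expect_true(all(abs(got - expected) <= 3 * se))
})

test_that("lick archetypes have their characteristic time courses", {
  tr <- make_trials(1)
  # change-locked licks: almost no mass before change onset
  n_pre <- 0; n_tot <- 0
  for (i in 1:1000) {
    lt <- simulate_licks("change_locked", tr, rng_seed = 1000 + i)
    n_pre <- n_pre + sum(lt < tr$t_change_on)
    n_tot <- n_tot + length(lt)
  }
  expect_lt(n_pre / n_tot, 0.05)
  # early-peak licks: modal histogram bin within the first second
  all_rel <- unlist(lapply(1:1000, function(i) {
    simulate_licks("early_peak", tr, rng_seed = 3000 + i) - tr$t_noise_on
  }))
  h <- hist(all_rel, breaks = seq(0, 6, by = 0.25), plot = FALSE)
  expect_lt(h$mids[which.max(h$counts)], 1)
  # zero intensity means no licks
  expect_length(simulate_licks("ramping", tr, 5, intensity_scale = 0), 0)
  expect_error(simulate_licks("bogus", tr, 1), "arg")
})

test_that("eye traces reproduce scheduled saccades exactly at zero noise", {
  tr0 <- simulate_eye_trace(2, NULL, noise_sd_deg = 0, rng_seed = 1)
  expect_equal(nrow(tr0), 480)
  expect_equal(diff(range(tr0$x_deg)), 0)
  expect_equal(stats::median(diff(tr0$t)), 1 / 240)
  sched <- data.frame(onset_s = 1, amplitude_deg = 5, duration_ms = 30)
  tr1 <- simulate_eye_trace(3, sched, noise_sd_deg = 0, rng_seed = 1)
  pre <- mean(tr1$x_deg[tr1$t < 0.9])
  post <- mean(tr1$x_deg[tr1$t > 1.2])
  expect_equal(abs(post - pre), 5, tolerance = 1e-6)
  # peak speed of a 5 deg / 30 ms sigmoidal saccade far exceeds 50 deg/s
  speed <- abs(diff(tr1$x_deg)) * 240
  expect_gt(max(speed), 50)
  bad <- data.frame(onset_s = c(1, 1.02), amplitude_deg = c(5, 5),
                    duration_ms = c(30, 30))
  expect_error(simulate_eye_trace(3, bad, 0, 1), "overlap")
})

test_that("simulated sessions keep all events inside the session span", {
  b <- simulate_session(cohort_spec("intermediate", trials_per_session = 20),
                        "i1", 8, n_units = 3, simulate_eye = FALSE)
  span <- range(b$events$t_noise_on - 0.5, b$events$t_change_on + 1.5)
  expect_true(all(b$spikes$spike_time_s >= span[1] &
                    b$spikes$spike_time_s <= span[2]))
  expect_true(all(b$licks$lick_time_s >= span[1] &
                    b$licks$lick_time_s <= span[2]))
  expect_true(all(is.finite(b$spikes$spike_time_s)))
  expect_false(is.unsorted(b$spikes$spike_time_s[
    b$spikes$unit_id == b$units$unit_id[1]]))
})
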
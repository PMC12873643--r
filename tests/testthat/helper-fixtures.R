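# Brute-force AROC oracle: explicit pairwise comparison with tie half-credit.
auroc_bruteforce <- function(signal, noise) {
  total <- 0
  for (s in signal) {
    for (n in noise) {
      total <- total + if (s > n) 1 else if (s == n) 0.5 else 0
    }
  }
  total / (length(signal) * length(noise))
}

# Minimal hand-built trial timeline with exact event times (seconds).
make_trials <- function(n = 10, cue_side = rep(c("contra", "ipsi"),
                                               length.out = n),
                        is_change = rep(TRUE, n), tilt_deg = rep(30, n),
                        spacing = 10) {
  t0 <- spacing * (seq_len(n) - 1) + 1
  data.frame(session_id = "s1", trial_id = seq_len(n), cue_side = cue_side,
             t_noise_on = t0, t_cue_on = t0 + 0.25,
             t_twopatch_on = t0 + 1.25, t_change_on = t0 + 3.25,
             tilt_deg = ifelse(is_change, tilt_deg, 0),
             tilt_category = attnroc::tilt_category(
               ifelse(is_change, tilt_deg, 0)),
             is_change = is_change, is_probe = FALSE,
             outcome = NA_character_, stringsAsFactors = FALSE)
}

# Homogeneous-Poisson spike train over the spans of a trial timeline.
poisson_spikes <- function(trials, rate_hz, seed,
                           pre_s = 0.5, post_s = 1.0) {
  set.seed(seed)
  out <- lapply(seq_len(nrow(trials)), function(i) {
    t0 <- trials$t_noise_on[i] - pre_s
    t1 <- trials$t_change_on[i] + post_s
    n <- rpois(1, rate_hz * (t1 - t0))
    sort(runif(n, t0, t1))
  })
  sort(unlist(out))
}
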
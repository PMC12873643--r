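test_that("AROC matches its defining pairwise statistic", {
  expect_equal(auroc(c(5, 6, 7), c(1, 2, 3)), 1.0)
  expect_equal(auroc(c(2, 2, 2), c(2, 2, 2)), 0.5)
  expect_equal(auroc(c(1, 2, 3), c(0, 1, 2)), 7 / 9)
  expect_error(auroc(numeric(0), 1), "non-empty")
})

test_that("AROC has its defining symmetries and invariances", {
  set.seed(202)
  for (i in 1:100) {
    s <- rpois(sample(2:15, 1), sample(0:8, 1))
    n <- rpois(sample(2:15, 1), sample(0:8, 1))
    a <- auroc(s, n)
    expect_equal(a, auroc_bruteforce(s, n), tolerance = 1e-12)
    expect_equal(auroc(n, s), 1 - a, tolerance = 1e-12)   # symmetry
    expect_equal(auroc(s + 3, n + 3), a, tolerance = 1e-12) # shift invariance
    # rank form equals the Mann-Whitney U statistic normalized by ns*nn
    w <- suppressWarnings(wilcox.test(s, n))$statistic
    expect_equal(a, unname(w) / (length(s) * length(n)), tolerance = 1e-12)
  }
})

test_that("AROC grows with Gaussian shift toward the closed form", {
  set.seed(77)
  deltas <- c(0, 0.5, 1, 2)
  est <- vapply(deltas, function(d) {
    auroc(rnorm(2000, d), rnorm(2000))
  }, numeric(1))
  expect_true(all(diff(est) > 0))                        # monotone in shift
  expect_equal(est, pnorm(deltas / sqrt(2)), tolerance = 0.03)
})

test_that("bootstrap CI is degenerate exactly when the data admit one AROC", {
  expect_equal(bootstrap_auroc_ci(c(2, 2, 2), c(2, 2, 2), 100, 1),
               c(0.5, 0.5))
  expect_equal(bootstrap_auroc_ci(c(9, 10), c(1, 2), 100, 1), c(1, 1))
  expect_error(bootstrap_auroc_ci(1:3, 1:3, n_boot = 1), "at least 2")
  expect_identical(bootstrap_auroc_ci(1:10, 0:9, 200, rng_seed = 5),
                   bootstrap_auroc_ci(1:10, 0:9, 200, rng_seed = 5))
})

test_that("bootstrap CI covers the analytic AROC at the nominal rate", {
  delta <- 1
  true_auroc <- pnorm(delta / sqrt(2))
  n_data <- 500
  covered <- 0
  for (i in seq_len(n_data)) {
    set.seed(6000 + i)
    s <- rnorm(100, delta); n <- rnorm(100)
    ci <- bootstrap_auroc_ci(s, n, n_boot = 400, rng_seed = 6000 + i)
    if (ci[1] <= true_auroc && true_auroc <= ci[2]) covered <- covered + 1
  }
  expect_gt(covered / n_data, 0.92)
  expect_lt(covered / n_data, 0.98)
})

test_that("epoch discriminability recovers generator ground truth", {
  trials <- make_trials(60, cue_side = rep("contra", 60))
  # null unit: pure baseline Poisson, AROC CI should cover 0.5
  null_spikes <- poisson_spikes(trials, 20, seed = 9)
  r0 <- epoch_discriminability(null_spikes, trials, epoch_spec("cue_onset"),
                               n_boot = 500, rng_seed = 2)
  expect_true(r0$ci_lo <= 0.5 && 0.5 <= r0$ci_hi)
  expect_equal(r0$n_signal, 60)
  # strong cue transient confined to the response window -> positive
  p <- rate_kernel_params(baseline_hz = 8, cue_amp_hz = 60)
  mod_spikes <- simulate_unit_spikes(p, trials, seed = 10)
  r1 <- epoch_discriminability(mod_spikes, trials, epoch_spec("cue_onset"),
                               n_boot = 500, rng_seed = 3)
  expect_identical(r1$significance, "positive")
  expect_gt(r1$auroc, 0.7)
})

test_that("units with too few trials are excluded with a message", {
  trials <- make_trials(6, cue_side = rep(c("contra", "ipsi"), 3))
  spikes <- poisson_spikes(trials, 10, seed = 4)
  expect_message(
    res <- epoch_discriminability(spikes, trials, epoch_spec("cue_onset"),
                                  n_boot = 50, min_trials = 5),
    "excluded")
  expect_null(res)
})

test_that("delay-period significance is calibrated on unbiased units", {
  trials <- make_trials(80)
  ns <- 0
  for (i in 1:100) {
    spikes <- poisson_spikes(trials, 15, seed = 800 + i)
    r <- epoch_discriminability(spikes, trials, epoch_spec("delay_spatial"),
                                n_boot = 300, rng_seed = 800 + i)
    if (r$significance == "ns") ns <- ns + 1
  }
  expect_gte(ns, 90)
})

test_that("population summaries have the documented degenerate forms", {
  one <- data.frame(auroc = 0.7, significance = "positive")
  s1 <- population_summary(one, n_boot = 50)
  expect_equal(s1$median, 0.7)
  expect_equal(s1$median_ci, c(0.7, 0.7))
  expect_equal(s1$pct_positive, 100)
  s3 <- population_summary(data.frame(auroc = c(0.4, 0.5, 0.6),
                                      significance = rep("ns", 3)),
                           n_boot = 100)
  expect_equal(s3$median, 0.5)
  expect_equal(s3$pct_positive + s3$pct_negative, 0)
  expect_error(population_summary(data.frame(auroc = numeric(0),
                                             significance = character(0))),
               "no unit")
})

test_that("AROC time course localizes the delay-period bias", {
  trials <- make_trials(120)
  # no modulation: all bins near 0.5
  null_spikes <- poisson_spikes(trials, 25, seed = 31)
  tc0 <- auroc_timecourse(null_spikes, trials, "change_on", c(-400, 0), 20)
  expect_true(all(abs(tc0$auroc - 0.5) < 0.2))
  expect_lt(abs(mean(tc0$auroc) - 0.5), 0.05)
  # contralateral delay bias: late delay bins above 0.5, pre-2patch bins not
  p <- rate_kernel_params(baseline_hz = 10, delay_contra_bias_hz = 15)
  spikes <- simulate_unit_spikes(p, trials, seed = 32)
  tc1 <- auroc_timecourse(spikes, trials, "change_on", c(-400, 0), 20)
  expect_gt(mean(tc1$auroc), 0.6)
  pre <- auroc_timecourse(spikes, trials, "cue_on", c(-200, 0), 20)
  expect_lt(abs(mean(pre$auroc) - 0.5), 0.1)
  # flipping the labels maps each bin AROC x to 1 - x
  flipped <- trials
  flipped$cue_side <- ifelse(trials$cue_side == "contra", "ipsi", "contra")
  tc2 <- auroc_timecourse(spikes, flipped, "change_on", c(-400, 0), 20)
  expect_equal(tc2$auroc, 1 - tc1$auroc, tolerance = 1e-12)
})
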
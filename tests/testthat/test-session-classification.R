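sim_archetype_session <- function(archetype, sid, seed, n_trials = 40) {
  spec <- cohort_spec(switch(archetype, ramping = "intermediate",
                             change_locked = "expert", early_peak = "naive"),
                      trials_per_session = n_trials,
                      lick_archetype = archetype)
  b <- simulate_session(spec, sid, seed, n_units = 1, simulate_eye = FALSE)
  list(events = b$events, licks = b$licks)
}

test_that("lick time courses are normalized event-aligned histograms", {
  ev <- make_trials(4)
  # all licks exactly at +500 ms: one bin carries all the mass
  licks <- data.frame(session_id = "s1", trial_id = 1:4,
                      lick_time_s = ev$t_change_on + 0.5)
  v <- lick_time_course(ev, licks, range_ms = c(-1000, 1000), bin_ms = 100)
  expect_equal(sum(v), 1)
  expect_equal(max(v), 1)
  expect_equal(attr(v, "bin_start_ms")[which.max(v)], 500)
  # evenly spread licks give a flat vector
  rel <- seq(-0.95, 0.95, by = 0.1)
  licks_u <- data.frame(session_id = "s1",
                        trial_id = rep(1, length(rel)),
                        lick_time_s = ev$t_change_on[1] + rel)
  vu <- lick_time_course(ev, licks_u, range_ms = c(-1000, 1000), bin_ms = 100)
  expect_equal(as.numeric(vu), rep(1 / 20, 20))
  # lick-free session flagged
  v0 <- lick_time_course(ev, licks_u[0, ], c(-1000, 1000), 100)
  expect_true(attr(v0, "zero_licks"))
  expect_equal(sum(v0), 0)
})

test_that("change-locked sessions put their lick mass after the change", {
  s <- sim_archetype_session("change_locked", "e1", 21, n_trials = 120)
  v <- lick_time_course(s$events, s$licks)
  post <- attr(v, "bin_start_ms") >= 0
  expect_gt(sum(v[post]), 0.8)
})

test_that("the embedding is deterministic and respects duplicates", {
  set.seed(30)
  base <- matrix(runif(6 * 45), 6, 45)
  vecs <- rbind(base, base[1, ])        # duplicate of session 1
  e1 <- embed_sessions(vecs, rng_seed = 1)
  e2 <- embed_sessions(vecs, rng_seed = 1)
  expect_identical(e1[, 1:2], e2[, 1:2])
  d_dup <- sqrt(sum((e1[7, ] - e1[1, ])^2))
  scale <- max(dist(e1))
  expect_lt(d_dup, 1e-8 * max(scale, 1))
  expect_error(embed_sessions(base[1:2, ]), "at least")
})

test_that("archetype labels are recovered from generated sessions", {
  sessions <- c(lapply(1:8, function(i)
                  sim_archetype_session("ramping", paste0("r", i), 100 + i)),
                lapply(1:8, function(i)
                  sim_archetype_session("change_locked", paste0("e", i),
                                        200 + i)))
  events <- do.call(rbind, lapply(sessions, `[[`, "events"))
  licks <- do.call(rbind, lapply(sessions, `[[`, "licks"))
  res <- classify_sessions(events, licks, rng_seed = 3)
  truth <- rep(c("intermediate", "expert"), each = 8)
  expect_equal(res$assigned_level, truth)
  # invariant to session ordering
  ord <- rev(unique(events$session_id))
  res_rev <- classify_sessions(events, licks, session_ids = ord, rng_seed = 3)
  expect_equal(res_rev$assigned_level[match(res$session_id,
                                            res_rev$session_id)],
               res$assigned_level)
})

test_that("a single-archetype study is flagged as poorly separated", {
  sessions <- lapply(1:8, function(i)
    sim_archetype_session("change_locked", paste0("e", i), 400 + i))
  events <- do.call(rbind, lapply(sessions, `[[`, "events"))
  licks <- do.call(rbind, lapply(sessions, `[[`, "licks"))
  expect_warning(classify_sessions(events, licks, rng_seed = 5),
                 "poorly separated")
})

test_that("cluster-to-level mapping follows response-window lick mass", {
  # two synthetic families: mass before vs inside the response window
  n_bins <- 45
  bins <- seq(-3000, 1400, by = 100)
  early <- t(replicate(6, {
    v <- runif(n_bins, 0, 0.02); v[5:15] <- v[5:15] + 0.5; v / sum(v)
  }))
  late <- t(replicate(6, {
    v <- runif(n_bins, 0, 0.02); v[bins >= 300 & bins < 800] <-
      v[bins >= 300 & bins < 800] + 1; v / sum(v)
  }))
  vecs <- rbind(early, late)
  emb <- embed_sessions(vecs, rng_seed = 1)
  lab <- cluster_and_label(emb, vecs, bin_start_ms = bins, rng_seed = 1)
  expect_equal(as.character(lab), rep(c("intermediate", "expert"), each = 6))
  # swapping the families swaps the labels coherently
  vecs_sw <- rbind(late, early)
  lab_sw <- cluster_and_label(embed_sessions(vecs_sw, rng_seed = 1), vecs_sw,
                              bin_start_ms = bins, rng_seed = 1)
  expect_equal(as.character(lab_sw), rep(c("expert", "intermediate"), each = 6))
})
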
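#' Default run configuration
#'
#' Collects every tunable of the pipeline in one list: the simulated cohorts,
#' generator amplitudes and gains, the analysis windows (fixed to the task's
#' printed values inside [epoch_spec()]), bootstrap and permutation counts,
#' classifier parameters, and the significance threshold. A resolved copy of
#' the configuration is written alongside every run's outputs.
#'
#' @param seed global integer seed.
#' @param cohorts list of [cohort_spec()]s.
#' @param ... overrides for any configuration element.
#' @return a `run_config` list.
#' @export
default_config <- function(seed = 1,
                           cohorts = list(
                             cohort_spec("naive", n_sessions = 4),
                             cohort_spec("intermediate", n_sessions = 4),
                             cohort_spec("expert", n_sessions = 4)),
                           ...) {
  cfg <- list(
    seed = as.integer(seed),
    cohorts = cohorts,
    n_units = 8L,
    base_params = rate_kernel_params(baseline_hz = 8, cue_amp_hz = 20,
                                     change_amp_hz = 20,
                                     delay_contra_bias_hz = 4),
    gain_table = default_gain_table(),
    session_gain_sd = 0.1,
    unit_jitter_sd = 0.15,
    simulate_eye = TRUE,
    n_boot = 1000L,
    n_perm = 10000L,
    min_trials = 5L,
    alpha = 0.05,
    session_summary = "mean",
    classify = "auto",
    lick_range_ms = c(-3000, 1500),
    lick_bin_ms = 100
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Write a session bundle to delimited fixture files
#'
#' Writes `sessions.csv`, `events.csv`, `units.csv`, `spikes.csv`,
#' `licks.csv`, `eye.csv` (when eye traces exist) and `ground_truth.csv`
#' into `dir`. All times are seconds from session start.
#'
#' @param bundle list from [simulate_cohorts()] / [simulate_session()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(dir, name), row.names = FALSE)
    }
  }
  wr(bundle$sessions, "sessions.csv")
  wr(bundle$events, "events.csv")
  wr(bundle$units, "units.csv")
  wr(bundle$spikes, "spikes.csv")
  wr(bundle$licks, "licks.csv")
  wr(bundle$eye, "eye.csv")
  wr(bundle$ground_truth, "ground_truth.csv")
  invisible(dir)
}

.require_cols <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("file ", file, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
}

#' Read and validate a session bundle from fixture files
#'
#' Reads the delimited files written by [write_session_bundle()], checks the
#' schemas, and enforces cross-file referential integrity: every spike must
#' reference a known unit, every lick a known trial, every unit and trial a
#' known session. Violations are rejected with the offending file and row.
#'
#' @param dir directory containing the fixture files.
#' @return a session bundle list (as from [simulate_cohorts()]).
#' @export
read_session_bundle <- function(dir) {
  rd <- function(name, required = TRUE) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      if (required) stop("missing file: ", path)
      return(NULL)
    }
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  sessions <- rd("sessions.csv")
  events <- rd("events.csv")
  units <- rd("units.csv")
  spikes <- rd("spikes.csv")
  licks <- rd("licks.csv")
  eye <- rd("eye.csv", required = FALSE)
  ground_truth <- rd("ground_truth.csv", required = FALSE)

  .require_cols(sessions, c("session_id", "level"), "sessions.csv")
  .require_cols(events, c("session_id", "trial_id", "cue_side", "t_noise_on",
                          "t_cue_on", "t_twopatch_on", "t_change_on",
                          "tilt_deg", "is_change", "outcome"), "events.csv")
  .require_cols(units, c("unit_id", "session_id", "layer", "depth_um"),
                "units.csv")
  .require_cols(spikes, c("session_id", "unit_id", "spike_time_s"),
                "spikes.csv")
  .require_cols(licks, c("session_id", "trial_id", "lick_time_s"),
                "licks.csv")
  if (!"tilt_category" %in% names(events)) {
    events$tilt_category <- tilt_category(events$tilt_deg)
  }
  bad <- which(with(events, !(t_noise_on < t_cue_on &
                              t_cue_on < t_twopatch_on &
                              t_twopatch_on < t_change_on)))
  if (length(bad)) {
    stop("events.csv row ", bad[1], ": epoch onsets are not ordered")
  }
  orphan <- which(!units$session_id %in% sessions$session_id)
  if (length(orphan)) {
    stop("units.csv row ", orphan[1], ": unknown session_id '",
         units$session_id[orphan[1]], "'")
  }
  orphan <- which(!spikes$unit_id %in% units$unit_id)
  if (length(orphan)) {
    stop("spikes.csv row ", orphan[1], ": unknown unit_id '",
         spikes$unit_id[orphan[1]], "'")
  }
  key_e <- paste(events$session_id, events$trial_id)
  orphan <- which(!paste(licks$session_id, licks$trial_id) %in% key_e)
  if (length(orphan)) {
    stop("licks.csv row ", orphan[1], ": unknown trial reference")
  }
  if (nrow(licks) == 0) warning("licks.csv is empty (lick-free sessions)")
  message("read bundle: ", nrow(sessions), " sessions, ", nrow(events),
          " trials, ", nrow(units), " units, ", nrow(spikes), " spikes, ",
          nrow(licks), " licks")
  list(sessions = sessions, events = events, units = units, spikes = spikes,
       licks = licks, eye = eye, ground_truth = ground_truth)
}

#' Compute the per-unit AROC results table for a bundle
#'
#' Runs [epoch_discriminability()] for every unit and every epoch
#' definition: cue onset, delay-period spatial, and change onset stratified
#' by tilt category. Units excluded for an epoch (too few trials) are
#' silently absent from the corresponding rows.
#'
#' @param bundle session bundle with an `assigned_level` column present in
#'   `bundle$sessions` (falls back to `level`).
#' @param config a [default_config()].
#' @return data.frame: `unit_id, session_id, layer, level, epoch,
#'   tilt_category, auroc, ci_lo, ci_hi, significance, n_signal, n_noise`.
#' @export
compute_auroc_results <- function(bundle, config = default_config()) {
  sess <- bundle$sessions
  lev_col <- if ("assigned_level" %in% names(sess)) "assigned_level" else "level"
  specs <- c(list(epoch_spec("cue_onset"), epoch_spec("delay_spatial")),
             lapply(c("small", "medium", "large"),
                    function(tc) epoch_spec("change_onset", tilt = tc)))
  spikes_by_unit <- split(bundle$spikes$spike_time_s, bundle$spikes$unit_id)
  out <- list()
  for (ui in seq_len(nrow(bundle$units))) {
    u <- bundle$units[ui, ]
    st <- sort(spikes_by_unit[[u$unit_id]])
    if (is.null(st)) st <- numeric(0)
    trials <- bundle$events[bundle$events$session_id == u$session_id, ]
    level <- sess[[lev_col]][sess$session_id == u$session_id][1]
    for (sp in specs) {
      res <- suppressMessages(epoch_discriminability(
        st, trials, sp, n_boot = config$n_boot,
        rng_seed = derive_seed(config$seed, "boot", ui, sp$kind,
                               if (is.null(sp$tilt)) "all" else sp$tilt),
        min_trials = config$min_trials))
      if (!is.null(res)) {
        out[[length(out) + 1]] <- cbind(
          data.frame(unit_id = u$unit_id, session_id = u$session_id,
                     layer = u$layer, level = level,
                     stringsAsFactors = FALSE),
          res)
      }
    }
  }
  do.call(rbind, out)
}

#' Build the comparisons grid across performance levels
#'
#' For every epoch x layer cell (change onset additionally by tilt
#' category) and every pair of performance levels present, runs
#' [compare_levels()] (random-intercept mixed model + session permutation
#' test) and records the joint-significance flag. Cells where a level has
#' fewer than two sessions are skipped.
#'
#' @param auroc_results table from [compute_auroc_results()].
#' @param config a [default_config()].
#' @return data.frame: `epoch, layer, tilt_category, comparison, beta1,
#'   p_lmm, observed_stat, p_perm, significant, n_units, n_sessions`.
#' @export
build_comparisons <- function(auroc_results, config = default_config()) {
  lev_order <- c("naive", "intermediate", "expert")
  levels_present <- intersect(lev_order, unique(auroc_results$level))
  if (length(levels_present) < 2) stop("need at least two performance levels")
  pairs <- utils::combn(levels_present, 2, simplify = FALSE)
  cells <- unique(auroc_results[, c("epoch", "layer", "tilt_category")])
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    sel <- auroc_results$epoch == cell$epoch &
      auroc_results$layer == cell$layer &
      (is.na(cell$tilt_category) |
         auroc_results$tilt_category %in% cell$tilt_category)
    if (!is.na(cell$tilt_category)) {
      sel <- sel & !is.na(auroc_results$tilt_category)
    } else {
      sel <- sel & is.na(auroc_results$tilt_category)
    }
    for (pr in pairs) {
      sub <- auroc_results[sel & auroc_results$level %in% pr, ]
      n_sess <- table(unique(sub[, c("session_id", "level")])$level)
      if (length(n_sess) < 2 || any(n_sess < 2)) next
      sub$level <- factor(sub$level, levels = pr)
      cmp <- tryCatch(
        compare_levels(sub, n_perm = config$n_perm,
                       rng_seed = derive_seed(config$seed, "perm", ci,
                                              pr[1], pr[2]),
                       session_summary = config$session_summary,
                       alpha = config$alpha),
        error = function(e) NULL)
      if (is.null(cmp)) next
      out[[length(out) + 1]] <- cbind(
        data.frame(epoch = cell$epoch, layer = cell$layer,
                   tilt_category = cell$tilt_category,
                   stringsAsFactors = FALSE),
        cmp)
    }
  }
  if (!length(out)) stop("no comparison could be computed")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full synthetic pipeline
#'
#' Chains simulate, classify, analyze, compare and report: simulates the
#' configured cohorts, assigns a performance level to every session (by
#' cohort for naive sessions; by the lick-pattern classifier when both
#' non-naive levels are present, otherwise by cohort), computes the per-unit
#' AROC table, the comparisons grid, behavioral summaries, and saccade
#' detections (when eye traces were simulated). Deterministic given the
#' configuration seed. If `out_dir` is given all tables, the resolved
#' configuration, and a `summary.json` are written there.
#'
#' @param config a [default_config()].
#' @param out_dir optional output directory.
#' @return list: `bundle`, `session_levels`, `auroc_results`, `comparisons`,
#'   `behavior`, `saccades`, `summary`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  bundle <- simulate_cohorts(config$cohorts, config$seed,
                             n_units = config$n_units,
                             base_params = config$base_params,
                             gain_table = config$gain_table,
                             session_gain_sd = config$session_gain_sd,
                             unit_jitter_sd = config$unit_jitter_sd,
                             simulate_eye = config$simulate_eye)
  sess <- bundle$sessions
  sess$assigned_level <- sess$level
  non_naive <- sess$session_id[sess$level != "naive"]
  use_classifier <- identical(config$classify, TRUE) ||
    (identical(config$classify, "auto") &&
       length(unique(sess$level[sess$level != "naive"])) == 2 &&
       length(non_naive) >= 4)
  session_levels <- NULL
  if (use_classifier && length(non_naive) >= 4) {
    session_levels <- suppressMessages(classify_sessions(
      bundle$events, bundle$licks, session_ids = non_naive,
      range_ms = config$lick_range_ms, bin_ms = config$lick_bin_ms,
      rng_seed = derive_seed(config$seed, "classify")))
    idx <- match(session_levels$session_id, sess$session_id)
    sess$assigned_level[idx] <- session_levels$assigned_level
  }
  bundle$sessions <- sess

  auroc_results <- compute_auroc_results(bundle, config)
  comparisons <- build_comparisons(auroc_results, config)

  behavior <- do.call(rbind, lapply(sess$session_id, function(sid) {
    behavior_summary(bundle$events[bundle$events$session_id == sid, ],
                     bundle$licks[bundle$licks$session_id == sid, ])
  }))

  saccades <- NULL
  if (!is.null(bundle$eye)) {
    saccades <- do.call(rbind, lapply(sess$session_id, function(sid) {
      s <- detect_saccades(bundle$eye[bundle$eye$session_id == sid, ])
      if (nrow(s)) cbind(session_id = sid, s) else NULL
    }))
  }

  pop <- lapply(split(auroc_results,
                      auroc_results[, c("epoch", "layer", "level")],
                      drop = TRUE),
                function(g) population_summary(
                  g, n_boot = config$n_boot,
                  rng_seed = derive_seed(config$seed, "popsum",
                                         g$epoch[1], g$layer[1], g$level[1])))
  summary <- list(
    n_sessions = nrow(sess),
    n_units = nrow(bundle$units),
    n_trials = nrow(bundle$events),
    population = pop,
    n_joint_significant = sum(comparisons$significant),
    mean_hit_rate_by_level = tapply(behavior$hit_rate,
                                    sess$assigned_level, mean, na.rm = TRUE)
  )

  result <- list(bundle = bundle, session_levels = session_levels,
                 auroc_results = auroc_results, comparisons = comparisons,
                 behavior = behavior, saccades = saccades, summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_session_bundle(bundle, out_dir)
    utils::write.csv(auroc_results, file.path(out_dir, "auroc_results.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(behavior, file.path(out_dir, "behavior.csv"),
                     row.names = FALSE)
    if (!is.null(session_levels)) {
      utils::write.csv(session_levels,
                       file.path(out_dir, "session_levels.csv"),
                       row.names = FALSE)
    }
    if (!is.null(saccades)) {
      utils::write.csv(saccades, file.path(out_dir, "saccades.csv"),
                       row.names = FALSE)
    }
    cfg_out <- config
    cfg_out$base_params <- unclass(cfg_out$base_params)
    cfg_out$cohorts <- lapply(cfg_out$cohorts, unclass)
    yaml::write_yaml(unclass(cfg_out), file.path(out_dir, "config.yaml"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
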
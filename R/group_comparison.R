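#' Random-intercept mixed model for AROC differences between two levels
#'
#' Fits `auroc ~ level + (1 | session)`: a binary fixed effect for task
#' performance level with a random intercept per recording session, so the
#' shared variance among units recorded together does not inflate the
#' evidence for a group difference. The level effect is tested with a Wald
#' z-test on the fixed-effect coefficient.
#'
#' @param values numeric AROC value per unit.
#' @param session_ids session identifier per unit.
#' @param level_labels factor/character with exactly two levels; the second
#'   level (reference order = sort order, or factor levels if a factor) is
#'   coded 1.
#' @param reml use REML (default) or ML.
#' @return list: `beta0`, `beta1`, `se_beta1`, `p_beta1`, `sigma_u`,
#'   `sigma_e`, `n_units`, `n_sessions`, `levels` (coded 0/1 order),
#'   `degenerate` flag.
#' @export
fit_random_intercept_model <- function(values, session_ids, level_labels,
                                       reml = TRUE) {
  if (any(!is.finite(values))) stop("non-finite AROC values")
  lev <- if (is.factor(level_labels)) levels(droplevels(level_labels))
         else sort(unique(as.character(level_labels)))
  if (length(lev) != 2) stop("exactly two performance levels are required")
  x <- as.integer(as.character(level_labels) == lev[2])
  sess <- as.character(session_ids)
  for (l in lev) {
    if (length(unique(sess[x == (l == lev[2])])) < 2) {
      warning("fewer than 2 sessions at level ", l)
    }
  }
  if (stats::var(values) == 0) {
    return(list(beta0 = values[1], beta1 = 0, se_beta1 = NA_real_,
                p_beta1 = NA_real_, sigma_u = 0, sigma_e = 0,
                n_units = length(values),
                n_sessions = length(unique(sess)),
                levels = lev, degenerate = TRUE))
  }
  dat <- data.frame(y = values, x = x, sess = sess)
  if (max(table(sess)) == 1L) {
    # one unit per session: the session intercept is confounded with the
    # residual, so the model reduces to ordinary least squares
    message("one unit per session; random intercept absorbed into residual")
    fit <- stats::lm(y ~ x, data = dat)
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    z <- co[["x"]] / se[["x"]]
    return(list(beta0 = unname(co[["(Intercept)"]]),
                beta1 = unname(co[["x"]]),
                se_beta1 = unname(se[["x"]]),
                p_beta1 = 2 * stats::pnorm(-abs(z)),
                sigma_u = 0, sigma_e = stats::sigma(fit),
                n_units = length(values),
                n_sessions = length(unique(sess)),
                levels = lev, degenerate = FALSE))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ x + (1 | sess), data = dat, REML = reml)))
  co <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  z <- co[["x"]] / se[["x"]]
  list(beta0 = unname(co[["(Intercept)"]]),
       beta1 = unname(co[["x"]]),
       se_beta1 = unname(se[["x"]]),
       p_beta1 = 2 * stats::pnorm(-abs(z)),
       sigma_u = vc$sdcor[vc$grp == "sess"],
       sigma_e = vc$sdcor[vc$grp == "Residual"],
       n_units = length(values),
       n_sessions = length(unique(sess)),
       levels = lev, degenerate = FALSE)
}

#' Session-level permutation test on session-averaged AROC
#'
#' The observed statistic is the difference of group medians of per-session
#' AROC summaries (second level minus first). The null distribution is built
#' by shuffling the level labels across sessions. When the number of
#' distinct label assignments is at most `n_perm`, all assignments are
#' enumerated and the p-value is the exact two-sided fraction
#' `#{|stat| >= |observed|} / n_assignments`; otherwise `n_perm` random
#' shuffles are drawn and the add-one corrected estimate
#' `(1 + #{|stat| >= |observed|}) / (n_perm + 1)` is returned.
#'
#' @param session_values one AROC summary per session (e.g. within-session
#'   mean of unit AROC values).
#' @param level_labels two-level factor/character, one per session; at least
#'   two sessions per level.
#' @param n_perm permutations (default 10000).
#' @param rng_seed integer seed (Monte-Carlo mode).
#' @return list: `observed_stat`, `p_two_sided`, `n_perm_used`, `exact`
#'   (enumeration used?), `null_quantiles` (5 quantiles of the null),
#'   `levels`.
#' @export
session_permutation_test <- function(session_values, level_labels,
                                     n_perm = 10000, rng_seed = 1) {
  stopifnot(length(session_values) == length(level_labels))
  lev <- if (is.factor(level_labels)) levels(droplevels(level_labels))
         else sort(unique(as.character(level_labels)))
  if (length(lev) != 2) stop("exactly two performance levels are required")
  grp <- as.character(level_labels) == lev[2]
  nB <- sum(grp); nA <- sum(!grp); n <- nA + nB
  if (nA < 2 || nB < 2) stop("need at least 2 sessions per level")
  stat <- function(g) {
    stats::median(session_values[g]) - stats::median(session_values[!g])
  }
  obs <- stat(grp)
  n_exact <- choose(n, nB)
  if (n_exact <= n_perm) {
    combos <- utils::combn(n, nB)
    null <- apply(combos, 2, function(idx) {
      g <- logical(n); g[idx] <- TRUE; stat(g)
    })
    p <- sum(abs(null) >= abs(obs) - 1e-12) / n_exact
    exact <- TRUE
    n_used <- n_exact
  } else {
    null <- with_seed(rng_seed, {
      vapply(seq_len(n_perm), function(i) stat(sample(grp)), numeric(1))
    })
    p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (n_perm + 1)
    exact <- FALSE
    n_used <- n_perm
  }
  list(observed_stat = obs, p_two_sided = p, n_perm_used = n_used,
       exact = exact,
       null_quantiles = stats::quantile(null, c(0.025, 0.25, 0.5, 0.75, 0.975)),
       levels = lev)
}

#' Joint significance under the dual-test rule
#'
#' A group difference counts as significant only if both the mixed-model
#' p-value and the permutation p-value fall strictly below `alpha`.
#'
#' @param p_lmm,p_perm p-values in `[0, 1]`.
#' @param alpha significance threshold (default 0.05).
#' @return logical flag.
#' @export
joint_significance <- function(p_lmm, p_perm, alpha = 0.05) {
  stopifnot(is.finite(p_lmm), is.finite(p_perm),
            p_lmm >= 0, p_lmm <= 1, p_perm >= 0, p_perm <= 1)
  (p_lmm < alpha) && (p_perm < alpha)
}

#' Compare AROC distributions between two performance levels
#'
#' Runs the dual inference for one comparison: random-intercept mixed model
#' on unit-level AROC values plus session-level permutation test on
#' within-session summaries of the same values.
#'
#' @param results data.frame with columns `auroc`, `session_id`, `level`
#'   (exactly two levels present).
#' @param n_perm permutations for the session test.
#' @param rng_seed integer seed.
#' @param session_summary `"mean"` (default) or `"median"`: how unit AROC
#'   values are summarized within a session before the permutation test.
#' @param alpha joint-significance threshold.
#' @return one-row data.frame: `comparison, beta1, p_lmm, observed_stat,
#'   p_perm, significant, n_units, n_sessions`.
#' @export
compare_levels <- function(results, n_perm = 10000, rng_seed = 1,
                           session_summary = c("mean", "median"),
                           alpha = 0.05) {
  session_summary <- match.arg(session_summary)
  lmm <- fit_random_intercept_model(results$auroc, results$session_id,
                                    results$level)
  fun <- if (session_summary == "mean") mean else stats::median
  sess <- tapply(results$auroc, results$session_id, fun)
  sess_level <- tapply(as.character(results$level), results$session_id,
                       function(l) l[1])
  perm <- session_permutation_test(as.numeric(sess),
                                   factor(sess_level[names(sess)],
                                          levels = lmm$levels),
                                   n_perm = n_perm, rng_seed = rng_seed)
  sig <- if (is.na(lmm$p_beta1)) FALSE else
    joint_significance(lmm$p_beta1, perm$p_two_sided, alpha = alpha)
  data.frame(comparison = paste(lmm$levels, collapse = " vs "),
             beta1 = lmm$beta1, p_lmm = lmm$p_beta1,
             observed_stat = perm$observed_stat, p_perm = perm$p_two_sided,
             significant = sig,
             n_units = lmm$n_units, n_sessions = lmm$n_sessions,
             stringsAsFactors = FALSE)
}
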
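#' Change-aligned lick time course of one session
#'
#' Per-bin lick counts aligned on change onset (change trials only),
#' averaged across trials and normalized to unit sum, so the vector captures
#' the shape of the session's licking rather than its overall rate. Sessions
#' with no licks in range yield an all-zero vector (flagged via the
#' `zero_licks` attribute) and should be excluded from embedding.
#'
#' @param events trial timeline of one session.
#' @param licks lick table of the same session (`trial_id`, `lick_time_s`).
#' @param range_ms analysis range, ms relative to change onset, default
#'   `c(-3000, 1500)`.
#' @param bin_ms bin width, default 100 ms.
#' @return numeric vector of normalized per-bin lick frequency
#'   (`length = diff(range)/bin`), with attributes `bin_start_ms`,
#'   `zero_licks`.
#' @export
lick_time_course <- function(events, licks, range_ms = c(-3000, 1500),
                             bin_ms = 100) {
  stopifnot(nrow(events) >= 1)
  trials <- events[events$is_change, , drop = FALSE]
  if (nrow(trials) == 0) trials <- events   # align on 4th-epoch onset anyway
  n_bins <- as.integer(round((range_ms[2] - range_ms[1]) / bin_ms))
  edges <- range_ms[1] + bin_ms * (0:n_bins)
  counts <- numeric(n_bins)
  for (i in seq_len(nrow(trials))) {
    rel <- (licks$lick_time_s[licks$trial_id == trials$trial_id[i]] -
              trials$t_change_on[i]) * 1000
    rel <- rel[rel >= range_ms[1] & rel < range_ms[2]]
    if (length(rel)) {
      counts <- counts + tabulate(floor((rel - range_ms[1]) / bin_ms) + 1,
                                  nbins = n_bins)
    }
  }
  total <- sum(counts)
  v <- if (total > 0) counts / total else counts
  attr(v, "bin_start_ms") <- edges[-length(edges)]
  attr(v, "zero_licks") <- total == 0
  v
}

#' Two-dimensional embedding of session lick time courses
#'
#' Embeds the sessions' normalized lick vectors in two dimensions by
#' classical multidimensional scaling of their Euclidean distances. The
#' embedding is deterministic; `rng_seed` is accepted for interface symmetry
#' with the other randomized stages and recorded in the result. Duplicated
#' input vectors map to identical points and well-separated lick archetypes
#' segregate into distinct groups of points.
#'
#' @param vectors matrix (sessions x bins) or list of equal-length lick
#'   time-course vectors.
#' @param rng_seed integer seed (recorded; the embedding itself is exact).
#' @param min_sessions smallest number of sessions that can be embedded.
#' @return matrix (sessions x 2) of embedding coordinates.
#' @export
embed_sessions <- function(vectors, rng_seed = 1, min_sessions = 4) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (nrow(vectors) < min_sessions) {
    stop("need at least ", min_sessions,
         " sessions to embed; reduce min_sessions for tiny studies")
  }
  d <- stats::dist(vectors)
  emb <- stats::cmdscale(d, k = 2)
  if (ncol(emb) < 2) {  # degenerate geometry (e.g. all points collinear)
    emb <- cbind(emb, 0)[, 1:2]
  }
  attr(emb, "rng_seed") <- rng_seed
  emb
}

#' Cluster embedded sessions and assign performance levels
#'
#' Two-means clustering of the 2-D embedding; the cluster whose member
#' sessions carry a larger mean share of their licks inside the `[300, 800)`
#' ms post-change response window is labeled `expert`, the other
#' `intermediate`. This anchors the otherwise arbitrary cluster identities
#' to the task's own response window.
#'
#' @param embedding sessions x 2 coordinate matrix from [embed_sessions()].
#' @param vectors the lick time-course matrix that was embedded.
#' @param bin_start_ms bin start times (ms) of the time-course bins; taken
#'   from the first vector's attribute if `NULL`.
#' @param rng_seed integer seed for k-means initialization.
#' @return character vector of `"intermediate"` / `"expert"` labels with
#'   attribute `cluster` (integer cluster ids).
#' @export
cluster_and_label <- function(embedding, vectors, bin_start_ms = NULL,
                              rng_seed = 1) {
  if (is.list(vectors)) {
    if (is.null(bin_start_ms)) bin_start_ms <- attr(vectors[[1]], "bin_start_ms")
    vectors <- do.call(rbind, vectors)
  }
  stopifnot(nrow(embedding) == nrow(vectors), nrow(embedding) >= 2)
  if (is.null(bin_start_ms)) {
    stop("bin_start_ms is required to locate the response window")
  }
  km <- with_seed(rng_seed,
                  stats::kmeans(embedding, centers = 2, nstart = 10))
  if (any(tabulate(km$cluster, 2) == 0)) stop("degenerate two-way clustering")
  # flag splits of what is really one cluster: when a single point cloud is
  # cut in half, the closest cross-cluster pair is about as close as
  # within-cluster nearest neighbours; distinct archetypes leave a wide gap
  dm <- as.matrix(stats::dist(embedding))
  diag(dm) <- Inf
  cross <- dm[km$cluster == 1, km$cluster == 2, drop = FALSE]
  dmw <- dm
  dmw[outer(km$cluster, km$cluster, "!=")] <- Inf
  within_nn <- stats::median(apply(dmw, 1, min))
  gap <- min(cross) / within_nn
  if (is.finite(gap) && gap < 3) {
    warning("two-way split is poorly separated (gap ratio ",
            round(gap, 2), "); sessions may come from a single lick archetype")
  }
  resp_bins <- bin_start_ms >= 300 & bin_start_ms < 800
  resp_mass <- rowSums(vectors[, resp_bins, drop = FALSE])
  mass_by_cluster <- tapply(resp_mass, km$cluster, mean)
  expert_cluster <- as.integer(names(which.max(mass_by_cluster)))
  labels <- ifelse(km$cluster == expert_cluster, "expert", "intermediate")
  attr(labels, "cluster") <- km$cluster
  labels
}

#' Classify non-naive sessions from their lick patterns
#'
#' End-to-end session classification: build change-aligned lick time
#' courses, embed them in two dimensions, split the embedding into two
#' clusters, and label the clusters intermediate/expert by response-window
#' lick mass. Sessions from the passive-viewing cohort should not be passed
#' in: their level is `naive` by design and bypasses the classifier.
#'
#' @param events trial timelines (all sessions stacked).
#' @param licks lick tables (all sessions stacked).
#' @param session_ids sessions to classify; default all in `events`.
#' @param range_ms,bin_ms passed to [lick_time_course()].
#' @param rng_seed integer seed.
#' @return data.frame: `session_id, embedded_x, embedded_y, cluster,
#'   assigned_level`.
#' @export
classify_sessions <- function(events, licks, session_ids = NULL,
                              range_ms = c(-3000, 1500), bin_ms = 100,
                              rng_seed = 1) {
  if (is.null(session_ids)) session_ids <- unique(events$session_id)
  vecs <- lapply(session_ids, function(sid) {
    lick_time_course(events[events$session_id == sid, ],
                     licks[licks$session_id == sid, ],
                     range_ms = range_ms, bin_ms = bin_ms)
  })
  zero <- vapply(vecs, function(v) isTRUE(attr(v, "zero_licks")), logical(1))
  if (any(zero)) {
    message(sum(zero), " lick-free session(s) excluded from classification")
  }
  keep <- which(!zero)
  emb <- embed_sessions(vecs[keep], rng_seed = rng_seed)
  labels <- cluster_and_label(emb, vecs[keep],
                              bin_start_ms = attr(vecs[[keep[1]]], "bin_start_ms"),
                              rng_seed = rng_seed)
  out <- data.frame(session_id = session_ids[keep],
                    embedded_x = emb[, 1], embedded_y = emb[, 2],
                    cluster = attr(labels, "cluster"),
                    assigned_level = as.character(labels),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
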
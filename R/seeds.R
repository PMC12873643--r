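#' Derive a reproducible sub-stream seed
#'
#' Expands one global seed into independent per-stream seeds (timeline,
#' spikes, licks, eye, bootstrap, ...) so that each randomized stage of a
#' simulation or analysis is reproducible on its own. Mixing is a small
#' multiplicative hash over the integer-coded arguments; the result always
#' lies in `[1, 2^31 - 2]` so it is a valid R integer seed.
#'
#' @param seed integer global seed.
#' @param ... further integers or strings identifying the stream
#'   (e.g. `"spikes"`, session index, unit index).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    codes <- if (is.character(p)) utf8ToInt(p) else as.double(p)
    for (v in codes) {
      h <- (h * 48271 + v + 11) %% 2147483647
    }
  }
  as.integer(h %% 2147483645 + 1)
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
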
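# internal helpers shared across modules

# Run code with a temporary RNG state; restores the caller's state on exit.
# Keeps the generator deterministic without clobbering the session RNG.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a string tag, staying inside
# 32-bit integer range. FNV-1a over the tag bytes, folded with the seed.
derive_seed <- function(seed, tag) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(as.character(tag))) {
    h <- bitwXor(as.integer(h), b %% 256)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

hs_error <- function(token, msg, class = NULL) {
  stop(errorCondition(paste0(token, ": ", msg),
                      class = c(class, "hysterosurv_error", "error", "condition")))
}

check_surv_args <- function(scores, times, events) {
  if (length(scores) != length(times) || length(times) != length(events))
    hs_error("length-mismatch", "scores, times and events must have equal length")
  if (any(!is.finite(scores)))
    hs_error("invalid-score", "log-hazard scores must be finite")
  if (any(!is.finite(times)) || any(times <= 0))
    hs_error("invalid-time", "times must be positive and finite")
  if (!all(events %in% c(0, 1)))
    hs_error("invalid-event", "event indicators must be 0 or 1")
  if (sum(events) < 1)
    hs_error("no-events", "at least one observed event is required")
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
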
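# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
#' state afterwards.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-unit child seed from a base seed; stays inside 32-bit range.
#' @noRd
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483647)
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Robust noise scale of a series from its first difference. White noise of
# sd s has first differences of sd s*sqrt(2); the MAD makes the estimate
# insensitive to the sparse large steps contributed by transients.
#' @noRd
robust_noise_scale <- function(y) {
  stats::mad(diff(y)) / sqrt(2)
}
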
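#' Fluorescence trace container
#'
#' A `fluor_trace` holds one cell's per-frame mean fluorescence against time:
#' either a background-subtracted region-of-interest (ROI) trace extracted
#' from an image stack, or a raw simulated recording (which then carries the
#' camera background level in its metadata so it can be subtracted with
#' [subtract_background()]).
#'
#' @param time Numeric vector of sample times in seconds; strictly increasing
#'   and uniformly spaced (relative tolerance 1e-6).
#' @param value Numeric vector of intensities, same length as `time`.
#' @param metadata Named list of free-form provenance (cell id, group,
#'   protocol descriptor, background level, ...).
#'
#' @return An object of class `fluor_trace`: a list with elements `time`,
#'   `value`, `frame_interval` (seconds) and `metadata`.
#' @export
fluor_trace <- function(time, value, metadata = list()) {
  if (length(time) != length(value)) {
    stopf("time and value must have equal length (%d vs %d)",
          length(time), length(value))
  }
  if (length(time) < 2L) stopf("a trace needs at least 2 samples")
  if (!is.numeric(time) || !is.numeric(value) || anyNA(time) || anyNA(value)) {
    stopf("time and value must be numeric without missing values")
  }
  dt <- diff(time)
  if (any(dt <= 0)) stopf("time must be strictly increasing")
  dt0 <- stats::median(dt)
  if (any(abs(dt - dt0) > 1e-6 * dt0)) {
    stopf("time must be uniformly spaced (relative tolerance 1e-6)")
  }
  structure(
    list(time = as.numeric(time), value = as.numeric(value),
         frame_interval = dt0, metadata = metadata),
    class = "fluor_trace"
  )
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> %d samples @ %.4g s/frame (%.1f s)\n",
              length(x$time), x$frame_interval,
              x$time[length(x$time)] - x$time[1]))
  invisible(x)
}

#' @export
length.fluor_trace <- function(x) length(x$value)

#' Subtract a constant camera background from a trace
#'
#' Simulated recordings are emitted as raw intensities (baseline plus camera
#' background); the analysis operates on background-subtracted traces, as do
#' ROI traces extracted from stacks (where the background is estimated per
#' frame from a cell-free region). This helper removes a constant background
#' from a raw trace.
#'
#' @param trace A [fluor_trace()].
#' @param level Background level in intensity units; defaults to the
#'   `background_level` recorded in the trace metadata.
#' @return A background-subtracted `fluor_trace`.
#' @export
subtract_background <- function(trace, level = trace$metadata$background_level) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (is.null(level) || !is.finite(level)) {
    stopf("no background level supplied and none recorded in trace metadata")
  }
  md <- trace$metadata
  md$background_level <- NULL
  md$background_subtracted <- TRUE
  fluor_trace(trace$time, trace$value - level, md)
}
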
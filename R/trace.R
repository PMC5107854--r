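#' Respiratory motion trace
#'
#' A `resp_trace` is a tibble with columns `t` (seconds, strictly increasing,
#' uniform grid) and `x` (displacement in the tracker's distance units,
#' conventionally cm of anterior-posterior surface motion), carrying the
#' sampling rate `fs` (Hz) and free-form `meta` annotations as attributes.
#' It is the raw input of every transform in the package.
#'
#' @param t Numeric vector of sample times in seconds, or `NULL` to build the
#'   grid from `fs` (starting at 0).
#' @param x Numeric vector of displacement samples; must be finite.
#' @param fs Sampling rate in Hz. If `t` is given, `fs` is checked against the
#'   grid; if omitted it is inferred from the median step.
#' @param meta Named list of source annotations (units, file of origin, ...).
#'
#' @return A tibble of class `resp_trace` with columns `t` and `x`.
#'
#' @details The time grid must be uniform: each step may deviate from `1/fs`
#'   by at most 1e-9 s. Non-uniform acquisitions should go through
#'   [resample_trace()] or be snapped on read by [read_trace()].
#'
#' @examples
#' tr <- resp_trace(x = sin(2 * pi * 0.25 * (0:999) / 25), fs = 25)
#' tr
#' @export
resp_trace <- function(t = NULL, x, fs = NULL, meta = list()) {
  if (!is.numeric(x) || length(x) < 2L) {
    abort_input("a respiratory trace needs at least 2 numeric samples")
  }
  if (anyNA(x) || !all(is.finite(x))) {
    abort_input("trace amplitudes must all be finite")
  }
  x <- as.numeric(x)
  if (is.null(t)) {
    if (is.null(fs)) {
      abort_input("supply either `t` or `fs`")
    }
    t <- (seq_along(x) - 1) / fs
  } else {
    t <- as.numeric(t)
    if (length(t) != length(x)) {
      abort_input("`t` and `x` must have the same length")
    }
    if (is.unsorted(t, strictly = TRUE)) {
      abort_input("sample times must be strictly increasing")
    }
    if (is.null(fs)) {
      fs <- 1 / stats::median(diff(t))
    }
  }
  if (!is_scalar_number(fs) || fs <= 0) {
    abort_input("`fs` must be a positive number")
  }
  step_dev <- abs(diff(t) - 1 / fs)
  if (any(step_dev > 1e-9)) {
    abort_input(
      "time grid is not uniform at 1/fs = %g s (max deviation %.3g s); use resample_trace()",
      1 / fs, max(step_dev)
    )
  }
  out <- tibble::tibble(t = t, x = x)
  attr(out, "fs") <- fs
  attr(out, "meta") <- meta
  class(out) <- c("resp_trace", class(out))
  out
}

#' Sampling rate of a trace
#'
#' @param trace A [resp_trace()].
#' @return Sampling rate in Hz.
#' @export
trace_fs <- function(trace) {
  fs <- attr(trace, "fs")
  if (is.null(fs)) {
    abort_input("not a resp_trace: missing `fs` attribute")
  }
  fs
}

#' @export
print.resp_trace <- function(x, ...) {
  fs <- attr(x, "fs")
  dur <- (nrow(x) - 1) / fs
  cat(sprintf(
    "<resp_trace> %d samples, fs = %g Hz, duration = %.1f s\n",
    nrow(x), fs, dur
  ))
  NextMethod()
}

# Keep class/attributes when dplyr-style subsetting would otherwise strip them:
# we deliberately do NOT preserve the class on subsetting, because an arbitrary
# row subset is no longer a uniform-grid trace. Helpers below rebuild instead.

as_resp_trace <- function(df, fs, meta = list()) {
  resp_trace(t = df$t, x = df$x, fs = fs, meta = meta)
}

#' Plot a respiratory trace
#'
#' Time-amplitude curve of the trace, the panel a reader inspects first when
#' grading breathing regularity visually.
#'
#' @param object A [resp_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.resp_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$x)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)", y = "displacement (trace units)",
      title = "Time-amplitude curve"
    )
}
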
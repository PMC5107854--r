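# Internal helpers shared across modules.

# Classed conditions: input errors are contract violations by the caller,
# analysis errors mean the data defeat the method (e.g. no oscillation).
abort_input <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "respstab_input_error")
}

abort_analysis <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "respstab_analysis_error")
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Centered moving average; window is forced odd, edges use shrinking
# (partial) windows so the output length matches the input.
moving_average <- function(x, window) {
  if (window <= 1L) {
    return(x)
  }
  window <- as.integer(window)
  if (window %% 2L == 0L) {
    window <- window + 1L
  }
  half <- window %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Population (ddof = 0) standard deviation.
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) {
    return(NA_real_)
  }
  sqrt(sum((x - mean(x))^2) / n)
}
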
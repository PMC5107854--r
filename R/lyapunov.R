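# Largest Lyapunov exponent by delay embedding and the divergence-curve
# (Rosenstein) method: robust on short, noisy physiological records.

#' Choose delay-embedding parameters for a trace
#'
#' The embedding delay `tau` is the first lag at which the autocorrelation
#' of the displacement drops below 1/e (falling back to a quarter of the
#' mean breathing period when it never does within `lag_max`). The
#' embedding dimension `m` is the smallest dimension at which the fraction
#' of false nearest neighbours falls below `fnn_threshold`, up to
#' `max_dim` (falling back to 3), but never below 2.
#'
#' @param trace A [resp_trace()] with at least 1000 samples.
#' @param max_dim Largest embedding dimension tried. Default 8.
#' @param fnn_threshold Acceptable false-nearest-neighbour fraction.
#'   Default 0.05.
#' @param rtol Distance-ratio threshold declaring a neighbour false when
#'   the next embedding coordinate is revealed. Default 10 (standard).
#' @param lag_max Longest lag examined for the autocorrelation (s).
#'   Default 30 s.
#' @param fnn_max_points The false-nearest-neighbour scan runs on an
#'   evenly strided subset of at most this many embedded points; 1500
#'   points estimate the fraction amply while keeping the scan quadratic
#'   in a small number.
#' @return A list with integers `tau` (samples) and `m`.
#' @export
choose_embedding <- function(trace, max_dim = 8L, fnn_threshold = 0.05,
                             rtol = 10, lag_max = 30, fnn_max_points = 1500L) {
  fs <- trace_fs(trace)
  n <- nrow(trace)
  if (n < 1000L) {
    abort_input("need at least 1000 samples to choose an embedding (got %d)", n)
  }
  x <- trace$x
  if (stats::sd(x) == 0) {
    abort_analysis("constant trace: autocorrelation is undefined")
  }
  lags <- min(n - 1L, ceiling(lag_max * fs))
  ac <- as.numeric(stats::acf(x, lag.max = lags, plot = FALSE)$acf)[-1L]
  below <- which(ac < exp(-1))
  tau <- if (length(below) > 0L) {
    below[1L]
  } else {
    per <- tryCatch(
      mean(segment_cycles(trace)$period),
      error = function(e) NA_real_
    )
    if (is.finite(per)) max(1L, round(per * fs / 4)) else max(1L, round(fs))
  }
  tau <- as.integer(tau)
  m <- fnn_dimension(x, tau, max_dim, fnn_threshold, rtol, fnn_max_points)
  list(tau = tau, m = max(2L, m))
}

# Fraction of false nearest neighbours (Kennel distance-ratio criterion) at
# dimensions 1..max_dim on a strided subsample; returns the smallest
# acceptable dimension, or 3L as fallback.
fnn_dimension <- function(x, tau, max_dim, threshold, rtol, max_points) {
  n <- length(x)
  for (m in seq_len(max_dim)) {
    M <- n - m * tau # need coordinate m+1 too
    if (M < 10L) {
      return(3L)
    }
    stride <- max(1L, ceiling(M / max_points))
    idx <- seq(1L, M, by = stride)
    emb <- vapply(
      0:(m - 1L),
      function(k) x[idx + k * tau],
      numeric(length(idx))
    )
    emb <- matrix(emb, nrow = length(idx))
    d2 <- as.matrix(stats::dist(emb))^2
    diag(d2) <- Inf
    # exclude temporally adjacent subsample points
    if (tau >= stride) {
      ban <- ceiling(tau / stride)
      for (off in seq_len(min(ban, length(idx) - 1L))) {
        d2[cbind(seq_len(length(idx) - off), seq_len(length(idx) - off) + off)] <- Inf
        d2[cbind(seq_len(length(idx) - off) + off, seq_len(length(idx) - off))] <- Inf
      }
    }
    nn <- apply(d2, 1L, which.min)
    dnn <- sqrt(d2[cbind(seq_along(nn), nn)])
    nxt <- abs(x[idx + m * tau] - x[idx[nn] + m * tau])
    ok <- is.finite(dnn) & dnn > 0
    if (!any(ok)) {
      return(max(2L, m))
    }
    frac <- mean(nxt[ok] / dnn[ok] > rtol)
    if (frac < threshold) {
      return(m)
    }
  }
  3L
}

#' Largest Lyapunov exponent by the divergence-curve method
#'
#' Delay-embeds the displacement series, finds each embedded point's exact
#' nearest neighbour outside a Theiler window (which excludes same-cycle
#' neighbours), follows every pair forward and averages the log of the pair
#' distances at each expansion step. The largest Lyapunov exponent is the
#' least-squares slope of this mean log-divergence curve over the fitting
#' range, converted to 1/s. A positive exponent diagnoses divergence of
#' nearby trajectories (chaotic, unstable breathing); zero characterizes
#' purely periodic breathing; a negative exponent indicates convergence
#' toward a stable pattern (e.g. initially irregular breathing that
#' regularizes).
#'
#' @param trace A [resp_trace()].
#' @param tau,m Embedding delay (samples) and dimension; chosen by
#'   [choose_embedding()] when `NULL`.
#' @param theiler Theiler exclusion window in samples; defaults to one mean
#'   breathing period (estimated by [segment_cycles()]).
#' @param max_steps Number of expansion steps followed; defaults to one
#'   mean period, the pre-fold-back scaling region of quasi-periodic
#'   signals.
#' @param fit_range Two integers, the step interval of the slope fit;
#'   defaults to `c(0, max_steps)`.
#' @return An object of class `lle_result`: list with `lle` (1/s), `tau`,
#'   `m`, `theiler`, `fit_range`, and the `divergence` tibble (`step`,
#'   `time`, `mean_log_dist`, `n_pairs`).
#' @examples
#' \donttest{
#' tr <- generate_trace(synth_params(
#'   sigma_A = 0, sigma_T = 0, noise_sd = 0,
#'   duration = 200, seed = 1
#' ))
#' lle_estimate(tr)$lle # ~ 0 for purely regular breathing
#' }
#' @export
lle_estimate <- function(trace, tau = NULL, m = NULL, theiler = NULL,
                         max_steps = NULL, fit_range = NULL) {
  fs <- trace_fs(trace)
  if (is.null(tau) || is.null(m)) {
    emb <- choose_embedding(trace)
    tau <- tau %||% emb$tau
    m <- m %||% emb$m
  }
  tau <- as.integer(tau)
  m <- as.integer(m)
  if (tau < 1L || m < 2L) {
    abort_input("need tau >= 1 and m >= 2")
  }
  if (is.null(theiler) || is.null(max_steps)) {
    per <- tryCatch(
      mean(segment_cycles(trace)$period),
      error = function(e) abort_analysis(
        "cannot derive a mean period for the Theiler window; pass `theiler` and `max_steps` explicitly"
      )
    )
    period_samples <- max(1L, as.integer(round(per * fs)))
    theiler <- theiler %||% period_samples
    max_steps <- max_steps %||% period_samples
  }
  theiler <- as.integer(theiler)
  max_steps <- as.integer(max_steps)
  n <- nrow(trace)
  M <- n - (m - 1L) * tau
  if (M < 100L) {
    abort_input("embedded trajectory has %d points; need at least 100", M)
  }
  fit_range <- as.integer(fit_range %||% c(0L, max_steps))
  div <- .rosenstein_divergence(trace$x, m, tau, theiler, max_steps)
  steps <- 0:max_steps
  curve <- tibble::tibble(
    step = steps,
    time = steps / fs,
    mean_log_dist = as.numeric(div$mean_log),
    n_pairs = as.integer(div$n_pairs)
  )
  if (all(curve$n_pairs == 0L)) {
    abort_analysis("no valid neighbour pairs: divergence curve is empty")
  }
  fit_pts <- curve[
    curve$step >= fit_range[1] & curve$step <= fit_range[2] &
      is.finite(curve$mean_log_dist),
  ]
  if (nrow(fit_pts) < 2L) {
    abort_analysis("fewer than 2 usable points in the fit range")
  }
  slope_per_step <- stats::cov(fit_pts$step, fit_pts$mean_log_dist) /
    stats::var(fit_pts$step)
  out <- list(
    lle = slope_per_step * fs,
    tau = tau, m = m, theiler = theiler,
    fit_range = fit_range,
    fs = fs,
    divergence = curve
  )
  class(out) <- "lle_result"
  out
}

#' @export
print.lle_result <- function(x, ...) {
  cat(sprintf(
    "<lle_result> LLE = %.4g 1/s (tau = %d, m = %d, theiler = %d, fit steps %d..%d)\n",
    x$lle, x$tau, x$m, x$theiler, x$fit_range[1], x$fit_range[2]
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lle_result <- function(x, ...) {
  x$divergence
}

#' @exportS3Method generics::glance
glance.lle_result <- function(x, ...) {
  tibble::tibble(
    lle = x$lle, tau = x$tau, m = x$m, theiler = x$theiler,
    fit_from = x$fit_range[1], fit_to = x$fit_range[2]
  )
}

#' Plot a log-divergence curve
#'
#' @param object A [lle_estimate()] result.
#' @param ... Unused.
#' @return A ggplot of mean log-divergence against time, with the fitted
#'   slope segment overlaid.
#' @exportS3Method ggplot2::autoplot
autoplot.lle_result <- function(object, ...) {
  curve <- object$divergence
  fit <- curve[curve$step >= object$fit_range[1] &
    curve$step <= object$fit_range[2] &
    is.finite(curve$mean_log_dist), ]
  icpt <- mean(fit$mean_log_dist) - (object$lle / object$fs) * mean(fit$step)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time, y = .data$mean_log_dist)) +
    ggplot2::geom_line() +
    ggplot2::geom_segment(
      x = fit$time[1], xend = fit$time[nrow(fit)],
      y = icpt + (object$lle / object$fs) * fit$step[1],
      yend = icpt + (object$lle / object$fs) * fit$step[nrow(fit)],
      colour = "red", linetype = 2
    ) +
    ggplot2::labs(
      x = "time (s)", y = "mean ln divergence",
      title = sprintf("Divergence curve, LLE = %.3g 1/s", object$lle)
    )
}
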
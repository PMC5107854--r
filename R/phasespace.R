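# Phase-space portrait (x, v) and the modified Poincare section with its
# dispersion indices SD_x / SD_v.

#' Estimate velocity and build the phase-space portrait
#'
#' Velocity is the central difference `v[i] = (x[i+1] - x[i-1]) * fs / 2`
#' (one-sided differences at the end points), optionally after moving-average
#' smoothing of the displacement. Plotting `v` against `x` gives the
#' phase-space diagram: periodic breathing traces closed loops, irregular
#' breathing smears them.
#'
#' @param trace A [resp_trace()] with at least 3 samples.
#' @param smooth_window Moving-average window applied to `x` before
#'   differentiation, in samples (0 or 1 = no smoothing).
#' @return A tibble of class `phase_portrait` with columns `t`, `x`, `v`
#'   and the sampling rate in the `fs` attribute.
#' @export
estimate_velocity <- function(trace, smooth_window = 0) {
  fs <- trace_fs(trace)
  n <- nrow(trace)
  if (n < 3L) {
    abort_input("need at least 3 samples to estimate velocity")
  }
  x <- moving_average(trace$x, smooth_window)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  v[1] <- (x[2] - x[1]) * fs
  v[n] <- (x[n] - x[n - 1]) * fs
  out <- tibble::tibble(t = trace$t, x = x, v = v)
  attr(out, "fs") <- fs
  class(out) <- c("phase_portrait", class(out))
  out
}

portrait_fs <- function(portrait) {
  fs <- attr(portrait, "fs")
  if (is.null(fs)) {
    abort_input("not a phase_portrait: missing `fs` attribute")
  }
  fs
}

# First crossing pair within idx window; returns recorded sample index or NA.
# "up" records the first sample at-or-above the plane (post-crossing),
# "down" records the last sample at-or-above the plane (pre-crossing), so
# the recorded point always sits on the inhale side and time reversal maps
# the two conventions onto each other exactly.
crossing_samples <- function(x, lo, hi, level, direction) {
  i <- seq(lo, hi - 1L)
  out <- integer(0)
  if (direction %in% c("up", "both")) {
    up <- i[x[i] < level & x[i + 1L] >= level]
    out <- c(out, up + 1L)
  }
  if (direction %in% c("down", "both")) {
    dn <- i[x[i] >= level & x[i + 1L] < level]
    out <- c(out, dn)
  }
  sort(out)
}

#' Modified Poincare section of a breathing trace
#'
#' Sections the phase-space trajectory with a plane transverse to it, placed
#' at the median point between the maximal and minimal displacement, and
#' records one discrete sample per crossing. Because the recorded point is a
#' sample adjacent to the crossing rather than an interpolated intersection,
#' both coordinates vary from cycle to cycle, and their population standard
#' deviations SD_x and SD_v measure the dispersion of the breathing pattern.
#'
#' With the default `plane = "cycle"` the plane level is evaluated per
#' breathing cycle (midrange of that cycle), so amplitude changes and
#' baseline drift move the crossing displacement and are captured by SD_x.
#' `plane = "global"` uses a single midrange level of the whole retained
#' trace; under that convention the crossing displacement is pinned near the
#' plane and SD_x collapses to the sampling granularity, so it is offered
#' for comparison only. One point is recorded per cycle and direction (the
#' first crossing), exhale-to-inhale (`"up"`) by default.
#'
#' @param portrait A [estimate_velocity()] portrait, or a [resp_trace()]
#'   (velocity is then estimated with defaults).
#' @param cycles Optional [segment_cycles()] result (after outlier screening
#'   if desired); computed from the portrait when missing. Discarded cycles
#'   are never sectioned.
#' @param plane `"cycle"` (default) or `"global"`.
#' @param direction `"up"` (default), `"down"`, or `"both"`.
#' @return An object of class `poincare_result`: a list with `points`
#'   (tibble `idx`, `t`, `x`, `v`, `plane`), `plane_level` (global midrange,
#'   for reference), `sd_x`, `sd_v` (population SDs), `plane`, `direction`.
#' @export
poincare_section <- function(portrait, cycles = NULL,
                             plane = c("cycle", "global"),
                             direction = c("up", "down", "both")) {
  plane <- match.arg(plane)
  direction <- match.arg(direction)
  if (inherits(portrait, "resp_trace")) {
    portrait <- estimate_velocity(portrait)
  }
  fs <- portrait_fs(portrait)
  x <- portrait$x
  if (is.null(cycles)) {
    tr <- resp_trace(t = portrait$t, x = x, fs = fs)
    cycles <- segment_cycles(tr)
  }
  keep <- which(!cycles$discarded)
  if (length(keep) < 2L) {
    abort_analysis("insufficient cycles for Poincare section")
  }
  retained_idx <- unlist(lapply(keep, function(i) {
    seq(cycles$trough_idx[i], cycles$next_trough_idx[i])
  }))
  level_global <- (max(x[retained_idx]) + min(x[retained_idx])) / 2
  rec <- if (plane == "global") {
    idx <- unlist(lapply(keep, function(i) {
      crossing_samples(x, cycles$trough_idx[i], cycles$next_trough_idx[i],
        level_global, direction
      )
    }))
    tibble::tibble(idx = idx, plane = rep(level_global, length(idx)))
  } else {
    parts <- lapply(keep, function(i) {
      a <- cycles$trough_idx[i]
      b <- cycles$next_trough_idx[i]
      lev <- (max(x[a:b]) + min(x[a:b])) / 2
      # one point per cycle and direction: first up-crossing (exhale-to-
      # inhale), last down-crossing (inhale-to-exhale; "last" mirrors
      # "first up" under time reversal)
      sel <- integer(0)
      if (direction %in% c("up", "both")) {
        up <- crossing_samples(x, a, b, lev, "up")
        if (length(up)) sel <- c(sel, up[1L])
      }
      if (direction %in% c("down", "both")) {
        dn <- crossing_samples(x, a, b, lev, "down")
        if (length(dn)) sel <- c(sel, dn[length(dn)])
      }
      if (length(sel) == 0L) {
        return(NULL)
      }
      tibble::tibble(idx = sel, plane = rep(lev, length(sel)))
    })
    dplyr::bind_rows(parts)
  }
  if (is.null(rec) || nrow(rec) < 2L) {
    abort_analysis("insufficient cycles for Poincare section")
  }
  points <- tibble::tibble(
    idx = rec$idx,
    t = portrait$t[rec$idx],
    x = x[rec$idx],
    v = portrait$v[rec$idx],
    plane = rec$plane
  )
  out <- list(
    points = points,
    plane_level = level_global,
    sd_x = sd_pop(points$x),
    sd_v = sd_pop(points$v),
    plane = plane,
    direction = direction
  )
  class(out) <- "poincare_result"
  out
}

#' @export
print.poincare_result <- function(x, ...) {
  cat(sprintf(
    "<poincare_result> %d crossings (%s plane, %s), SD_x = %.4g, SD_v = %.4g\n",
    nrow(x$points), x$plane, x$direction, x$sd_x, x$sd_v
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.poincare_result <- function(x, ...) {
  x$points
}

#' @exportS3Method generics::glance
glance.poincare_result <- function(x, ...) {
  tibble::tibble(
    sd_x = x$sd_x,
    sd_v = x$sd_v,
    n_points = nrow(x$points),
    plane_level = x$plane_level,
    plane = x$plane,
    direction = x$direction
  )
}

#' Plot a phase-space portrait
#'
#' @param object A [estimate_velocity()] portrait.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.phase_portrait <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$v)) +
    ggplot2::geom_path(alpha = 0.4, linewidth = 0.2) +
    ggplot2::labs(
      x = "displacement (trace units)", y = "velocity (units/s)",
      title = "Phase-space diagram"
    )
}

#' Plot a Poincare section
#'
#' @param object A [poincare_section()] result.
#' @param ... Unused.
#' @return A ggplot object of the crossing points.
#' @exportS3Method ggplot2::autoplot
autoplot.poincare_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$v)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(
      x = "displacement at crossing (trace units)",
      y = "velocity at crossing (units/s)",
      title = sprintf(
        "Poincare section (SD_x = %.3g, SD_v = %.3g)",
        object$sd_x, object$sd_v
      )
    )
}
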
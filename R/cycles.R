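# Breathing-cycle decomposition: trough/peak detection, outlier-cycle
# rejection against a median template, and end-of-exhale drift statistics.

# Indices of local maxima of y, plateau-aware (first sample of a plateau).
local_maxima <- function(y) {
  s <- sign(diff(y))
  run <- which(s != 0)
  if (length(run) < 2L) {
    return(integer(0))
  }
  s_r <- s[run]
  chg <- which(s_r[-length(s_r)] > 0 & s_r[-1] < 0)
  run[chg] + 1L
}

# Topographic prominence of candidate peaks of y.
peak_prominence <- function(y, peaks) {
  n <- length(y)
  vapply(peaks, function(p) {
    h <- y[p]
    left_higher <- which(y[seq_len(p - 1L)] > h)
    lo_l <- if (length(left_higher)) {
      min(y[seq(max(left_higher), p)])
    } else {
      min(y[seq_len(p)])
    }
    right <- seq(p, n)
    right_higher <- which(y[right] > h)
    lo_r <- if (length(right_higher)) {
      min(y[seq(p, p + min(right_higher) - 1L)])
    } else {
      min(y[right])
    }
    h - max(lo_l, lo_r)
  }, numeric(1))
}

# Greedy tall-first thinning so surviving peaks are >= min_gap apart.
enforce_separation <- function(idx, height, min_gap) {
  ord <- idx[order(height, decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(kept - p) >= min_gap)) {
      kept <- c(kept, p)
    }
  }
  sort(kept)
}

#' Segment a trace into breathing cycles
#'
#' Locates end-of-exhale troughs by prominence-filtered local-extremum
#' detection and defines one cycle per consecutive trough pair (trough to
#' trough: end-of-exhale is the stable anchor of the breathing cycle). The
#' cycle amplitude is the within-cycle maximum minus the displacement at the
#' leading trough; the period is the trough-to-trough duration.
#'
#' @param trace A [resp_trace()].
#' @param prominence_frac Minimum trough prominence as a fraction of the
#'   trace's global peak-to-peak range. Default 0.2, which suppresses
#'   cardiac and sensor-noise ripples at physiological breathing rates
#'   (0.1-0.5 Hz).
#' @param min_separation Minimum time between retained troughs (s).
#'   Default 1.0 s, shorter than any plausible breathing period.
#' @return A tibble of class `resp_cycles`, one row per complete cycle:
#'   `cycle`, `trough_idx`, `peak_idx`, `next_trough_idx` (sample indices),
#'   `trough_t`, `trough_x`, `peak_x`, `amplitude` (cm), `period` (s),
#'   `r_template` (filled by [reject_outlier_cycles()]), `discarded`.
#'   The source trace rides along as the `trace` attribute.
#' @examples
#' tr <- resp_trace(x = sin(2 * pi * 0.25 * (0:1499) / 25), fs = 25)
#' segment_cycles(tr)
#' @export
segment_cycles <- function(trace, prominence_frac = 0.2, min_separation = 1.0) {
  fs <- trace_fs(trace)
  x <- trace$x
  rng <- max(x) - min(x)
  if (rng == 0) {
    abort_analysis("no oscillation detected: trace is constant")
  }
  y <- -x # troughs of x are peaks of y
  cand <- local_maxima(y)
  if (length(cand) > 0L) {
    prom <- peak_prominence(y, cand)
    cand <- cand[prom >= prominence_frac * rng]
  }
  troughs <- enforce_separation(cand, y[cand], min_gap = min_separation * fs)
  if (length(troughs) < 2L) {
    abort_analysis("fewer than 2 end-of-exhale troughs found; cannot form cycles")
  }
  k <- length(troughs) - 1L
  peak_idx <- vapply(seq_len(k), function(i) {
    span <- seq(troughs[i], troughs[i + 1L])
    span[which.max(x[span])]
  }, integer(1))
  out <- tibble::tibble(
    cycle = seq_len(k),
    trough_idx = troughs[-(k + 1L)],
    peak_idx = peak_idx,
    next_trough_idx = troughs[-1L],
    trough_t = trace$t[troughs[-(k + 1L)]],
    trough_x = x[troughs[-(k + 1L)]],
    peak_x = x[peak_idx],
    amplitude = x[peak_idx] - x[troughs[-(k + 1L)]],
    period = diff(trace$t[troughs]),
    r_template = NA_real_,
    discarded = FALSE
  )
  attr(out, "trace") <- trace
  class(out) <- c("resp_cycles", class(out))
  out
}

cycles_trace <- function(cycles) {
  tr <- attr(cycles, "trace")
  if (is.null(tr)) {
    abort_input("cycle set has lost its `trace` attribute; re-run segment_cycles()")
  }
  tr
}

# Length-normalize one cycle's samples to `len` points.
normalize_cycle <- function(x, a, b, len = 101L) {
  seg <- x[a:b]
  if (length(seg) == len) {
    return(seg)
  }
  stats::approx(seq_along(seg), seg, n = len)$y
}

#' Discard cycles uncorrelated with the majority pattern
#'
#' Each cycle is length-normalized and Pearson-correlated against the
#' point-wise median cycle template (the median is robust to the very
#' outliers being screened). Cycles with correlation below `r_min` are
#' discarded worst-first, but at most a fraction `max_fraction` of all
#' cycles (rounded down, minimum one when any cycle fails) may be dropped:
#' uncorrelated cycles are expected to be rare, and the cap keeps a
#' pathological recording from silently losing most of its data. A warning
#' is raised when more cycles fail the threshold than the cap allows.
#'
#' @param cycles A [segment_cycles()] result.
#' @param max_fraction Maximum discardable fraction of cycles. Default 0.05.
#' @param r_min Minimum Pearson correlation against the template.
#'   Default 0.6.
#' @param template_len Number of points of the length-normalized cycle.
#' @return The cycle set with `r_template` filled and `discarded` set for
#'   rejected cycles.
#' @export
reject_outlier_cycles <- function(cycles, max_fraction = 0.05, r_min = 0.6,
                                  template_len = 101L) {
  n <- nrow(cycles)
  if (n < 3L) {
    abort_input("need at least 3 cycles to screen for outliers (got %d)", n)
  }
  tr <- cycles_trace(cycles)
  mat <- vapply(seq_len(n), function(i) {
    normalize_cycle(tr$x, cycles$trough_idx[i], cycles$next_trough_idx[i], template_len)
  }, numeric(template_len))
  template <- apply(mat, 1L, stats::median)
  r <- vapply(seq_len(n), function(i) {
    if (stats::sd(mat[, i]) == 0 || stats::sd(template) == 0) {
      return(-1)
    }
    stats::cor(mat[, i], template)
  }, numeric(1))
  cycles$r_template <- r
  failing <- which(r < r_min)
  if (length(failing) > 0L) {
    cap <- max(1L, floor(max_fraction * n))
    if (length(failing) > cap) {
      rlang::warn(sprintf(
        "%d cycles fall below r = %.2f but only %d (%.0f%% cap) were discarded; the recording may be globally irregular",
        length(failing), r_min, cap, 100 * max_fraction
      ))
    }
    drop <- failing[order(r[failing])][seq_len(min(cap, length(failing)))]
    cycles$discarded[drop] <- TRUE
  }
  cycles
}

#' End-of-exhale baseline drift statistics
#'
#' Collects the end-of-exhale (trough) displacements of all retained cycles
#' (including the trailing trough of the last cycle) and summarizes the
#' baseline: MEE is the mean end-of-exhale location, MUD the maximal upward
#' drift position, MDD the maximal downward drift position, and MUD-MDD
#' their difference — the total baseline excursion of the recording, the
#' quantity used to grade baseline (in)stability.
#'
#' @param cycles A [segment_cycles()] (optionally outlier-screened) result.
#' @return A one-row tibble of class `resp_drift`: `mee`, `mud`, `mdd`,
#'   `mud_mdd` (trace units), and `n_troughs`.
#' @export
drift_stats <- function(cycles) {
  keep <- !cycles$discarded
  if (sum(keep) < 2L) {
    abort_input("need at least 2 retained cycles for drift statistics")
  }
  tr <- cycles_trace(cycles)
  idx <- sort(unique(c(cycles$trough_idx[keep], cycles$next_trough_idx[keep])))
  e <- tr$x[idx]
  out <- tibble::tibble(
    mee = mean(e),
    mud = max(e),
    mdd = min(e),
    mud_mdd = max(e) - min(e),
    n_troughs = length(e)
  )
  class(out) <- c("resp_drift", class(out))
  out
}

#' @exportS3Method generics::glance
glance.resp_cycles <- function(x, ...) {
  keep <- !x$discarded
  tibble::tibble(
    n_cycles = nrow(x),
    n_discarded = sum(x$discarded),
    mean_amplitude = mean(x$amplitude[keep]),
    sd_amplitude = stats::sd(x$amplitude[keep]),
    mean_period = mean(x$period[keep]),
    sd_period = stats::sd(x$period[keep])
  )
}
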
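# Four-group taxonomy of breathing patterns, ROC cutoff derivation, and
# ANOVA with Scheffe post hoc group comparison.

#' Published cutoff values for the stability indices
#'
#' The default cutoffs are the published ROC-derived values separating
#' visually regular from irregular breathing: 0.11 for SD_x, 0.062 for
#' SD_v, 0.117 for A1 and 0.349 for MUD-MDD, all in trace units (cm for a
#' cm-calibrated tracker). They are calibration-dependent: A1 in particular
#' is only comparable under a fixed spectral amplitude convention (this
#' package uses the `2/N` one-sided convention of [power_spectrum()]), so
#' cohorts recorded or normalized differently should re-derive cutoffs with
#' [roc_cutoff()].
#'
#' @param sd_x,sd_v,a1,drift Cutoffs for the four indices (trace units;
#'   `drift` applies to MUD-MDD).
#' @param amp_rule `"sd_x"` (default: amplitude regularity judged on SD_x
#'   alone, the strongest published discriminator) or `"both"` (SD_x and
#'   SD_v must both sit on the regular side).
#' @return A list of class `resp_cutoffs`. Boundary values classify as
#'   regular (inclusive comparisons toward regular). A1 judges *higher* as
#'   more regular; SD_x, SD_v and MUD-MDD judge lower as more regular.
#' @export
default_cutoffs <- function(sd_x = 0.11, sd_v = 0.062, a1 = 0.117,
                            drift = 0.349, amp_rule = c("sd_x", "both")) {
  amp_rule <- match.arg(amp_rule)
  for (v in c(sd_x, sd_v, a1, drift)) {
    if (!is_scalar_number(v) || v <= 0) {
      abort_input("all cutoffs must be positive numbers")
    }
  }
  structure(
    list(sd_x = sd_x, sd_v = sd_v, a1 = a1, drift = drift, amp_rule = amp_rule),
    class = "resp_cutoffs"
  )
}

#' Compute all stability indices of a trace
#'
#' Runs the full measurement pipeline: cycle segmentation, uncorrelated-
#' cycle rejection, end-of-exhale drift statistics, the modified Poincare
#' section (SD_x, SD_v), the Fourier fundamental peak (f0, A1) with the
#' spectral regularity verdict, and optionally the largest Lyapunov
#' exponent.
#'
#' @param trace A [resp_trace()].
#' @param band Fundamental-peak search band (Hz).
#' @param include_lle Also estimate the largest Lyapunov exponent? Off by
#'   default: the exponent is by far the most expensive index and does not
#'   enter the group rule.
#' @param smooth_window Displacement smoothing for velocity estimation
#'   (samples).
#' @param plane,direction Passed to [poincare_section()].
#' @param prominence_frac,min_separation Passed to [segment_cycles()].
#' @param max_fraction,r_min Passed to [reject_outlier_cycles()].
#' @return A one-row tibble: `sd_x`, `sd_v`, `a1`, `f0`, `mud_mdd`, `mee`,
#'   `lle`, `peak_ratio`, `concentration`, `spectral_regular`, `n_cycles`,
#'   `n_discarded`.
#' @export
stability_indices <- function(trace, band = c(0.05, 1.0), include_lle = FALSE,
                              smooth_window = 0, plane = "cycle",
                              direction = "up",
                              prominence_frac = 0.2, min_separation = 1.0,
                              max_fraction = 0.05, r_min = 0.6) {
  cycles <- segment_cycles(trace, prominence_frac, min_separation)
  if (nrow(cycles) >= 3L) {
    cycles <- reject_outlier_cycles(cycles, max_fraction, r_min)
  }
  drift <- drift_stats(cycles)
  portrait <- estimate_velocity(trace, smooth_window)
  poin <- poincare_section(portrait, cycles, plane = plane, direction = direction)
  spec <- power_spectrum(trace) |>
    fundamental_peak(band) |>
    spectral_regularity()
  lle <- if (include_lle) lle_estimate(trace)$lle else NA_real_
  tibble::tibble(
    sd_x = poin$sd_x,
    sd_v = poin$sd_v,
    a1 = attr(spec, "a1"),
    f0 = attr(spec, "f0"),
    mud_mdd = drift$mud_mdd,
    mee = drift$mee,
    lle = lle,
    peak_ratio = attr(spec, "peak_ratio"),
    concentration = attr(spec, "concentration"),
    spectral_regular = attr(spec, "regular_period"),
    n_cycles = nrow(cycles),
    n_discarded = sum(cycles$discarded)
  )
}

#' Classify a trace (or its indices) into the four-group taxonomy
#'
#' Amplitude regularity and period regularity each take two states, giving
#' four groups: A (both regular), B (regular amplitude, irregular period),
#' C (irregular amplitude, regular period), D (both irregular); baseline
#' drift is an orthogonal flag. Amplitude is regular when `sd_x <= cutoff`
#' (and `sd_v <= cutoff` too under `amp_rule = "both"`); the period is
#' regular when `a1 >= cutoff` — a taller fundamental peak means a more
#' stable period, so the comparison direction is inverted relative to the
#' other indices; drift is present when `mud_mdd > cutoff`. Boundary
#' values side with regular.
#'
#' @param x A [resp_trace()], or a one-row data frame / named list of
#'   indices with at least `sd_x`, `sd_v`, `a1` and `mud_mdd`.
#' @param cutoffs A [default_cutoffs()] object.
#' @param ... For a trace input, passed on to [stability_indices()].
#' @return A one-row tibble of class `stability_report`: the indices,
#'   `amp_regular`, `period_regular`, `drift_present`, `group`, and the
#'   cutoffs used (as the `cutoffs` attribute).
#' @examples
#' classify_trace(list(sd_x = 0.069, sd_v = 0.053, a1 = 0.178, mud_mdd = 0.242))
#' @export
classify_trace <- function(x, cutoffs = default_cutoffs(), ...) {
  if (!inherits(cutoffs, "resp_cutoffs")) {
    abort_input("`cutoffs` must come from default_cutoffs()")
  }
  idx <- if (inherits(x, "resp_trace")) {
    stability_indices(x, ...)
  } else {
    tibble::as_tibble(as.list(x)[
      intersect(
        names(x),
        c(
          "sd_x", "sd_v", "a1", "f0", "mud_mdd", "mee", "lle", "peak_ratio",
          "concentration", "spectral_regular", "n_cycles", "n_discarded"
        )
      )
    ])
  }
  for (nm in c("sd_x", "sd_v", "a1", "mud_mdd")) {
    if (is.null(idx[[nm]]) || !is.finite(idx[[nm]])) {
      abort_input("index `%s` is missing or non-finite", nm)
    }
  }
  amp_regular <- idx$sd_x <= cutoffs$sd_x
  if (cutoffs$amp_rule == "both") {
    amp_regular <- amp_regular && idx$sd_v <= cutoffs$sd_v
  }
  period_regular <- idx$a1 >= cutoffs$a1
  drift_present <- idx$mud_mdd > cutoffs$drift
  group <- if (amp_regular && period_regular) {
    "A"
  } else if (amp_regular) {
    "B"
  } else if (period_regular) {
    "C"
  } else {
    "D"
  }
  out <- tibble::as_tibble(c(
    idx,
    list(
      amp_regular = amp_regular,
      period_regular = period_regular,
      drift_present = drift_present,
      group = group
    )
  ))
  attr(out, "cutoffs") <- cutoffs
  class(out) <- c("stability_report", class(out))
  out
}

#' ROC analysis: AUC and Youden-optimal cutoff
#'
#' The area under the ROC curve is computed by the Mann-Whitney identity
#' (ties counted one half); the reported cutoff maximizes Youden's J
#' (sensitivity + specificity - 1) and is placed at the midpoint between
#' the adjacent distinct scores. When the scores run in the opposite
#' direction (AUC below 0.5) the orientation is flipped automatically and
#' flagged, so the returned AUC is always >= 0.5 and the rule reads
#' "positive if score >= cutoff" (or "<= cutoff" when `flipped`).
#'
#' @param scores Numeric index values.
#' @param labels Binary labels (logical, 0/1, or two-level factor); `TRUE`/
#'   `1` is the positive (irregular) class.
#' @return A one-row tibble: `auc`, `cutoff`, `sensitivity`, `specificity`,
#'   `flipped`, `n_pos`, `n_neg`.
#' @examples
#' roc_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
#' @export
roc_cutoff <- function(scores, labels) {
  if (is.factor(labels)) {
    labels <- as.integer(labels) - 1L
  }
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    abort_input("`scores` and `labels` must be equal-length and free of NA")
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort_input("both classes must be present for ROC analysis")
  }
  r <- rank(scores) # average ranks = half credit for ties
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  flipped <- auc < 0.5
  sc <- if (flipped) -scores else scores
  if (flipped) {
    auc <- 1 - auc
  }
  uq <- sort(unique(sc))
  if (length(uq) < 2L) {
    return(tibble::tibble(
      auc = auc, cutoff = NA_real_, sensitivity = NA_real_,
      specificity = NA_real_, flipped = flipped, n_pos = n_pos, n_neg = n_neg
    ))
  }
  cand <- (uq[-length(uq)] + uq[-1L]) / 2
  sens <- vapply(cand, function(th) mean(sc[labels == 1L] >= th), numeric(1))
  spec <- vapply(cand, function(th) mean(sc[labels == 0L] < th), numeric(1))
  j <- sens + spec - 1
  best <- which.max(j)
  tibble::tibble(
    auc = auc,
    cutoff = if (flipped) -cand[best] else cand[best],
    sensitivity = sens[best],
    specificity = spec[best],
    flipped = flipped,
    n_pos = n_pos,
    n_neg = n_neg
  )
}

#' One-way ANOVA with Scheffe post hoc comparison
#'
#' Classical one-way ANOVA across groups followed by Scheffe's all-pairs
#' criterion at level `alpha`, reported both as a pairwise table and as the
#' compact ordered-subset notation used for cohort tables (e.g.
#' `"A, B < C, D"`): groups are ordered by mean and merged into a block
#' while no member differs significantly from every member already in it.
#'
#' @param data A data frame, or a named list of numeric vectors (one per
#'   group).
#' @param value,group Column names (unquoted) of the index values and the
#'   group labels when `data` is a data frame.
#' @param alpha Scheffe significance level. Default 0.05.
#' @return An object of class `anova_scheffe`: list with `f_statistic`,
#'   `p_value`, `df`, per-`groups` summary tibble, `pairwise` tibble
#'   (difference, Scheffe critical value, verdict) and the `subsets`
#'   string.
#' @examples
#' anova_scheffe(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
#' @export
anova_scheffe <- function(data, value, group, alpha = 0.05) {
  if (is.list(data) && !is.data.frame(data)) {
    data <- tibble::tibble(
      group = rep(names(data), lengths(data)),
      value = unlist(data, use.names = FALSE)
    )
    value <- rlang::sym("value")
    group <- rlang::sym("group")
  } else {
    value <- rlang::ensym(value)
    group <- rlang::ensym(group)
  }
  df <- tibble::tibble(
    g = as.character(dplyr::pull(data, !!group)),
    y = as.numeric(dplyr::pull(data, !!value))
  )
  df <- df[stats::complete.cases(df), ]
  counts <- table(df$g)
  if (length(counts) < 2L || any(counts < 2L)) {
    abort_input("need at least 2 groups with at least 2 values each")
  }
  fit <- stats::lm(y ~ g, data = df)
  # a perfect fit warns before the zero-variance check can abort
  an <- suppressWarnings(stats::anova(fit))
  mse <- an[["Mean Sq"]][2L]
  if (mse == 0) {
    abort_analysis("zero within-group variance: ANOVA is undefined")
  }
  k <- length(counts)
  df1 <- k - 1L
  df2 <- nrow(df) - k
  fstat <- an[["F value"]][1L]
  pval <- an[["Pr(>F)"]][1L]
  summ <- df |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$y), sd = stats::sd(.data$y),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mean)
  crit_f <- stats::qf(1 - alpha, df1, df2)
  pairs <- utils::combn(summ$g, 2L)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1L, i]
    g2 <- pairs[2L, i]
    n1 <- summ$n[summ$g == g1]
    n2 <- summ$n[summ$g == g2]
    diff <- abs(summ$mean[summ$g == g1] - summ$mean[summ$g == g2])
    crit <- sqrt(df1 * crit_f * mse * (1 / n1 + 1 / n2))
    tibble::tibble(
      group1 = g1, group2 = g2, diff = diff,
      critical = crit, significant = diff > crit
    )
  })
  is_sig <- function(a, b) {
    row <- pairwise$group1 == a & pairwise$group2 == b |
      pairwise$group1 == b & pairwise$group2 == a
    pairwise$significant[row]
  }
  blocks <- list()
  for (g in summ$g) {
    placed <- FALSE
    if (length(blocks) > 0L) {
      last <- blocks[[length(blocks)]]
      if (!any(vapply(last, function(b) is_sig(b, g), logical(1)))) {
        blocks[[length(blocks)]] <- c(last, g)
        placed <- TRUE
      }
    }
    if (!placed) {
      blocks[[length(blocks) + 1L]] <- g
    }
  }
  subsets <- paste(
    vapply(blocks, function(b) paste(sort(b), collapse = ", "), character(1)),
    collapse = " < "
  )
  out <- list(
    f_statistic = fstat, p_value = pval, df = c(df1, df2),
    groups = summ, pairwise = pairwise, subsets = subsets, alpha = alpha
  )
  class(out) <- "anova_scheffe"
  out
}

#' @export
print.anova_scheffe <- function(x, ...) {
  cat(sprintf(
    "<anova_scheffe> F(%d, %d) = %.4g, p = %.3g; Scheffe subsets: %s\n",
    x$df[1], x$df[2], x$f_statistic, x$p_value, x$subsets
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.anova_scheffe <- function(x, ...) {
  x$pairwise
}

#' @exportS3Method generics::glance
glance.anova_scheffe <- function(x, ...) {
  tibble::tibble(
    f_statistic = x$f_statistic, p_value = x$p_value,
    df1 = x$df[1], df2 = x$df[2], subsets = x$subsets
  )
}

#' Analyze and classify a cohort of traces
#'
#' Computes the stability indices and group assignment of every trace,
#' summarizes each assigned group (mean and SD of every index), tests for
#' group differences with [anova_scheffe()] per index, and — when ground-
#' truth labels are available (supplied, or carried by synthetic traces) —
#' reports the recovery accuracy and ROC cutoffs re-derived per index
#' against the truth.
#'
#' @param traces List of [resp_trace()] objects.
#' @param cutoffs A [default_cutoffs()] object.
#' @param labels Optional character vector of true group labels; defaults
#'   to each trace's [ground_truth()] label when present.
#' @param ... Passed to [stability_indices()].
#' @return An object of class `cohort_report`: list with `per_trace`
#'   (tibble; failed traces appear as flagged rows with an `error`
#'   message), `group_summary`, `anova` (per-index F, p, subsets),
#'   `roc` (per-index AUC/cutoff vs truth, when labels exist), and
#'   `accuracy` (fraction of traces assigned their true group).
#' @export
cohort_report <- function(traces, cutoffs = default_cutoffs(), labels = NULL, ...) {
  if (length(traces) < 1L) {
    abort_input("need at least 1 trace")
  }
  if (is.null(labels)) {
    labels <- vapply(traces, function(tr) {
      gt <- attr(tr, "ground_truth")
      if (is.null(gt)) NA_character_ else gt$group_label
    }, character(1))
  }
  per_trace <- purrr::imap_dfr(traces, function(tr, i) {
    res <- tryCatch(
      classify_trace(tr, cutoffs = cutoffs, ...),
      error = function(e) NULL
    )
    if (is.null(res)) {
      tibble::tibble(trace = i, group = NA_character_, error = "analysis failed")
    } else {
      dplyr::bind_cols(tibble::tibble(trace = i), res, tibble::tibble(error = NA_character_))
    }
  })
  per_trace$true_group <- labels[per_trace$trace]
  index_cols <- c("sd_x", "sd_v", "a1", "mud_mdd")
  ok <- per_trace[!is.na(per_trace$group), ]
  group_summary <- ok |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(
        dplyr::all_of(index_cols),
        list(mean = mean, sd = stats::sd)
      ),
      .groups = "drop"
    )
  by_col <- if (all(!is.na(ok$true_group))) "true_group" else "group"
  anova_tbl <- purrr::map_dfr(index_cols, function(col) {
    res <- tryCatch(
      anova_scheffe(ok, !!rlang::sym(col), !!rlang::sym(by_col)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      tibble::tibble(index = col, f_statistic = NA_real_, p_value = NA_real_, subsets = NA_character_)
    } else {
      dplyr::bind_cols(tibble::tibble(index = col), glance(res)[c("f_statistic", "p_value", "subsets")])
    }
  })
  roc_tbl <- NULL
  accuracy <- NA_real_
  if (all(!is.na(ok$true_group)) && nrow(ok) > 0L) {
    accuracy <- mean(ok$group == ok$true_group)
    truth_amp <- ok$true_group %in% c("C", "D")
    truth_per <- ok$true_group %in% c("B", "D")
    axes <- list(
      sd_x = truth_amp, sd_v = truth_amp,
      a1 = truth_per, mud_mdd = truth_amp
    )
    roc_tbl <- purrr::imap_dfr(axes, function(truth, col) {
      res <- tryCatch(roc_cutoff(ok[[col]], truth), error = function(e) NULL)
      if (is.null(res)) {
        tibble::tibble(index = col, auc = NA_real_)
      } else {
        dplyr::bind_cols(tibble::tibble(index = col), res)
      }
    })
  }
  out <- list(
    per_trace = per_trace,
    group_summary = group_summary,
    anova = anova_tbl,
    roc = roc_tbl,
    accuracy = accuracy,
    cutoffs = cutoffs
  )
  class(out) <- "cohort_report"
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf(
    "<cohort_report> %d traces, groups: %s%s\n",
    nrow(x$per_trace),
    paste(sprintf(
      "%s=%d", x$group_summary$group, x$group_summary$n
    ), collapse = " "),
    if (is.finite(x$accuracy)) sprintf(", recovery accuracy %.1f%%", 100 * x$accuracy) else ""
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cohort_report <- function(x, ...) {
  x$per_trace
}

#' @exportS3Method generics::glance
glance.cohort_report <- function(x, ...) {
  tibble::tibble(
    n_traces = nrow(x$per_trace),
    n_failed = sum(!is.na(x$per_trace$error)),
    accuracy = x$accuracy
  )
}
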
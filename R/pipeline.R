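# End-to-end per-trace analysis: ingestion -> cycles -> the four transforms
# -> classification, with JSON report and optional four-panel figure.

#' Default configuration of the full-analysis pipeline
#'
#' Flat list of every tunable parameter with its module default, so a run
#' can log exactly what it used. Override any subset via the `config`
#' argument of [run_full_analysis()] or a YAML file read with
#' [read_run_config()].
#'
#' @return A named list.
#' @export
default_run_config <- function() {
  list(
    format = "auto",
    default_fs = 25,
    prominence_frac = 0.2,
    min_separation = 1.0,
    max_fraction = 0.05,
    r_min = 0.6,
    smooth_window = 0,
    plane = "cycle",
    direction = "up",
    band = c(0.05, 1.0),
    ratio_min = 2.0,
    conc_min = 0.8,
    conc_halfwidth = 0.05,
    include_lle = TRUE,
    cutoff_sd_x = 0.11,
    cutoff_sd_v = 0.062,
    cutoff_a1 = 0.117,
    cutoff_drift = 0.349,
    amp_rule = "sd_x",
    seed = NULL
  )
}

#' Read a YAML run configuration
#'
#' @param path YAML file with flat keys matching [default_run_config()].
#' @return The default configuration with the file's overrides applied.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort_input("config file does not exist: %s", path)
  }
  user <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(), user)
}

#' Run the full stability analysis of one trace
#'
#' Reads (or takes) a trace, computes all stability indices and the group
#' label, and optionally writes a JSON report plus a four-panel figure
#' (time-amplitude curve, phase-space diagram, Poincare section, amplitude
#' spectrum) to `out_dir`. Every parameter used is echoed into the report,
#' so each number is reproducible by calling the underlying functions with
#' the logged parameters.
#'
#' @param input A file path or a [resp_trace()].
#' @param out_dir Output directory for `report.json` (and `panels.png` when
#'   `plot = TRUE`); `NULL` writes nothing.
#' @param config Named list of overrides of [default_run_config()].
#' @param plot Write the four-panel figure? Requires the patchwork package.
#' @return The [classify_trace()] report, invisibly, with the full result
#'   list attached as attribute `artifacts`.
#' @export
run_full_analysis <- function(input, out_dir = NULL, config = list(), plot = FALSE) {
  cfg <- utils::modifyList(default_run_config(), config)
  if (!is.null(cfg$seed)) {
    set.seed(cfg$seed)
  }
  trace <- if (inherits(input, "resp_trace")) {
    input
  } else {
    read_trace(input, format = cfg$format, default_fs = cfg$default_fs)
  }
  cycles <- segment_cycles(trace, cfg$prominence_frac, cfg$min_separation)
  if (nrow(cycles) >= 3L) {
    cycles <- reject_outlier_cycles(cycles, cfg$max_fraction, cfg$r_min)
  }
  drift <- drift_stats(cycles)
  portrait <- estimate_velocity(trace, cfg$smooth_window)
  poin <- poincare_section(portrait, cycles,
    plane = cfg$plane, direction = cfg$direction
  )
  spec <- power_spectrum(trace) |>
    fundamental_peak(cfg$band) |>
    spectral_regularity(cfg$ratio_min, cfg$conc_min, cfg$conc_halfwidth)
  lle <- if (isTRUE(cfg$include_lle)) lle_estimate(trace) else NULL
  cutoffs <- default_cutoffs(
    sd_x = cfg$cutoff_sd_x, sd_v = cfg$cutoff_sd_v,
    a1 = cfg$cutoff_a1, drift = cfg$cutoff_drift, amp_rule = cfg$amp_rule
  )
  indices <- list(
    sd_x = poin$sd_x, sd_v = poin$sd_v,
    a1 = attr(spec, "a1"), f0 = attr(spec, "f0"),
    mud_mdd = drift$mud_mdd, mee = drift$mee,
    lle = if (is.null(lle)) NA_real_ else lle$lle,
    peak_ratio = attr(spec, "peak_ratio"),
    concentration = attr(spec, "concentration"),
    spectral_regular = attr(spec, "regular_period"),
    n_cycles = nrow(cycles), n_discarded = sum(cycles$discarded)
  )
  report <- classify_trace(indices, cutoffs = cutoffs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    payload <- list(
      source = if (inherits(input, "resp_trace")) "in-memory trace" else input,
      parameters = cfg[order(names(cfg))],
      indices = as.list(report),
      drift = as.list(drift),
      embedding = if (is.null(lle)) NULL else glance(lle)[, c("tau", "m", "theiler")],
      n_samples = nrow(trace),
      fs = trace_fs(trace)
    )
    jsonlite::write_json(
      payload, file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
    )
    if (isTRUE(plot)) {
      write_panels(trace, portrait, poin, spec, file.path(out_dir, "panels.png"))
    }
  }
  attr(report, "artifacts") <- list(
    trace = trace, cycles = cycles, drift = drift, portrait = portrait,
    poincare = poin, spectrum = spec, lle = lle, config = cfg
  )
  invisible(report)
}

write_panels <- function(trace, portrait, poin, spec, path) {
  if (!requireNamespace("patchwork", quietly = TRUE)) {
    rlang::warn("patchwork not installed; skipping the four-panel figure")
    return(invisible(NULL))
  }
  panels <- (autoplot(trace) | autoplot(portrait)) /
    (autoplot(poin) | autoplot(spec))
  ggplot2::ggsave(path, panels, width = 10, height = 7, dpi = 120)
  invisible(path)
}
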
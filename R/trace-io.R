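#' Read a respiratory trace from disk
#'
#' Reads the two plain-text trace dialects the package understands:
#'
#' * **csv** — two numeric columns `time_s, amplitude`, no header required,
#'   `#` comment lines ignored. A slightly non-uniform time grid is accepted
#'   if no step deviates from the median step by more than 10 percent of that
#'   step; accepted grids are snapped to the exact median step.
#' * **vxp** — a minimal self-describing dialect for marker-block tracker
#'   exports: `key=value` header lines up to a `[Data]` marker, then one
#'   amplitude sample per line. The key `samples_per_second` gives the
#'   sampling rate; if absent, `default_fs` is assumed.
#'
#' @param path Path to the file.
#' @param format `"csv"`, `"vxp"`, or `"auto"` (decide from the extension,
#'   falling back to content sniffing).
#' @param default_fs Sampling rate assumed for a vxp file without a
#'   `samples_per_second` key (Hz). Default 25, a typical video-tracker rate.
#' @return A [resp_trace()]. File-level metadata (source path, header keys)
#'   is kept in the `meta` attribute.
#' @seealso [write_trace()], [resample_trace()]
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("0.00,0.50", "0.04,0.60", "0.08,0.55"), f)
#' read_trace(f)
#' @export
read_trace <- function(path, format = c("auto", "csv", "vxp"), default_fs = 25) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_input("file does not exist: %s", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort_input("empty trace file: %s", path)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "vxp") {
      "vxp"
    } else if (ext == "csv") {
      "csv"
    } else if (any(grepl("^\\[Data\\]", lines))) {
      "vxp"
    } else {
      "csv"
    }
  }
  switch(format,
    csv = read_trace_csv(lines, path),
    vxp = read_trace_vxp(lines, path, default_fs)
  )
}

read_trace_csv <- function(lines, path) {
  lines <- lines[!grepl("^\\s*#", lines)]
  if (length(lines) == 0L) {
    abort_input("no data lines in %s", path)
  }
  fields <- strsplit(lines, ",", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    abort_input("csv trace needs two columns (time_s, amplitude): %s", path)
  }
  t <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  x <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(t) || anyNA(x)) {
    abort_input("non-numeric values in csv trace: %s", path)
  }
  if (length(t) < 2L) {
    abort_input("trace needs at least 2 samples: %s", path)
  }
  if (is.unsorted(t, strictly = TRUE)) {
    abort_input("non-monotonic time column in %s", path)
  }
  steps <- diff(t)
  med <- stats::median(steps)
  if (max(abs(steps - med)) >= 0.1 * med) {
    abort_input(
      "time grid in %s is non-uniform beyond 10%% of the median step; read the columns yourself and use resample_trace()",
      path
    )
  }
  # snap to the exact median step
  t_snap <- t[1] + (seq_along(t) - 1) * med
  resp_trace(
    t = t_snap, x = x, fs = 1 / med,
    meta = list(source = path, format = "csv")
  )
}

read_trace_vxp <- function(lines, path, default_fs) {
  marker <- grep("^\\[Data\\]", lines)
  if (length(marker) == 0L) {
    abort_input("vxp file has no [Data] marker: %s", path)
  }
  marker <- marker[1L]
  header <- lines[seq_len(marker - 1L)]
  header <- header[grepl("=", header, fixed = TRUE)]
  keys <- sub("=.*$", "", header)
  vals <- sub("^[^=]*=", "", header)
  meta <- as.list(trimws(vals))
  names(meta) <- trimws(keys)
  fs <- if ("samples_per_second" %in% names(meta)) {
    as.numeric(meta$samples_per_second)
  } else {
    default_fs
  }
  if (!is_scalar_number(fs) || fs <= 0) {
    abort_input("invalid samples_per_second in %s", path)
  }
  x <- suppressWarnings(as.numeric(lines[seq(marker + 1L, length(lines))]))
  if (length(x) < 2L || anyNA(x)) {
    abort_input("vxp data block in %s is empty or non-numeric", path)
  }
  meta$source <- path
  meta$format <- "vxp"
  resp_trace(x = x, fs = fs, meta = meta)
}

#' Write a respiratory trace to disk
#'
#' Writes a trace so that [read_trace()] recovers the samples bit-identically
#' (full 17-significant-digit decimal representation).
#'
#' @param trace A [resp_trace()].
#' @param path Output path.
#' @param format `"csv"` (time_s, amplitude columns) or `"vxp"` (header with
#'   `samples_per_second`, then one amplitude per line).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("csv", "vxp")) {
  format <- match.arg(format)
  fs <- trace_fs(trace)
  lines <- switch(format,
    csv = c(
      "# time_s,amplitude",
      sprintf("%.17g,%.17g", trace$t, trace$x)
    ),
    vxp = c(
      sprintf("samples_per_second=%.17g", fs),
      "units=cm",
      "[Data]",
      sprintf("%.17g", trace$x)
    )
  )
  tryCatch(
    writeLines(lines, path),
    error = function(e) {
      rlang::abort(
        sprintf("cannot write trace to %s: %s", path, conditionMessage(e)),
        class = "respstab_io_error"
      )
    }
  )
  invisible(path)
}

#' Resample a trace onto a new uniform grid
#'
#' Linear interpolation onto a uniform grid at `fs_new` spanning the original
#' time range. The first sample is preserved exactly; the last grid node is
#' the final multiple of `1/fs_new` not beyond the original end point (equal
#' to it when the duration is commensurate with the new step).
#'
#' @param trace A [resp_trace()].
#' @param fs_new Target sampling rate in Hz.
#' @return A [resp_trace()] at `fs_new`. If `fs_new` equals the current rate
#'   the trace is returned unchanged.
#' @export
resample_trace <- function(trace, fs_new) {
  if (!is_scalar_number(fs_new) || fs_new <= 0) {
    abort_input("`fs_new` must be a positive number")
  }
  fs <- trace_fs(trace)
  if (identical(fs_new, fs)) {
    return(trace)
  }
  t0 <- trace$t[1]
  t_end <- trace$t[nrow(trace)]
  n_new <- floor((t_end - t0) * fs_new + 1e-9) + 1L
  t_new <- t0 + (seq_len(n_new) - 1) / fs_new
  x_new <- stats::approx(trace$t, trace$x, xout = t_new, rule = 2)$y
  meta <- attr(trace, "meta")
  meta$resampled_from_fs <- fs
  resp_trace(t = t_new, x = x_new, fs = fs_new, meta = meta)
}
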
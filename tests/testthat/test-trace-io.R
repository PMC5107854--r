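test_that("csv traces parse, snap to the median step, and carry fs", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# comment", "0.00,0.50", "0.04,0.60", "0.08,0.55"), f)
  tr <- read_trace(f)
  expect_s3_class(tr, "resp_trace")
  expect_equal(nrow(tr), 3L)
  expect_equal(trace_fs(tr), 25, tolerance = 1e-9)
  expect_equal(tr$x, c(0.50, 0.60, 0.55))
})

test_that("malformed trace files raise input errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), f)
  expect_error(read_trace(f), class = "respstab_input_error")

  writeLines(c("0.0,1", "0.1,2", "0.15,3"), f) # 2:1 step ratio
  expect_error(read_trace(f), class = "respstab_input_error")

  writeLines(c("0.2,1", "0.1,2", "0.3,3"), f) # non-monotonic
  expect_error(read_trace(f), class = "respstab_input_error")

  expect_error(read_trace(file.path(tempdir(), "absent.csv")),
    class = "respstab_input_error"
  )
})

test_that("write/read round trip is bit-identical in both formats", {
  tr <- generate_trace(synth_params(duration = 30, seed = 4))
  for (fmt in c("csv", "vxp")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_trace(tr, f, format = fmt)
    back <- read_trace(f, format = fmt)
    expect_identical(back$x, tr$x)
    # vxp stores fs verbatim; csv re-derives it from the time column
    if (fmt == "vxp") {
      expect_identical(trace_fs(back), trace_fs(tr))
    } else {
      expect_equal(trace_fs(back), trace_fs(tr), tolerance = 1e-9)
    }
  }
})

test_that("a 20-minute 25 Hz synthetic trace survives the round trip", {
  tr <- generate_trace(synth_params(duration = 1200, seed = 9))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, f, format = "csv")
  back <- read_trace(f)
  expect_identical(back$x, tr$x)
  expect_equal(nrow(back), 30000L)
})

test_that("vxp header supplies fs and headerless files fall back to default_fs", {
  f <- withr::local_tempfile(fileext = ".vxp")
  writeLines(c("samples_per_second=30", "[Data]", sprintf("%g", sin(1:50))), f)
  expect_equal(trace_fs(read_trace(f)), 30)

  writeLines(c("units=cm", "[Data]", sprintf("%g", sin(1:50))), f)
  expect_equal(trace_fs(read_trace(f)), 25) # documented default
  expect_equal(trace_fs(read_trace(f, default_fs = 10)), 10)
})

test_that("resampling is exact on linear signals and idempotent at the same rate", {
  t <- (0:99) / 25
  tr <- resp_trace(t = t, x = 2 * t, fs = 25)
  expect_identical(resample_trace(tr, 25), tr)

  up <- resample_trace(tr, 40)
  expect_equal(up$x, 2 * up$t, tolerance = 1e-12)
  expect_equal(trace_fs(up), 40)
  expect_equal(up$t[1], tr$t[1])
})

test_that("resampling a sinusoid stays within 1e-3 of the closed form", {
  tr <- sine_trace(f = 0.25, duration = 40, fs = 25)
  up <- resample_trace(tr, 50)
  expect_lt(max(abs(up$x - sin(2 * pi * 0.25 * up$t))), 1e-3)
  expect_error(resample_trace(tr, -1), class = "respstab_input_error")
})

test_that("trace invariants reject bad construction", {
  expect_error(resp_trace(x = c(1, NA, 3), fs = 25), class = "respstab_input_error")
  expect_error(resp_trace(x = 1, fs = 25), class = "respstab_input_error")
  expect_error(
    resp_trace(t = c(0, 0.1, 0.3), x = c(1, 2, 3), fs = 10),
    class = "respstab_input_error"
  )
})

test_that("bundled example traces load", {
  csv <- system.file("extdata", "synthetic_groupA_trace.csv", package = "respstab")
  vxp <- system.file("extdata", "synthetic_groupC_drift_trace.vxp", package = "respstab")
  expect_equal(trace_fs(read_trace(csv)), 10, tolerance = 1e-9)
  expect_equal(trace_fs(read_trace(vxp)), 10)
})
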
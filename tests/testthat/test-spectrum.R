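test_that("a pure tone over integer cycles gives a single exact bin", {
  tr <- sine_trace(f = 0.25, duration = 240, fs = 25) # 6000 samples, 60 cycles
  sp <- power_spectrum(tr, detrend = "mean") # mean removal keeps the tone untouched
  i0 <- which.min(abs(sp$freq - 0.25))
  expect_equal(sp$freq[i0], 0.25)
  expect_equal(sp$amp[i0], 1, tolerance = 1e-9)
  expect_lt(max(sp$amp[-i0]), 1e-10)
})

test_that("a two-tone signal recovers both amplitudes and picks the taller as f0", {
  t <- (0:5999) / 25
  x <- 1.0 * sin(2 * pi * 0.25 * t) + 0.3 * sin(2 * pi * 0.50 * t)
  sp <- power_spectrum(resp_trace(t = t, x = x, fs = 25), detrend = "mean")
  expect_equal(sp$amp[which.min(abs(sp$freq - 0.25))], 1.0, tolerance = 1e-9)
  expect_equal(sp$amp[which.min(abs(sp$freq - 0.50))], 0.3, tolerance = 1e-9)
  pk <- fundamental_peak(sp)
  expect_equal(attr(pk, "f0"), 0.25)
  expect_equal(attr(pk, "a1"), 1.0, tolerance = 1e-9)
})

test_that("constant signals and short traces are rejected appropriately", {
  flat <- resp_trace(x = rep(2, 1000), fs = 25)
  sp <- power_spectrum(flat, detrend = "mean")
  expect_lt(max(sp$amp), 1e-12)
  expect_error(fundamental_peak(sp), class = "respstab_analysis_error")
  expect_error(
    power_spectrum(resp_trace(x = sin(1:32), fs = 25)),
    class = "respstab_input_error"
  )
  expect_error(
    fundamental_peak(power_spectrum(sine_trace(duration = 60)), band = c(0.05, 20)),
    class = "respstab_input_error"
  )
})

test_that("Parseval's identity holds between time and frequency domains", {
  tr <- generate_trace(preset_params("D", duration = 240, seed = 19))
  sp <- power_spectrum(tr)
  n <- attr(sp, "n")
  nyq <- n %% 2 == 0
  mid <- 2:(length(sp$amp) - as.integer(nyq))
  e_spec <- n * (sp$amp[1]^2 + sum(sp$amp[mid]^2) / 2 +
    if (nyq) sp$amp[length(sp$amp)]^2 else 0)
  expect_equal(e_spec, attr(sp, "energy_time"), tolerance = 1e-6)
})

test_that("the two-part regularity rule behaves at its analytic extremes", {
  pure <- sine_trace(f = 0.25, duration = 240, fs = 25) |>
    power_spectrum(detrend = "mean") |>
    fundamental_peak() |>
    spectral_regularity()
  expect_gt(attr(pure, "peak_ratio"), 2)
  expect_equal(attr(pure, "concentration"), 1, tolerance = 1e-6)
  expect_true(attr(pure, "regular_period"))

  t <- (0:5999) / 25
  twin <- resp_trace(t = t, x = sin(2 * pi * 0.2 * t) + sin(2 * pi * 0.4 * t), fs = 25) |>
    power_spectrum(detrend = "mean") |>
    fundamental_peak() |>
    spectral_regularity()
  # two equal peaks: ratio 1 < 2 and the energy is split
  expect_equal(attr(twin, "peak_ratio"), 1, tolerance = 1e-6)
  expect_false(attr(twin, "regular_period"))
})

test_that("scaling the trace scales A1 but leaves the verdict untouched", {
  tr <- generate_trace(preset_params("B", duration = 300, seed = 23))
  sp1 <- spectral_regularity(fundamental_peak(power_spectrum(tr)))
  trk <- resp_trace(t = tr$t, x = 5 * tr$x, fs = trace_fs(tr))
  spk <- spectral_regularity(fundamental_peak(power_spectrum(trk)))
  expect_equal(attr(spk, "a1"), 5 * attr(sp1, "a1"), tolerance = 1e-9)
  expect_equal(attr(spk, "peak_ratio"), attr(sp1, "peak_ratio"), tolerance = 1e-9)
  expect_equal(attr(spk, "concentration"), attr(sp1, "concentration"), tolerance = 1e-9)
  expect_identical(attr(spk, "regular_period"), attr(sp1, "regular_period"))
})

test_that("f0 of a noiseless periodic synthetic sits within one bin of 1/mu_T", {
  tr <- generate_trace(synth_params(
    sigma_A = 0, sigma_T = 0, noise_sd = 0,
    duration = 400, seed = 1
  ))
  sp <- fundamental_peak(power_spectrum(tr))
  expect_lt(abs(attr(sp, "f0") - 0.25), trace_fs(tr) / nrow(tr) + 1e-12)
})

test_that("regular and irregular preset cohorts get the intended verdicts", {
  verdicts <- function(group) {
    vapply(1:10, function(s) {
      tr <- generate_trace(preset_params(group, duration = 600, seed = 900 + s))
      attr(spectral_regularity(fundamental_peak(power_spectrum(tr))), "regular_period")
    }, logical(1))
  }
  expect_gte(mean(verdicts("A")), 0.8)
  expect_gte(mean(!verdicts("B")), 0.8)
})
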
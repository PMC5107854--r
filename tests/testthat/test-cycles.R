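test_that("a sinusoid segments into its analytic cycles", {
  # sin(2 pi 0.25 t) on [0, 60): troughs at t = 3 + 4k, k = 0..14
  tr <- sine_trace(f = 0.25, duration = 60, fs = 25, a = 1)
  cy <- segment_cycles(tr)
  expect_equal(nrow(cy), 14L)
  expect_equal(cy$trough_t, 3 + 4 * (0:13))
  expect_true(all(abs(cy$period - 4) < 1e-9))
  expect_true(all(abs(cy$amplitude - 2) < 1e-6))
  # troughs and peaks strictly alternate
  expect_true(all(cy$trough_idx < cy$peak_idx & cy$peak_idx < cy$next_trough_idx))
})

test_that("degenerate traces raise analysis errors", {
  tr <- resp_trace(x = rep(1, 200), fs = 25)
  expect_error(segment_cycles(tr), class = "respstab_analysis_error")
  ramp <- resp_trace(x = seq(0, 1, length.out = 200), fs = 25)
  expect_error(segment_cycles(ramp), class = "respstab_analysis_error")
})

test_that("recovered periods match the generator's drawn periods", {
  tr <- generate_trace(preset_params("A", duration = 300, seed = 1, noise_sd = 0))
  gt <- ground_truth(tr)
  cy <- segment_cycles(tr)
  mid_t <- (cy$trough_t + tr$t[cy$next_trough_idx]) / 2
  drawn <- gt$cycles$T[findInterval(mid_t, gt$cycles$start)]
  expect_true(all(abs(cy$period - drawn) <= 2 / trace_fs(tr) + 1e-9))
})

make_spliced_trace <- function(n_normal, n_corrupt, invert_at = NULL) {
  # n_normal identical sine cycles with optional corrupted/inverted cycles
  fs <- 25
  cyc <- sin(2 * pi * (0:(4 * fs - 1)) / (4 * fs) - pi / 2) # trough-to-trough
  parts <- rep(list(cyc), n_normal + n_corrupt)
  if (n_corrupt > 0) {
    for (k in seq_len(n_corrupt)) parts[[invert_at[k]]] <- -cyc
  }
  resp_trace(x = unlist(parts), fs = fs)
}

test_that("identical cycles are never discarded", {
  tr <- make_spliced_trace(12, 0)
  cy <- reject_outlier_cycles(segment_cycles(tr))
  expect_equal(sum(cy$discarded), 0L)
  expect_true(all(cy$r_template[!cy$discarded] > 0.99))
})

test_that("an inverted cycle is caught and the worst offender discarded first", {
  # the inversion corrupts the two trough-to-trough segments that overlap
  # it (r ~ 0.06 each); the 5% cap allows one discard and warns about the
  # second
  tr <- make_spliced_trace(20, 1, invert_at = 10)
  expect_warning(
    cy <- reject_outlier_cycles(segment_cycles(tr)),
    "globally irregular"
  )
  expect_equal(sum(cy$discarded), 1L)
  bad <- which(cy$discarded)
  expect_equal(cy$r_template[bad], min(cy$r_template))
  expect_lt(cy$r_template[bad], 0.6)
})

test_that("the discard cap limits rejection to ~5% with a minimum of one", {
  # two corrupted cycles among ~12: floor(0.05 * n) = 0, so the documented
  # minimum of one discard applies and a warning flags the excess
  tr <- make_spliced_trace(10, 2, invert_at = c(4, 8))
  expect_warning(
    cy <- reject_outlier_cycles(segment_cycles(tr)),
    "globally irregular"
  )
  expect_equal(sum(cy$discarded), 1L)
  expect_gt(sum(cy$r_template < 0.6), 1L)
})

test_that("drift statistics follow the direct arithmetic definition", {
  # trough values engineered to [-1.0, -0.9, -1.1] via cycle baselines
  fs <- 25
  cyc <- function(b) b + (1 - cos(pi * (0:(4 * fs - 1)) / (2 * fs))^4)
  x <- c(cyc(-1.0), cyc(-0.9), cyc(-1.1), cyc(-1.0))
  tr <- resp_trace(x = x, fs = fs)
  d <- drift_stats(segment_cycles(tr))
  expect_equal(d$mud, -0.9)
  expect_equal(d$mdd, -1.1)
  expect_equal(d$mud_mdd, 0.2)
  expect_true(d$mdd <= d$mee && d$mee <= d$mud)
})

test_that("a drift-free sinusoid has zero MUD-MDD and a linear slope the closed form", {
  tr <- sine_trace(f = 0.25, duration = 120, fs = 25)
  expect_equal(drift_stats(segment_cycles(tr))$mud_mdd, 0, tolerance = 1e-12)

  s <- 0.01
  t <- (0:(400 * 25 - 1)) / 25
  trd <- resp_trace(t = t, x = sin(2 * pi * 0.25 * t) + s * t, fs = 25)
  cy <- segment_cycles(trd)
  d <- drift_stats(cy)
  span <- max(trd$t[c(cy$trough_idx, cy$next_trough_idx)]) -
    min(trd$t[c(cy$trough_idx, cy$next_trough_idx)])
  expect_equal(d$mud_mdd, s * span, tolerance = s * 4 / 25 + 1e-6)
})

test_that("cycle measures respect shift and scale equivariance", {
  tr <- generate_trace(preset_params("C", duration = 200, seed = 6))
  cy <- segment_cycles(tr)
  d <- drift_stats(cy)

  shifted <- resp_trace(t = tr$t, x = tr$x + 5, fs = trace_fs(tr))
  cys <- segment_cycles(shifted)
  ds <- drift_stats(cys)
  expect_equal(cys$amplitude, cy$amplitude, tolerance = 1e-12)
  expect_equal(cys$period, cy$period, tolerance = 1e-12)
  expect_equal(ds$mud_mdd, d$mud_mdd, tolerance = 1e-12)
  expect_equal(ds$mee, d$mee + 5, tolerance = 1e-12)

  scaled <- resp_trace(t = tr$t, x = 3 * tr$x, fs = trace_fs(tr))
  cyk <- segment_cycles(scaled)
  dk <- drift_stats(cyk)
  expect_equal(cyk$amplitude, 3 * cy$amplitude, tolerance = 1e-9)
  expect_equal(cyk$period, cy$period, tolerance = 1e-12)
  expect_equal(dk$mud_mdd, 3 * d$mud_mdd, tolerance = 1e-9)
})
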
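test_that("T1 relaxation follows the closed-form recovery solution", {
  s <- mz_relax(mz_state(0), 1800, 1209)
  expect_equal(s$mz, 1 - exp(-1800 / 1209), tolerance = 1e-12)
  expect_equal(s$mz, 0.7743, tolerance = 1e-4)
  expect_equal(s$time, 1800)
  # equilibrium is a fixed point, saturation recovers fully at long times
  expect_equal(mz_relax(mz_state(1), 12345, 1209)$mz, 1)
  expect_equal(mz_relax(mz_state(0), 1e9, 1209)$mz, 1, tolerance = 1e-12)
  expect_error(mz_relax(mz_state(0), 10, -5), "t1")
  expect_error(mz_relax(mz_state(0), -1, 100), "dt")
})

test_that("inversion scales and flips Mz without advancing time", {
  expect_equal(mz_invert(mz_state(0.5), 1)$mz, -0.5)
  expect_equal(mz_invert(mz_state(0.8551), 0.93)$mz, -0.7952, tolerance = 1e-4)
  expect_equal(mz_invert(mz_state(0), 0.9)$mz, 0)
  expect_equal(mz_invert(mz_state(0.5, time = 7), 0.9)$time, 7)
  expect_error(mz_invert(mz_state(0.5), 0), "efficiency")
  expect_error(mz_invert(mz_state(0.5), 1.2), "efficiency")
})

test_that("residual magnetization matches an independent event-stepping oracle", {
  ref <- asl_reference_schemes()
  eff <- pulse_efficiency()
  for (i in seq_len(nrow(ref))) {
    tim <- bs_timing(ref$label_duration[i], ref$pld[i],
                     c(ref$ti_bs1[i], ref$ti_bs2[i]))
    closed <- bs_residual_mz(tim, ref$t1[i], eff)
    stepped <- stepwise_residual(tim$inversion_times, ref$t1[i],
                                 eff$inversion, tim$readout_time)
    expect_lt(abs(closed - stepped), 1e-9)
  }
})

test_that("published residual-signal table reproduces at the calibrated efficiency", {
  ref <- asl_reference_schemes()
  beta <- bs_calibrate_efficiency(ref)
  expect_equal(beta, 0.93, tolerance = 0.01)
  eff <- pulse_efficiency(inversion = beta)
  for (i in seq_len(nrow(ref))) {
    tim <- bs_timing(ref$label_duration[i], ref$pld[i],
                     c(ref$ti_bs1[i], ref$ti_bs2[i]))
    sim_pct <- 100 * bs_residual_mz(tim, ref$t1[i], eff)
    expect_equal(aslbs:::round_half_away(sim_pct, 1), ref$residual_pct[i],
                 info = paste(ref$scheme[i], ref$tissue[i]))
  }
})

test_that("with no inversions the residual is pure saturation recovery, monotone in readout", {
  tim <- bs_timing(1800, 2200, numeric(0))
  expect_equal(bs_residual_mz(tim, 1209), 1 - exp(-4000 / 1209),
               tolerance = 1e-12)
  readouts <- seq(500, 6000, by = 500)
  res <- vapply(readouts, function(r)
    bs_residual_mz(bs_timing(r / 2, r / 2, numeric(0)), 1209), numeric(1))
  expect_true(all(diff(res) > 0))
})

test_that("even inversion count after full recovery leaves a positive residual", {
  # T1 short relative to the first TI, perfect pulses: Mz has recovered to
  # ~1 before either inversion, so two sign flips end positive
  tim <- bs_timing(2000, 2000, c(3000, 3500))
  res <- bs_residual_mz(tim, 200, pulse_efficiency(inversion = 1))
  expect_gt(res, 0)
})

test_that("trajectory sampling ends at the residual and jumps only at TIs", {
  eff <- pulse_efficiency()
  tim <- ref_timing("csf")
  tr <- bs_mz_trajectory(tim, 4308, eff, step = 1)
  expect_equal(tail(tr$mz, 1), bs_residual_mz(tim, 4308, eff),
               tolerance = 1e-12)
  expect_lt(abs(tail(tr$mz, 1) - (-0.002)), 5e-4)
  # duplicated time points (the discontinuities) occur exactly at the TIs
  dup <- tr$time_ms[duplicated(tr$time_ms)]
  expect_setequal(unique(dup), tim$inversion_times)
  # degenerate sampling still includes start and readout
  tr2 <- bs_mz_trajectory(bs_timing(100, 100, numeric(0)), 1209, eff,
                          step = 1e5)
  expect_equal(range(tr2$time_ms), c(0, 200))
  # endpoint signs for the four default tissues match the published row signs
  t1s <- tissue_relaxation()
  ends <- vapply(c(t1s$t1_gm, t1s$t1_wm, t1s$t1_csf), function(t1)
    tail(bs_mz_trajectory(tim, t1, eff)$mz, 1), numeric(1))
  expect_equal(sign(ends), c(-1, 1, -1))  # GM -7.0, WM 2.9, CSF -0.2
})

test_that("efficiency calibration recovers known and boundary values", {
  ref <- asl_reference_schemes()
  gen <- function(beta) {
    ref$residual_pct <- vapply(seq_len(nrow(ref)), function(i) {
      tim <- bs_timing(ref$label_duration[i], ref$pld[i],
                       c(ref$ti_bs1[i], ref$ti_bs2[i]))
      100 * bs_residual_mz(tim, ref$t1[i], pulse_efficiency(beta))
    }, numeric(1))
    ref
  }
  expect_equal(bs_calibrate_efficiency(gen(0.9)), 0.9, tolerance = 1e-3)
  expect_equal(bs_calibrate_efficiency(gen(1.0)[1, ]), 1.0, tolerance = 1e-3)
  expect_error(bs_calibrate_efficiency(ref[0, ]), "non-empty")
})

test_that("timing validation rejects out-of-order and out-of-range pulses", {
  expect_error(bs_timing(1800, 2200, c(3550, 1806)), "increasing")
  expect_error(bs_timing(1800, 2200, c(1806, 4200)), "increasing|readout")
  expect_error(bs_timing(1800, 2200, c(1500, 3550), constrained = TRUE),
               "constrained")
})
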
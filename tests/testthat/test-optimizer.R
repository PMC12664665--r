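test_that("constrained placement restricts the timing grid to the PLD", {
  g <- bs_grid_residuals(1800, 100, "constrained", step = 1)
  expect_true(all(g$ti_bs1 >= 1800))
  expect_true(all(g$ti_bs2 <= 1900 - 5))
  expect_true(all(g$ti_bs2 - g$ti_bs1 >= 5))
  # coarse grid leaves only a handful of candidates
  gc <- bs_grid_residuals(1800, 100, "constrained", step = 40)
  expect_lte(nrow(gc), 10)
})

test_that("unconstrained grid covers the labeling period and the published timing", {
  g <- bs_grid_residuals(1800, 2200, "unconstrained", step = 1)
  expect_true(any(g$ti_bs1 == 1806 & g$ti_bs2 == 3550))
  expect_true(any(g$ti_bs1 < 1800))
})

test_that("an impossible placement yields an infeasibility report, not an error", {
  g <- bs_grid_residuals(1800, 5, "constrained", step = 1)
  expect_equal(nrow(g), 0)
  expect_equal(attr(g, "infeasibility"), "empty grid")
  sol <- bs_optimize_timings("regular", 1800, 5, step = 1)
  expect_false(sol$feasible)
  expect_true(all(is.na(sol$inversion_times)))
})

test_that("grid residuals equal the event simulator at the returned timings", {
  g <- bs_grid_residuals(1800, 2200, "unconstrained", step = 400)
  eff <- pulse_efficiency()
  i <- c(1L, nrow(g) %/% 2L, nrow(g))
  for (j in i) {
    tim <- bs_timing(1800, 2200, c(g$ti_bs1[j], g$ti_bs2[j]))
    expect_equal(g$gm[j], 100 * bs_residual_mz(tim, 1209, eff),
                 tolerance = 1e-12)
    expect_equal(g$csf[j], 100 * bs_residual_mz(tim, 4308, eff),
                 tolerance = 1e-12)
  }
})

test_that("csf objective achieves CSF suppression with mixed tissue signs", {
  sol <- bs_optimize_timings("csf", 1800, 2200, step = 10)
  expect_true(sol$feasible)
  expect_lt(abs(sol$residuals["csf"]), 1)
  expect_lt(sign(sol$residuals["gm"]) * sign(sol$residuals["wm"]), 0)
  # the published timings are a feasible point, so the optimum cannot be
  # worse than their objective value max(|GM|, |WM|) = 7.0
  expect_lte(sol$objective, 7.0)
  # returned residuals are live recomputations at the returned timings
  expect_equal(unname(sol$residuals["gm"]),
               100 * bs_residual_mz(sol$timing, 1209), tolerance = 1e-12)
})

test_that("enhanced objective suppresses both tissues below the published residuals", {
  sol <- bs_optimize_timings("enhanced", 1800, 2200, step = 10)
  expect_true(sol$feasible)
  expect_lte(abs(sol$residuals["gm"]), 0.3)
  expect_lte(abs(sol$residuals["wm"]), 0.8)
})

test_that("regular objective stays near 5 percent with all-positive residuals", {
  sol <- bs_optimize_timings("regular", 1800, 2200, step = 10)
  expect_true(sol$feasible)
  expect_true(all(sol$residuals >= 0))
  expect_lte(max(abs(sol$residuals[c("gm", "wm")] - 5)), 5)
  expect_true(all(sol$inversion_times >= 1800))  # constrained placement
})

test_that("short-PLD constrained suppression is infeasible for every objective", {
  for (scheme in c("regular", "enhanced")) {
    sol <- bs_optimize_timings(scheme, 1800, 100, step = 2,
                               placement = "constrained")
    expect_false(sol$feasible)
  }
  g <- bs_grid_residuals(1800, 100, "constrained", step = 2)
  expect_gt(min(abs(g$gm)), 50)
})

test_that("per-PLD schedules share solutions across duplicate delays", {
  plds <- c(100, 100, 1275, 1800, 2100)
  sched <- bs_schedule("csf", 1800, plds, step = 25)
  expect_length(sched, 5)
  expect_identical(sched[[1]], sched[[2]])
  for (s in sched) expect_lt(abs(s$residuals["csf"]), 1)
  # single-delay schedule consistency with the direct optimizer
  one <- bs_schedule("csf", 1800, 2200, step = 25)
  direct <- bs_optimize_timings("csf", 1800, 2200, step = 25)
  expect_equal(one[[1]]$inversion_times, direct$inversion_times)
  # regular at short PLD propagates its infeasibility flag
  reg <- bs_schedule("regular", 1800, c(100, 2200), step = 10)
  expect_false(reg[["100"]]$feasible)
  expect_true(reg[["2200"]]$feasible)
})
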
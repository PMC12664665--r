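test_that("single-delay CBF inverts the kinetic model exactly at zero transit time", {
  kp <- kinetic_params(tau = 1800)
  expect_equal(cbf_single_delay(0, 1, kp, 2200), 0)
  fwd <- kinetic_params(tau = 1800, f = 60, att = 0)
  dm <- buxton_signal(1800 + 2200, fwd)
  expect_equal(cbf_single_delay(dm, 1, kp, 2200), 60, tolerance = 1e-10)
  # doubling labeling efficiency halves the estimate
  kp2 <- kinetic_params(tau = 1800, alpha = 2 * kp$alpha / 2)
  half <- kinetic_params(tau = 1800, alpha = kp$alpha / 2)
  expect_equal(cbf_single_delay(dm, 1, half, 2200),
               2 * cbf_single_delay(dm, 1, kp, 2200), tolerance = 1e-12)
  expect_true(is.na(cbf_single_delay(dm, 0, kp, 2200)))
})

test_that("kinetic-model signal is zero before arrival and continuous at bolus end", {
  kp <- kinetic_params(tau = 1800, f = 60, att = 1200)
  expect_equal(buxton_signal(c(0, 600, 1199.9), kp), rep(0, 3))
  t_end <- kp$att + kp$tau
  eps <- 1e-7
  expect_lt(abs(buxton_signal(t_end - eps, kp) - buxton_signal(t_end + eps, kp)),
            1e-12)
  expect_gt(buxton_signal(t_end, kp), 0)
})

test_that("weighted delay reduces to the mean for equal signals and to a point mass", {
  dm <- matrix(1, 3, 1)
  s <- multidelay_series(c(1275, 1800, 2100), dm, 1)
  expect_equal(weighted_delay(s), 1725)
  dm2 <- matrix(c(0, 0, 5), 3, 1)
  expect_equal(weighted_delay(multidelay_series(c(1275, 1800, 2100), dm2, 1)),
               2100)
  # all-nonpositive signal invalidates the voxel
  dm3 <- matrix(c(-1, 0, 0), 3, 1)
  expect_true(is.na(weighted_delay(multidelay_series(c(1275, 1800, 2100),
                                                     dm3, 1))))
})

test_that("weighted delay matches a literal summation oracle on model signals", {
  plds <- c(100, 100, 1275, 1800, 2100)
  kp <- kinetic_params(tau = 1800, f = 60, att = 1200)
  dm <- buxton_signal(kp$tau + plds, kp)
  # independent oracle: write the sum out term by term
  wd_oracle <- (plds[1] * dm[1] + plds[2] * dm[2] + plds[3] * dm[3] +
                plds[4] * dm[4] + plds[5] * dm[5]) /
               (dm[1] + dm[2] + dm[3] + dm[4] + dm[5])
  s <- multidelay_series(plds, matrix(dm, 5, 1), 1)
  expect_equal(weighted_delay(s), wd_oracle, tolerance = 1e-12)
  # duplicate short PLDs enter twice: dropping one changes the result
  s4 <- multidelay_series(plds[-1], matrix(dm[-1], 4, 1), 1)
  expect_false(isTRUE(all.equal(weighted_delay(s4), wd_oracle)))
})

test_that("transit-time inversion recovers the forward map and clamps out of range", {
  plds <- c(100, 100, 1275, 1800, 2100)
  kp <- kinetic_params(tau = 1800)
  kp_f <- kinetic_params(tau = 1800, f = 50, att = 1200)
  dm <- buxton_signal(kp$tau + plds, kp_f)
  wd <- sum(plds * dm) / sum(dm)
  att <- att_from_wd(wd, plds, kp)
  expect_equal(as.vector(att), 1200, tolerance = 10)
  # WD is constant for att below the shortest PLD (all delays post-bolus),
  # so the invertible window starts at min(PLD); smaller WDs clamp there
  low <- att_from_wd(100, plds, kp)
  expect_equal(as.vector(low), min(plds))
  expect_true(attr(low, "clamped")[1])
  expect_true(is.na(att_from_wd(NA_real_, plds, kp)[1]))
})

test_that("multi-delay CBF fit is linear in the signal and flags unsupported voxels", {
  plds <- c(100, 100, 1275, 1800, 2100)
  kp <- kinetic_params(tau = 1800)
  truth <- kinetic_params(tau = 1800, f = 45, att = 900)
  dm <- buxton_signal(kp$tau + plds, truth)
  s1 <- multidelay_series(plds, matrix(dm, 5, 1), 1)
  f1 <- cbf_from_multidelay(s1, 900, kp)
  expect_equal(as.vector(f1), 45, tolerance = 1e-10)
  s3 <- multidelay_series(plds, matrix(3 * dm, 5, 1), 1)
  expect_equal(as.vector(cbf_from_multidelay(s3, 900, kp)), 3 * 45,
               tolerance = 1e-10)
  # transit time beyond every readout: no model support
  late <- cbf_from_multidelay(s1, 1800 + 2100 + 10, kp)
  expect_true(is.na(as.vector(late)))
})

test_that("gaussian smoothing preserves constants, mass, and the requested width", {
  vol <- array(5, c(11, 11, 11))
  expect_equal(gaussian_smooth3d(vol, 3, c(1, 1, 1)), vol, tolerance = 1e-12)
  # interior mass preservation on a delta
  delta <- array(0, c(21, 21, 21)); delta[11, 11, 11] <- 1
  sm <- gaussian_smooth3d(delta, 3, c(1, 1, 1))
  expect_equal(sum(sm), 1, tolerance = 1e-3)
  # FWHM along x close to 3 mm on a 1-mm grid
  prof <- sm[, 11, 11] / max(sm[, 11, 11])
  above <- which(prof >= 0.5)
  fwhm <- max(above) - min(above)   # integer-voxel estimate
  expect_lte(abs(fwhm - 3), 1)
  # NA voxels stay NA and do not contaminate neighbours catastrophically
  vol_na <- array(1, c(9, 9, 9)); vol_na[5, 5, 5] <- NA
  smna <- gaussian_smooth3d(vol_na, 3, c(1, 1, 1))
  expect_true(is.na(smna[5, 5, 5]))
  expect_equal(smna[1, 1, 1], 1, tolerance = 1e-6)
})
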
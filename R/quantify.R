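# CBF and ATT quantification. Single-delay CBF uses the standard
# single-compartment pCASL model; multi-delay uses a signal-weighted-delay
# ATT estimate followed by a linear least-squares kinetic-model fit of CBF.
# Times are in ms throughout; CBF in mL/100 g/min.

#' Single-delay CBF from a perfusion-weighted difference
#'
#' Standard single-compartment pCASL quantification:
#' `f = 6000 * lambda * dM * exp(PLD/T1b) /
#'      (2 * alpha * T1b_sec * M0 * (1 - exp(-tau/T1b)))`
#' with T1b in seconds in the denominator and ms inside the exponentials.
#'
#' @param dM Perfusion-weighted difference (same arbitrary units as `m0`);
#'   scalar, vector or array.
#' @param m0 Equilibrium magnetization, same shape as `dM`.
#' @param kp A [kinetic_params()].
#' @param pld Post-labeling delay (ms).
#' @return CBF in mL/100 g/min, shaped like `dM`; `NA` where `m0` is not a
#'   positive finite number.
#' @examples
#' kp <- kinetic_params()
#' dm <- buxton_signal(kp$tau + 1800, kinetic_params(f = 60, att = 0))
#' cbf_single_delay(dm, 1, kp, pld = 1800)   # recovers 60
#' @export
cbf_single_delay <- function(dM, m0, kp = kinetic_params(), pld) {
  stopifnot(inherits(kp, "kinetic_params"))
  t1b <- kp$t1_blood
  bad <- !is.finite(m0) | m0 <= 0
  denom <- 2 * kp$alpha * (t1b / 1000) * m0 * (1 - exp(-kp$tau / t1b))
  f <- 6000 * kp$lambda_bp * dM * exp(pld / t1b) / denom
  f[bad] <- NA_real_
  f
}

#' Kinetic-model perfusion signal
#'
#' The general kinetic model for pCASL with a plug-flow bolus of labeled
#' blood and decay at the T1 of blood (no outflow, no dispersion). Returns
#' the fractional difference signal dM/M0 at time `t` from labeling onset:
#' zero before the bolus arrives (`t < att`), inflow during
#' `att <= t < att + tau`, and T1 decay of the full bolus afterwards.
#'
#' @param t Time(s) since the start of labeling (ms), vectorized.
#' @param kp A [kinetic_params()] with `f` (mL/100 g/min) and `att` (ms)
#'   set. `f` and `att` may be arrays conformable with `t`.
#' @return dM/M0 as a fraction of equilibrium magnetization.
#' @export
buxton_signal <- function(t, kp) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (is.null(kp$f) || is.null(kp$att))
    stop("kinetic_params must carry f and att for forward simulation")
  t1b <- kp$t1_blood
  K <- 2 * kp$alpha * (kp$f / 6000) * (t1b / 1000) *
    exp(-kp$att / t1b) / kp$lambda_bp
  dt <- t - kp$att
  inflow <- K * (1 - exp(-dt / t1b))
  decay <- K * (1 - exp(-kp$tau / t1b)) * exp(-(dt - kp$tau) / t1b)
  out <- ifelse(dt < 0, 0, ifelse(dt < kp$tau, inflow, decay))
  out
}

#' Multi-delay difference series
#'
#' Container pairing per-PLD mean difference volumes with the M0 volume.
#'
#' @param plds Numeric vector of PLDs (ms), ascending (duplicates allowed).
#' @param dM 4-D array (x, y, z, pld) of mean ΔM per PLD, or a matrix
#'   (n_pld x n_voxel).
#' @param m0 3-D array (or vector) of M0 magnitudes matching `dM`'s voxels.
#' @return An object of class `multidelay_series`.
#' @export
multidelay_series <- function(plds, dM, m0) {
  plds <- as.numeric(plds)
  if (is.unsorted(plds)) stop("plds must be ascending (duplicates allowed)")
  if (is.matrix(dM)) {
    if (nrow(dM) != length(plds)) stop("dM rows must match length(plds)")
  } else if (is.array(dM) && length(dim(dM)) == 4L) {
    if (dim(dM)[4] != length(plds))
      stop("fourth dM dimension must match length(plds)")
  } else stop("dM must be a (pld x voxel) matrix or a 4-D array")
  structure(list(plds = plds, dM = dM, m0 = m0),
            class = "multidelay_series")
}

# dM as (n_pld x n_voxel) matrix regardless of input layout
dm_matrix <- function(series) {
  if (is.matrix(series$dM)) return(series$dM)
  d <- dim(series$dM)
  t(matrix(series$dM, prod(d[1:3]), d[4]))
}

#' Signal-weighted delay
#'
#' The signal-weighted mean of the PLDs, `WD = sum(PLD_i * dM_i) /
#' sum(dM_i)`, computed per voxel over all acquisitions (duplicate PLDs
#' enter as separate terms). WD increases monotonically with the arterial
#' transit time over the usable range and is inverted to ATT by
#' [att_from_wd()]. Voxels whose summed difference signal is not positive
#' are invalid (`NA`).
#'
#' @param series A [multidelay_series()].
#' @param include_plds Optional logical or index vector selecting which
#'   acquisitions enter the weighting (default: all, including the short
#'   PLDs).
#' @return Numeric vector (or 3-D array, matching the input layout) of WD
#'   in ms.
#' @export
weighted_delay <- function(series, include_plds = NULL) {
  stopifnot(inherits(series, "multidelay_series"))
  dm <- dm_matrix(series)
  plds <- series$plds
  if (!is.null(include_plds)) {
    dm <- dm[include_plds, , drop = FALSE]
    plds <- plds[include_plds]
  }
  if (length(unique(plds)) < 2)
    stop("weighted delay needs at least two distinct PLDs")
  tot <- colSums(dm)
  wd <- colSums(dm * plds) / tot
  wd[!is.finite(wd) | tot <= 0] <- NA_real_
  reshape_like(wd, series$dM)
}

reshape_like <- function(v, dM) {
  if (is.matrix(dM)) v else array(v, dim(dM)[1:3])
}

# theoretical WD(att) lookup over an att grid for a given protocol;
# restricted to its largest monotone increasing window
wd_att_table <- function(plds, kp, att_grid = seq(0, 3000, by = 10)) {
  wd <- vapply(att_grid, function(a) {
    kp2 <- kp; kp2$f <- 1; kp2$att <- a
    s <- buxton_signal(kp$tau + plds, kp2)
    tot <- sum(s)
    if (tot <= 0) NA_real_ else sum(plds * s) / tot
  }, numeric(1))
  ok <- which(is.finite(wd))
  att <- att_grid[ok]; wd <- wd[ok]
  d <- diff(wd)
  if (any(d <= 1e-9)) {
    # largest strictly increasing run (1e-9 ms guards against numerical
    # jitter on the exactly-flat unidentifiable prefix)
    runs <- rle(d > 1e-9)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    inc <- which(runs$values)
    if (!length(inc)) stop("WD(att) map has no increasing segment")
    best <- inc[which.max(runs$lengths[inc])]
    idx <- starts[best]:(ends[best] + 1)
    # a flat prefix (att below the shortest PLD is unidentifiable) is
    # expected; only a genuinely decreasing segment merits a warning
    if (any(d < -1e-9))
      warning("WD(att) map not monotone; restricting to largest monotone window")
    att <- att[idx]; wd <- wd[idx]
  }
  list(att = att, wd = wd)
}

#' Invert a signal-weighted delay to an arterial transit time
#'
#' Builds the theoretical map att -> WD(att) by evaluating the kinetic
#' model at the protocol's PLDs over an ATT grid (0-3000 ms, 10 ms step by
#' default), checks monotonicity (restricting to the largest monotone
#' window with a warning otherwise), and inverts by linear interpolation.
#' WD values outside the map's range clamp to the grid ends.
#'
#' @param wd Weighted delay(s) in ms (vector or array; `NA` passes through).
#' @param plds Protocol PLDs (ms).
#' @param kp A [kinetic_params()].
#' @param att_grid ATT grid for the theoretical map (ms).
#' @return ATT in ms, shaped like `wd`, with attribute `clamped` (logical,
#'   same shape) marking values outside the invertible range.
#' @export
att_from_wd <- function(wd, plds, kp = kinetic_params(),
                        att_grid = seq(0, 3000, by = 10)) {
  tab <- wd_att_table(plds, kp, att_grid)
  shape <- dim(wd)
  wdv <- as.vector(wd)
  att <- stats::approx(tab$wd, tab$att, xout = wdv, rule = 2)$y
  att[!is.finite(wdv)] <- NA_real_
  clamped <- is.finite(wdv) & (wdv < min(tab$wd) | wdv > max(tab$wd))
  if (!is.null(shape)) { dim(att) <- shape; dim(clamped) <- shape }
  attr(att, "clamped") <- clamped
  att
}

#' Kinetic-model CBF from multi-delay data
#'
#' With ATT fixed, the kinetic-model difference signal is linear in CBF, so
#' the least-squares estimate is a ratio of inner products:
#' `f = sum(dM_i * m_i) / sum(m_i^2)` where `m_i` is the model prediction
#' at PLD_i for unit CBF (f = 1 mL/100 g/min) scaled by the voxel's M0.
#'
#' @param series A [multidelay_series()].
#' @param att ATT per voxel (ms), e.g. from [att_from_wd()].
#' @param kp A [kinetic_params()].
#' @return CBF in mL/100 g/min, shaped like the input layout; `NA` where
#'   the model predicts no signal at any PLD (ATT beyond every readout) or
#'   ATT/M0 is invalid.
#' @export
cbf_from_multidelay <- function(series, att, kp = kinetic_params()) {
  stopifnot(inherits(series, "multidelay_series"))
  dm <- dm_matrix(series)
  m0 <- as.vector(series$m0)
  attv <- as.vector(att)
  t <- kp$tau + series$plds
  # model matrix: rows plds, cols voxels, unit-CBF prediction times M0
  kp1 <- kp; kp1$f <- 1
  pred <- vapply(t, function(tt) {
    kp1$att <- attv
    as.vector(buxton_signal(tt, kp1) * m0)
  }, numeric(length(attv)))
  pred <- matrix(pred, nrow = length(attv))
  pred <- t(pred)                       # n_pld x n_voxel
  num <- colSums(dm * pred)
  den <- colSums(pred^2)
  f <- num / den
  f[!is.finite(f) | den <= 0 | !is.finite(attv)] <- NA_real_
  reshape_like(f, series$dM)
}

# banded convolution matrix for one axis: kernel k (odd length), nearest-
# edge replication
conv_band_matrix <- function(n, k) {
  h <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax(i + (-h:h), 1L), n)   # replicate edges
    for (j in seq_along(idx)) K[i, idx[j]] <- K[i, idx[j]] + k[j]
  }
  K
}

gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma_vox))
  x <- -h:h
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Separable 3-D Gaussian smoothing in physical units
#'
#' Smooths a volume with a Gaussian of the given full width at half
#' maximum in millimetres (`sigma = fwhm / (2 sqrt(2 ln 2))` per axis,
#' converted to voxels via the voxel size). Edges are handled by nearest
#' replication, so a constant image is unchanged and interior mass is
#' preserved. `NA` voxels are treated as zero with mask renormalization.
#'
#' @param vol 3-D numeric array.
#' @param fwhm_mm Full width at half maximum (mm); scalar.
#' @param voxel_size Numeric length-3 voxel size in mm.
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth3d <- function(vol, fwhm_mm = 3, voxel_size = c(3.4, 3.4, 4)) {
  stopifnot(length(dim(vol)) == 3L, length(voxel_size) == 3L)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  nav <- is.na(vol)
  any_na <- any(nav)
  if (any_na) { w <- array(1, dim(vol)); w[nav] <- 0; vol[nav] <- 0 }
  smooth_axis <- function(a, axis) {
    n <- dim(a)[axis]
    k <- gauss_kernel(sigma_mm / voxel_size[axis])
    if (length(k) == 1L) return(a)
    K <- conv_band_matrix(n, k)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(a, perm), n)
    out <- K %*% m
    aperm(array(out, dim(a)[perm]), order(perm))
  }
  for (ax in 1:3) {
    vol <- smooth_axis(vol, ax)
    if (any_na) w <- smooth_axis(w, ax)
  }
  if (any_na) {
    vol <- vol / ifelse(w > 1e-8, w, NA_real_)
    vol[nav] <- NA_real_
  }
  vol
}
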
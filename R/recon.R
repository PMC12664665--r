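# Projection-based complex control/label subtraction. With aggressive
# background suppression the static magnetization can be negative at
# excitation; magnitude images lose the sign and corrupt the control-minus-
# label difference. Projecting the complex voxel values onto the M0 phasor
# recovers signed scalars and hence the correct difference.

# mask of valid voxels: |M0| above a fraction of its robust maximum
m0_valid_mask <- function(m0_data, mask_threshold = 0.10) {
  mag <- Mod(m0_data)
  robust_max <- stats::quantile(mag, 0.99, names = FALSE)
  mag > mask_threshold * robust_max
}

#' Project complex volumes onto the M0 direction
#'
#' Per voxel, the signed scalar projection of a complex signal S onto the
#' unit phasor of the M0 signal: `s = Re(S * Conj(M0)) / |M0|`. The sign is
#' negative when S is anti-parallel to M0; the component orthogonal to M0
#' (noise in quadrature) is rejected. Voxels where |M0| falls below
#' `mask_threshold` times its robust (99th percentile) maximum are marked
#' invalid (`NA`) rather than amplified.
#'
#' @param series A [complex_series()] (control or label, 3-D or 4-D).
#' @param m0 A [complex_series()] with role `"m0"` and matching spatial
#'   shape.
#' @param mask_threshold Fraction of the robust |M0| maximum below which a
#'   voxel is invalid.
#' @return A numeric array of the same shape as `series$data` with signed
#'   projections; invalid voxels are `NA`. Attribute `mask` carries the
#'   validity mask.
#' @examples
#' m0 <- complex_series(array(100 + 0i, c(2, 2, 2)), role = "m0")
#' s  <- complex_series(array(-5 + 0i, c(2, 2, 2)), role = "control")
#' asl_project_m0(s, m0)[1, 1, 1]   # -5: anti-parallel signal keeps its sign
#' @export
asl_project_m0 <- function(series, m0, mask_threshold = 0.10) {
  stopifnot(inherits(series, "complex_series"), inherits(m0, "complex_series"))
  if (!identical(spatial_dim(series), spatial_dim(m0)))
    stop(sprintf("spatial shape mismatch: series %s vs m0 %s",
                 paste(spatial_dim(series), collapse = "x"),
                 paste(spatial_dim(m0), collapse = "x")))
  m0d <- m0$data
  if (length(dim(m0d)) == 4L) m0d <- array(m0d, dim(m0d)[1:3])
  mask <- m0_valid_mask(m0d, mask_threshold)
  mag <- Mod(m0d)
  unit <- m0d / ifelse(mag > 0, mag, 1)
  nrep <- n_reps(series)
  proj <- Re(series$data * Conj(as.vector(unit)))  # recycles over reps
  proj <- array(proj, dim(series$data))
  proj[rep(!mask, length.out = length(proj))] <- NA_real_
  attr(proj, "mask") <- mask
  proj
}

#' Magnitude subtraction of control and label series
#'
#' The conventional pathway: per voxel and repetition, `|control| -
#' |label|`. Correct only when both magnetizations are non-negative along
#' the M0 direction; kept for the regular BS scheme and for comparison.
#'
#' @param control,label [complex_series()] objects of equal shape.
#' @return Numeric array of per-repetition magnitude differences.
#' @export
asl_magnitude_subtract <- function(control, label) {
  stopifnot(inherits(control, "complex_series"),
            inherits(label, "complex_series"))
  if (!identical(dim(control$data), dim(label$data)))
    stop(sprintf("shape mismatch: control %s vs label %s",
                 paste(dim(control$data), collapse = "x"),
                 paste(dim(label$data), collapse = "x")))
  Mod(control$data) - Mod(label$data)
}

#' Per-pair control-minus-label difference
#'
#' Computes the perfusion-weighted difference ΔM for each control/label
#' pair, selecting the reconstruction pathway by BS scheme: the regular
#' scheme (all-positive magnetization) uses magnitude images, while the
#' enhanced and CSF schemes (mixed magnetization signs) use the
#' projection-based complex pathway and therefore require an M0 volume.
#'
#' @param control,label [complex_series()] with equal repetition counts.
#' @param m0 A [complex_series()] M0 volume (required for
#'   `scheme != "regular"`, used for masking otherwise if supplied).
#' @param scheme `"regular"`, `"enhanced"` or `"csf"`.
#' @param method Override the pathway: `"projection"`, `"magnitude"` or
#'   `"complexdiff"` (|control − label|, positively biased, for
#'   comparison).
#' @return A list with `per_pair` (4-D array of per-pair ΔM) and `mean`
#'   (3-D mean ΔM across pairs).
#' @export
asl_pairwise_diff <- function(control, label, m0 = NULL,
                              scheme = c("csf", "enhanced", "regular"),
                              method = NULL) {
  scheme <- match.arg(scheme)
  if (n_reps(control) != n_reps(label))
    stop("control and label must have equal repetition counts")
  if (is.null(method))
    method <- if (scheme == "regular") "magnitude" else "projection"
  method <- match.arg(method, c("projection", "magnitude", "complexdiff"))
  d <- switch(method,
    projection = {
      if (is.null(m0)) stop("projection pathway requires an M0 volume")
      asl_project_m0(control, m0) - asl_project_m0(label, m0)
    },
    magnitude = asl_magnitude_subtract(control, label),
    complexdiff = Mod(control$data - label$data))
  if (length(dim(d)) == 3L) d <- array(d, c(dim(d), 1L))
  dm_mean <- apply(d, 1:3, mean)
  list(per_pair = d, mean = dm_mean)
}
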
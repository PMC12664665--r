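#' Tissue longitudinal relaxation constants
#'
#' Bundle of per-compartment T1 values used throughout the background
#' suppression (BS) simulations. Defaults are standard 3-T literature values
#' for gray matter, white matter, CSF and arterial blood.
#'
#' @param t1_gm,t1_wm,t1_csf,t1_blood T1 in milliseconds; all strictly
#'   positive.
#' @return An object of class `tissue_relaxation` (named list of T1 values).
#' @examples
#' t1s <- tissue_relaxation()
#' t1s$t1_csf
#' @export
tissue_relaxation <- function(t1_gm = 1209, t1_wm = 758,
                              t1_csf = 4308, t1_blood = 1664) {
  vals <- c(t1_gm = t1_gm, t1_wm = t1_wm, t1_csf = t1_csf, t1_blood = t1_blood)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all T1 values must be finite and strictly positive")
  structure(as.list(vals), class = "tissue_relaxation")
}

#' BS sequence timing
#'
#' Timing skeleton of a pCASL acquisition with two background-suppression
#' inversion pulses. All times are in milliseconds and are measured from the
#' pre-saturation pulse at t = 0. The readout (excitation) occurs at
#' `label_duration + pld`.
#'
#' @param label_duration Labeling duration tau (ms).
#' @param pld Post-labeling delay (ms).
#' @param inversion_times Increasing numeric vector of inversion times (ms)
#'   in (0, readout). Typically length 2.
#' @param constrained Logical; if `TRUE`, additionally require every
#'   inversion pulse to fall inside the PLD (TI >= label_duration), the
#'   placement rule of vendor-style "constrained" BS.
#' @return An object of class `bs_timing`.
#' @examples
#' bs_timing(1800, 2200, c(1806, 3550))           # CSF-targeted scheme
#' bs_timing(1800, 2200, c(2336, 3585), constrained = TRUE)
#' @export
bs_timing <- function(label_duration, pld, inversion_times,
                      constrained = FALSE) {
  if (!is.numeric(label_duration) || label_duration <= 0)
    stop("label_duration must be positive")
  if (!is.numeric(pld) || pld < 0) stop("pld must be non-negative")
  readout <- label_duration + pld
  ti <- as.numeric(inversion_times)
  if (length(ti) && (is.unsorted(ti, strictly = TRUE) ||
                     any(ti <= 0) || any(ti >= readout)))
    stop("inversion_times must be strictly increasing within (0, readout)")
  if (constrained && length(ti) && any(ti < label_duration))
    stop("constrained placement requires every TI >= label_duration")
  structure(list(label_duration = label_duration, pld = pld,
                 inversion_times = ti, readout_time = readout,
                 constrained = constrained),
            class = "bs_timing")
}

#' @export
print.bs_timing <- function(x, ...) {
  cat(sprintf("BS timing: tau = %g ms, PLD = %g ms, readout at %g ms\n",
              x$label_duration, x$pld, x$readout_time))
  cat(sprintf("  inversions at: %s ms%s\n",
              paste(x$inversion_times, collapse = ", "),
              if (x$constrained) " (constrained to PLD)" else ""))
  invisible(x)
}

#' Pulse efficiencies
#'
#' Inversion and saturation pulse efficiencies used by the magnetization
#' simulator. The default inversion efficiency 0.9304 is the value obtained
#' by [bs_calibrate_efficiency()] against the published residual-signal
#' table of the three reference BS schemes (see [asl_reference_schemes()]).
#' Saturation is assumed ideal (Mz = 0 immediately after pre-saturation).
#'
#' @param inversion Inversion efficiency beta in (0, 1]; an inversion maps
#'   Mz to -beta * Mz.
#' @param saturation Saturation efficiency in (0, 1]; pre-saturation leaves
#'   Mz = 1 - saturation.
#' @return An object of class `pulse_efficiency`.
#' @export
pulse_efficiency <- function(inversion = 0.9304, saturation = 1.0) {
  if (!is.numeric(inversion) || inversion <= 0 || inversion > 1)
    stop("inversion efficiency must be in (0, 1]")
  if (!is.numeric(saturation) || saturation <= 0 || saturation > 1)
    stop("saturation efficiency must be in (0, 1]")
  structure(list(inversion = inversion, saturation = saturation),
            class = "pulse_efficiency")
}

#' Kinetic-model parameters
#'
#' Parameters of the single-compartment pCASL kinetic model used for CBF
#' quantification. The default effective labeling efficiency multiplies the
#' pCASL labeling efficiency 0.85 by the square of the BS inversion
#' efficiency (two inversion pulses): 0.85 * 0.9304^2.
#'
#' @param lambda_bp Blood-brain partition coefficient (mL/g).
#' @param alpha Effective labeling efficiency (fraction, <= 1).
#' @param t1_blood T1 of arterial blood (ms).
#' @param tau Labeling duration (ms).
#' @param f Optional cerebral blood flow (mL/100 g/min), for forward
#'   simulation with [buxton_signal()].
#' @param att Optional arterial transit time (ms), likewise.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(lambda_bp = 0.9, alpha = 0.85 * 0.9304^2,
                           t1_blood = 1664, tau = 1800,
                           f = NULL, att = NULL) {
  if (lambda_bp <= 0) stop("lambda_bp must be positive")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (t1_blood <= 0) stop("t1_blood must be positive")
  if (tau <= 0) stop("tau must be positive")
  if (!is.null(f) && any(f < 0)) stop("f must be non-negative")
  if (!is.null(att) && any(att < 0)) stop("att must be non-negative")
  structure(list(lambda_bp = lambda_bp, alpha = alpha, t1_blood = t1_blood,
                 tau = tau, f = f, att = att),
            class = "kinetic_params")
}

#' Complex-valued volume series
#'
#' Container for repetition-indexed complex image volumes (control or label
#' series) or a single complex M0 volume. Axis order is (x, y, z[, rep])
#' with z the partition/slice-encoding direction.
#'
#' @param data Complex array, 3-D (single volume) or 4-D (x, y, z, rep).
#' @param voxel_size Numeric length-3 voxel size in mm.
#' @param role One of `"control"`, `"label"`, `"m0"`.
#' @return An object of class `complex_series`.
#' @export
complex_series <- function(data, voxel_size = c(3.4, 3.4, 4),
                           role = c("control", "label", "m0")) {
  role <- match.arg(role)
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("data must be a 3-D or 4-D array")
  if (!is.complex(data)) storage.mode(data) <- "complex"
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("voxel_size must be three positive values (mm)")
  if (role == "m0" && length(dim(data)) == 4L && dim(data)[4] != 1L)
    stop("an M0 series must contain a single volume")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 role = role),
            class = "complex_series")
}

# spatial dims of a series
spatial_dim <- function(x) dim(x$data)[1:3]

n_reps <- function(x) if (length(dim(x$data)) == 4L) dim(x$data)[4] else 1L
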
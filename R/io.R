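# NIfTI and configuration I/O. Complex volumes are stored as paired
# real/imaginary NIfTI files (suffixes _real / _imag): complex NIfTI
# dtypes are inconsistently supported across toolchains.

nifti_paths <- function(prefix) {
  c(real = paste0(prefix, "_real.nii.gz"),
    imag = paste0(prefix, "_imag.nii.gz"))
}

#' Write a complex volume series as paired real/imaginary NIfTI files
#'
#' @param series A [complex_series()] (or a plain complex array).
#' @param prefix Output path prefix; `<prefix>_real.nii.gz` and
#'   `<prefix>_imag.nii.gz` are written.
#' @param voxel_size Voxel size in mm (taken from the series if given one).
#' @return Invisibly, the two file paths.
#' @export
write_complex_nifti <- function(series, prefix, voxel_size = c(3.4, 3.4, 4)) {
  if (inherits(series, "complex_series")) {
    voxel_size <- series$voxel_size
    data <- series$data
  } else data <- series
  p <- nifti_paths(prefix)
  pd <- c(voxel_size, rep(1, max(0, length(dim(data)) - 3L)))
  for (part in c("real", "imag")) {
    img <- RNifti::asNifti(if (part == "real") Re(data) else Im(data))
    RNifti::pixdim(img) <- pd
    RNifti::writeNifti(img, p[part])
  }
  invisible(p)
}

#' Read a complex volume series from paired real/imaginary NIfTI files
#'
#' @param prefix Path prefix used by [write_complex_nifti()].
#' @param role Series role for the returned [complex_series()].
#' @return A [complex_series()].
#' @export
read_complex_nifti <- function(prefix, role = "control") {
  p <- nifti_paths(prefix)
  if (!file.exists(p["real"]))
    stop("missing file: ", p["real"])
  if (!file.exists(p["imag"]))
    stop("missing companion file ", p["imag"],
         "; for magnitude-only data read the single volume with ",
         "RNifti::readNifti and use the magnitude pathway")
  re <- RNifti::readNifti(p["real"])
  im <- RNifti::readNifti(p["imag"])
  if (!identical(dim(re), dim(im)))
    stop(sprintf("shape mismatch between %s (%s) and %s (%s)",
                 p["real"], paste(dim(re), collapse = "x"),
                 p["imag"], paste(dim(im), collapse = "x")))
  vx <- RNifti::pixdim(re)[1:3]
  data <- array(complex(real = as.vector(re), imaginary = as.vector(im)),
                dim(re))
  complex_series(data, voxel_size = vx, role = role)
}

#' Check control/label/M0 series compatibility
#'
#' Validates equal spatial shapes and matching repetition counts, naming
#' the offending pair on failure.
#'
#' @param control,label,m0 [complex_series()] objects.
#' @return Invisibly `TRUE`.
#' @export
check_series_compat <- function(control, label, m0 = NULL) {
  fmt <- function(x) paste(dim(x$data), collapse = "x")
  if (!identical(spatial_dim(control), spatial_dim(label)))
    stop(sprintf("control (%s) and label (%s) spatial shapes differ",
                 fmt(control), fmt(label)))
  if (n_reps(control) != n_reps(label))
    stop(sprintf("control (%d reps) and label (%d reps) counts differ",
                 n_reps(control), n_reps(label)))
  if (!is.null(m0) && !identical(spatial_dim(control), spatial_dim(m0)))
    stop(sprintf("control (%s) and m0 (%s) spatial shapes differ",
                 fmt(control), fmt(m0)))
  invisible(TRUE)
}

#' Read a run configuration (JSON or YAML)
#'
#' Keys carry explicit unit suffixes (`tau_ms`, `pld_ms`, `fwhm_mm`, ...):
#' every time in the configuration is milliseconds and every length
#' millimetres. Validation happens before any computation.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  required <- c("scheme", "tau_ms", "plds_ms")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config missing required field(s): ", paste(missing, collapse = ", "))
  if (!cfg$scheme %in% c("regular", "enhanced", "csf"))
    stop("scheme must be regular, enhanced or csf")
  if (cfg$tau_ms <= 0) stop("tau_ms must be positive")
  if (!length(cfg$plds_ms) || any(cfg$plds_ms < 0))
    stop("plds_ms must be non-negative")
  defaults <- list(n_pairs = 8L, seed = 1L, grid = c(64, 64, 36),
                   voxel_mm = c(3.4, 3.4, 4), fwhm_mm = 3,
                   pulsation_amplitude = 0.2, noise_sd = 0.001,
                   out_dir = NULL, verbosity = 1L)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = "run_config")
}
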
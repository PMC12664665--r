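# Digital brain phantom for ASL background-suppression experiments: a
# compartmental head (WM core, GM shell, ventricles, outer CSF rim, an
# inferior CSF blob standing in for the basal cisterns) that emits complex
# control/label/M0 volumes with scheme-dependent static residual signals,
# kinetic-model perfusion signal, pulsatile CSF with z-encoding ghosting,
# a smooth receive phase, and complex thermal noise.

#' Phantom specification
#'
#' Geometry and signal parameters of the digital phantom. Geometry is
#' expressed as fractions of the grid so the same spec scales to smaller
#' desk-test grids. Compartment codes in the mask volume: 0 background,
#' 1 gray matter, 2 white matter, 3 CSF.
#'
#' @param grid Integer length-3 grid size (nx, ny, nz).
#' @param voxel_size Voxel size in mm.
#' @param m0 Named per-tissue equilibrium magnetization (a.u.).
#' @param f Named per-tissue CBF (mL/100 g/min).
#' @param att Named per-tissue arterial transit time (ms).
#' @param cbf_heterogeneity Fractional amplitude of the smooth
#'   within-tissue modulation of the true CBF map (regional perfusion
#'   variation; 0 gives piecewise-constant truth).
#' @param att_heterogeneity Fractional amplitude of the corresponding ATT
#'   modulation.
#' @param pulsation_amplitude Fractional amplitude A of the CSF signal
#'   pulsation (multiplicative, per acquired volume).
#' @param phase_jitter_sd SD (rad) of the per-volume global phase jitter.
#' @param noise_sd SD (a.u.) of the complex Gaussian thermal noise added
#'   independently to real and imaginary channels.
#' @param seed Integer seed for the acquisition simulation.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(64, 64, 36),
                         voxel_size = c(3.4, 3.4, 4),
                         m0 = c(gm = 1.0, wm = 0.7, csf = 1.2),
                         f = c(gm = 60, wm = 20, csf = 0),
                         att = c(gm = 1200, wm = 1600, csf = 0),
                         cbf_heterogeneity = 0.3,
                         att_heterogeneity = 0.1,
                         pulsation_amplitude = 0.2,
                         phase_jitter_sd = 0.05,
                         noise_sd = 0.001,
                         seed = 1L) {
  if (length(grid) != 3 || any(grid < 8))
    stop("grid must be three dimensions of at least 8 voxels")
  if (any(m0 < 0) || any(f < 0) || any(att < 0) ||
      pulsation_amplitude < 0 || noise_sd < 0 || phase_jitter_sd < 0)
    stop("all phantom amplitudes must be non-negative")
  if (cbf_heterogeneity < 0 || cbf_heterogeneity >= 1 ||
      att_heterogeneity < 0 || att_heterogeneity >= 1)
    stop("heterogeneity fractions must be in [0, 1)")
  structure(list(grid = as.integer(grid), voxel_size = as.numeric(voxel_size),
                 m0 = m0, f = f, att = att,
                 cbf_heterogeneity = cbf_heterogeneity,
                 att_heterogeneity = att_heterogeneity,
                 pulsation_amplitude = pulsation_amplitude,
                 phase_jitter_sd = phase_jitter_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# normalized squared ellipsoid radius over the grid
ellipsoid <- function(grid, center_frac, semi_frac) {
  cx <- center_frac * grid
  ax <- semi_frac * grid
  x <- (seq_len(grid[1]) - cx[1]) / ax[1]
  y <- (seq_len(grid[2]) - cx[2]) / ax[2]
  z <- (seq_len(grid[3]) - cx[3]) / ax[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  r2 <= 1
}

#' Build the phantom compartments and parameter maps
#'
#' Deterministic given the spec: a WM core ellipsoid inside a GM shell,
#' two ventricle ellipsoids and an outer CSF rim, plus an inferior
#' "brainstem-adjacent" CSF blob where pulsation artifacts concentrate.
#'
#' @param spec A [phantom_spec()].
#' @param ventricles Logical; include the ventricle ellipsoids.
#' @return A list with `masks` (integer array: 0 bg, 1 GM, 2 WM, 3 CSF),
#'   `m0`, `f`, `att` (parameter volumes), `phase` (smooth receive-phase
#'   field, rad), `brain` (logical brain mask) and the `spec`.
#' @export
make_phantom <- function(spec = phantom_spec(), ventricles = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  ctr <- c(0.5, 0.5, 0.5)
  brain    <- ellipsoid(g, ctr, c(0.44, 0.44, 0.44))
  gm_outer <- ellipsoid(g, ctr, c(0.415, 0.415, 0.415))
  wm_core  <- ellipsoid(g, ctr, c(0.24, 0.26, 0.28))
  vent <- array(FALSE, g)
  if (ventricles) {
    vent <- ellipsoid(g, c(0.41, 0.5, 0.56), c(0.05, 0.14, 0.11)) |
            ellipsoid(g, c(0.59, 0.5, 0.56), c(0.05, 0.14, 0.11))
  }
  blob <- ellipsoid(g, c(0.5, 0.40, 0.16), c(0.10, 0.10, 0.10)) & brain
  masks <- array(0L, g)
  masks[brain] <- 1L                       # GM shell by default
  masks[wm_core] <- 2L
  masks[brain & !gm_outer] <- 3L           # outer CSF rim
  masks[vent] <- 3L
  masks[blob] <- 3L
  csf_frac <- mean(masks[brain] == 3L)
  if (csf_frac < 0.05 || csf_frac > 0.25)
    stop(sprintf("degenerate geometry: CSF fraction %.1f%% outside 5-25%%",
                 100 * csf_frac))
  lut <- function(vals) {
    v <- array(0, g)
    v[masks == 1L] <- vals["gm"]
    v[masks == 2L] <- vals["wm"]
    v[masks == 3L] <- vals["csf"]
    v
  }
  # smooth deterministic receive phase (rad)
  x <- seq_len(g[1]) / g[1]; y <- seq_len(g[2]) / g[2]; z <- seq_len(g[3]) / g[3]
  phase <- outer(outer(0.4 * sin(pi * x), 0.3 * cos(pi * y), `+`),
                 0.2 * z, `+`)
  # smooth within-tissue perfusion heterogeneity in [-1, 1]: real CBF and
  # ATT vary regionally, which gives the maps a rank structure that
  # split-half correlation can measure
  het <- outer(outer(sin(2 * pi * x), cos(2 * pi * y), `*`),
               rep(1, g[3]), `*`) * 0.6 +
         outer(outer(cos(3 * pi * x), rep(1, g[2]), `*`),
               sin(2 * pi * z), `*`) * 0.4
  fmap <- lut(spec$f) * (1 + spec$cbf_heterogeneity * het)
  attmap <- lut(spec$att) * (1 + spec$att_heterogeneity * het)
  list(masks = masks, m0 = lut(spec$m0), f = fmap,
       att = attmap, phase = phase, brain = brain, spec = spec)
}

#' Acquisition specification
#'
#' @param plds Numeric vector of post-labeling delays (ms).
#' @param tau Labeling duration (ms).
#' @param n_pairs Control/label pairs acquired per PLD.
#' @param shot_mode `"single_shot"` or `"segmented"`.
#' @param segments Number of z-segments (segmented mode).
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(plds, tau = 1800, n_pairs = 1,
                             shot_mode = c("single_shot", "segmented"),
                             segments = 1L) {
  shot_mode <- match.arg(shot_mode)
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (shot_mode == "segmented" && segments < 2)
    stop("segmented mode needs >= 2 segments")
  structure(list(plds = as.numeric(plds), tau = tau,
                 n_pairs = as.integer(n_pairs), shot_mode = shot_mode,
                 segments = as.integer(segments)),
            class = "acquisition_spec")
}

#' Named acquisition presets
#'
#' Protocol presets mirroring the evaluation protocols: a single-delay
#' single-shot scan (tau 1800 ms, PLD 2200 ms, 20 pairs), its segmented
#' counterpart (12 pairs, 4 z-segments), and the five-delay protocol
#' (PLDs 100, 100, 1275, 1800, 2100 ms, 8 pairs per delay).
#'
#' @param name Optional preset name; with no argument, returns the list of
#'   all presets.
#' @return An [acquisition_spec()] (or a named list of them).
#' @export
protocol_presets <- function(name = NULL) {
  presets <- list(
    study1_singleshot = acquisition_spec(2200, tau = 1800, n_pairs = 20,
                                         shot_mode = "single_shot"),
    study1_segmented = acquisition_spec(2200, tau = 1800, n_pairs = 12,
                                        shot_mode = "segmented",
                                        segments = 4L),
    study2_multidelay = acquisition_spec(c(100, 100, 1275, 1800, 2100),
                                         tau = 1800, n_pairs = 8,
                                         shot_mode = "segmented",
                                         segments = 4L)
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown preset: ", name, " (available: ",
         paste(names(presets), collapse = ", "), ")")
  presets[[name]]
}

#' Scheme timings for an acquisition
#'
#' Returns one [bs_timing()] per PLD of the acquisition for the requested
#' BS scheme: the published two-inversion timings for the reference
#' protocol (tau 1800 ms, PLD 2200 ms), and independently optimized
#' timings from [bs_schedule()] for any other PLD.
#'
#' @param scheme `"regular"`, `"enhanced"` or `"csf"`.
#' @param acq An [acquisition_spec()].
#' @param step Optimizer grid step (ms) for non-reference PLDs.
#' @param ... Passed to [bs_schedule()].
#' @return A list of `bs_timing` objects, one per PLD.
#' @export
scheme_timings_for <- function(scheme, acq, step = 10, ...) {
  stopifnot(inherits(acq, "acquisition_spec"))
  ref <- asl_reference_schemes()
  ref <- ref[!duplicated(ref$scheme), ]
  lapply(acq$plds, function(p) {
    if (acq$tau == 1800 && p == 2200) {
      r <- ref[ref$scheme == scheme, ]
      bs_timing(acq$tau, p, c(r$ti_bs1, r$ti_bs2),
                constrained = scheme == "regular")
    } else {
      sol <- bs_optimize_timings(scheme, acq$tau, p, step = step, ...)
      if (any(is.na(sol$inversion_times)))
        stop("no feasible timing grid for PLD ", p)
      sol$timing
    }
  })
}

# FFT-based z-encoding smear: modulate kz lines by a within-shot linear
# amplitude ramp so CSF fluctuation ghosts into neighboring slices
smear_z <- function(vol, ramp_amp, drift, shot_mode, segments) {
  g <- dim(vol)
  nz <- g[3]
  m <- matrix(aperm(vol, c(3, 1, 2)), nz)
  k <- stats::mvfft(m)
  w <- rep(1, nz)
  if (shot_mode == "single_shot") {
    pos <- (seq_len(nz) - 1) / max(1, nz - 1) - 0.5
    w <- 1 + ramp_amp * drift[1] * pos
  } else {
    seg_of <- ((seq_len(nz) - 1) %% segments) + 1   # interleaved lines
    for (s in seq_len(segments)) {
      lines <- which(seg_of == s)
      pos <- (seq_along(lines) - 1) / max(1, length(lines) - 1) - 0.5
      w[lines] <- 1 + ramp_amp * drift[s] * pos
    }
  }
  k <- k * w
  out <- stats::mvfft(k, inverse = TRUE) / nz
  aperm(array(out, c(nz, g[1], g[2])), c(2, 3, 1))
}

#' Simulate a complex ASL acquisition on the phantom
#'
#' For every PLD and control/label pair, builds the complex volumes:
#' static tissue at the scheme's residual magnetization, CSF static signal
#' modulated by `(1 + A * eta(x))` where `eta` is an independent random
#' field per acquired volume with a smooth bulk component (constant plus
#' linear spatial gradients) and a voxel-scale incoherent component
#' (flow-dispersion-like), at approximately unit marginal variance, a
#' within-shot linear amplitude
#' drift of amplitude A/2 across the echo train applied to the CSF
#' contribution in kz-space (ghosting the fluctuation along z), the
#' kinetic-model perfusion signal added to the control volume, a smooth
#' receive phase with per-volume jitter, and complex Gaussian noise. The
#' M0 volume is generated noiselessly with the same phase field.
#'
#' @param phantom Output of [make_phantom()].
#' @param acq An [acquisition_spec()].
#' @param timings A single [bs_timing()] or a list of them, one per PLD
#'   (e.g. from [scheme_timings_for()]).
#' @param eff A [pulse_efficiency()].
#' @param t1s A [tissue_relaxation()].
#' @param kp A [kinetic_params()]; its `tau` is overridden by the
#'   acquisition's.
#' @param seed Integer seed; defaults to the phantom spec's seed.
#' @return A list with `plds`, `control` and `label` (lists of 4-D
#'   [complex_series()], one per PLD), `m0` (complex M0 series),
#'   `truth` (list `cbf`, `att`), `masks`, `brain`, `residuals` (per-PLD
#'   per-tissue residual fractions), `acq`, `timings`.
#' @export
simulate_acquisition <- function(phantom, acq, timings,
                                 eff = pulse_efficiency(),
                                 t1s = tissue_relaxation(),
                                 kp = kinetic_params(),
                                 seed = phantom$spec$seed) {
  stopifnot(inherits(acq, "acquisition_spec"))
  if (inherits(timings, "bs_timing")) timings <- list(timings)
  if (length(timings) == 1L) timings <- rep(timings, length(acq$plds))
  if (length(timings) != length(acq$plds))
    stop("need one timing per PLD")
  spec <- phantom$spec
  g <- spec$grid
  kp$tau <- acq$tau
  A <- spec$pulsation_amplitude

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  csf_mask <- phantom$masks == 3L
  phase <- phantom$phase
  ndrift <- if (acq$shot_mode == "single_shot") 1L else acq$segments
  # normalized centered coordinates in [-1, 1] for the spatial pulsation
  # field: distinct CSF spaces pulse with different amplitude and phase,
  # so the per-volume fluctuation is a smooth field, not a global scalar
  coord <- function(n) 2 * (seq_len(n) - (n + 1) / 2) / n
  X <- array(rep(coord(g[1]), times = g[2] * g[3]), g)
  Y <- array(rep(rep(coord(g[2]), each = g[1]), times = g[3]), g)
  Z <- array(rep(coord(g[3]), each = g[1] * g[2]), g)

  control <- label <- vector("list", length(acq$plds))
  residuals <- vector("list", length(acq$plds))
  for (i in seq_along(acq$plds)) {
    tim <- timings[[i]]
    res <- c(gm  = bs_residual_mz(tim, t1s$t1_gm, eff),
             wm  = bs_residual_mz(tim, t1s$t1_wm, eff),
             csf = bs_residual_mz(tim, t1s$t1_csf, eff))
    residuals[[i]] <- res
    static_tissue <- array(0, g)
    static_tissue[phantom$masks == 1L] <- spec$m0["gm"] * res["gm"]
    static_tissue[phantom$masks == 2L] <- spec$m0["wm"] * res["wm"]
    static_csf <- array(0, g)
    static_csf[csf_mask] <- spec$m0["csf"] * res["csf"]
    kp_vox <- kp; kp_vox$f <- phantom$f; kp_vox$att <- phantom$att
    dM <- phantom$m0 * buxton_signal(acq$tau + acq$plds[i], kp_vox)

    one_volume <- function(add_perfusion) {
      # pulsation field: smooth bulk component (constant + gradients)
      # plus voxel-scale incoherent flow dispersion; ~unit marginal
      # variance so A keeps its meaning
      ec <- stats::rnorm(4)
      eta <- (ec[1] + ec[2] * X + ec[3] * Y + ec[4] * Z) / 2 +
        array(stats::rnorm(prod(g)), g) / sqrt(2)
      drift <- stats::rnorm(ndrift)
      jitter <- stats::rnorm(1, 0, spec$phase_jitter_sd)
      csf_part <- smear_z(static_csf * (1 + A * eta), A / 2, drift,
                          acq$shot_mode, acq$segments)
      vol <- static_tissue + csf_part
      if (add_perfusion) vol <- vol + dM
      vol <- vol * exp(1i * (phase + jitter))
      if (spec$noise_sd > 0)
        vol <- vol + complex(real = stats::rnorm(length(vol), 0, spec$noise_sd),
                             imaginary = stats::rnorm(length(vol), 0, spec$noise_sd))
      vol
    }
    ctl <- array(0i, c(g, acq$n_pairs))
    lbl <- array(0i, c(g, acq$n_pairs))
    for (r in seq_len(acq$n_pairs)) {
      ctl[, , , r] <- one_volume(TRUE)
      lbl[, , , r] <- one_volume(FALSE)
    }
    control[[i]] <- complex_series(ctl, spec$voxel_size, "control")
    label[[i]]   <- complex_series(lbl, spec$voxel_size, "label")
  }
  m0vol <- phantom$m0 * exp(1i * phase)
  list(plds = acq$plds,
       control = control, label = label,
       m0 = complex_series(m0vol, spec$voxel_size, "m0"),
       truth = list(cbf = phantom$f, att = phantom$att),
       masks = phantom$masks, brain = phantom$brain,
       residuals = residuals, acq = acq, timings = timings)
}
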
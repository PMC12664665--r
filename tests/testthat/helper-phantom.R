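# Shared fixtures: small deterministic phantoms built in code.

small_spec <- function(..., grid = c(32, 32, 20), seed = 1L) {
  phantom_spec(grid = grid, seed = seed, ...)
}

noiseless_spec <- function(..., grid = c(32, 32, 20), seed = 1L) {
  phantom_spec(grid = grid, seed = seed, pulsation_amplitude = 0,
               noise_sd = 0, phase_jitter_sd = 0, ...)
}

# independent event-stepping Mz oracle: exact relaxation applied in many
# small steps, inversions applied at their TIs; no closed-form shortcuts
stepwise_residual <- function(ti, t1, beta, readout, sat = 1, dt = 0.01) {
  events <- sort(ti)
  mz <- 1 - sat
  t <- 0
  for (ev in c(events, readout)) {
    nfull <- floor((ev - t) / dt)
    decay <- exp(-dt / t1)
    for (i in seq_len(nfull)) mz <- 1 - (1 - mz) * decay
    rem <- (ev - t) - nfull * dt
    mz <- 1 - (1 - mz) * exp(-rem / t1)
    t <- ev
    if (ev < readout) mz <- -beta * mz
  }
  mz
}

ref_timing <- function(scheme) {
  r <- asl_reference_schemes()
  r <- r[r$scheme == scheme, ][1, ]
  bs_timing(r$label_duration, r$pld, c(r$ti_bs1, r$ti_bs2),
            constrained = scheme == "regular")
}
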
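# aslbs

Background-suppression (BS) design and perfusion quantification for
arterial spin labeling (ASL) MRI, with a focus on schemes that null the
**CSF** signal rather than gray/white matter.

## Why

ASL measures cerebral blood flow (CBF) from the tiny (<1% of M0)
difference between control and label images, so fluctuations of the static
background dominate its noise budget. BS inversion pulses are timed so that
static longitudinal magnetization crosses zero at the readout. Conventional
schemes null gray and white matter — but CSF pulsates with the cardiac
cycle, and its large residual under tissue-focused BS produces bright/dark
artifacts in CBF maps that 3D readouts smear along the slice direction. A
CSF-targeted scheme suppresses that noise source at the cost of a few
percent of residual tissue signal, which complex (projection-based)
reconstruction handles correctly regardless of magnetization sign.

The package provides:

* `bs_residual_mz()`, `bs_mz_trajectory()` — closed-form longitudinal
  magnetization through pre-saturation / inversion pulse trains:
  `Mz' = 1 − (1 − Mz)·exp(−Δt/T1)` between events, `Mz → −β·Mz` at each
  inversion;
* `bs_calibrate_efficiency()` — recover the inversion efficiency β from a
  table of observed residual signals (β ≈ 0.9304 for the reference
  schemes);
* `bs_optimize_timings()`, `bs_grid_residuals()`, `bs_schedule()` —
  exhaustive two-pulse timing search for regular / enhanced / CSF design
  goals under constrained (PLD-only) or unconstrained placement;
* `asl_project_m0()`, `asl_pairwise_diff()` — signed control−label
  differences by projecting complex voxel values onto the M0 phasor,
  `s = Re(S·conj(M0))/|M0|`;
* `cbf_single_delay()`, `buxton_signal()`, `weighted_delay()`,
  `att_from_wd()`, `cbf_from_multidelay()` — single-compartment CBF and
  signal-weighted-delay arterial-transit-time (ATT) quantification;
* `voxel_se()`, `voxel_cov()`, `split_half_rs()`, `cov_histogram()` —
  voxelwise reproducibility metrics;
* `make_phantom()`, `simulate_acquisition()`, `protocol_presets()`,
  `run_pipeline()` — a digital brain phantom with pulsatile CSF,
  z-encoding ghosting, complex noise, and an end-to-end pipeline.

A thin command-line interface ships at `inst/cli/aslbs.R` with subcommands
`design`, `simulate-mz`, `phantom`, `recon`, `quantify`, `metrics`, `run`.

## Worked example

```r
library(aslbs)

## calibrate the inversion efficiency against the published residual table
beta <- bs_calibrate_efficiency(asl_reference_schemes())
eff  <- pulse_efficiency(beta)

## residual signals (percent of M0) for the CSF-targeted scheme
tim <- bs_timing(1800, 2200, c(1806, 3550))
round(100 * c(gm  = bs_residual_mz(tim, 1209, eff),
              wm  = bs_residual_mz(tim,  758, eff),
              csf = bs_residual_mz(tim, 4308, eff)), 1)
#>   gm   wm  csf
#> -7.0  2.9 -0.2

## design a CSF-suppressing timing from scratch
bs_optimize_timings("csf", tau = 1800, pld = 2200, step = 10)
#> csf BS solution: TI = (1823.0, 3536.2) ms
#>   residuals: GM -5.03%  WM 5.03%  CSF 0.81%
```

The first block reproduces the published residual pattern of the
CSF-targeted scheme: CSF suppressed to −0.2% of equilibrium while gray and
white matter retain ≈7% and ≈3% with opposite signs — which is why the
projection-based complex subtraction, not magnitude subtraction, must be
used. The second block shows the optimizer finding its own feasible timing:
CSF held below 1% with both tissues near ±5%.

An end-to-end phantom experiment (simulate → reconstruct → quantify →
metrics, deterministic given the seed):

```r
summary <- run_pipeline(list(scheme = "csf", tau_ms = 1800, plds_ms = 2200,
                             n_pairs = 20, seed = 1))
summary$mean_cov_pct    # mean voxelwise CoV of per-pair CBF maps (GM∪WM)
summary$split_half_rs   # split-half spatial Spearman correlation
```

Under the default pulsatile phantom, the CSF-targeted scheme yields a mean
CoV near 11% and Rs near 0.90, versus CoV of 13–33% and Rs of 0.45–0.61
for the tissue-focused schemes — the ordering the method predicts.

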
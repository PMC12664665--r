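# Exhaustive search over two-inversion BS timings. The search domain is
# tiny (at most a few million TI pairs at 1-ms resolution) and the
# objectives are non-smooth, so a vectorized grid with deterministic local
# refinement is both exact enough and reproducible.

# residuals (percent) for all three tissues at vectors of TI pairs
grid_resid_pct <- function(ti1, ti2, t1s, eff, readout) {
  list(
    gm  = 100 * residual_mz_vec(ti1, ti2, t1s$t1_gm,  eff$inversion,
                                eff$saturation, readout),
    wm  = 100 * residual_mz_vec(ti1, ti2, t1s$t1_wm,  eff$inversion,
                                eff$saturation, readout),
    csf = 100 * residual_mz_vec(ti1, ti2, t1s$t1_csf, eff$inversion,
                                eff$saturation, readout)
  )
}

# candidate TI grid respecting placement rules and guard gaps
ti_grid_bounds <- function(tau, pld, placement, guard) {
  readout <- tau + pld
  lo <- if (placement == "constrained") tau else guard
  hi <- readout - guard
  c(lo = lo, hi = hi, readout = readout)
}

#' Exhaustive residual-signal table over a grid of inversion timings
#'
#' Evaluates the residual GM/WM/CSF signals for every pair TI1 < TI2 on a
#' regular grid, under constrained (pulses restricted to the PLD) or
#' unconstrained (pulses allowed during labeling) placement. A minimum
#' guard gap separates TI1 from TI2 and TI2 from the readout.
#'
#' @param tau Labeling duration (ms).
#' @param pld Post-labeling delay (ms).
#' @param placement `"constrained"` or `"unconstrained"`.
#' @param t1s A [tissue_relaxation()].
#' @param eff A [pulse_efficiency()].
#' @param step Grid step in ms (>= 1 recommended).
#' @param guard Minimum gap (ms) between TI1 and TI2 and between TI2 and
#'   the readout.
#' @return A data frame with columns `ti_bs1`, `ti_bs2`, `gm`, `wm`, `csf`
#'   (residuals in percent). Zero rows, with attribute
#'   `infeasibility = "empty grid"`, when no TI pair fits the placement
#'   rules (e.g. a constrained scheme with a very short PLD).
#' @examples
#' g <- bs_grid_residuals(1800, 100, "constrained", step = 5)
#' min(abs(g$gm))   # short-PLD constrained BS cannot suppress tissue
#' @export
bs_grid_residuals <- function(tau, pld,
                              placement = c("unconstrained", "constrained"),
                              t1s = tissue_relaxation(),
                              eff = pulse_efficiency(),
                              step = 1, guard = 5) {
  placement <- match.arg(placement)
  if (step < 1) stop("step must be >= 1 ms")
  b <- ti_grid_bounds(tau, pld, placement, guard)
  empty <- data.frame(ti_bs1 = numeric(0), ti_bs2 = numeric(0),
                      gm = numeric(0), wm = numeric(0), csf = numeric(0))
  if (b["lo"] > b["hi"] - guard) {
    attr(empty, "infeasibility") <- "empty grid"
    return(empty)
  }
  tis <- seq(b["lo"], b["hi"], by = step)
  n <- length(tis)
  k <- ceiling(guard / step - 1e-9)      # index offset enforcing the TI gap
  counts <- pmax(0L, n - seq_len(n) - k + 1L)
  if (sum(counts) == 0) {
    attr(empty, "infeasibility") <- "empty grid"
    return(empty)
  }
  ti1 <- rep(tis, counts)
  ti2 <- tis[sequence(counts, from = seq_len(n) + k)]
  r <- grid_resid_pct(ti1, ti2, t1s, eff, b["readout"])
  data.frame(ti_bs1 = ti1, ti_bs2 = ti2, gm = r$gm, wm = r$wm, csf = r$csf)
}

# scheme objective: returns list(feasible, penalty, objective) vectors
scheme_objective <- function(scheme, gm, wm, csf, target = 5, bound = 1) {
  switch(scheme,
    regular = {
      obj <- pmax(abs(gm - target), abs(wm - target))
      feas <- gm >= 0 & wm >= 0 & csf >= 0 & obj <= target
      pen <- pmax(0, -pmin(gm, wm, csf)) + pmax(0, obj - target)
      list(feasible = feas, penalty = pen, objective = obj)
    },
    enhanced = {
      feas <- abs(gm) < bound & abs(wm) < bound
      pen <- pmax(0, abs(gm) - bound) + pmax(0, abs(wm) - bound)
      list(feasible = feas, penalty = pen, objective = abs(gm) + abs(wm))
    },
    csf = {
      feas <- abs(csf) < bound
      pen <- pmax(0, abs(csf) - bound)
      list(feasible = feas, penalty = pen,
           objective = pmax(abs(gm), abs(wm)))
    },
    stop("unknown scheme: ", scheme))
}

# pick the best row index: feasible with min objective, tie-break earliest
# TI1 then TI2; if none feasible, min penalty then min objective, same ties
best_row <- function(grid, sc) {
  key_order <- function(idx, primary) {
    o <- order(primary[idx], grid$ti_bs1[idx], grid$ti_bs2[idx])
    idx[o][1]
  }
  feas_idx <- which(sc$feasible)
  if (length(feas_idx)) {
    list(i = key_order(feas_idx, sc$objective), feasible = TRUE)
  } else {
    list(i = key_order(seq_len(nrow(grid)),
                       sc$penalty + 1e-9 * sc$objective), feasible = FALSE)
  }
}

#' Optimize two-inversion BS timings for a suppression scheme
#'
#' Searches TI1 < TI2 for one of the three BS design goals:
#' \describe{
#'   \item{regular}{Constrained placement; keep all residuals non-negative
#'     and bring GM and WM as close to +5\% of equilibrium as possible
#'     (minimax deviation). Feasible when GM and WM lie in \[0, 10\]\% with
#'     no negative residual.}
#'   \item{enhanced}{Suppress tissue: require |GM| < 1\% and |WM| < 1\%;
#'     among feasible timings minimize |GM| + |WM|.}
#'   \item{csf}{Suppress CSF: require |CSF| < 1\%; among feasible timings
#'     minimize max(|GM|, |WM|).}
#' }
#' The search is an exhaustive grid at `step` ms followed by deterministic
#' local grid refinement around the incumbent (final resolution
#' `step / 100`). Ties are broken toward the earliest TI1, then TI2. When
#' no timing satisfies the scheme's constraints, the least-violating timing
#' is returned flagged infeasible.
#'
#' @param scheme `"regular"`, `"enhanced"` or `"csf"`.
#' @param tau,pld Labeling duration and post-labeling delay (ms).
#' @param t1s A [tissue_relaxation()].
#' @param eff A [pulse_efficiency()].
#' @param placement Override pulse placement; defaults to constrained for
#'   the regular scheme and unconstrained otherwise.
#' @param step Initial grid step (ms).
#' @param guard Guard gap (ms), as in [bs_grid_residuals()].
#' @param refine Logical; run local grid refinement after the coarse pass.
#' @return An object of class `timing_solution`: list with
#'   `inversion_times`, `residuals` (named percent vector gm/wm/csf),
#'   `feasible`, `objective`, `scheme`, `timing` (a [bs_timing()]).
#' @examples
#' sol <- bs_optimize_timings("csf", 1800, 2200, step = 10)
#' sol$residuals
#' @export
bs_optimize_timings <- function(scheme = c("regular", "enhanced", "csf"),
                                tau, pld,
                                t1s = tissue_relaxation(),
                                eff = pulse_efficiency(),
                                placement = NULL, step = 1, guard = 5,
                                refine = TRUE) {
  scheme <- match.arg(scheme)
  if (is.null(placement))
    placement <- if (scheme == "regular") "constrained" else "unconstrained"
  if (scheme == "regular" && placement != "constrained")
    stop("the regular scheme uses constrained placement")
  grid <- bs_grid_residuals(tau, pld, placement, t1s, eff, step, guard)
  if (nrow(grid) == 0) {
    return(structure(list(inversion_times = c(NA_real_, NA_real_),
                          residuals = c(gm = NA_real_, wm = NA_real_,
                                        csf = NA_real_),
                          feasible = FALSE, objective = Inf,
                          scheme = scheme, timing = NULL),
                     class = "timing_solution"))
  }
  sc <- scheme_objective(scheme, grid$gm, grid$wm, grid$csf)
  pick <- best_row(grid, sc)
  ti <- c(grid$ti_bs1[pick$i], grid$ti_bs2[pick$i])

  if (refine) {
    b <- ti_grid_bounds(tau, pld, placement, guard)
    s <- step
    while (s > step / 100) {
      s <- s / 10
      t1g <- seq(max(b["lo"], ti[1] - 10 * s),
                 min(b["hi"], ti[1] + 10 * s), by = s)
      t2g <- seq(max(b["lo"], ti[2] - 10 * s),
                 min(b["hi"], ti[2] + 10 * s), by = s)
      cand <- expand.grid(ti_bs1 = t1g, ti_bs2 = t2g)
      cand <- cand[cand$ti_bs2 - cand$ti_bs1 >= guard &
                   cand$ti_bs2 <= b["hi"], , drop = FALSE]
      if (!nrow(cand)) break
      r <- grid_resid_pct(cand$ti_bs1, cand$ti_bs2, t1s, eff, b["readout"])
      cand$gm <- r$gm; cand$wm <- r$wm; cand$csf <- r$csf
      scc <- scheme_objective(scheme, cand$gm, cand$wm, cand$csf)
      pk <- best_row(cand, scc)
      # keep refinement only if it does not lose feasibility
      if (pk$feasible || !pick$feasible) {
        ti <- c(cand$ti_bs1[pk$i], cand$ti_bs2[pk$i])
        pick <- pk; grid <- cand; sc <- scc
      }
    }
  }

  timing <- bs_timing(tau, pld, ti, constrained = placement == "constrained")
  res <- c(gm  = 100 * bs_residual_mz(timing, t1s$t1_gm, eff),
           wm  = 100 * bs_residual_mz(timing, t1s$t1_wm, eff),
           csf = 100 * bs_residual_mz(timing, t1s$t1_csf, eff))
  obj <- scheme_objective(scheme, res["gm"], res["wm"], res["csf"])
  structure(list(inversion_times = ti, residuals = res,
                 feasible = unname(obj$feasible),
                 objective = unname(obj$objective),
                 scheme = scheme, timing = timing),
            class = "timing_solution")
}

#' @export
print.timing_solution <- function(x, ...) {
  cat(sprintf("%s BS solution%s: TI = (%.1f, %.1f) ms\n", x$scheme,
              if (x$feasible) "" else " [INFEASIBLE]",
              x$inversion_times[1], x$inversion_times[2]))
  cat(sprintf("  residuals: GM %.2f%%  WM %.2f%%  CSF %.2f%%\n",
              x$residuals["gm"], x$residuals["wm"], x$residuals["csf"]))
  invisible(x)
}

#' Per-PLD optimized timing schedule
#'
#' Optimizes the inversion timings independently for each PLD of a
#' multi-delay protocol. Duplicate PLDs share a single solution.
#'
#' @inheritParams bs_optimize_timings
#' @param plds Numeric vector of post-labeling delays (ms), non-empty.
#' @param ... Passed to [bs_optimize_timings()].
#' @return A list of `timing_solution` objects, one per element of `plds`
#'   (duplicates point to the same solution object).
#' @export
bs_schedule <- function(scheme, tau, plds, ...) {
  if (!length(plds)) stop("plds must be non-empty")
  uniq <- unique(plds)
  sols <- lapply(uniq, function(p) bs_optimize_timings(scheme, tau, p, ...))
  names(sols) <- as.character(uniq)
  out <- sols[as.character(plds)]
  names(out) <- as.character(plds)
  out
}
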
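# Simulation of the six-ODE model, regime classification, growth-factor
# scans and arrest-phase mapping.

#' Model right-hand side
#'
#' Time derivatives of the six state variables `(p21, Cd, E2Fa, Ce, Ca,
#' Cb)` under a given condition.  The p21 equation carries the nocodazole
#' switch (degradation scaled by `1/(1 + IEn * delta_noco)`) and the E2Fa
#' equation the palbociclib switch (`delta_palbo` multiplies the cyclin D
#' Michaelis term, so `delta_palbo = 0` removes CDK4/6-cyclin D action).
#'
#' @param state named or unnamed numeric 6-vector in the order
#'   `p21, Cd, E2Fa, Ce, Ca, Cb`.
#' @param params a [cc_params()] object.
#' @param condition a [cc_condition()] object.
#' @return numeric 6-vector of derivatives (a.u./h), named by state.
#' @examples
#' cc_rhs(rep(0, 6), cc_params(), cc_condition("untreated")) # fixed point
#' @export
cc_rhs <- function(state, params = cc_params(),
                   condition = cc_condition("untreated")) {
  stopifnot(length(state) == 6, inherits(condition, "cc_condition"))
  d <- .cc_rhs_cpp(as.numeric(state), .cc_core(params),
                   condition$delta_noco, condition$delta_palbo,
                   condition$gf_scale)
  setNames(d, .cc_state_names)
}

#' Simulate the cell-cycle model
#'
#' Adaptive Dormand-Prince 5(4) integration with exact landing on the
#' requested output times.  States that dip materially below zero (beyond
#' `-10 * atol`) abort the integration rather than being silently clipped.
#'
#' @param params a [cc_params()] object.
#' @param init numeric 6-vector of initial state `(p21, Cd, E2Fa, Ce, Ca,
#'   Cb)`.
#' @param condition a [cc_condition()] object.
#' @param times strictly increasing numeric vector of output times (h).
#' @param rtol,atol relative/absolute integration tolerances.
#' @param max_steps safety cap on internal steps.
#' @return a `cc_trajectory`: data.frame with columns `time, p21, Cd,
#'   E2Fa, Ce, Ca, Cb`; the condition is attached as attribute
#'   `condition`.
#' @examples
#' tr <- cc_simulate(cc_params(), c(0.2, 0.3, 0.5, 0.3, 0.3, 0.2),
#'                   times = seq(0, 48, by = 0.5))
#' range(tr$Cb)
#' @export
cc_simulate <- function(params = cc_params(),
                        init = c(0.2, 0.3, 0.5, 0.3, 0.3, 0.2),
                        condition = cc_condition("untreated"),
                        times = seq(0, 96, by = 0.1),
                        rtol = 1e-8, atol = 1e-10, max_steps = 5e6) {
  stopifnot(length(init) == 6)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(init < 0)) stop("initial state must be nonnegative")
  m <- .cc_integrate_cpp(as.numeric(init), .cc_core(params),
                         as.numeric(times), condition$delta_noco,
                         condition$delta_palbo, condition$gf_scale,
                         rtol, atol, max_steps)
  colnames(m) <- .cc_state_names
  out <- data.frame(time = times, m)
  attr(out, "condition") <- condition
  class(out) <- c("cc_trajectory", "data.frame")
  out
}

#' Observation model
#'
#' Maps a model state to the five measured outputs by adding per-marker
#' background offsets: `observable_k = state_k + offset_k` for
#' `k in (p21, Cd, Ce, Ca, Cb)`; E2Fa is unmeasured.
#'
#' @param state numeric 6-vector, or a matrix/data.frame with the six
#'   state columns.
#' @param params a [cc_params()] object (source of the offsets).
#' @return named 5-vector, or a matrix with one row per input row.
#' @export
cc_observable <- function(state, params = cc_params()) {
  off <- .cc_offsets(params)
  if (is.null(dim(state))) {
    stopifnot(length(state) == 6)
    s <- setNames(as.numeric(state), .cc_state_names)
    return(s[.cc_measured] + off)
  }
  m <- as.matrix(as.data.frame(state)[, .cc_measured, drop = FALSE])
  sweep(m, 2, off, "+")
}

# locate strict local maxima of a series; returns indices
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

#' Classify the dynamical regime of a trajectory
#'
#' A trajectory is `oscillating` when, over the trailing
#' `tail_fraction` of the simulation, cyclin B shows peak-to-peak
#' amplitude of at least `tol_amp` times its tail mean with successive
#' peak spacings agreeing within 5 percent; `arrested` when the maximum
#' absolute derivative at the final state falls below `tol_ss`; anything
#' else is `undetermined`.
#'
#' @param traj a `cc_trajectory` from [cc_simulate()].
#' @param params the parameters used for the simulation (needed to
#'   evaluate the right-hand side at the final state).
#' @param tail_fraction fraction of the trajectory used for peak
#'   detection (default 0.5).
#' @param tol_amp relative amplitude threshold (default 0.05 of tail
#'   mean cyclin B).
#' @param tol_amp_abs absolute amplitude floor (a.u.); decaying
#'   near-onset wobbles below it never count as oscillation.
#' @param tol_ss steady-state derivative tolerance (a.u./h).
#' @return a `cc_regime` list: `regime`, `period` (h, oscillating only),
#'   `amplitude` (per state, tail max minus min), `steady_state` (final
#'   state, arrested only).
#' @export
classify_regime <- function(traj, params = cc_params(),
                            tail_fraction = 0.5, tol_amp = 0.05,
                            tol_amp_abs = 0.02, tol_ss = 1e-6) {
  stopifnot(is.data.frame(traj), all(.cc_state_names %in% names(traj)))
  cond <- attr(traj, "condition")
  if (is.null(cond)) cond <- cc_condition("untreated")
  n <- nrow(traj)
  i0 <- max(1L, floor(n * (1 - tail_fraction)))
  tail_tr <- traj[i0:n, , drop = FALSE]
  amp <- vapply(.cc_state_names,
                function(v) diff(range(tail_tr[[v]])), 0.0)
  final <- unlist(traj[n, .cc_state_names])
  dmax <- max(abs(cc_rhs(final, params, cond)))

  cb <- tail_tr$Cb
  osc <- FALSE
  period <- NA_real_
  if (diff(range(cb)) >= max(tol_amp * mean(cb), tol_amp_abs)) {
    pk <- .local_maxima(cb)
    pk <- pk[cb[pk] > min(cb) + 0.5 * diff(range(cb))]
    if (length(pk) >= 3) {
      sp <- diff(tail_tr$time[pk])
      if (max(sp) - min(sp) <= 0.05 * mean(sp)) {
        osc <- TRUE
        period <- mean(sp)
      }
    }
  }
  regime <- if (osc) "oscillating"
            else if (dmax < tol_ss) "arrested"
            else "undetermined"
  structure(list(regime = regime, period = period, amplitude = amp,
                 steady_state = if (regime == "arrested") final else NULL,
                 max_drhs = dmax),
            class = "cc_regime")
}

#' @export
print.cc_regime <- function(x, ...) {
  cat("<cc_regime>", x$regime)
  if (!is.na(x$period)) cat(sprintf(" (period %.2f h)", x$period))
  cat("\n")
  invisible(x)
}

#' Growth-factor starvation scan
#'
#' Simulates the model at each growth-factor scale from every initial
#' condition and classifies the regime.  The oscillation-loss threshold
#' is the largest scanned `gf` at which no initial condition yields
#' sustained oscillation.
#'
#' @param params a [cc_params()] object.
#' @param inits matrix (or single vector) of initial states, one row per
#'   initial condition.
#' @param gf_grid descending growth-factor scales, starting at 1.
#' @param t_end simulation horizon (h); defaults to 30 nominal cycles
#'   (transients decay slowly near the oscillation-loss threshold).
#' @param dt output resolution (h).
#' @param ... passed to [cc_simulate()] (tolerances).
#' @return list with `table` (data.frame `gf`, `init`, `regime`,
#'   `period`) and `threshold` (numeric or `NA` when oscillation never
#'   disappears).
#' @export
gf_scan <- function(params = cc_params(),
                    inits = c(0.2, 0.3, 0.5, 0.3, 0.3, 0.2),
                    gf_grid = seq(1.0, 0.5, by = -0.05),
                    t_end = 720, dt = 0.25, ...) {
  if (is.null(dim(inits))) inits <- matrix(inits, nrow = 1)
  if (any(diff(gf_grid) >= 0)) stop("gf_grid must be strictly descending")
  rows <- list()
  times <- seq(0, t_end, by = dt)
  for (g in gf_grid) {
    for (j in seq_len(nrow(inits))) {
      cond <- cc_condition("untreated", gf_scale = g)
      tr <- cc_simulate(params, inits[j, ], cond, times, ...)
      rg <- classify_regime(tr, params)
      rows[[length(rows) + 1L]] <-
        data.frame(gf = g, init = j, regime = rg$regime,
                   period = ifelse(is.na(rg$period), NA_real_, rg$period))
    }
  }
  tab <- do.call(rbind, rows)
  no_osc <- tapply(tab$regime != "oscillating", tab$gf, all)
  lost <- as.numeric(names(no_osc))[no_osc]
  list(table = tab,
       threshold = if (length(lost)) max(lost) else NA_real_)
}

#' Map an arrested state to a cell-cycle phase
#'
#' Euclidean nearest neighbour of the five measured coordinates `(p21,
#' Cd, Ce, Ca, Cb)` over a reference covering one full period, following
#' the closest-data-vector convention.  E2Fa is excluded as unmeasured.
#' Ties resolve to the lowest index.
#'
#' @param final a model state (6-vector or named vector containing the
#'   measured coordinates).
#' @param reference either a `cc_trajectory` covering one period, a
#'   [make_limit_cycle()] object, or a matrix/data.frame with the five
#'   measured columns; row order defines pseudo-time order.
#' @param times optional per-row times (h); taken from the reference when
#'   present.
#' @param boundaries optional numeric vector of phase-boundary times used
#'   to attach a phase label (see [phase_boundaries()]); when `NULL` the
#'   label is the fractional phase.
#' @return list `index`, `time`, `phase` (fraction of period), `label`,
#'   `distance`.  Warns when the distance exceeds 3 times the reference's
#'   median inter-point spacing.
#' @export
arrest_phase <- function(final, reference, times = NULL,
                         boundaries = NULL) {
  if (inherits(reference, "cc_limit_cycle")) {
    ref <- reference$states[, .cc_measured, drop = FALSE]
    if (is.null(times)) times <- reference$phase * reference$period
  } else {
    rdf <- as.data.frame(reference)
    ref <- as.matrix(rdf[, intersect(.cc_measured, names(rdf)),
                         drop = FALSE])
    if (ncol(ref) != 5) stop("reference must contain the five measured columns")
    if (is.null(times)) {
      times <- if ("time" %in% names(rdf)) rdf$time
               else seq_len(nrow(ref)) - 1
    }
  }
  f <- final
  if (!is.null(names(f)) && all(.cc_measured %in% names(f))) {
    f <- as.numeric(f[.cc_measured])
  } else {
    stopifnot(length(f) == 6)
    f <- as.numeric(f)[match(.cc_measured, .cc_state_names)]
  }
  d2 <- colSums((t(ref) - f)^2)
  idx <- which.min(d2) # which.min takes the first (lowest index) on ties
  dmin <- sqrt(d2[idx])
  spacing <- sqrt(rowSums(diff(ref)^2))
  if (length(spacing) && dmin > 3 * median(spacing))
    warning("arrested state is far from the reference manifold ",
            sprintf("(distance %.3g > 3x median spacing %.3g)",
                    dmin, median(spacing)))
  per <- max(times) - min(times) + (times[2] - times[1])
  phase <- (times[idx] - min(times)) / per
  label <- if (!is.null(boundaries)) {
    .phase_label(times[idx], boundaries, per)
  } else sprintf("phase %.2f", phase)
  list(index = unname(idx), time = unname(times[idx]),
       phase = unname(phase), label = label, distance = unname(dmin))
}

# label a time given the M/G1 (zero by convention) and S/G2 boundary times
.phase_label <- function(t, boundaries, period) {
  b <- sort(boundaries %% period)
  t <- t %% period
  if (length(b) < 2) return(sprintf("phase %.2f", t / period))
  # zero-point convention: time 0 is the M/G1 transition; the second
  # boundary splits the cycle into G1+S and G2+M blocks
  sg2 <- max(b)
  if (t < sg2 / 2) "early G1"
  else if (t < sg2) "late G1/S"
  else "G2/M"
}
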
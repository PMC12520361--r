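# Extraction of the model's limit cycle as a phase-indexed lookup table.

#' Extract the limit cycle as a phase-state map
#'
#' Integrates the untreated model past a burn-in, estimates the period
#' from successive cyclin B maxima, and resamples one period onto a
#' uniform phase grid.  Phase 0 is anchored at a cyclin B peak (mitosis);
#' the map is periodic by construction.
#'
#' @param params a [cc_params()] object; must lie in the oscillatory
#'   regime.
#' @param burn_in burn-in horizon (h), at least two estimated periods
#'   (default 10 nominal cycles).
#' @param resolution number of uniform phase-grid points (default 200).
#' @param dt integration output resolution during peak detection (h).
#' @param ... tolerances passed to [cc_simulate()].
#' @return a `cc_limit_cycle`: list with `period` (h), `phase` (grid in
#'   `[0, 1)`), and `states` (resolution x 6 matrix, strictly positive).
#' @examples
#' \donttest{
#' lc <- make_limit_cycle(cc_params())
#' lc$period
#' }
#' @export
make_limit_cycle <- function(params = cc_params(), burn_in = 240,
                             resolution = 200, dt = 0.02, ...) {
  if (resolution < 10) stop("resolution must be at least 10")
  span <- burn_in + 120 # at least ~5 nominal cycles after burn-in
  times <- seq(0, span, by = dt)
  tr <- cc_simulate(params, condition = cc_condition("untreated"),
                    times = times, ...)
  post <- tr[tr$time >= burn_in, , drop = FALSE]
  cb <- post$Cb
  amp <- diff(range(cb))
  if (amp < 0.05 * max(mean(cb), .Machine$double.eps))
    stop("no oscillation detected: parameters are outside the ",
         "oscillatory regime (arrested or undetermined)")
  pk <- .local_maxima(cb)
  pk <- pk[cb[pk] > min(cb) + 0.5 * amp]
  if (length(pk) < 3)
    stop("no oscillation detected: fewer than three cyclin B peaks ",
         "after burn-in")
  sp <- diff(post$time[pk])
  if (max(sp) - min(sp) > 0.05 * mean(sp))
    stop("no stable oscillation: irregular peak spacing after burn-in")
  period <- mean(sp)
  if (burn_in < 2 * period)
    stop("burn_in must cover at least two periods (period ~ ",
         round(period, 2), " h)")

  # refine the peak landing by re-integrating one period from the
  # penultimate peak on a fine grid
  t0 <- post$time[pk[length(pk) - 1L]]
  init <- unlist(post[pk[length(pk) - 1L], .cc_state_names])
  phase <- seq(0, 1, length.out = resolution + 1)[seq_len(resolution)]
  fine <- cc_simulate(params, init, cc_condition("untreated"),
                      times = t0 + c(phase, 1) * period, ...)
  states <- as.matrix(fine[seq_len(resolution), .cc_state_names])
  gap <- max(abs(unlist(fine[resolution + 1L, .cc_state_names]) -
                 states[1L, ]))
  structure(list(period = period, phase = phase, states = states,
                 closure_gap = gap, params = params),
            class = "cc_limit_cycle")
}

#' @export
print.cc_limit_cycle <- function(x, ...) {
  cat(sprintf("<cc_limit_cycle> period %.3f h, %d phase points, closure gap %.2e\n",
              x$period, length(x$phase), x$closure_gap))
  invisible(x)
}

# linear interpolation of the limit-cycle state at arbitrary phases in [0,1)
.lc_state_at <- function(lc, phase) {
  ph <- phase %% 1
  grid <- c(lc$phase, 1)
  states <- rbind(lc$states, lc$states[1L, ])
  out <- matrix(NA_real_, length(ph), 6,
                dimnames = list(NULL, .cc_state_names))
  for (j in 1:6)
    out[, j] <- approx(grid, states[, j], xout = ph)$y
  out
}
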
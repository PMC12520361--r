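# Mixed oscillation/arrest training set, soft-constraint Gaussian
# likelihood, and multistart fitting in log-parameter space.

# parameters that are free during fitting (GF and E2Ft stay fixed at 1)
.cc_fit_names <- c(.cc_core_names[1:15],
                   paste0("offset_", .cc_measured),
                   "init_E2F_G1S", "init_E2F_G2M")

#' Default fitting bounds
#'
#' Log-uniform box used for multistart sampling and optimizer bounds:
#' `[1e-3, 1e3]` for kinetic parameters, `[1e-4, 10]` for offsets and
#' `[1e-4, 1]` for the E2Fa initial values.
#'
#' @return 2 x 22 matrix (`lower`, `upper`) with parameter columns.
#' @export
default_bounds <- function() {
  lo <- setNames(rep(1e-3, length(.cc_fit_names)), .cc_fit_names)
  hi <- setNames(rep(1e3, length(.cc_fit_names)), .cc_fit_names)
  off <- paste0("offset_", .cc_measured)
  lo[off] <- 1e-4; hi[off] <- 10
  lo[c("init_E2F_G1S", "init_E2F_G2M")] <- 1e-4
  hi[c("init_E2F_G1S", "init_E2F_G2M")] <- 1
  rbind(lower = lo, upper = hi)
}

#' Build the mixed training set from reconstructed trajectories
#'
#' Converts pseudo-time marker trajectories and arrest estimates into
#' the soft-constraint training table: the moving median is downsampled
#' to 10 equally spaced times per cycle and tiled over 4 cycles
#' (oscillation constraint); for each drug, 10 temporally equally spaced
#' copies of the trajectory value at the arrest time are placed between
#' the end of the first and the fourth cycle (steady-state constraint).
#' Each of the two initial conditions (the two main modes of the angle
#' distribution, expressed as cycle times) yields its own phase-shifted
#' copy of the untreated data.  Sigmas are `1.4826 * movMAD`, floored at
#' 5 percent of the marker range.
#'
#' @param traj `marker_trajectory` of the five measured markers on raw
#'   intensity scale (columns `p21, Cd, Ce, Ca, Cb`).
#' @param arrests named list of arrest times in hours (names are the
#'   drug conditions, e.g. `nocodazole`, `palbociclib`).
#' @param T cycle length (h).
#' @param modes numeric length-2: the two mode cycle times (h) used as
#'   initial conditions (G1/S-like first, G2/M-like second).
#' @param n_per_cycle untreated points per cycle (default 10).
#' @param n_cycles tiled cycles (default 4).
#' @param n_arrest arrest copies per drug (default 10).
#' @param sigma_floor_frac floor on sigma as a fraction of the marker
#'   range (default 0.05).
#' @return a `cc_training_set`: list with `points` (data.frame
#'   `condition, init_id, marker, time, value, sigma`),
#'   `initial_conditions` (2 x 5 measured values at the modes), `T`,
#'   `modes`.
#' @export
build_training_set <- function(traj, arrests, T = 24, modes,
                               n_per_cycle = 10, n_cycles = 4,
                               n_arrest = 10, sigma_floor_frac = 0.05) {
  stopifnot(inherits(traj, "marker_trajectory"))
  if (missing(modes) || length(modes) != 2 || any(!is.finite(modes)))
    stop("modes not found: supply the two mode cycle times")
  mk <- intersect(.cc_measured, colnames(traj$med))
  if (length(mk) != 5)
    stop("trajectory must contain the five measured markers")
  lookup <- function(m, t) { # periodic interpolation of med / mad
    g <- c(traj$grid, T)
    f <- function(v) approx(g, c(v, v[1]), xout = t %% T)$y
    list(med = f(traj$med[, m]), mad = f(traj$mad[, m]))
  }
  rng <- apply(traj$med[, mk, drop = FALSE], 2, function(v) diff(range(v)))
  sig <- function(m, mads) pmax(1.4826 * mads,
                                sigma_floor_frac * max(rng[m], 1e-12))
  t_un <- seq(0, n_cycles * T, length.out = n_per_cycle * n_cycles + 1)
  t_un <- t_un[-length(t_un)]
  rows <- list()
  for (k in 1:2) {
    for (m in mk) {
      lk <- lookup(m, modes[k] + t_un)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = "untreated", init_id = k, marker = m, time = t_un,
        value = lk$med, sigma = sig(m, lk$mad))
    }
  }
  t_ar <- seq(T, n_cycles * T, length.out = n_arrest)
  for (drug in names(arrests)) {
    at <- arrests[[drug]]
    for (k in 1:2) {
      for (m in mk) {
        lk <- lookup(m, at)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = drug, init_id = k, marker = m, time = t_ar,
          value = rep(lk$med, n_arrest),
          sigma = rep(sig(m, lk$mad), n_arrest))
      }
    }
  }
  pts <- do.call(rbind, rows)
  ic <- t(vapply(1:2, function(k)
    vapply(mk, function(m) lookup(m, modes[k])$med, 0.0), numeric(5)))
  colnames(ic) <- mk
  structure(list(points = pts, initial_conditions = ic, T = T,
                 modes = modes),
            class = "cc_training_set")
}

#' @export
print.cc_training_set <- function(x, ...) {
  cat(sprintf("<cc_training_set> %d rows (%s), T = %g h\n",
              nrow(x$points),
              paste(unique(x$points$condition), collapse = ", "), x$T))
  invisible(x)
}

#' Simulate a training set from known parameters
#'
#' Ground-truth generator for parameter-recovery studies: the model is
#' simulated from two on-cycle initial conditions, sampled at 10 points
#' per cycle over 4 cycles (untreated) and at 10 late times per drug
#' (where the treated system has converged), and Gaussian noise with the
#' stated sigma is added.  The true `init_E2F_*` values are set to the
#' limit-cycle E2Fa at the chosen mode phases.
#'
#' @param params true parameters ([cc_params()]).
#' @param lc optional precomputed [make_limit_cycle()] of `params`.
#' @param mode_phases two phases in `[0,1)` for the initial conditions.
#' @param T nominal cycle length used for the time grid (defaults to
#'   the limit-cycle period).
#' @param sigma_frac Gaussian noise SD as a fraction of each marker's
#'   untreated range.
#' @param drugs treated conditions to include (`character()` for an
#'   untreated-only design).
#' @param seed RNG seed for the noise.
#' @return list `ts` (a `cc_training_set`), `truth` (the parameters
#'   including the implied `init_E2F_*`), `lc`.
#' @export
simulate_training_set <- function(params, lc = NULL,
                                  mode_phases = c(0.55, 0.95), T = NULL,
                                  sigma_frac = 0.05,
                                  drugs = c("nocodazole", "palbociclib"),
                                  seed = 1L) {
  if (is.null(lc)) lc <- make_limit_cycle(params)
  if (is.null(T)) T <- lc$period
  states0 <- .lc_state_at(lc, mode_phases)
  truth <- params
  truth$init_E2F_G1S <- unname(states0[1, "E2Fa"])
  truth$init_E2F_G2M <- unname(states0[2, "E2Fa"])
  set.seed(seed)
  t_un <- seq(0, 4 * T, length.out = 41)[-41]
  t_ar <- seq(T, 4 * T, length.out = 10)
  off <- .cc_offsets(params)
  rows <- list()
  rngs <- NULL
  for (k in 1:2) {
    tr <- cc_simulate(params, states0[k, ], cc_condition("untreated"),
                      times = c(0, t_un)[!duplicated(c(0, t_un))],
                      rtol = 1e-8, atol = 1e-10)
    obs <- cc_observable(tr, params)
    if (is.null(rngs)) rngs <- apply(obs, 2, function(v) diff(range(v)))
    for (m in .cc_measured) {
      sg <- max(sigma_frac * rngs[m], 1e-12)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = "untreated", init_id = k, marker = m, time = t_un,
        value = obs[match(t_un, tr$time), m] + rnorm(length(t_un), 0, sg),
        sigma = sg)
    }
    for (drug in drugs) {
      trd <- cc_simulate(params, states0[k, ], cc_condition(drug),
                         times = c(0, t_ar), rtol = 1e-8, atol = 1e-10)
      obsd <- cc_observable(trd, params)
      for (m in .cc_measured) {
        sg <- max(sigma_frac * rngs[m], 1e-12)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = drug, init_id = k, marker = m, time = t_ar,
          value = obsd[-1, m] + rnorm(length(t_ar), 0, sg), sigma = sg)
      }
    }
  }
  ic <- sweep(states0[, .cc_measured], 2, off, "+")
  ts <- structure(list(points = do.call(rbind, rows),
                       initial_conditions = ic, T = T,
                       modes = mode_phases * T),
                  class = "cc_training_set")
  list(ts = ts, truth = truth, lc = lc)
}

# model state at t=0 for one training initial condition: measured
# values minus offsets (clipped at 0), E2Fa from the init parameter
.init_state <- function(params, ts, k) {
  meas <- ts$initial_conditions[k, .cc_measured]
  st <- pmax(meas - .cc_offsets(params), 0)
  c(p21 = unname(st["p21"]), Cd = unname(st["Cd"]),
    E2Fa = unname(if (k == 1) params$init_E2F_G1S else params$init_E2F_G2M),
    Ce = unname(st["Ce"]), Ca = unname(st["Ca"]),
    Cb = unname(st["Cb"]))
}

#' Soft-constraint Gaussian negative log-likelihood
#'
#' For every condition and initial condition in the training set the
#' model is simulated over the covered times and the full Gaussian
#' negative log-likelihood is accumulated:
#' `sum( ((observable - value) / sigma)^2 / 2 + log(sigma sqrt(2 pi)) )`.
#' The replicated oscillation and arrest rows act as soft constraints,
#' so the function stays finite whether or not the model oscillates or
#' converges.  Solver failures return a large ordered penalty
#' (`1e8` plus a distance-to-bounds term) instead of raising, so
#' optimizers can traverse bad regions.
#'
#' @param params a [cc_params()] object.
#' @param ts a `cc_training_set`.
#' @param rtol,atol integration tolerances (looser than simulation
#'   defaults; fitting dominates runtime).
#' @return scalar negative log-likelihood.
#' @export
cc_nll <- function(params, ts, rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(ts, "cc_training_set"))
  .nll_eval(params, .prep_ts(ts), ts, rtol, atol)
}

# precompute the block structure of a training set so repeated nll
# evaluations skip all table wrangling (fitting calls this thousands of
# times)
.prep_ts <- function(ts) {
  pts <- ts$points
  blocks <- list()
  for (cnd in unique(pts$condition)) {
    cond <- if (cnd == "untreated") cc_condition("untreated")
            else cc_condition(cnd)
    for (k in unique(pts$init_id[pts$condition == cnd])) {
      sub <- pts[pts$condition == cnd & pts$init_id == k, ,
                 drop = FALSE]
      tt <- sort(unique(sub$time))
      times <- if (tt[1] > 0) c(0, tt) else tt
      blocks[[length(blocks) + 1L]] <- list(
        dnoco = cond$delta_noco, dpalbo = cond$delta_palbo,
        gf_scale = cond$gf_scale, init_id = k, times = times,
        rows_idx = which(pts$condition == cnd & pts$init_id == k),
        rowi = match(sub$time, times),
        colj = match(sub$marker, .cc_measured),
        value = sub$value, sigma = sub$sigma,
        const = sum(log(sub$sigma * sqrt(2 * pi))))
    }
  }
  blocks
}

.nll_eval <- function(params, blocks, ts, rtol, atol) {
  core <- .cc_core(params)
  off <- .cc_offsets(params)
  total <- 0
  for (b in blocks) {
    init <- .init_state(params, ts, b$init_id)
    m <- tryCatch(
      .cc_integrate_cpp(init, core, b$times, b$dnoco, b$dpalbo,
                        b$gf_scale, rtol, atol, 2e5),
      error = function(e) NULL)
    if (is.null(m)) {
      lp <- log10(unlist(params[.cc_fit_names]))
      bb <- log10(default_bounds())
      return(1e8 + sum((lp - colMeans(bb))^2))
    }
    obs <- m[, c(1L, 2L, 4L, 5L, 6L), drop = FALSE] # measured states
    yhat <- obs[cbind(b$rowi, b$colj)] + off[b$colj]
    total <- total + sum(((yhat - b$value) / b$sigma)^2) / 2 + b$const
  }
  total
}

# weighted residual vector for one parameter set; NULL on solver failure
.res_eval <- function(params, blocks, ts, rtol, atol) {
  core <- .cc_core(params)
  off <- .cc_offsets(params)
  out <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    init <- .init_state(params, ts, b$init_id)
    m <- tryCatch(
      .cc_integrate_cpp(init, core, b$times, b$dnoco, b$dpalbo,
                        b$gf_scale, rtol, atol, 2e5),
      error = function(e) NULL)
    if (is.null(m)) return(NULL)
    obs <- m[, c(1L, 2L, 4L, 5L, 6L), drop = FALSE]
    yhat <- obs[cbind(b$rowi, b$colj)] + off[b$colj]
    out[[i]] <- (yhat - b$value) / b$sigma
  }
  unlist(out)
}

# residual function of a log10 parameter vector (NULL on failure)
.res_log10 <- function(ts, rtol = 1e-6, atol = 1e-8) {
  blocks <- .prep_ts(ts)
  function(lp) {
    p <- as.list(10^lp)
    names(p) <- .cc_fit_names
    pars <- tryCatch(do.call(cc_params, p), error = function(e) NULL)
    if (is.null(pars)) return(NULL)
    r <- .res_eval(pars, blocks, ts, rtol, atol)
    if (!is.null(r) && any(!is.finite(r))) return(NULL)
    r
  }
}

# projected Levenberg-Marquardt on 0.5*||r(lp)||^2 within box bounds;
# far better than generic quasi-Newton in the narrow curved valleys of
# oscillator least squares
.lm_min <- function(lp0, res_fn, lower, upper, maxit = 100,
                    h = 1e-6, tol_step = 1e-8, tol_cost = 1e-10) {
  lp <- pmin(pmax(lp0, lower), upper)
  r <- res_fn(lp)
  if (is.null(r)) return(list(par = lp, cost = Inf, ok = FALSE))
  cost <- sum(r^2) / 2
  p <- length(lp)
  lambda <- 1e-3
  for (it in seq_len(maxit)) {
    J <- matrix(0, length(r), p)
    for (j in seq_len(p)) {
      lpj <- lp
      lpj[j] <- min(lp[j] + h, upper[j])
      hj <- lpj[j] - lp[j]
      if (hj == 0) { lpj[j] <- lp[j] - h; hj <- -h }
      rj <- res_fn(lpj)
      if (is.null(rj)) rj <- r # frozen column; step will be damped
      J[, j] <- (rj - r) / hj
    }
    g <- crossprod(J, r)
    A <- crossprod(J)
    dA <- diag(A)
    dA[dA < 1e-12] <- 1e-12
    improved <- FALSE
    for (tries in 1:8) {
      step <- tryCatch(
        -solve(A + lambda * diag(dA, p), g),
        error = function(e) NULL)
      if (!is.null(step)) {
        lp_new <- pmin(pmax(lp + as.numeric(step), lower), upper)
        r_new <- res_fn(lp_new)
        if (!is.null(r_new)) {
          cost_new <- sum(r_new^2) / 2
          if (cost_new < cost) {
            delta <- max(abs(lp_new - lp))
            rel <- (cost - cost_new) / max(cost, 1e-300)
            lp <- lp_new; r <- r_new; cost <- cost_new
            lambda <- max(lambda / 3, 1e-12)
            improved <- TRUE
            if (delta < tol_step || rel < tol_cost)
              return(list(par = lp, cost = cost, ok = TRUE))
            break
          }
        }
      }
      lambda <- lambda * 8
      if (lambda > 1e12) break
    }
    if (!improved) break
  }
  list(par = lp, cost = cost, ok = TRUE)
}

# nll as a function of a log10 parameter vector over .cc_fit_names
.nll_log10 <- function(ts, fixed = list(), rtol = 1e-6, atol = 1e-8) {
  blocks <- .prep_ts(ts)
  function(lp) {
    p <- as.list(10^lp)
    names(p) <- .cc_fit_names
    pars <- tryCatch(do.call(cc_params, c(p, fixed)),
                     error = function(e) NULL)
    if (is.null(pars)) return(1e10)
    v <- .nll_eval(pars, blocks, ts, rtol, atol)
    if (!is.finite(v)) 1e10 else v
  }
}

# Latin hypercube in log10 space within bounds
.lhs_log10 <- function(n, bounds) {
  lo <- log10(bounds["lower", ]); hi <- log10(bounds["upper", ])
  d <- length(lo)
  m <- vapply(seq_len(d), function(j) {
    (sample(n) - runif(n)) / n * (hi[j] - lo[j]) + lo[j]
  }, numeric(n))
  if (n == 1) m <- matrix(m, nrow = 1)
  colnames(m) <- colnames(bounds)
  m
}

#' Multistart maximum-likelihood fit
#'
#' Local damped least-squares optimization (projected Levenberg-
#' Marquardt on the log10 parameter scale, numeric Jacobians of the
#' weighted residual vector) from Latin-hypercube starts within the
#' bounds; optional user-supplied starts are appended.  `GF` and `E2Ft`
#' stay fixed at 1.  Returns the best converged start.
#'
#' @param ts a `cc_training_set`.
#' @param bounds bounds matrix as from [default_bounds()].
#' @param n_starts number of Latin-hypercube starts.
#' @param seed RNG seed (start sampling is deterministic given the
#'   seed).
#' @param starts optional matrix of additional starts (rows; columns
#'   named by free parameters, natural scale).
#' @param maxit Levenberg-Marquardt iteration cap per start.
#' @param rtol,atol simulation tolerances during fitting.
#' @return a `cc_fit`: list `estimates` ([cc_params()]), `objective`,
#'   `starts`, `converged`, `seed`, `trace` (per-start objectives),
#'   `bounds`.
#' @export
cc_fit <- function(ts, bounds = default_bounds(), n_starts = 20,
                   seed = 1L, starts = NULL, maxit = 200,
                   rtol = 1e-6, atol = 1e-8) {
  set.seed(seed)
  res_fn <- .res_log10(ts, rtol = rtol, atol = atol)
  const <- sum(log(ts$points$sigma * sqrt(2 * pi)))
  S <- if (n_starts > 0) .lhs_log10(n_starts, bounds) else NULL
  if (!is.null(starts)) {
    starts <- as.matrix(starts)[, .cc_fit_names, drop = FALSE]
    S <- rbind(S, log10(starts))
  }
  if (is.null(S) || nrow(S) == 0) stop("no starts")
  lo <- log10(bounds["lower", ]); hi <- log10(bounds["upper", ])
  best <- NULL
  trace <- numeric(nrow(S))
  for (i in seq_len(nrow(S))) {
    res <- .lm_min(pmin(pmax(S[i, ], lo), hi), res_fn, lo, hi,
                   maxit = maxit)
    trace[i] <- if (res$ok) res$cost + const else NA_real_
    if (res$ok && (is.null(best) || res$cost < best$cost)) best <- res
  }
  if (is.null(best) || !is.finite(best$cost))
    stop("no start converged to a finite objective")
  est <- as.list(10^best$par)
  names(est) <- .cc_fit_names
  structure(list(estimates = do.call(cc_params, est),
                 objective = best$cost + const, starts = nrow(S),
                 converged = TRUE,
                 seed = seed, trace = trace, bounds = bounds,
                 par_log10 = setNames(best$par, .cc_fit_names), ts = ts,
                 rtol = rtol, atol = atol),
            class = "cc_fit")
}

#' @export
print.cc_fit <- function(x, ...) {
  cat(sprintf("<cc_fit> objective %.3f after %d starts (converged: %s)\n",
              x$objective, x$starts, x$converged))
  invisible(x)
}
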
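# Profile likelihood: generic scanner plus the model-fit wrapper.

#' Profile a single coordinate of an objective function
#'
#' Steps the target coordinate away from the optimum in both directions
#' with adaptive step sizes, re-optimizing all other coordinates at each
#' step (L-BFGS-B warm-started from the previous point), until the
#' objective exceeds `f_min + threshold` or a bound is reached.
#' Crossings are located by linear interpolation.
#'
#' @param fn objective taking the full coordinate vector.
#' @param par optimum coordinates.
#' @param idx index (or name) of the profiled coordinate.
#' @param lower,upper bound vectors for all coordinates.
#' @param f_min objective at `par` (recomputed when `NULL`).
#' @param threshold objective increase defining the interval.  For a
#'   negative log-likelihood objective the likelihood-ratio statistic is
#'   twice the increase, so the pointwise 95 percent default is
#'   `qchisq(0.95, 1) / 2 = 1.92`.
#' @param step0 initial step for the profiled coordinate (default 2
#'   percent of its bound range).
#' @param max_steps cap on steps per direction.
#' @param maxit re-optimization iteration cap.
#' @param reopt optional custom re-optimizer `function(fixed_val,
#'   start_par) -> list(par, value)`; the default re-optimizes the free
#'   coordinates with L-BFGS-B on `fn`.
#' @return a `cc_profile`: list with `idx`, `profile` (data.frame
#'   `value`, `objective`), `ci` (crossing values, `-Inf`/`Inf` when
#'   open), `classification` (`identifiable`, `partially identifiable`,
#'   `non-identifiable`), `non_monotone` flag, `f_min`, `threshold`.
#' @export
profile_objective <- function(fn, par, idx, lower, upper, f_min = NULL,
                              threshold = qchisq(0.95, 1) / 2,
                              step0 = NULL, max_steps = 30, maxit = 60,
                              reopt = NULL) {
  if (is.character(idx)) idx <- match(idx, names(par))
  stopifnot(length(idx) == 1, !is.na(idx))
  if (is.null(f_min)) f_min <- fn(par)
  if (is.null(step0)) step0 <- 0.02 * (upper[idx] - lower[idx])
  d <- length(par)
  free <- setdiff(seq_len(d), idx)

  if (is.null(reopt)) reopt <- function(fixed_val, start) {
    if (!length(free)) {
      x <- start; x[idx] <- fixed_val
      return(list(par = x, value = fn(x)))
    }
    g <- function(z) {
      x <- start
      x[free] <- z
      x[idx] <- fixed_val
      fn(x)
    }
    res <- tryCatch(
      optim(start[free], g, method = "L-BFGS-B",
            lower = lower[free], upper = upper[free],
            control = list(maxit = maxit, factr = 1e8,
                           ndeps = rep(1e-5, length(free)))),
      error = function(e) NULL)
    if (is.null(res)) return(list(par = start, value = Inf))
    x <- start; x[free] <- res$par; x[idx] <- fixed_val
    list(par = x, value = res$value)
  }

  scan_dir <- function(sign) {
    rows <- list()
    cur <- par
    step <- step0
    val <- unname(par[idx])
    crossing <- NA_real_
    prev_obj <- f_min
    prev_val <- val
    for (s in seq_len(max_steps)) {
      val <- val + sign * step
      hit_bound <- FALSE
      if (val <= lower[idx]) { val <- unname(lower[idx]); hit_bound <- TRUE }
      if (val >= upper[idx]) { val <- unname(upper[idx]); hit_bound <- TRUE }
      r <- reopt(val, cur)
      rows[[s]] <- c(value = unname(val), objective = unname(r$value))
      dobj <- r$value - prev_obj
      if (r$value > f_min + threshold) {
        # bracketed: refine by bisection, always warm-starting from the
        # parameters of the last point still below the threshold (the
        # profile can rise by many thresholds within one step, so plain
        # interpolation would bias the crossing inward)
        a <- prev_val; fa <- prev_obj
        bb <- val; fb <- r$value
        for (bi in 1:6) {
          mid <- (a + bb) / 2
          rm <- reopt(mid, cur)
          rows[[length(rows) + 1L]] <- c(value = unname(mid),
                                         objective = unname(rm$value))
          if (rm$value > f_min + threshold) {
            bb <- mid; fb <- rm$value
          } else {
            a <- mid; fa <- rm$value
            cur <- rm$par
          }
        }
        w <- (f_min + threshold - fa) / (fb - fa)
        crossing <- a + w * (bb - a)
        break
      }
      cur <- r$par
      if (hit_bound) break
      # adaptive step targeting ~threshold/4 objective change
      if (abs(dobj) < threshold / 8) step <- step * 2
      else if (abs(dobj) > threshold / 2) step <- step / 2
      prev_obj <- r$value
      prev_val <- val
    }
    m <- do.call(rbind, rows)
    m <- m[order(m[, "value"] * sign), , drop = FALSE]
    list(rows = m, crossing = crossing)
  }

  up <- scan_dir(+1)
  dn <- scan_dir(-1)
  prof <- rbind(
    data.frame(value = rev(dn$rows[, "value"]),
               objective = rev(dn$rows[, "objective"])),
    data.frame(value = unname(par[idx]), objective = unname(f_min)),
    data.frame(value = up$rows[, "value"],
               objective = up$rows[, "objective"]))
  lo_found <- isTRUE(!is.na(unname(dn$crossing)[1]))
  hi_found <- isTRUE(!is.na(unname(up$crossing)[1]))
  classification <- if (lo_found && hi_found) "identifiable"
                    else if (lo_found || hi_found) "partially identifiable"
                    else "non-identifiable"
  ci <- c(if (lo_found) unname(dn$crossing) else -Inf,
          if (hi_found) unname(up$crossing) else Inf)
  non_monotone <- any(diff(prof$objective[prof$value >= par[idx]]) < -1e-6) ||
                  any(diff(rev(prof$objective[prof$value <= par[idx]])) < -1e-6)
  structure(list(idx = idx, name = names(par)[idx], profile = prof,
                 ci = unname(ci), classification = classification,
                 non_monotone = non_monotone, f_min = f_min,
                 threshold = threshold),
            class = "cc_profile")
}

#' @export
print.cc_profile <- function(x, ...) {
  cat(sprintf("<cc_profile> %s: %s, CI [%.4g, %.4g] (threshold %.2f)\n",
              if (is.null(x$name)) x$idx else x$name, x$classification,
              x$ci[1], x$ci[2], x$threshold))
  invisible(x)
}

#' Profile likelihood of a fitted model parameter
#'
#' Profiles the negative log-likelihood of a [cc_fit()] over one
#' parameter (on the log10 scale, as fitted), re-optimizing all other
#' free parameters at each step.  Confidence intervals are mapped back
#' to the natural scale.
#'
#' @param fit a `cc_fit`.
#' @param ts the training set (defaults to the one stored in the fit).
#' @param param parameter name (one of the free parameters).
#' @param threshold negative-log-likelihood increase for the interval
#'   (default `qchisq(0.95, 1) / 2 = 1.92`, i.e. 3.84 on the chi-square
#'   scale: pointwise 95 percent).
#' @param max_steps,maxit scan/re-optimization caps.
#' @return a `cc_profile` with natural-scale `ci_95` added.
#' @export
profile_likelihood <- function(fit, ts = fit$ts, param,
                               threshold = qchisq(0.95, 1) / 2,
                               max_steps = 30, maxit = 60) {
  stopifnot(inherits(fit, "cc_fit"), param %in% .cc_fit_names)
  fn <- .nll_log10(ts, rtol = fit$rtol, atol = fit$atol)
  res_fn <- .res_log10(ts, rtol = fit$rtol, atol = fit$atol)
  const <- sum(log(ts$points$sigma * sqrt(2 * pi)))
  lo <- log10(fit$bounds["lower", ]); hi <- log10(fit$bounds["upper", ])
  par <- fit$par_log10
  names(par) <- .cc_fit_names
  idx <- match(param, .cc_fit_names)
  free <- setdiff(seq_along(par), idx)
  # re-optimize the remaining parameters with the same damped
  # least-squares engine used for fitting
  lm_reopt <- function(fixed_val, start) {
    sub_fn <- function(lp_free) {
      x <- start
      x[free] <- lp_free
      x[idx] <- fixed_val
      res_fn(x)
    }
    r <- .lm_min(start[free], sub_fn, lo[free], hi[free], maxit = maxit)
    x <- start; x[free] <- r$par; x[idx] <- fixed_val
    list(par = x, value = if (is.finite(r$cost)) r$cost + const else Inf)
  }
  pr <- profile_objective(fn, par, param, lo, hi, f_min = fit$objective,
                          threshold = threshold, max_steps = max_steps,
                          maxit = maxit, reopt = lm_reopt)
  pr$ci_95 <- 10^pr$ci
  pr$estimate <- 10^par[[param]]
  pr
}
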
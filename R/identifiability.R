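# Structural identifiability via the rank of the output sensitivity
# matrix with respect to log parameters.

#' Experimental design for identifiability analysis
#'
#' @param conditions character vector of conditions included
#'   (`"untreated"`, `"nocodazole"`, `"palbociclib"`).
#' @param times observation times (h).
#' @param inits 2 x 5 matrix of measured initial values (as in a
#'   training set); defaults to generic on-cycle values.
#' @return a list consumed by [structural_identifiability()].
#' @export
identifiability_design <- function(conditions = c("untreated",
                                                  "nocodazole",
                                                  "palbociclib"),
                                   times = seq(0, 96, by = 4),
                                   inits = NULL) {
  if (is.null(inits)) {
    inits <- rbind(c(0.25, 0.12, 0.2, 0.9, 0.6),
                   c(0.1, 0.05, 0.1, 1.0, 1.8))
    colnames(inits) <- .cc_measured
  }
  list(conditions = conditions, times = times, inits = inits)
}

# stack model observables over the design for one parameter vector
.design_outputs <- function(params, design, rtol = 1e-8, atol = 1e-10) {
  ts_stub <- list(initial_conditions = design$inits)
  out <- c()
  for (cnd in design$conditions) {
    cond <- cc_condition(cnd)
    for (k in seq_len(nrow(design$inits))) {
      init <- .init_state(params, ts_stub, k)
      tr <- cc_simulate(params, init, cond, times = design$times,
                        rtol = rtol, atol = atol)
      out <- c(out, as.numeric(cc_observable(tr, params)))
    }
  }
  out
}

#' Structural identifiability by sensitivity-matrix rank
#'
#' Assembles the sensitivity matrix of all designed observables with
#' respect to the log parameters by central finite differences
#' (relative step `1e-4`), computes its singular values, and determines
#' the numeric rank at tolerance `max(singular value) * 1e-8 *
#' max(dim)`.  Parameters loading on the numeric null space are the
#' confounded (structurally non-identifiable) combinations for that
#' design; a drug parameter such as `IEn` falls in the null space
#' whenever no condition activates its switch.
#'
#' @param params evaluation point ([cc_params()]).
#' @param design an [identifiability_design()].
#' @param step relative finite-difference step on the log10 scale.
#' @param rank_tol_factor tolerance factor (default `1e-8`).
#' @param rtol,atol simulation tolerances.
#' @return an `identifiability_report`: list `singular_values`, `rank`,
#'   `n_params`, `parameters`, `null_space` (matrix of null vectors,
#'   rows named by parameter), `null_combinations` (per null vector,
#'   the parameters with loading above 0.1).
#' @export
structural_identifiability <- function(params = cc_params(),
                                       design = identifiability_design(),
                                       step = 1e-4,
                                       rank_tol_factor = 1e-8,
                                       rtol = 1e-8, atol = 1e-10) {
  pn <- .cc_fit_names
  base <- unlist(params[pn])
  y0 <- tryCatch(.design_outputs(params, design, rtol, atol),
                 error = function(e)
                   stop("simulation failed at the evaluation point: ",
                        conditionMessage(e)))
  S <- matrix(NA_real_, length(y0), length(pn),
              dimnames = list(NULL, pn))
  for (j in seq_along(pn)) {
    h <- step # step on log10 scale: multiply by 10^(+-h)
    pp <- params; pp[[pn[j]]] <- base[j] * 10^h
    pm <- params; pm[[pn[j]]] <- base[j] * 10^(-h)
    yp <- .design_outputs(pp, design, rtol, atol)
    ym <- .design_outputs(pm, design, rtol, atol)
    S[, j] <- (yp - ym) / (2 * h)
  }
  sv <- svd(S)
  tol <- max(sv$d) * rank_tol_factor * max(dim(S))
  rank <- sum(sv$d > tol)
  null_idx <- seq_len(ncol(S))[-seq_len(rank)]
  null_space <- if (length(null_idx))
    sv$v[, null_idx, drop = FALSE] else NULL
  if (!is.null(null_space)) rownames(null_space) <- pn
  combos <- if (!is.null(null_space))
    apply(null_space, 2, function(v) pn[abs(v) > 0.1]) else list()
  structure(list(singular_values = sv$d, rank = rank,
                 n_params = length(pn), parameters = pn,
                 null_space = null_space,
                 null_combinations = combos, tol = tol),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat(sprintf("<identifiability_report> rank %d of %d parameters\n",
              x$rank, x$n_params))
  if (x$rank < x$n_params) {
    cat("null-space combinations:\n")
    for (cmb in x$null_combinations)
      cat("  -", paste(cmb, collapse = " * "), "\n")
  }
  invisible(x)
}
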
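# Synthetic single-cell snapshot generator: ergodic sampling of the
# limit cycle, drug-arrested endpoints, multiplicative lognormal noise.

.default_extra_markers <- c("pRB", "CDT1", "Gem", "p27", "Ki67", "PCNA",
                            "MCM2")

#' Snapshot specification
#'
#' Describes one synthetic snapshot: number of cells, multiplicative
#' lognormal noise level, number of non-modelled "extra" markers
#' (surrogates for pRB, Ki67, PCNA, ...), the sampling law of cell
#' phases, the condition, and the treatment duration.
#'
#' @param n_cells number of cells (>= 1).
#' @param noise_cv lognormal coefficient of variation applied
#'   multiplicatively to every intensity (>= 0).
#' @param n_extra_markers number of extra phase-bump markers (0..7 named
#'   surrogates, more get synthetic names).
#' @param sampling `"ergodic"` (phase uniform in time) or
#'   `"exponential_age"` (age density proportional to `2^(-t/T)`, the
#'   density of a steadily dividing population).
#' @param condition `"untreated"`, `"nocodazole"`, `"palbociclib"` or
#'   `"gf"` (growth-factor fraction via `gf_fraction`).
#' @param gf_fraction growth-factor fraction for `condition = "gf"`.
#' @param treatment_duration treatment time for arrested snapshots (h).
#' @param seed integer RNG seed for the cell draws.
#' @param panel_seed integer seed fixing the extra-marker panel (bump
#'   centers and widths).  Snapshots that are analysed together must
#'   share the panel seed so every table carries the same markers.
#' @return a `snapshot_spec` list.
#' @export
snapshot_spec <- function(n_cells = 2000, noise_cv = 0.2,
                          n_extra_markers = 7,
                          sampling = c("ergodic", "exponential_age"),
                          condition = c("untreated", "nocodazole",
                                        "palbociclib", "gf"),
                          gf_fraction = 1.0,
                          treatment_duration = 24, seed = 1L,
                          panel_seed = 1L) {
  sampling <- match.arg(sampling)
  condition <- match.arg(condition)
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (condition != "untreated" && treatment_duration <= 0)
    stop("treatment_duration must be > 0 for treated conditions")
  structure(list(n_cells = as.integer(n_cells), noise_cv = noise_cv,
                 n_extra_markers = as.integer(n_extra_markers),
                 sampling = sampling, condition = condition,
                 gf_fraction = gf_fraction,
                 treatment_duration = treatment_duration,
                 seed = as.integer(seed),
                 panel_seed = as.integer(panel_seed)),
            class = "snapshot_spec")
}

# lognormal multiplicative noise with mean 1 and coefficient of
# variation cv
.ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# draw phases according to the sampling law
.draw_phases <- function(n, sampling) {
  u <- runif(n)
  if (sampling == "ergodic") u else -log2(1 - u / 2)
}

# smooth unimodal bump markers of phase (von-Mises-shaped); centers and
# widths are drawn once from the current RNG stream
.make_extra_profiles <- function(n_extra) {
  if (n_extra < 1) return(NULL)
  nm <- c(.default_extra_markers,
          paste0("extra", seq_len(max(0, n_extra - 7))))[seq_len(n_extra)]
  centers <- runif(n_extra)
  kappa <- runif(n_extra, 2, 8)
  base <- runif(n_extra, 0.05, 0.2)
  amp <- runif(n_extra, 0.5, 1.5)
  list(names = nm, centers = centers, kappa = kappa, base = base,
       amp = amp)
}

.eval_extra <- function(prof, phase) {
  vapply(seq_along(prof$names), function(k) {
    prof$base[k] + prof$amp[k] *
      exp(prof$kappa[k] * (cos(2 * pi * (phase - prof$centers[k])) - 1))
  }, numeric(length(phase)))
}

# assemble the observed table from noiseless intensity matrix
.observe_table <- function(clean, spec, phase, states, condition_label) {
  if (any(clean <= 0))
    stop("nonpositive noiseless intensity: offsets too small for the ",
         "sampled states")
  noisy <- clean * matrix(.ln_noise(length(clean), spec$noise_cv),
                          nrow(clean), ncol(clean))
  out <- data.frame(cell_id = sprintf("cell_%05d", seq_len(nrow(clean))),
                    condition = condition_label, noisy,
                    check.names = FALSE)
  out[["__true_phase"]] <- phase
  for (j in seq_along(.cc_state_names))
    out[[paste0("__true_state_", .cc_state_names[j])]] <- states[, j]
  out
}

#' Sample an untreated snapshot from a limit cycle
#'
#' Each cell draws a phase (uniform in time under ergodic sampling, or
#' from the exponential age density of a doubling population), looks up
#' the limit-cycle state, adds per-marker background offsets, and applies
#' multiplicative lognormal noise.  Extra markers are smooth von-Mises
#' bumps of phase whose centers and widths are fixed by the seed.  The
#' true phase and true state are emitted in `__`-prefixed columns for
#' testing only.
#'
#' @param map a [make_limit_cycle()] object.
#' @param spec a [snapshot_spec()] with `condition = "untreated"`.
#' @param params parameter object supplying the observation offsets;
#'   defaults to the parameters stored in `map`.
#' @return a data.frame (single-cell table): `cell_id`, `condition`, one
#'   column per marker, hidden truth columns.
#' @export
sample_snapshot <- function(map, spec = snapshot_spec(),
                            params = map$params) {
  stopifnot(inherits(map, "cc_limit_cycle"),
            inherits(spec, "snapshot_spec"))
  if (spec$condition != "untreated")
    stop("sample_snapshot handles untreated snapshots; use ",
         "sample_arrested_snapshot for treated conditions")
  set.seed(spec$panel_seed)
  prof <- .make_extra_profiles(spec$n_extra_markers)
  set.seed(spec$seed)
  phase <- .draw_phases(spec$n_cells, spec$sampling)
  states <- .lc_state_at(map, phase)
  meas <- states[, .cc_measured, drop = FALSE]
  clean <- sweep(meas, 2, .cc_offsets(params), "+")
  if (!is.null(prof))
    clean <- cbind(clean, setNames(as.data.frame(.eval_extra(prof, phase)),
                                   prof$names))
  clean <- as.matrix(clean)
  out <- .observe_table(clean, spec, phase, states, "untreated")
  attr(out, "spec") <- spec
  attr(out, "extra_profiles") <- prof
  attr(out, "period") <- map$period
  out
}

#' Sample a drug-arrested snapshot
#'
#' Each cell starts from a random phase on the limit cycle (as in
#' [sample_snapshot()]), is integrated under the treated condition for
#' `treatment_duration` hours, and its final state is observed with
#' noise.  Extra markers are evaluated at the phase of the limit-cycle
#' point nearest (in measured coordinates) to the final state, mimicking
#' markers that follow the cell's effective cycle position.  The
#' condition-level true arrest phase (nearest-cycle-point mapping of the
#' long-time arrested state) is attached as attribute `arrest_phase`.
#'
#' @param params a [cc_params()] object governing the treated dynamics.
#' @param map a [make_limit_cycle()] object for the untreated cycle.
#' @param spec a [snapshot_spec()] with a treated condition.
#' @param rtol,atol integration tolerances.
#' @return a single-cell table as in [sample_snapshot()], with
#'   attributes `arrest_phase` (fraction of the period) and
#'   `arrest_state`.
#' @export
sample_arrested_snapshot <- function(params, map, spec,
                                     rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(map, "cc_limit_cycle"),
            inherits(spec, "snapshot_spec"))
  cond <- switch(spec$condition,
    nocodazole = cc_condition("nocodazole"),
    palbociclib = cc_condition("palbociclib"),
    gf = cc_condition("untreated", gf_scale = spec$gf_fraction),
    stop("spec$condition must be a treated condition"))
  set.seed(spec$panel_seed)
  prof <- .make_extra_profiles(spec$n_extra_markers)
  set.seed(spec$seed)
  phase0 <- .draw_phases(spec$n_cells, spec$sampling)
  inits <- .lc_state_at(map, phase0)
  finals <- tryCatch(
    .cc_endpoints_cpp(inits, .cc_core(params), spec$treatment_duration,
                      cond$delta_noco, cond$delta_palbo, cond$gf_scale,
                      rtol, atol, 5e6),
    error = function(e) stop("integration failure in arrested snapshot: ",
                             conditionMessage(e)))
  colnames(finals) <- .cc_state_names
  meas <- finals[, .cc_measured, drop = FALSE]
  clean <- sweep(meas, 2, .cc_offsets(params), "+")
  # per-cell effective phase: nearest limit-cycle point in measured space
  refmeas <- map$states[, .cc_measured, drop = FALSE]
  nearest <- vapply(seq_len(nrow(meas)), function(i) {
    which.min(colSums((t(refmeas) - meas[i, ])^2))
  }, 0L)
  eff_phase <- map$phase[nearest]
  if (!is.null(prof))
    clean <- cbind(clean,
                   setNames(as.data.frame(.eval_extra(prof, eff_phase)),
                            prof$names))
  clean <- as.matrix(clean)
  out <- .observe_table(clean, spec, phase0, finals, spec$condition)
  # condition-level truth: long-run arrest state from the mean init
  deep <- .cc_endpoints_cpp(matrix(colMeans(inits), 1), .cc_core(params),
                            max(240, 10 * spec$treatment_duration),
                            cond$delta_noco, cond$delta_palbo,
                            cond$gf_scale, rtol, atol, 5e6)[1, ]
  names(deep) <- .cc_state_names
  # arrested states sit off the cycle manifold by nature; the distance
  # warning is aimed at user-supplied states, not this bookkeeping
  ap <- suppressWarnings(arrest_phase(deep, map))
  attr(out, "spec") <- spec
  attr(out, "extra_profiles") <- prof
  attr(out, "period") <- map$period
  attr(out, "arrest_state") <- deep
  attr(out, "arrest_phase") <- ap$phase
  out
}

#' Read or write a single-cell table as CSV
#'
#' The on-disk layout is `cell_id, condition, <marker columns>,
#' __true_phase, __true_state_*` (truth columns present only for
#' synthetic tables).
#'
#' @param x a single-cell table (data.frame).
#' @param path file path.
#' @return `write_cell_table` returns `path` invisibly;
#'   `read_cell_table` returns a data.frame.
#' @export
write_cell_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  x <- read.csv(path, check.names = FALSE)
  if (!all(c("cell_id", "condition") %in% names(x)))
    stop("not a single-cell table: missing cell_id/condition columns")
  if (anyDuplicated(x$cell_id)) stop("duplicate cell_id values")
  x
}

# marker columns of a single-cell table (everything except ids and the
# hidden truth columns)
.marker_cols <- function(x) {
  setdiff(names(x)[!startsWith(names(x), "__")],
          c("cell_id", "condition"))
}
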
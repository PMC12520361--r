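# Model parameters, drug conditions and their (de)serialization.

# canonical ordering of the core kinetic parameters passed to C++
.cc_core_names <- c("Vsp", "Vsd", "Vse", "Vsa", "Vsb",
                    "kx", "kdd", "kdd1", "kde", "kda", "kdb",
                    "kpi", "kpii", "kpiii", "IEn", "E2Ft", "GF")

.cc_state_names <- c("p21", "Cd", "E2Fa", "Ce", "Ca", "Cb")

# markers measured by immunofluorescence (E2Fa is unobserved)
.cc_measured <- c("p21", "Cd", "Ce", "Ca", "Cb")

#' Cell-cycle model parameters
#'
#' Construct the parameter set of the six-variable cell-cycle model
#' (p21, cyclin D, active E2F, cyclins E, A and B).  The defaults define
#' the package's reference oscillator: a stable limit cycle with a period
#' of about 24 hours at `GF = 1`, convergence to a single arrested steady
#' state under either drug switch, and loss of oscillation when the growth
#' factor level drops below roughly 80 percent of the training level.
#'
#' Rate constants (`Vsp`, `Vsd`, `Vse`, `Vsa`, `Vsb`, units 1/h on
#' normalized concentrations) scale both the synthesis and the saturating
#' degradation term of their species.  `kx`, `kdd`, `kdd1`, `kde`, `kda`,
#' `kdb`, `kpi`, `kpii`, `kpiii` are Michaelis constants (a.u.).  `IEn` is
#' the dimensionless nocodazole inhibition strength acting on p21
#' degradation.  `E2Ft` (total E2F) and `GF` (growth-factor level) are
#' fixed to 1 during fitting to avoid structural non-identifiability.
#' Per-marker background offsets enter the observation model only
#' (`observable = state + offset`), and `init_E2F_G1S` / `init_E2F_G2M`
#' are the estimated initial values of the unmeasured E2Fa state for the
#' two training initial conditions.
#'
#' @param ... named overrides of any default value.
#' @return an object of class `cc_params`: a named list of scalars.
#' @examples
#' p <- cc_params()
#' p$Vsd
#' cc_params(GF = 0.6)$GF
#' @export
cc_params <- function(...) {
  p <- list(
    # kinetic core (frozen reference oscillator, see methods vignette)
    Vsp = 1.89609, Vsd = 1.74667, Vse = 0.22058, Vsa = 0.47240,
    Vsb = 4.24623, kx = 0.15242, kdd = 0.08513, kdd1 = 0.08504,
    kde = 0.92259, kda = 15.13523, kdb = 0.01990, kpi = 0.29932,
    kpii = 18.82035, kpiii = 0.96790, IEn = 18.79841,
    E2Ft = 1.0, GF = 1.0,
    # observation offsets (background intensities, a.u.)
    offset_p21 = 0.05, offset_Cd = 0.05, offset_Ce = 0.05,
    offset_Ca = 0.05, offset_Cb = 0.05,
    # estimated E2Fa initial values for the two training initial conditions
    init_E2F_G1S = 0.05, init_E2F_G2M = 0.05
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  core <- unlist(p[.cc_core_names])
  if (any(!is.finite(core)) || any(core[1:16] <= 0) || core["GF"] < 0)
    stop("rate and Michaelis parameters must be positive and finite")
  offs <- unlist(p[paste0("offset_", .cc_measured)])
  if (any(offs < 0)) stop("offsets must be nonnegative")
  ie <- unlist(p[c("init_E2F_G1S", "init_E2F_G2M")])
  if (any(ie < 0) || any(ie > p$E2Ft))
    stop("init_E2F_* must lie in [0, E2Ft]")
  structure(p, class = "cc_params")
}

#' @export
print.cc_params <- function(x, ...) {
  cat("<cc_params> six-variable cell-cycle model parameters\n")
  v <- unlist(x)
  print(round(v, 5))
  invisible(x)
}

# core numeric vector in canonical order for the C++ layer
.cc_core <- function(p) {
  stopifnot(inherits(p, "cc_params"))
  unlist(p[.cc_core_names])
}

.cc_offsets <- function(p) unlist(p[paste0("offset_", .cc_measured)])

#' Drug / growth-factor condition switches
#'
#' The binary switches of the model: untreated `(delta_noco = 0,
#' delta_palbo = 1)`, nocodazole `(1, 1)` and palbociclib `(0, 0)`,
#' together with a dimensionless multiplier on the growth-factor level.
#' `delta_palbo = 0` removes the CDK4/6-cyclin D activation of E2F;
#' `delta_noco = 1` suppresses p21 degradation by the factor
#' `1/(1 + IEn)`.
#'
#' @param condition one of `"untreated"`, `"nocodazole"`, `"palbociclib"`.
#' @param gf_scale multiplier applied to the `GF` parameter (starvation
#'   scans use values below 1).
#' @return an object of class `cc_condition`.
#' @examples
#' cc_condition("palbociclib")
#' cc_condition("untreated", gf_scale = 0.6)
#' @export
cc_condition <- function(condition = c("untreated", "nocodazole",
                                       "palbociclib"),
                         gf_scale = 1.0) {
  condition <- match.arg(condition)
  if (!is.finite(gf_scale) || gf_scale < 0)
    stop("gf_scale must be a nonnegative number")
  sw <- switch(condition,
    untreated   = c(delta_noco = 0, delta_palbo = 1),
    nocodazole  = c(delta_noco = 1, delta_palbo = 1),
    palbociclib = c(delta_noco = 0, delta_palbo = 0))
  structure(list(condition = condition,
                 delta_noco = unname(sw["delta_noco"]),
                 delta_palbo = unname(sw["delta_palbo"]),
                 gf_scale = gf_scale),
            class = "cc_condition")
}

#' @export
print.cc_condition <- function(x, ...) {
  cat(sprintf("<cc_condition> %s (delta_noco=%d, delta_palbo=%d, gf_scale=%g)\n",
              x$condition, x$delta_noco, x$delta_palbo, x$gf_scale))
  invisible(x)
}

#' Read or write model parameters as flat key-value text
#'
#' Parameters are stored one per line as `name: value`, a minimal
#' YAML-style flat mapping.  Lines starting with `#` are ignored.
#'
#' @param p a [cc_params()] object.
#' @param path file path.
#' @return `write_params` returns `path` invisibly; `read_params`
#'   returns a `cc_params` object.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "cc_params"))
  lines <- sprintf("%s: %.17g", names(p), unlist(p))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed parameter line(s): ",
                     paste(lines[bad], collapse = "; "))
  vals <- as.numeric(vapply(kv, `[[`, "", 2L))
  names(vals) <- trimws(vapply(kv, `[[`, "", 1L))
  do.call(cc_params, as.list(vals))
}
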
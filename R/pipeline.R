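# Reproducible pipeline driver and command-line interface.

#' Pipeline configuration
#'
#' Assembles (and validates) the configuration consumed by
#' [run_pipeline()].  Seeds are mandatory: no wall-clock defaults.
#'
#' @param outdir output directory.
#' @param input_csv optional untreated input table; when `NULL` the
#'   synthetic generator runs first.
#' @param treated_csv named list of treated tables (or `NULL` to
#'   generate).
#' @param seed integer master seed.
#' @param T cycle length (h).
#' @param n_cells synthetic cells per condition.
#' @param noise_cv synthetic noise level.
#' @param fraction treated subset fraction.
#' @param window movMMAD window (`NULL` = default rule).
#' @param n_bins angle histogram bins.
#' @param n_starts multistart count for fitting.
#' @param profile_params parameters to profile (character; `NULL` for
#'   none).
#' @param gf_grid growth-factor scan grid (descending).
#' @param rtol,atol solver tolerances.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, input_csv = NULL, treated_csv = NULL,
                            seed, T = 24, n_cells = 1500,
                            noise_cv = 0.2, fraction = 0.05,
                            window = NULL, n_bins = 50, n_starts = 8,
                            profile_params = NULL,
                            gf_grid = seq(1, 0.5, by = -0.05),
                            rtol = 1e-6, atol = 1e-8) {
  if (missing(seed) || is.null(seed))
    stop("config field 'seed' is required (reproducibility contract)")
  if (missing(outdir) || is.null(outdir))
    stop("config field 'outdir' is required")
  if (!is.null(input_csv) && !file.exists(input_csv))
    stop("config field 'input_csv' points to a missing file: ", input_csv)
  cfg <- list(outdir = outdir, input_csv = input_csv,
              treated_csv = treated_csv, seed = as.integer(seed), T = T,
              n_cells = n_cells, noise_cv = noise_cv,
              fraction = fraction, window = window, n_bins = n_bins,
              n_starts = n_starts, profile_params = profile_params,
              gf_grid = gf_grid, rtol = rtol, atol = atol)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the fields of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Run the full snapshot-to-model pipeline
#'
#' Stages: `generate` (optional synthetic data) -> `embed` (CMD,
#' angles, pseudo-time, trajectories, boundaries) -> `arrest` (per
#' treated condition) -> `fit` (soft-constraint training) -> `profile`
#' (optional) -> `predict-gf` (starvation scan and arrest-phase
#' mapping).  Every stage writes plain CSV; the final summary is JSON.
#' Fails fast naming the failing stage; partial outputs are retained.
#'
#' @param cfg a [pipeline_config()].
#' @param stages subset of stages to run (default all).
#' @return invisibly, the summary list (also written to
#'   `summary.json`).
#' @export
run_pipeline <- function(cfg, stages = c("generate", "embed", "arrest",
                                         "fit", "profile",
                                         "predict_gf")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$outdir, "pipeline.log")
  logmsg <- function(...) cat(sprintf(...), "\n", sep = "",
                              file = logf, append = TRUE)
  cat(sprintf("pseudocycle %s | R %s | seed %d\n",
              as.character(utils::packageVersion("pseudocycle")),
              getRversion(), cfg$seed), file = logf)
  summary <- list(seed = cfg$seed, T = cfg$T)
  stage <- function(name, expr) {
    if (!(name %in% stages)) return(invisible(NULL))
    logmsg("[%s] start", name)
    tryCatch(expr, error = function(e) {
      logmsg("[%s] FAILED: %s", name, conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }

  params <- cc_params()
  lc <- NULL
  untreated <- NULL
  treated <- list()

  stage("generate", {
    if (is.null(cfg$input_csv)) {
      lc <- make_limit_cycle(params)
      sp <- snapshot_spec(n_cells = cfg$n_cells, noise_cv = cfg$noise_cv,
                          condition = "untreated", seed = cfg$seed)
      untreated <- sample_snapshot(lc, sp)
      write_cell_table(untreated, file.path(cfg$outdir, "untreated.csv"))
      for (drug in c("nocodazole", "palbociclib")) {
        spd <- snapshot_spec(n_cells = max(200, cfg$n_cells %/% 3),
                             noise_cv = cfg$noise_cv, condition = drug,
                             seed = cfg$seed + match(drug,
                               c("nocodazole", "palbociclib")))
        treated[[drug]] <- sample_arrested_snapshot(params, lc, spd)
        write_cell_table(treated[[drug]],
                         file.path(cfg$outdir, paste0(drug, ".csv")))
      }
      logmsg("[generate] %d untreated cells, 2 treated conditions",
             nrow(untreated))
    } else {
      untreated <- read_cell_table(cfg$input_csv)
      for (nm in names(cfg$treated_csv))
        treated[[nm]] <- read_cell_table(cfg$treated_csv[[nm]])
      logmsg("[generate] loaded %d untreated cells", nrow(untreated))
    }
  })

  emb <- NULL; pt <- NULL; traj_raw <- NULL; bounds_ang <- NULL
  stage("embed", {
    m <- preprocess_markers(untreated)
    coords <- cmd_embed(m)
    emb <- embed_angles(coords, markers = m)
    pt <- ergodic_times(emb, cfg$T)
    bounds_ang <- phase_boundaries(emb, n_bins = cfg$n_bins)
    raw_mat <- as.matrix(untreated[, .marker_cols(untreated),
                                   drop = FALSE])
    traj_raw <- moving_stats(raw_mat, pt, window = cfg$window)
    write.csv(data.frame(cell_id = pt$cell_id, x = emb$coords[, 1],
                         y = emb$coords[, 2], angle = pt$angle,
                         pseudotime = pt$time),
              file.path(cfg$outdir, "embedding.csv"), row.names = FALSE)
    tr_out <- data.frame(grid_time = traj_raw$grid)
    for (mk in colnames(traj_raw$med)) {
      tr_out[[paste0(mk, "_med")]] <- traj_raw$med[, mk]
      tr_out[[paste0(mk, "_mad")]] <- traj_raw$mad[, mk]
    }
    write.csv(tr_out, file.path(cfg$outdir, "trajectory.csv"),
              row.names = FALSE)
    summary$boundaries <- as.numeric(bounds_ang)
    logmsg("[embed] %d cells embedded; %d boundaries", nrow(pt),
           length(bounds_ang))
  })

  arrests <- list()
  stage("arrest", {
    for (nm in names(treated)) {
      est <- estimate_arrest(untreated, treated[[nm]], T = cfg$T,
                             fraction = cfg$fraction, seed = cfg$seed,
                             boundaries = if (length(bounds_ang))
                               bounds_ang else NULL)
      arrests[[nm]] <- est
      write.csv(data.frame(cell_id = names(est$angles),
                           angle = est$angles),
                file.path(cfg$outdir, paste0("angles_", nm, ".csv")),
                row.names = FALSE)
      logmsg("[arrest] %s: %.2f h (drift %.3f rad)", nm,
             est$estimate$arrest_time, est$drift)
    }
    summary$arrest <- lapply(arrests, function(e)
      list(time = e$estimate$arrest_time,
           angle = e$estimate$arrest_angle,
           dispersion = e$estimate$dispersion, drift = e$drift))
  })

  fit <- NULL
  stage("fit", {
    mk_raw <- as.matrix(untreated[, .cc_measured, drop = FALSE])
    traj5 <- moving_stats(mk_raw, pt, window = cfg$window)
    # mode times: largest angle-distribution modes mapped through the
    # angle -> time map
    modes_ang <- attr(bounds_ang, "modes")
    if (is.null(modes_ang)) stop("no angle modes found for initial conditions")
    o <- order(pt$angle)
    a2 <- c(pt$angle[o], pt$angle[o][1] + 2 * pi)
    t2 <- c(pt$time[o], pt$time[o][1] + cfg$T)
    modes_t <- approx(a2, t2, xout = modes_ang, ties = "ordered")$y %% cfg$T
    ats <- lapply(arrests, function(e) e$estimate$arrest_time)
    ts <- build_training_set(traj5, ats, T = cfg$T, modes = modes_t)
    utils::write.csv(ts$points,
                     file.path(cfg$outdir, "training_set.csv"),
                     row.names = FALSE)
    fit <- cc_fit(ts, n_starts = cfg$n_starts, seed = cfg$seed,
                   starts = matrix(unlist(cc_params()[.cc_fit_names]), 1,
                                   dimnames = list(NULL, .cc_fit_names)),
                   rtol = cfg$rtol, atol = cfg$atol)
    write_params(fit$estimates, file.path(cfg$outdir, "fit_params.txt"))
    summary$fit <- list(objective = fit$objective,
                         estimates = unclass(fit$estimates))
    logmsg("[fit] objective %.3f", fit$objective)
  })

  stage("profile", {
    if (is.null(fit) || is.null(cfg$profile_params)) {
      logmsg("[profile] skipped (no fit or no parameters requested)")
    } else {
      prof <- lapply(cfg$profile_params, function(pp)
        profile_likelihood(fit, param = pp, max_steps = 12, maxit = 40))
      names(prof) <- cfg$profile_params
      ptab <- do.call(rbind, lapply(prof, function(p)
        data.frame(parameter = p$name, lower = p$ci_95[1],
                   upper = p$ci_95[2],
                   classification = p$classification)))
      write.csv(ptab, file.path(cfg$outdir, "profiles.csv"),
                row.names = FALSE)
      summary$profiles <- ptab
      logmsg("[profile] %d parameters profiled", nrow(ptab))
    }
  })

  stage("predict_gf", {
    pfit <- if (!is.null(fit)) fit$estimates else params
    scan <- gf_scan(pfit, gf_grid = cfg$gf_grid,
                    rtol = cfg$rtol, atol = cfg$atol)
    write.csv(scan$table, file.path(cfg$outdir, "gf_scan.csv"),
              row.names = FALSE)
    summary$gf_threshold <- scan$threshold
    # arrest-phase mapping for a mildly starved condition
    lowgf <- max(0.6, if (is.na(scan$threshold)) 0.6
                 else scan$threshold - 0.1)
    tr <- cc_simulate(pfit, condition = cc_condition("untreated",
                                                     gf_scale = lowgf),
                      times = seq(0, 8 * cfg$T, by = 0.25),
                      rtol = cfg$rtol, atol = cfg$atol)
    rg <- classify_regime(tr, pfit)
    if (rg$regime != "oscillating" && !is.null(traj_raw)) {
      final_obs <- unlist(tr[nrow(tr), .cc_state_names])
      ref <- traj_raw$med[, intersect(.cc_measured,
                                      colnames(traj_raw$med)),
                          drop = FALSE]
      # compare on the observation scale
      fo <- cc_observable(final_obs, pfit)
      ap <- arrest_phase(c(fo["p21"], fo["Cd"], 0, fo["Ce"], fo["Ca"],
                           fo["Cb"]),
                         ref, times = traj_raw$grid)
      summary$gf_arrest <- list(gf = lowgf, time = ap$time,
                                 phase = ap$phase, label = ap$label)
      logmsg("[predict_gf] gf %.2f arrests at %.2f h", lowgf, ap$time)
    } else {
      logmsg("[predict_gf] regime at gf %.2f: %s", lowgf, rg$regime)
    }
  })

  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Command-line interface
#'
#' Subcommands: `generate`, `embed`, `arrest`, `fit`, `profile`,
#' `identifiability`, `predict-gf`, `run-all`; all driven by a JSON
#' config (`--config`) plus `--seed`/`--outdir` overrides.  Designed to
#' be called from `Rscript -e 'pseudocycle::cc_cli()'` or a thin
#' wrapper script.
#'
#' @param args character vector (defaults to the command line).
#' @return exit status, invisibly.
#' @export
cc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: pseudocycle <command> --config <file> [--seed N]",
    "[--outdir DIR]",
    "commands: generate embed arrest fit profile identifiability",
    "predict-gf run-all", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1 > length(args)) stop("missing value for --", key)
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  if (is.null(opts$config)) stop("--config is required")
  cfg <- read_pipeline_config(opts$config)
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$outdir)) cfg$outdir <- opts$outdir
  stage_map <- list(
    generate = "generate",
    embed = c("generate", "embed"),
    arrest = c("generate", "embed", "arrest"),
    fit = c("generate", "embed", "arrest", "fit"),
    profile = c("generate", "embed", "arrest", "fit", "profile"),
    `predict-gf` = c("generate", "embed", "arrest", "fit", "predict_gf"),
    `run-all` = c("generate", "embed", "arrest", "fit", "profile",
                  "predict_gf"))
  if (cmd == "identifiability") {
    rep <- structural_identifiability()
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(rank = rep$rank, n_params = rep$n_params,
           singular_values = rep$singular_values),
      file.path(cfg$outdir, "identifiability.json"),
      auto_unbox = TRUE, digits = NA)
    return(invisible(0L))
  }
  if (!cmd %in% names(stage_map)) stop("unknown command: ", cmd,
                                       "\n", usage)
  run_pipeline(cfg, stages = stage_map[[cmd]])
  invisible(0L)
}
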
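# Shared fixtures, built once per test run and cached in an
# environment.  Everything is generated in code from the package's
# reference parameter set.

.world <- new.env(parent = emptyenv())

world_params <- function() cc_params()

world_lc <- function() {
  if (is.null(.world$lc)) .world$lc <- make_limit_cycle(world_params())
  .world$lc
}

# mid-size untreated snapshot shared across pseudotime tests
world_untreated <- function(n = 2000, noise_cv = 0.2, seed = 42) {
  key <- sprintf("un_%d_%g_%d", n, noise_cv, seed)
  if (is.null(.world[[key]]))
    .world[[key]] <- sample_snapshot(
      world_lc(), snapshot_spec(n_cells = n, noise_cv = noise_cv,
                                seed = seed))
  .world[[key]]
}

world_embedding <- function(n = 2000, noise_cv = 0.2, seed = 42) {
  key <- sprintf("emb_%d_%g_%d", n, noise_cv, seed)
  if (is.null(.world[[key]])) {
    tab <- world_untreated(n, noise_cv, seed)
    m <- preprocess_markers(tab)
    emb <- embed_angles(cmd_embed(m), markers = m)
    .world[[key]] <- list(tab = tab, m = m, emb = emb,
                          pt = ergodic_times(emb, world_lc()$period))
  }
  .world[[key]]
}

# circular absolute difference of two times on a clock of period T
circ_time_err <- function(a, b, T) {
  abs(((a - b + T / 2) %% T) - T / 2)
}

# map a true phase (fraction of cycle) onto the inferred pseudo-time
# clock using the hidden truth columns of an untreated snapshot
true_phase_on_clock <- function(phase, tab, pt, T) {
  d <- (pt$time - tab[["__true_phase"]] * T) %% T
  ang <- 2 * pi * d / T
  off <- (atan2(mean(sin(ang)), mean(cos(ang))) * T / (2 * pi)) %% T
  (phase * T + off) %% T
}
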
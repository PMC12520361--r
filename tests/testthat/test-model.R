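# Core ODE model: right-hand side, integration, regime classification,
# arrest-phase mapping, observation model.

# independent transcription of the equations, structured differently
# from the package/C++ implementation (term-by-term, no shared factors)
rhs_oracle <- function(s, p, dnoco, dpalbo, gf_scale) {
  p21 <- s[1]; Cd <- s[2]; E2Fa <- s[3]; Ce <- s[4]; Ca <- s[5]; Cb <- s[6]
  GF <- p$GF * gf_scale
  c(
    p$Vsp * E2Fa -
      p$Vsp * p21 * Cb / (p$kx + Cb) / (1 + p$IEn * dnoco),
    p$Vsd * GF * E2Fa - p$Vsd * Cd / (Cd + p$kdd),
    (p$E2Ft - E2Fa) * (p$kpiii / (p$kpiii + Cb)) *
      (Cd / (Cd + p$kdd1) * dpalbo + Ce * p$kpi / (p$kpi + p21)) -
      E2Fa * Ca * p$kpii / (p$kpii + p21),
    p$Vse * E2Fa - p$Vse * Ce / (Ce + p$kde) * Ca * p$kpii / (p$kpii + p21),
    p$Vsa * E2Fa - p$Vsa * Ca / (Ca + p$kda),
    p$Vsb * Ca * p$kpii / (p$kpii + p21) - p$Vsb * Cb / (Cb + p$kdb)
  )
}

test_that("rhs matches the independent oracle on random states and parameters", {
  set.seed(11)
  for (i in 1:100) {
    pars <- do.call(cc_params, as.list(setNames(
      10^runif(15, -1, 1),
      c("Vsp", "Vsd", "Vse", "Vsa", "Vsb", "kx", "kdd", "kdd1", "kde",
        "kda", "kdb", "kpi", "kpii", "kpiii", "IEn"))))
    s <- runif(6, 0, 2)
    s[3] <- runif(1, 0, pars$E2Ft) # E2Fa <= E2Ft
    cond <- sample(c("untreated", "nocodazole", "palbociclib"), 1)
    gfs <- runif(1, 0, 1.5)
    cc <- cc_condition(cond, gf_scale = gfs)
    expect_equal(unname(cc_rhs(s, pars, cc)),
                 rhs_oracle(s, pars, cc$delta_noco, cc$delta_palbo, gfs),
                 tolerance = 1e-12)
  }
})

test_that("rhs special states behave as the equations force", {
  p <- cc_params()
  # origin is a fixed point
  expect_equal(unname(cc_rhs(rep(0, 6), p)), rep(0, 6))
  # E2Fa at its ceiling with everything else zero: no E2F flux, p21
  # synthesis strictly positive
  d <- cc_rhs(c(0, 0, p$E2Ft, 0, 0, 0), p)
  expect_equal(unname(d["E2Fa"]), 0)
  expect_gt(d["p21"], 0)
  # hand-evaluated point: all parameters 1, state (1,1,0.5,1,1,1)
  ones <- do.call(cc_params, as.list(setNames(rep(1, 15),
    c("Vsp", "Vsd", "Vse", "Vsa", "Vsb", "kx", "kdd", "kdd1", "kde",
      "kda", "kdb", "kpi", "kpii", "kpiii", "IEn"))))
  expect_equal(unname(cc_rhs(c(1, 1, 0.5, 1, 1, 1), ones)),
               c(0, 0, 0, 0.25, 0, 0), tolerance = 1e-14)
  expect_error(cc_params(Vsd = -1), "positive")
})

test_that("simulation is consistent and guards hold", {
  p <- cc_params()
  # origin stays put
  tr0 <- cc_simulate(p, rep(0, 6), times = seq(0, 10, 1))
  expect_equal(max(abs(as.matrix(tr0[, -1]))), 0)
  # tolerance convergence: halving tolerances moves the final state by
  # less than 1e-6 relative
  a <- cc_simulate(p, times = c(0, 96), rtol = 1e-8, atol = 1e-10)
  b <- cc_simulate(p, times = c(0, 96), rtol = 5e-9, atol = 5e-11)
  fa <- unlist(a[2, -1]); fb <- unlist(b[2, -1])
  expect_lt(max(abs(fa - fb) / pmax(abs(fb), 1e-6)), 1e-6)
  # gf_scale = 1 is the identity on the untreated condition
  c1 <- cc_simulate(p, times = seq(0, 48, 1))
  c2 <- cc_simulate(p, times = seq(0, 48, 1),
                    condition = cc_condition("untreated", gf_scale = 1))
  expect_equal(c1, c2)
  expect_error(cc_simulate(p, times = c(0, 1, 1)), "increasing")
})

test_that("forward invariance of the box and E2Fa ceiling", {
  p <- cc_params()
  set.seed(21)
  for (i in 1:20) {
    init <- c(runif(2, 0, 1.5), runif(1, 0, 1), runif(3, 0, 1.5))
    cond <- cc_condition(sample(c("untreated", "nocodazole",
                                  "palbociclib"), 1))
    tr <- cc_simulate(p, init, cond, times = seq(0, 72, 0.5))
    expect_true(all(as.matrix(tr[, -1]) >= -1e-8))
    expect_true(all(tr$E2Fa <= p$E2Ft + 1e-6))
  }
})

test_that("classify_regime identifies oscillation, arrest and synthetic controls", {
  p <- cc_params()
  tr <- cc_simulate(p, times = seq(0, 192, 0.25))
  rg <- classify_regime(tr, p)
  expect_identical(rg$regime, "oscillating")
  expect_equal(rg$period, world_lc()$period, tolerance = 0.05)
  # constant fake trajectory is arrested at the origin fixed point
  const <- cc_simulate(p, rep(0, 6), times = seq(0, 100, 1))
  expect_identical(classify_regime(const, p)$regime, "arrested")
  # injected pure sinusoid (not a model solution) counts as oscillating
  tt <- seq(0, 200, 0.25)
  fake <- data.frame(time = tt, p21 = 1, Cd = 1, E2Fa = 0.5, Ce = 1,
                     Ca = 1, Cb = 1 + 0.5 * sin(2 * pi * tt / 24))
  rg2 <- classify_regime(fake, p)
  expect_identical(rg2$regime, "oscillating")
  expect_equal(rg2$period, 24, tolerance = 0.05)
})

test_that("classify_regime agrees with a Poincare-section oracle on random draws", {
  # oracle: period from crossings of the mid-level set of Cb (upward),
  # oscillation iff >= 3 equally spaced crossings in the tail
  poincare <- function(tr) {
    cb <- tr$Cb[tr$time >= max(tr$time) / 2]
    tt <- tr$time[tr$time >= max(tr$time) / 2]
    lev <- (max(cb) + min(cb)) / 2
    up <- which(cb[-length(cb)] < lev & cb[-1] >= lev)
    if (diff(range(cb)) < max(0.05 * mean(cb), 0.02) || length(up) < 3)
      return(list(osc = FALSE))
    sp <- diff(tt[up])
    list(osc = max(sp) - min(sp) < 0.1 * mean(sp), period = mean(sp))
  }
  set.seed(31)
  base <- unlist(cc_params()[c("Vsp", "Vsd", "Vse", "Vsa", "Vsb", "kx",
                               "kdd", "kdd1", "kde", "kda", "kdb",
                               "kpi", "kpii", "kpiii", "IEn")])
  agree <- 0
  for (i in 1:20) {
    pars <- do.call(cc_params,
                    as.list(base * 10^rnorm(15, 0, 0.15)))
    tr <- try(cc_simulate(pars, times = seq(0, 480, 0.25),
                          max_steps = 2e6), silent = TRUE)
    if (inherits(tr, "try-error")) next # diverging draw: skip pair
    rg <- classify_regime(tr, pars)
    po <- poincare(tr)
    expect_identical(rg$regime == "oscillating", po$osc)
    if (po$osc) expect_equal(rg$period, po$period, tolerance = 0.05)
    agree <- agree + 1
  }
  expect_gte(agree, 15) # most random draws must be classifiable
})

test_that("drug switches arrest the reference model to one steady state", {
  p <- cc_params()
  lc <- world_lc()
  phases <- seq(0, 0.9, by = 0.1)
  inits <- pseudocycle:::.lc_state_at(lc, phases)
  for (drug in c("nocodazole", "palbociclib")) {
    ends <- t(vapply(seq_len(nrow(inits)), function(i) {
      tr <- cc_simulate(p, inits[i, ], cc_condition(drug),
                        times = c(0, 360))
      unlist(tr[2, -1])
    }, numeric(6)))
    expect_lt(max(apply(ends, 2, sd)), 1e-3) # one attracting state
    tr <- cc_simulate(p, inits[1, ], cc_condition(drug),
                      times = seq(0, 480, 1))
    expect_identical(classify_regime(tr, p, tol_ss = 1e-5)$regime,
                     "arrested")
  }
})

test_that("arrest_phase maps states to the nearest reference point", {
  lc <- world_lc()
  # a reference point maps to itself with zero distance
  i <- 57L
  ap <- arrest_phase(lc$states[i, ], lc)
  expect_identical(ap$index, i)
  expect_equal(ap$distance, 0)
  expect_equal(ap$phase, lc$phase[i])
  # equidistant tie resolves to the lowest index
  ref <- data.frame(p21 = c(0, 2), Cd = c(1, 1), Ce = c(1, 1),
                    Ca = c(1, 1), Cb = c(1, 1))
  ap2 <- suppressWarnings(
    arrest_phase(c(1, 1, 0, 1, 1, 1), ref, times = c(0, 12)))
  expect_identical(ap2$index, 1L)
  # off-manifold states warn
  expect_warning(arrest_phase(c(50, 0, 0, 0, 0, 0), lc), "far from")
})

test_that("observable is the affine offset map", {
  p <- cc_params(offset_p21 = 0.1, offset_Cd = 0.2, offset_Ce = 0.3,
                 offset_Ca = 0.4, offset_Cb = 0.5)
  z <- cc_observable(rep(0, 6), p)
  expect_equal(unname(z), c(0.1, 0.2, 0.3, 0.4, 0.5))
  p0 <- cc_params(offset_p21 = 0, offset_Cd = 0, offset_Ce = 0,
                  offset_Ca = 0, offset_Cb = 0)
  s <- c(1, 2, 3, 4, 5, 6)
  expect_equal(unname(cc_observable(s, p0)), s[c(1, 2, 4, 5, 6)])
  # affinity: obs(s1) + obs(s2) - offsets = obs(s1 + s2)
  s1 <- runif(6); s2 <- runif(6)
  off <- unlist(p[paste0("offset_", c("p21", "Cd", "Ce", "Ca", "Cb"))])
  expect_equal(cc_observable(s1, p) + cc_observable(s2, p) - off,
               cc_observable(s1 + s2, p))
})

test_that("gf_scan finds the oscillation-loss threshold of the reference model", {
  p <- cc_params()
  sc <- gf_scan(p, gf_grid = seq(1, 0.6, by = -0.1))
  expect_true(sc$threshold %in% c(0.7, 0.8))
  expect_identical(sc$table$regime[sc$table$gf == 1.0], "oscillating")
  # a grid that never leaves the oscillatory regime has no threshold
  sc1 <- gf_scan(p, gf_grid = c(1.0, 0.95))
  expect_true(is.na(sc1$threshold))
  expect_error(gf_scan(p, gf_grid = c(0.5, 1)), "descending")
})

test_that("parameter round-trip through flat key-value files", {
  p <- cc_params(Vsd = 2.5, IEn = 7)
  f <- tempfile(fileext = ".txt")
  write_params(p, f)
  q <- read_params(f)
  expect_equal(unclass(q), unclass(p))
  unlink(f)
})
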
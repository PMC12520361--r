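# Training: training-set construction, the soft-constraint likelihood,
# fitting, profiles and structural identifiability.

make_fake_traj <- function(T = 24, grid_n = 50) {
  grid <- seq(0, T, length.out = grid_n + 1)[seq_len(grid_n)]
  med <- cbind(p21 = 1 + 0.5 * sin(2 * pi * grid / T),
               Cd = 0.5 + 0.2 * cos(2 * pi * grid / T),
               Ce = 0.3 + 0.1 * sin(4 * pi * grid / T),
               Ca = 1 + 0.3 * cos(2 * pi * grid / T + 1),
               Cb = 0.8 + 0.6 * sin(2 * pi * grid / T + 2))
  structure(list(grid = grid, med = med, mad = med * 0 + 0.05,
                 window = 51, T = T),
            class = "marker_trajectory")
}

test_that("build_training_set tiles cycles and arrest copies as specified", {
  traj <- make_fake_traj()
  ts <- build_training_set(traj, arrests = list(nocodazole = 3,
                                                palbociclib = 5),
                           T = 24, modes = c(4, 18))
  pts <- ts$points
  un <- pts[pts$condition == "untreated", ]
  # 10 points per cycle x 4 cycles x 5 markers x 2 initial conditions
  expect_equal(nrow(un), 40 * 5 * 2)
  expect_true(all(un$time >= 0 & un$time < 96))
  # the tiled copies repeat with period T
  one <- un[un$marker == "Cb" & un$init_id == 1, ]
  expect_equal(one$value[1:10], one$value[11:20])
  # the phase shift between the two initial conditions matches the modes
  a1 <- un[un$marker == "p21" & un$init_id == 1 & un$time == 0, "value"]
  expect_equal(a1, approx(c(traj$grid, 24), c(traj$med[, "p21"],
                                              traj$med[1, "p21"]),
                          xout = 4)$y)
  # arrest rows: 10 identical copies per drug, marker and init, with
  # times in [T, 4T]
  ar <- pts[pts$condition == "nocodazole" & pts$marker == "Ca" &
            pts$init_id == 2, ]
  expect_equal(nrow(ar), 10)
  expect_equal(length(unique(ar$value)), 1L)
  expect_true(all(ar$time >= 24 & ar$time <= 96))
  # sigma floor engages when mad is zero
  traj0 <- traj; traj0$mad[] <- 0
  ts0 <- build_training_set(traj0, list(nocodazole = 3), T = 24,
                            modes = c(4, 18))
  expect_true(all(ts0$points$sigma > 0))
  expect_error(build_training_set(traj, list(), T = 24, modes = NA),
               "modes")
})

test_that("nll is the exact Gaussian objective with scaling identities", {
  p <- cc_params()
  stt <- simulate_training_set(p, lc = world_lc(), seed = 3)
  # reduced chi-square ~ 1 at the generating parameters
  v <- cc_nll(stt$truth, stt$ts)
  const <- sum(log(stt$ts$points$sigma * sqrt(2 * pi)))
  red <- 2 * (v - const) / nrow(stt$ts$points)
  expect_gt(red, 0.8); expect_lt(red, 1.2)
  # model output identical to data: only the constant term remains
  exact <- stt$ts
  blocks <- pseudocycle:::.prep_ts(exact)
  # rebuild values from a noiseless evaluation (residuals come back in
  # block order; map through each block's source rows)
  r <- pseudocycle:::.res_eval(stt$truth, blocks, exact, 1e-8, 1e-10)
  idx <- unlist(lapply(blocks, `[[`, "rows_idx"))
  exact$points$value[idx] <- exact$points$value[idx] +
    r * exact$points$sigma[idx]
  expect_equal(cc_nll(stt$truth, exact, rtol = 1e-8, atol = 1e-10),
               sum(log(exact$points$sigma * sqrt(2 * pi))),
               tolerance = 1e-6)
  # doubling sigmas divides the weighted SSE by 4
  ts2 <- stt$ts; ts2$points$sigma <- 2 * ts2$points$sigma
  sse1 <- cc_nll(stt$truth, stt$ts) - const
  const2 <- sum(log(ts2$points$sigma * sqrt(2 * pi)))
  sse2 <- cc_nll(stt$truth, ts2) - const2
  expect_equal(sse2, sse1 / 4, tolerance = 1e-8)
})

test_that("nll stays finite along a random segment through bad regions", {
  p <- cc_params()
  stt <- simulate_training_set(p, lc = world_lc(), seed = 4)
  truth_lp <- log10(unlist(stt$truth[pseudocycle:::.cc_fit_names]))
  set.seed(18)
  other <- truth_lp + rnorm(22, 0, 1.5) # far away, mostly non-oscillatory
  fn <- pseudocycle:::.nll_log10(stt$ts)
  vals <- vapply(seq(0, 1, length.out = 21), function(w) {
    fn((1 - w) * truth_lp + w * other)
  }, 0.0)
  expect_true(all(is.finite(vals)))
})

test_that("fit recovers the generator and is deterministic under a seed", {
  p <- cc_params()
  stt <- simulate_training_set(p, lc = world_lc(), seed = 5)
  truth_v <- unlist(stt$truth[pseudocycle:::.cc_fit_names])
  set.seed(19)
  starts <- matrix(truth_v * 10^rnorm(22, 0, 0.12), 1,
                   dimnames = list(NULL, pseudocycle:::.cc_fit_names))
  fit <- cc_fit(stt$ts, n_starts = 0, starts = starts, seed = 1,
                maxit = 40)
  # optimality: at least as good as the truth
  expect_lte(fit$objective, cc_nll(stt$truth, stt$ts) + 1e-6)
  est <- unlist(fit$estimates[pseudocycle:::.cc_fit_names])
  frac_ok <- mean(abs(log(est / truth_v)) < log(1.25))
  expect_gte(frac_ok, 0.8)
  fit2 <- cc_fit(stt$ts, n_starts = 0, starts = starts, seed = 1,
                 maxit = 40)
  expect_identical(fit$par_log10, fit2$par_log10)
})

test_that("profile_objective matches the linear-Gaussian closed form", {
  # quadratic toy objective: nll of y = a + b x with known sigma
  set.seed(20)
  x <- seq(-1, 1, length.out = 40)
  sigma <- 0.3
  y <- 1.5 + 0.8 * x + rnorm(40, 0, sigma)
  fn <- function(th) sum((y - th[1] - th[2] * x)^2) / (2 * sigma^2)
  co <- coef(lm(y ~ x))
  par <- c(a = unname(co[1]), b = unname(co[2]))
  pr <- profile_objective(fn, par, "b", lower = c(-10, -10),
                          upper = c(10, 10), step0 = 0.02)
  # analytic profile CI: b_hat +- 1.96 sigma / sqrt(sum((x - xbar)^2))
  se <- sigma / sqrt(sum((x - mean(x))^2))
  expect_identical(pr$classification, "identifiable")
  expect_equal(pr$ci[1], par["b"] - 1.96 * se, tolerance = 0.01,
               ignore_attr = TRUE)
  expect_equal(pr$ci[2], par["b"] + 1.96 * se, tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("a structurally degenerate product pair yields a flat profile", {
  # model depends only on the product th1 * th2
  set.seed(22)
  x <- seq(0.1, 2, length.out = 30)
  y <- 2 * x + rnorm(30, 0, 0.1)
  fn <- function(th) sum((y - th[1] * th[2] * x)^2) / (2 * 0.01)
  opt <- optim(c(1, 2), fn, method = "BFGS")
  # bounds chosen so the compensating parameter never saturates inside
  # the scanned range: the profile stays flat to both bounds
  pr <- profile_objective(fn, setNames(opt$par, c("t1", "t2")), "t1",
                          lower = c(0.01, 1e-3), upper = c(100, 1e3),
                          step0 = 0.5, max_steps = 25)
  expect_identical(pr$classification, "non-identifiable")
  expect_true(all(is.infinite(pr$ci)))
})

test_that("structural identifiability: full design has full rank, untreated-only drops IEn", {
  p <- cc_params()
  rep_full <- structural_identifiability(p)
  expect_equal(rep_full$rank, rep_full$n_params)
  rep_un <- structural_identifiability(
    p, identifiability_design(conditions = "untreated"))
  expect_equal(rep_un$rank, rep_un$n_params - 1L)
  expect_identical(unlist(rep_un$null_combinations), "IEn")
  # duplicating a parameter via an extra scale on Vsa*kda-like pairing:
  # emulate by adding a column identical to another (rank drops by 1)
  # -- constructed directly on the sensitivity matrix contract
  S <- matrix(rnorm(200), 20)
  S2 <- cbind(S, S[, 3])
  sv <- svd(S2)$d
  tol <- max(sv) * 1e-8 * max(dim(S2))
  expect_equal(sum(sv > tol), 10L)
})

test_that("removing arrest data widens (or keeps) profile intervals", {
  p <- cc_params()
  stt <- simulate_training_set(p, lc = world_lc(), seed = 6)
  un_only <- simulate_training_set(p, lc = world_lc(), seed = 6,
                                   drugs = character(0))
  truth_v <- unlist(stt$truth[pseudocycle:::.cc_fit_names])
  set.seed(23)
  starts <- matrix(truth_v * 10^rnorm(22, 0, 0.1), 1,
                   dimnames = list(NULL, pseudocycle:::.cc_fit_names))
  fit_j <- cc_fit(stt$ts, n_starts = 0, starts = starts, seed = 1,
                  maxit = 40)
  fit_u <- cc_fit(un_only$ts, n_starts = 0, starts = starts, seed = 1,
                  maxit = 40)
  for (pp in c("IEn", "kdd1")) {
    pr_j <- profile_likelihood(fit_j, param = pp, max_steps = 10,
                               maxit = 15)
    pr_u <- profile_likelihood(fit_u, param = pp, max_steps = 10,
                               maxit = 15)
    w_j <- diff(log10(pr_j$ci_95))
    w_u <- diff(log10(pr_u$ci_95))
    # exact profiles satisfy w_u >= w_j; allow the numerical crossing
    # location a small slack
    expect_gte(w_u, w_j - 0.05)
  }
  # IEn never enters untreated dynamics: its untreated-only profile is
  # flat (non- or at best partially identifiable)
  pr_ien <- profile_likelihood(fit_u, param = "IEn", max_steps = 8,
                               maxit = 10)
  expect_true(pr_ien$classification != "identifiable")
})
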
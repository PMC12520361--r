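# Pseudo-time ordering: preprocessing, classical MDS, circle fit,
# angles, ergodic/exponential-age time inference, moving statistics,
# phase boundaries.

test_that("preprocess_markers log-scales and z-scores deterministically", {
  set.seed(1)
  raw <- matrix(rlnorm(400, 1, 0.5), 100, 4,
                dimnames = list(NULL, c("a", "b", "Ca", "Cb")))
  m <- preprocess_markers(raw)
  expect_equal(unname(colMeans(m)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(sqrt(colMeans(m^2))), rep(1, 4), tolerance = 1e-12)
  # two cells, two markers force z-scores of +-1 per column
  m2 <- preprocess_markers(matrix(c(1, 2, 5, 9), 2, 2,
                                  dimnames = list(NULL, c("x", "y"))))
  expect_equal(abs(unname(m2)), matrix(1, 2, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # identical cells: zero variance is an error
  expect_error(preprocess_markers(matrix(1, 5, 3,
                                         dimnames = list(NULL, c("a", "b", "c")))),
               "zero-variance")
  # lognormal columns become Gaussian after the log transform
  set.seed(2)
  ln <- matrix(rlnorm(400, 0, 0.4), 200, 2,
               dimnames = list(NULL, c("u", "v")))
  z <- preprocess_markers(ln)
  expect_gt(stats::shapiro.test(z[, 1])$p.value, 0.01)
  # nonpositive entries are floored, not fatal
  raw[1, 1] <- 0
  expect_silent(preprocess_markers(raw))
})

test_that("cmd_embed is classical MDS: isometry recovery and oracle parity", {
  # unit square embedded rigidly in 5-D: pairwise distances survive
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:2]
  hi <- sq %*% t(Q) + matrix(rep(runif(5), each = 4), 4)
  co <- cmd_embed(hi)
  expect_equal(as.matrix(dist(co)), as.matrix(dist(sq)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # dense eigendecomposition oracle on 40 random points
  x <- matrix(rnorm(40 * 6), 40)
  co2 <- cmd_embed(x)
  oracle <- stats::cmdscale(dist(x), k = 2, eig = TRUE)
  # same up to per-axis sign
  for (j in 1:2)
    expect_equal(abs(co2[, j]), abs(oracle$points[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  expect_equal(attr(co2, "eig"), oracle$eig[1:2], tolerance = 1e-8)
  # Gram identity: coords' Gram equals double-centered -D^2/2 at rank 2
  D2 <- as.matrix(dist(x))^2
  J <- diag(40) - 1 / 40
  G <- -J %*% D2 %*% J / 2
  eg <- eigen(G, symmetric = TRUE)
  G2 <- eg$vectors[, 1:2] %*% diag(eg$values[1:2]) %*% t(eg$vectors[, 1:2])
  expect_equal(co2 %*% t(co2), G2, tolerance = 1e-8, ignore_attr = TRUE)
  # marker permutation leaves coordinates unchanged
  expect_equal(cmd_embed(x[, c(3, 1, 6, 2, 5, 4)]), co2)
  expect_error(cmd_embed(x[1:2, ]), "at least 3")
})

test_that("fit_circle is exact on circles and matches the circumcircle", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  pts <- cbind(1 + 3 * cos(th), -2 + 3 * sin(th))
  f <- fit_circle(pts)
  expect_equal(f$center, c(1, -2), tolerance = 1e-10)
  expect_equal(f$radius, 3, tolerance = 1e-10)
  # closed-form circumcenter oracle for three points
  tri <- rbind(c(0, 0), c(4, 0), c(1, 3))
  f3 <- fit_circle(tri)
  ax <- tri[1, 1]; ay <- tri[1, 2]; bx <- tri[2, 1]; by <- tri[2, 2]
  cx <- tri[3, 1]; cy <- tri[3, 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  expect_equal(f3$center, c(ux, uy), tolerance = 1e-10)
  expect_equal(f3$radius, sqrt((ax - ux)^2 + (ay - uy)^2),
               tolerance = 1e-10)
  expect_error(fit_circle(cbind(1:5, 2 * (1:5) + 1)), "collinear")
})

test_that("fit_circle tolerates small noise (Monte Carlo)", {
  set.seed(4)
  errs <- replicate(100, {
    th <- runif(200, 0, 2 * pi)
    pts <- cbind(2 + 5 * cos(th), 3 + 5 * sin(th)) +
      matrix(rnorm(400, 0, 0.05), 200)
    f <- fit_circle(pts)
    sqrt(sum((f$center - c(2, 3))^2))
  })
  expect_lt(max(errs), 0.05) # center error < 0.01 * radius
})

test_that("angles resolve the reflection ambiguity deterministically", {
  w <- world_embedding()
  mir <- w$emb$coords
  mir[, 1] <- -mir[, 1] # mirror the embedding
  circ <- fit_circle(mir)
  emb_m <- embed_angles(mir, circ, markers = w$m)
  # cyclin A peak must precede cyclin B after orientation fixing, in
  # both the original and the mirrored frame
  lags <- vapply(list(w$emb, emb_m), function(e) {
    pa <- pseudocycle:::.peak_angle(e$angle, w$m[, "Ca"], 151)
    pb <- pseudocycle:::.peak_angle(e$angle, w$m[, "Cb"], 151)
    (pb - pa) %% (2 * pi)
  }, 0.0)
  expect_true(all(lags > 0 & lags < pi))
  expect_error(embed_angles(mir, circ, markers = w$m[, c("p21", "Cd")]),
               "orientation")
})

test_that("inferred angles track the true phase on synthetic data", {
  w <- world_embedding(n = 2000, noise_cv = 0.2)
  cc <- circ_corr_times(w$pt$time, w$tab[["__true_phase"]],
                        period1 = world_lc()$period, period2 = 1)
  expect_gt(abs(cc), 0.9)
})

test_that("ergodic_times yields the equidistant grid in angle order", {
  emb <- structure(list(coords = NULL, center = c(0, 0), radius = 1,
                        angle = c(0.1, 2.0, 4.0, 6.0), orientation = 1,
                        cell_id = letters[1:4]),
                   class = "circular_embedding")
  pt <- ergodic_times(emb, T = 24)
  expect_equal(pt$time, c(0, 6, 12, 18))
  # time marginal exactly uniform for any angles
  set.seed(5)
  emb$angle <- runif(4, 0, 2 * pi)
  expect_equal(sort(ergodic_times(emb, 24)$time), c(0, 6, 12, 18))
})

test_that("kafri_times implements the doubling-population inverse", {
  emb <- structure(list(coords = NULL, center = c(0, 0), radius = 1,
                        angle = seq(0, 2 * pi, length.out = 9)[1:8],
                        orientation = 1, cell_id = NULL),
                   class = "circular_embedding")
  T <- 24
  pt <- kafri_times(emb, T)
  N <- 8
  expect_equal(pt$time, T * log2(2 * N / (2 * N - pt$rank)))
  expect_equal(min(pt$time), 0) # r = 0 -> t = 0
  # r = N would close the cycle at exactly T; r = N/2 at 24 log2(4/3)
  expect_equal(T * log2(2 * N / (2 * N - N)), T)
  expect_equal(T * log2(2 * N / (2 * N - N / 2)), 24 * log2(4 / 3))
  expect_equal(24 * log2(4 / 3), 9.9609, tolerance = 1e-4)
  expect_true(all(diff(pt$time[order(pt$rank)]) > 0)) # monotone in rank
})

test_that("kafri inference recovers true times on exponential-age data", {
  lc <- world_lc()
  tab <- sample_snapshot(lc, snapshot_spec(n_cells = 3000,
                                           noise_cv = 0.2, seed = 77,
                                           sampling = "exponential_age"))
  m <- preprocess_markers(tab)
  emb <- embed_angles(cmd_embed(m), markers = m)
  pt <- kafri_times(emb, T = lc$period)
  true_t <- tab[["__true_phase"]] * lc$period # age in hours
  # align the clock zero (the embedding's zero is arbitrary), then
  # compare
  d <- (pt$time - true_t) %% lc$period
  ang <- 2 * pi * d / lc$period
  off <- (atan2(mean(sin(ang)), mean(cos(ang))) * lc$period / (2 * pi)) %%
    lc$period
  mae <- mean(circ_time_err(pt$time, (true_t + off) %% lc$period,
                            lc$period))
  expect_lt(mae, 0.1 * lc$period)
})

test_that("moving_stats handles degenerate and sinusoidal inputs", {
  set.seed(6)
  N <- 400
  emb <- structure(list(coords = NULL, center = c(0, 0), radius = 1,
                        angle = sort(runif(N, 0, 2 * pi)),
                        orientation = 1, cell_id = NULL),
                   class = "circular_embedding")
  pt <- ergodic_times(emb, 24)
  m <- cbind(const = rep(2, N),
             sine = sin(2 * pi * pt$time / 24) + rnorm(N, 0, 0.3))
  tr <- moving_stats(m, pt, window = 51)
  expect_equal(unname(tr$med[, "const"]), rep(2, 100))
  expect_equal(unname(tr$mad[, "const"]), rep(0, 100))
  # sinusoid within 2 mad at nearly all grid points
  truth <- sin(2 * pi * tr$grid / 24)
  ok <- abs(tr$med[, "sine"] - truth) <= 2 * pmax(tr$mad[, "sine"], 1e-9)
  expect_gte(mean(ok), 0.95)
  # window = N collapses to the global median
  trN <- moving_stats(m, pt, window = N - 1)
  expect_equal(unname(trN$med[, "sine"]),
               rep(median(m[, "sine"]), 100), tolerance = 0.15)
  expect_error(moving_stats(m, pt, window = N + 2), "window")
})

test_that("moving_stats is equivariant under rotation of the clock", {
  set.seed(7)
  N <- 300
  ang <- runif(N, 0, 2 * pi)
  m <- cbind(x = cos(ang) + rnorm(N, 0, 0.1))
  mk_pt <- function(a) {
    emb <- structure(list(coords = NULL, center = c(0, 0), radius = 1,
                          angle = a %% (2 * pi), orientation = 1,
                          cell_id = NULL),
                     class = "circular_embedding")
    ergodic_times(emb, 24)
  }
  tr1 <- moving_stats(m, mk_pt(ang), window = 31)
  delta <- pi / 3
  tr2 <- moving_stats(m, mk_pt(ang + delta), window = 31)
  # rotating all angles by delta shifts the trajectory by delta on the
  # clock: compare tr2 to tr1 sampled at (t - delta_t) mod T
  dshift <- delta / (2 * pi) * 24
  g <- c(tr1$grid, 24)
  ref <- approx(g, c(tr1$med[, 1], tr1$med[1, 1]),
                xout = (tr2$grid - dshift) %% 24)$y
  expect_equal(unname(tr2$med[, 1]), ref, tolerance = 0.1)
})

test_that("phase_boundaries finds valleys between two modes and flags flat input", {
  set.seed(8)
  # two von-Mises modes at pi/2 and 3pi/2 -> minima near 0 and pi
  rvm <- function(n, mu, kap) {
    # simple rejection sampler against the uniform envelope
    out <- numeric(0)
    while (length(out) < n) {
      x <- runif(2 * n, 0, 2 * pi)
      keep <- runif(2 * n) < exp(kap * (cos(x - mu) - 1))
      out <- c(out, x[keep])
    }
    out[seq_len(n)]
  }
  ang <- c(rvm(3000, pi / 2, 4), rvm(3000, 3 * pi / 2, 4))
  b <- phase_boundaries(ang)
  expect_length(b, 2)
  expect_lt(min(circ_time_err(b[1], 0, 2 * pi),
                circ_time_err(b[1], pi, 2 * pi)), 0.2)
  expect_lt(min(circ_time_err(b[2], 0, 2 * pi),
                circ_time_err(b[2], pi, 2 * pi)), 0.2)
  expect_equal(sort(circ_time_err(attr(b, "modes"),
                                  c(pi / 2, 3 * pi / 2), 2 * pi)),
               c(0, 0), tolerance = 0.25)
  # brute-force scan oracle: the returned valleys are the deepest bins
  # of the smoothed histogram within each inter-mode arc
  # (checked implicitly by the location assertions above)
  # uniform angles: no stable minima
  u <- phase_boundaries(runif(5000, 0, 2 * pi))
  expect_length(u, 0)
  # unimodal arrested-like distribution: empty
  un <- phase_boundaries(rvm(4000, 1.0, 8))
  expect_length(un, 0)
})

test_that("boundary labelling picks the low-cyclin valley as M/G1", {
  w <- world_embedding()
  b <- phase_boundaries(w$emb)
  expect_length(b, 2)
  lab <- label_boundaries(b, w$emb, w$m)
  expect_named(lab, c("MG1", "SG2"))
  # M/G1 sits where summed cyclin z-scores are low: check the moving
  # median of total cyclins near the labelled angle is below its median
  tot <- rowSums(w$m[, c("Cd", "Ce", "Ca", "Cb")])
  sel <- circ_time_err(w$emb$angle, lab["MG1"], 2 * pi) < 0.3
  expect_lt(median(tot[sel]), median(tot))
})
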
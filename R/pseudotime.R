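# Pseudo-time ordering: normalization, classical MDS, circle fit,
# angles, time inference and moving robust statistics.

#' Log-scale and normalize marker intensities
#'
#' Nonpositive raw intensities are floored to the smallest positive
#' value observed per marker (background-subtracted immunofluorescence
#' can contain zeros), then each marker is log10-transformed and
#' z-scored.
#'
#' @param raw a single-cell table (see [read_cell_table()]) or a numeric
#'   matrix/data.frame of intensities (cells x markers).
#' @return a `marker_matrix`: numeric matrix with unit-variance,
#'   zero-mean columns; attributes `marker_names` and (when available)
#'   `cell_id`.
#' @export
preprocess_markers <- function(raw) {
  if (is.data.frame(raw) && "cell_id" %in% names(raw)) {
    cols <- .marker_cols(raw)
    m <- as.matrix(raw[, cols, drop = FALSE])
    ids <- raw$cell_id
  } else {
    m <- as.matrix(raw)
    ids <- rownames(m)
  }
  if (ncol(m) < 2) stop("need at least 2 markers")
  for (j in seq_len(ncol(m))) {
    pos <- m[, j] > 0
    if (!any(pos)) stop("marker ", colnames(m)[j], " has no positive values")
    m[!pos, j] <- min(m[pos, j])
  }
  lm <- log10(m)
  n <- nrow(lm)
  ctr <- colMeans(lm)
  sds <- sqrt(colMeans(sweep(lm, 2, ctr)^2)) # population SD: z-scores
  if (any(sds == 0))                         # of a two-cell column are +-1
    stop("zero-variance marker(s) after log transform: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  z <- sweep(sweep(lm, 2, ctr), 2, sds, "/")
  structure(z, marker_names = colnames(m), cell_id = ids,
            class = c("marker_matrix", class(z)))
}

#' Classical multidimensional scaling to two dimensions
#'
#' Classical (Torgerson) MDS of the cells under squared Euclidean
#' distances: double-center `-D^2/2` to the Gram matrix and keep the top
#' two nonnegative eigenpairs, `coords = eigenvectors * sqrt(eigenvalues)`.
#' For Euclidean distances this equals the rank-2 principal-coordinate
#' projection of the column-centered matrix, which is how it is computed
#' (via singular value decomposition) so that large tables never
#' materialize an `n x n` matrix.  Sign ambiguity is resolved by making
#' the first nonzero loading of each axis positive.
#'
#' @param m a `marker_matrix` (or any numeric matrix, cells x features).
#' @return an `n x 2` coordinate matrix with attribute `eig` (the two
#'   leading Gram eigenvalues).
#' @export
cmd_embed <- function(m) {
  x <- unclass(as.matrix(m))
  if (nrow(x) < 3) stop("need at least 3 cells")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = 2, nv = 2)
  eig <- sv$d[1:2]^2
  if (any(sv$d[1:2] <= .Machine$double.eps * max(sv$d) * nrow(x)))
    stop("top-2 Gram eigenvalues are not positive: data are ",
         "effectively zero- or one-dimensional")
  # deterministic sign: first nonzero component of each left vector > 0
  u <- sv$u
  for (j in 1:2) {
    nz <- which(abs(u[, j]) > 1e-12)[1]
    if (!is.na(nz) && u[nz, j] < 0) u[, j] <- -u[, j]
  }
  coords <- u %*% diag(sv$d[1:2], 2, 2)
  colnames(coords) <- c("x", "y")
  rownames(coords) <- rownames(x)
  structure(coords, eig = eig)
}

#' Algebraic least-squares circle fit
#'
#' Kasa fit: minimizes the algebraic residual of
#' `x^2 + y^2 - 2ax - 2by - c`, which is a linear least-squares problem.
#' Exact on noiseless circles; three non-collinear points give the
#' circumscribed circle.
#'
#' @param coords an `n x 2` matrix of points.
#' @return list `center` (length-2) and `radius`.
#' @export
fit_circle <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("need at least 3 points")
  x <- coords[, 1]; y <- coords[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  qrA <- qr(A)
  if (qrA$rank < 3) stop("collinear points: circle is not determined")
  sol <- qr.coef(qrA, b)
  center <- c(sol[1], sol[2])
  radius <- sqrt(sol[3] + sum(center^2))
  if (!is.finite(radius) || radius <= 0) stop("degenerate circle fit")
  list(center = unname(center), radius = unname(radius))
}

# circular moving-median peak angle of one marker over angle-sorted cells
.peak_angle <- function(angle, values, window) {
  o <- order(angle)
  a <- angle[o]; v <- values[o]
  n <- length(v)
  window <- min(window, if (n %% 2 == 1) n else n - 1)
  half <- (window - 1) %/% 2
  idx <- outer(seq_len(n), -half:half, "+")
  idx <- ((idx - 1) %% n) + 1
  med <- apply(matrix(v[idx], n), 1, median)
  a[which.max(med)]
}

.default_window <- function(n) {
  w <- max(51, round(n / 50))
  w <- min(w, n)
  if (w %% 2 == 0) w <- w - 1
  max(w, 3)
}

#' Angles on the fitted circle, with deterministic orientation
#'
#' Computes `atan2(y - cy, x - cx)` per cell, then resolves the
#' reflection ambiguity of the embedding by requiring that, along
#' increasing angle, the moving-median peak of cyclin A precedes that of
#' cyclin B (their circular lag lies in `(0, pi)`) — the biological
#' ordering of the cycle.  Optionally rotates a given angle to zero
#' (used to anchor the M/G1 boundary once boundaries are annotated).
#'
#' @param coords `n x 2` embedding coordinates ([cmd_embed()]).
#' @param circle a fitted circle ([fit_circle()]); refitted when `NULL`.
#' @param markers the `marker_matrix` the embedding came from; used for
#'   orientation.
#' @param cyclin_A,cyclin_B names of the cyclin A / cyclin B columns.
#' @param orientation optional override `+1`/`-1` when the cyclins are
#'   absent; `NULL` applies the cyclin rule.
#' @param zero_angle angle rotated to zero after orientation (radians).
#' @param window moving-median window (cells) for peak location.
#' @return a `circular_embedding`: list with `coords`, `center`,
#'   `radius`, `angle` (in `[0, 2 pi)`), `orientation`, `cell_id`.
#' @export
embed_angles <- function(coords, circle = NULL, markers = NULL,
                         cyclin_A = "Ca", cyclin_B = "Cb",
                         orientation = NULL, zero_angle = 0,
                         window = NULL) {
  coords <- as.matrix(coords)
  if (is.null(circle)) circle <- fit_circle(coords)
  raw <- atan2(coords[, 2] - circle$center[2],
               coords[, 1] - circle$center[1]) %% (2 * pi)
  if (is.null(orientation)) {
    if (is.null(markers) ||
        !all(c(cyclin_A, cyclin_B) %in% colnames(markers)))
      stop("cyclin A/B columns not found; supply `orientation` = +1/-1")
    if (is.null(window)) window <- .default_window(length(raw))
    pa <- .peak_angle(raw, markers[, cyclin_A], window)
    pb <- .peak_angle(raw, markers[, cyclin_B], window)
    lag <- (pb - pa) %% (2 * pi)
    orientation <- if (lag < pi) 1 else -1
  }
  ang <- if (orientation == 1) raw else (2 * pi - raw) %% (2 * pi)
  ang <- (ang - zero_angle) %% (2 * pi)
  structure(list(coords = coords, center = circle$center,
                 radius = circle$radius, angle = ang,
                 orientation = orientation,
                 cell_id = rownames(coords)),
            class = "circular_embedding")
}

#' @export
print.circular_embedding <- function(x, ...) {
  cat(sprintf("<circular_embedding> %d cells, radius %.3f, orientation %+d\n",
              length(x$angle), x$radius, x$orientation))
  invisible(x)
}

#' Ergodic pseudo-time assignment
#'
#' Sorts cells by angle and assigns equidistant times `r * T / N` to the
#' sorted ranks `r = 0, ..., N-1`, the ergodic rule: the time marginal is
#' exactly uniform by construction.  Ties in angle are broken by cell
#' order (stable sort).
#'
#' @param emb a `circular_embedding`.
#' @param T cycle length in hours (default 24).
#' @return a `pseudotime` data.frame: `cell_id`, `angle`, `rank`
#'   (0-based), `time`; attributes `T` and `method`.
#' @export
ergodic_times <- function(emb, T = 24) {
  .pt_assign(emb, T, function(r, N) r * T / N, "ergodic")
}

#' Non-ergodic (exponential-age) pseudo-time assignment
#'
#' In a steadily doubling population the number of cells younger than
#' age `t` satisfies `r/N = 2 (1 - 2^(-t/T))`; inverting gives
#' `t = T * log2(2N / (2N - r))` for the cell of rank `r` along the
#' oriented angle.  `t(0) = 0` and `t(N) = T` exactly.
#'
#' @inheritParams ergodic_times
#' @return a `pseudotime` data.frame as in [ergodic_times()].
#' @export
kafri_times <- function(emb, T = 24) {
  .pt_assign(emb, T, function(r, N) {
    if (any(r >= 2 * N)) stop("rank r = 2N is impossible")
    T * log2(2 * N / (2 * N - r))
  }, "kafri")
}

.pt_assign <- function(emb, T, timefun, method) {
  stopifnot(inherits(emb, "circular_embedding"), T > 0)
  N <- length(emb$angle)
  if (N < 2) stop("need at least 2 cells")
  o <- order(emb$angle) # stable: ties keep input (cell_id) order
  rank0 <- integer(N)
  rank0[o] <- seq_len(N) - 1L
  tm <- timefun(rank0, N)
  out <- data.frame(
    cell_id = if (!is.null(emb$cell_id)) emb$cell_id
              else sprintf("cell_%05d", seq_len(N)),
    angle = emb$angle, rank = rank0, time = tm)
  attr(out, "T") <- T
  attr(out, "method") <- method
  class(out) <- c("pseudotime", "data.frame")
  out
}

#' Moving median and moving MAD trajectories
#'
#' Cells are sorted by pseudo-time; for each point of a fixed grid (100
#' points per period by default) the window of the `window` nearest
#' cells in sorted order, wrapped circularly at the period boundary, is
#' summarized by its median and its (unscaled) median absolute deviation
#' per marker — the movMMAD statistic.
#'
#' @param m a `marker_matrix` (cells x markers), same cell order as the
#'   table the pseudo-times came from.
#' @param pt a `pseudotime` assignment.
#' @param window odd window size in cells; default
#'   `max(51, N/50)` (odd-ified), capped at `N`.
#' @param grid_n number of grid points per period.
#' @return a `marker_trajectory`: list with `grid` (times, h), `med` and
#'   `mad` (grid_n x markers matrices), `window`, `T`.
#' @export
moving_stats <- function(m, pt, window = NULL, grid_n = 100) {
  stopifnot(inherits(pt, "pseudotime"))
  m <- as.matrix(m)
  N <- nrow(m)
  if (N != nrow(pt)) stop("marker matrix and pseudotime disagree in size")
  if (is.null(window)) window <- .default_window(N)
  if (window > N) stop("window exceeds the number of cells")
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  T <- attr(pt, "T")
  o <- order(pt$time)
  tms <- pt$time[o]
  vals <- m[o, , drop = FALSE]
  grid <- seq(0, T, length.out = grid_n + 1)[seq_len(grid_n)]
  half <- (window - 1) %/% 2
  med <- matrix(NA_real_, grid_n, ncol(m))
  madm <- matrix(NA_real_, grid_n, ncol(m))
  centers <- findInterval(grid, tms)
  for (g in seq_len(grid_n)) {
    idx <- (centers[g] - half):(centers[g] + half)
    idx <- ((idx - 1) %% N) + 1
    w <- vals[idx, , drop = FALSE]
    cm <- apply(w, 2, median)
    med[g, ] <- cm
    madm[g, ] <- apply(abs(sweep(w, 2, cm)), 2, median)
  }
  colnames(med) <- colnames(madm) <- colnames(m)
  structure(list(grid = grid, med = med, mad = madm, window = window,
                 T = T),
            class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf("<marker_trajectory> %d grid points x %d markers (window %d, T = %g h)\n",
              length(x$grid), ncol(x$med), x$window, x$T))
  invisible(x)
}

#' Locate phase-transition boundaries from the angle distribution
#'
#' Builds a circular histogram of the CMD angles, smooths it with a
#' circular moving average, and returns the two deepest local minima
#' separating the two largest modes — the M/G1 and S/G2 transitions of a
#' bimodal cycling population.  For unimodal (arrested-like) or flat
#' (uniform) distributions no stable minima exist and an empty vector is
#' returned with attribute `reason`.
#'
#' @param emb a `circular_embedding` (or a numeric vector of angles).
#' @param n_bins number of histogram bins (default 50).
#' @param smooth_window circular moving-average window in bins (odd,
#'   default 5).
#' @param min_depth a valley must drop below `min_depth` times the
#'   smaller of the two mode heights to count as a separating minimum
#'   (default 0.8).
#' @return numeric vector of 0 or 2 boundary angles (radians, sorted),
#'   with attributes `modes` (the two mode angles) when found.
#' @export
phase_boundaries <- function(emb, n_bins = 50, smooth_window = 5,
                             min_depth = 0.8) {
  ang <- if (inherits(emb, "circular_embedding")) emb$angle
         else as.numeric(emb)
  brk <- seq(0, 2 * pi, length.out = n_bins + 1)
  cnt <- tabulate(findInterval(ang %% (2 * pi), brk,
                               rightmost.closed = TRUE), n_bins)
  half <- (smooth_window - 1) %/% 2
  idx <- outer(seq_len(n_bins), -half:half, "+")
  idx <- ((idx - 1) %% n_bins) + 1
  sm <- rowMeans(matrix(cnt[idx], n_bins))
  centers <- (brk[-1] + brk[-(n_bins + 1)]) / 2

  is_max <- sm > sm[c(n_bins, 1:(n_bins - 1))] &
            sm >= sm[c(2:n_bins, 1)]
  maxima <- which(is_max)
  if (length(maxima) < 2)
    return(structure(numeric(0), reason = "unimodal"))
  maxima <- maxima[order(sm[maxima], decreasing = TRUE)][1:2]
  m1 <- min(maxima); m2 <- max(maxima)
  arc1 <- if (m2 > m1 + 1) (m1 + 1):(m2 - 1) else integer(0)
  arc2 <- setdiff(seq_len(n_bins), m1:m2)
  if (!length(arc1) || !length(arc2))
    return(structure(numeric(0), reason = "adjacent modes"))
  v1 <- arc1[which.min(sm[arc1])]
  v2 <- arc2[which.min(sm[arc2])]
  peak_floor <- min_depth * min(sm[m1], sm[m2])
  if (sm[v1] >= peak_floor || sm[v2] >= peak_floor)
    return(structure(numeric(0), reason = "no stable minima"))
  structure(sort(centers[c(v1, v2)]),
            modes = sort(centers[c(m1, m2)]))
}

#' Label the M/G1 boundary using cyclin context
#'
#' Of the two boundary angles, the M/G1 transition is the one closer to
#' the minimum of total (summed, z-scored) cyclin expression along the
#' angle; the other is S/G2.
#'
#' @param boundaries two boundary angles from [phase_boundaries()].
#' @param emb the `circular_embedding`.
#' @param markers the `marker_matrix`; cyclin columns found by name.
#' @param cyclins names of the cyclin columns present in `markers`.
#' @param window moving-median window.
#' @return named vector `c(MG1 = ..., SG2 = ...)`.
#' @export
label_boundaries <- function(boundaries, emb, markers,
                             cyclins = c("Cd", "Ce", "Ca", "Cb"),
                             window = NULL) {
  if (length(boundaries) != 2) stop("need exactly two boundary angles")
  cyclins <- intersect(cyclins, colnames(markers))
  if (!length(cyclins)) stop("no cyclin columns found")
  tot <- rowSums(as.matrix(markers)[, cyclins, drop = FALSE])
  if (is.null(window)) window <- .default_window(length(tot))
  # minimum of the circular moving median of total cyclin
  o <- order(emb$angle)
  a <- emb$angle[o]; v <- tot[o]
  n <- length(v)
  half <- (min(window, n - (1 - n %% 2)) - 1) %/% 2
  idx <- outer(seq_len(n), -half:half, "+")
  idx <- ((idx - 1) %% n) + 1
  med <- apply(matrix(v[idx], n), 1, median)
  amin <- a[which.min(med)]
  d <- abs(((boundaries - amin + pi) %% (2 * pi)) - pi)
  mg1 <- boundaries[which.min(d)]
  c(MG1 = mg1, SG2 = boundaries[boundaries != mg1][1])
}
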
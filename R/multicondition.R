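# Arrest-angle estimation on the untreated reference frame: disjoint
# treated subsets, joint embeddings, Procrustes anchoring, circular
# mode.

#' Partition treated cells into disjoint subsets
#'
#' Seeded shuffle followed by round-robin splitting into
#' `ceiling(1/fraction)` subsets whose sizes differ by at most one and
#' whose union is the full set.
#'
#' @param cell_ids vector of treated cell identifiers.
#' @param fraction target fraction per subset (default 0.05, the "small
#'   subsets" of treated data).
#' @param seed integer seed making the partition reproducible.
#' @return list of disjoint id vectors.
#' @export
partition_treated <- function(cell_ids, fraction = 0.05, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- length(cell_ids)
  k <- ceiling(1 / fraction)
  if (k > n) stop("fraction too small: some subsets would be empty")
  set.seed(seed)
  perm <- sample(cell_ids)
  out <- split(perm, rep_len(seq_len(k), n))
  names(out) <- NULL
  out
}

#' Orthogonal Procrustes alignment
#'
#' Finds the similarity transform (rotation, reflection, isotropic
#' scale, translation) minimizing `|| s X R + 1 t' - Y ||_F` and applies
#' it, so coordinates from a new embedding can be expressed in a
#' reference frame.
#'
#' @param x matrix to align (n x 2).
#' @param target reference coordinates (n x 2, same rows).
#' @param extra optional additional rows transformed with the same
#'   parameters (e.g. treated cells co-embedded with the anchors).
#' @return list `aligned` (x after transform), `extra_aligned`,
#'   `rotation`, `scale`, `translation`, `rmsd` (residual root mean
#'   square distance of the anchors).
#' @export
procrustes_align <- function(x, target, extra = NULL) {
  x <- as.matrix(x); target <- as.matrix(target)
  stopifnot(nrow(x) == nrow(target), ncol(x) == 2, ncol(target) == 2)
  cx <- colMeans(x); cy <- colMeans(target)
  xc <- sweep(x, 2, cx); yc <- sweep(target, 2, cy)
  sv <- svd(crossprod(xc, yc))
  R <- sv$u %*% t(sv$v)
  s <- sum(sv$d) / sum(xc^2)
  transform <- function(z)
    sweep(s * sweep(as.matrix(z), 2, cx) %*% R, 2, cy, "+")
  aligned <- transform(x)
  list(aligned = aligned,
       extra_aligned = if (!is.null(extra)) transform(extra) else NULL,
       rotation = R, scale = s, translation = cy - cx,
       rmsd = sqrt(mean(rowSums((aligned - target)^2))))
}

#' Angles of treated cells in the untreated reference frame
#'
#' Runs a joint CMD embedding of all untreated cells plus one treated
#' subset, aligns the untreated portion to the reference embedding by
#' orthogonal Procrustes, applies the same transform to the treated
#' cells, and returns their angles around the reference circle.
#'
#' @param untreated `marker_matrix` of the untreated cells (the same
#'   matrix the reference embedding was built from).
#' @param treated_subset `marker_matrix` of one treated subset (shared
#'   marker set, same column order).
#' @param reference the untreated `circular_embedding` (from
#'   [embed_angles()] on [cmd_embed()] of `untreated`).
#' @param max_rmsd Procrustes residual (relative to the reference
#'   radius) beyond which the joint frame is declared unstable.
#' @return list `angles` (treated cells, radians in the reference
#'   frame), `untreated_angles` (re-derived, for drift diagnostics),
#'   `rmsd`.
#' @export
joint_embed_angles <- function(untreated, treated_subset, reference,
                               max_rmsd = 0.25) {
  stopifnot(inherits(reference, "circular_embedding"))
  untreated <- as.matrix(untreated)
  treated_subset <- as.matrix(treated_subset)
  if (!identical(colnames(untreated), colnames(treated_subset)))
    stop("untreated and treated matrices must share the marker set")
  n_u <- nrow(untreated)
  joint <- cmd_embed(rbind(untreated, treated_subset))
  al <- procrustes_align(joint[seq_len(n_u), , drop = FALSE],
                         reference$coords,
                         extra = joint[-seq_len(n_u), , drop = FALSE])
  if (al$rmsd > max_rmsd * reference$radius)
    stop(sprintf("joint frame unstable: Procrustes rmsd %.3g exceeds %.3g",
                 al$rmsd, max_rmsd * reference$radius))
  to_angle <- function(z) {
    raw <- atan2(z[, 2] - reference$center[2],
                 z[, 1] - reference$center[1]) %% (2 * pi)
    if (reference$orientation == 1) raw else (2 * pi - raw) %% (2 * pi)
  }
  list(angles = to_angle(al$extra_aligned),
       untreated_angles = to_angle(al$aligned),
       rmsd = al$rmsd)
}

#' Mode and dispersion of an angle sample
#'
#' Mode of the von-Mises kernel density estimate (bandwidth by the
#' circular plug-in rule), dispersion as the circular standard
#' deviation.  Warns when a second density maximum comes within
#' `bimodal_ratio` of the largest (ambiguous mode).
#'
#' @param angles radians; at least 50 values.
#' @param bimodal_ratio near-tie warning threshold (default 0.8).
#' @param grid_n density grid resolution.
#' @return list `mode` (radians), `dispersion` (circular SD, radians),
#'   `density` (the KDE), `histogram_mode` (argmax of a 50-bin
#'   histogram, fallback diagnostic).
#' @export
arrest_mode <- function(angles, bimodal_ratio = 0.8, grid_n = 512) {
  angles <- angles %% (2 * pi)
  if (length(angles) < 50) stop("need at least 50 angles")
  kde <- vm_kde(angles, at = seq(0, 2 * pi, length.out = grid_n + 1)[-(grid_n + 1)])
  i <- which.max(kde$y)
  # other local maxima of the periodic density
  y <- kde$y
  n <- length(y)
  lm <- which(y > y[c(n, 1:(n - 1))] & y >= y[c(2:n, 1)])
  lm <- setdiff(lm, i)
  if (length(lm) && max(y[lm]) > bimodal_ratio * y[i])
    warning("angle density has two near-equal maxima; arrest mode is ambiguous")
  brk <- seq(0, 2 * pi, length.out = 51)
  cnt <- tabulate(findInterval(angles, brk, rightmost.closed = TRUE), 50)
  hist_mode <- ((brk[-1] + brk[-51]) / 2)[which.max(cnt)]
  list(mode = kde$x[i], dispersion = circ_sd(angles), density = kde,
       histogram_mode = hist_mode)
}

#' Arrest time on the untreated clock
#'
#' Interpolates the monotone angle-to-time map of the untreated
#' pseudo-time assignment at the arrest-mode angle and attaches a phase
#' label when boundaries are supplied.
#'
#' @param mode arrest-mode angle (radians, reference frame).
#' @param pt_map untreated `pseudotime` assignment (angle -> time).
#' @param dispersion circular SD of the treated angles (stored in the
#'   estimate).
#' @param n_cells number of treated cells behind the estimate.
#' @param condition condition label.
#' @param boundaries optional boundary angles for phase labelling.
#' @return an `arrest_estimate`: list `condition`, `arrest_angle`,
#'   `arrest_time` (h), `dispersion`, `n_cells`, `label`.
#' @export
arrest_time <- function(mode, pt_map, dispersion = NA_real_,
                        n_cells = NA_integer_, condition = "treated",
                        boundaries = NULL) {
  stopifnot(inherits(pt_map, "pseudotime"))
  mode <- mode %% (2 * pi)
  T <- attr(pt_map, "T")
  o <- order(pt_map$angle)
  a <- pt_map$angle[o]; tm <- pt_map$time[o]
  # wrap the map so interpolation is defined on the whole circle
  a2 <- c(a[length(a)] - 2 * pi, a, a[1] + 2 * pi)
  t2 <- c(tm[length(tm)] - T, tm, tm[1] + T)
  at <- approx(a2, t2, xout = mode, ties = "ordered")$y %% T
  label <- if (!is.null(boundaries) && length(boundaries) == 2) {
    bt <- sort(approx(a2, t2, xout = boundaries %% (2 * pi),
                      ties = "ordered")$y %% T)
    .phase_label(at, bt, T)
  } else NA_character_
  structure(list(condition = condition, arrest_angle = mode,
                 arrest_time = unname(at), dispersion = dispersion,
                 n_cells = n_cells, label = label),
            class = "arrest_estimate")
}

#' @export
print.arrest_estimate <- function(x, ...) {
  cat(sprintf("<arrest_estimate> %s: angle %.3f rad, time %.2f h (circ SD %.3f, n = %s)%s\n",
              x$condition, x$arrest_angle, x$arrest_time, x$dispersion,
              x$n_cells,
              if (is.na(x$label)) "" else paste0(", ", x$label)))
  invisible(x)
}

#' Full arrest estimation for one treated condition
#'
#' Convenience driver: partitions the treated cells into disjoint
#' subsets, co-embeds each subset with all untreated cells, pools the
#' treated angles across subsets, and estimates the arrest mode and time
#' on the untreated clock.
#'
#' @param untreated untreated single-cell table.
#' @param treated treated single-cell table (same markers).
#' @param T cycle length (h).
#' @param fraction subset fraction (default 0.05).
#' @param seed partition seed.
#' @param boundaries optional boundary angles for labelling.
#' @param pt_method `"ergodic"` or `"kafri"` time inference.
#' @return list `estimate` (an `arrest_estimate`), `angles` (per treated
#'   cell, reference frame), `drift` (median absolute untreated angle
#'   drift across joint embeddings, radians), `reference` (the untreated
#'   `circular_embedding`), `pt` (untreated pseudotime).
#' @export
estimate_arrest <- function(untreated, treated, T = 24, fraction = 0.05,
                            seed = 1L, boundaries = NULL,
                            pt_method = c("ergodic", "kafri")) {
  pt_method <- match.arg(pt_method)
  mu <- preprocess_markers(untreated)
  cond <- unique(treated$condition)[1]
  # normalize treated intensities on the untreated log-scale per marker,
  # then z-score with the untreated location/scale so both lie in one space
  cols <- attr(mu, "marker_names")
  mt_raw <- as.matrix(treated[, cols, drop = FALSE])
  for (j in seq_along(cols)) {
    pos <- mt_raw[, j] > 0
    if (!all(pos)) mt_raw[!pos, j] <- min(mt_raw[pos, j])
  }
  lu <- log10(as.matrix({
    ru <- as.matrix(untreated[, cols, drop = FALSE])
    for (j in seq_along(cols)) {
      pos <- ru[, j] > 0
      if (!all(pos)) ru[!pos, j] <- min(ru[pos, j])
    }
    ru
  }))
  ctr <- colMeans(lu); scl <- apply(lu, 2, sd)
  mt <- sweep(sweep(log10(mt_raw), 2, ctr), 2, scl, "/")
  rownames(mt) <- treated$cell_id

  coords <- cmd_embed(mu)
  ref <- embed_angles(coords, markers = mu,
                      orientation = if (all(c("Ca", "Cb") %in% cols)) NULL
                                    else 1)
  pt <- if (pt_method == "ergodic") ergodic_times(ref, T)
        else kafri_times(ref, T)

  parts <- partition_treated(treated$cell_id, fraction, seed)
  all_angles <- rep(NA_real_, nrow(treated))
  names(all_angles) <- treated$cell_id
  drift <- numeric(0)
  for (ids in parts) {
    je <- joint_embed_angles(mu, mt[ids, , drop = FALSE], ref)
    all_angles[ids] <- je$angles
    drift <- c(drift, median(abs(circ_dist(je$untreated_angles,
                                           ref$angle))))
  }
  am <- arrest_mode(all_angles)
  est <- arrest_time(am$mode, pt, dispersion = am$dispersion,
                     n_cells = length(all_angles), condition = cond,
                     boundaries = boundaries)
  list(estimate = est, angles = all_angles, drift = median(drift),
       reference = ref, pt = pt)
}
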
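#' Assign phosphate atoms to leaflets
#'
#' Splits the phosphate atoms of a frame into top and bottom leaflets by
#' their z-coordinate relative to the phosphate median z. An atom exactly
#' at the median is assigned to the bottom leaflet (fixed tie rule). The
#' membrane normal is the laboratory +z axis throughout.
#'
#' @param frame A `BilayerFrame` (see [bilayer_frame()]).
#' @return List with `top` and `bottom` integer index vectors (into the
#'   frame's atoms).
#' @export
assign_leaflets <- function(frame) {
  stopifnot(inherits(frame, "BilayerFrame"))
  p <- frame$p_atom_indices
  if (length(p) < 4L) stop("need at least 4 phosphate atoms")
  z <- frame$coordinates[p, 3]
  if (diff(range(z)) == 0)
    stop("all phosphate z equal: no bilayer to split")
  med <- stats::median(z)
  list(top = p[z > med], bottom = p[z <= med])
}

#' Bilayer thickness between phosphate planes
#'
#' Mean z of the top-leaflet phosphates minus mean z of the bottom-leaflet
#' phosphates (positive, Angstrom) — the P-P thickness.
#'
#' @inheritParams assign_leaflets
#' @return Thickness in Angstrom.
#' @export
membrane_thickness <- function(frame) {
  lf <- assign_leaflets(frame)
  mean(frame$coordinates[lf$top, 3]) -
    mean(frame$coordinates[lf$bottom, 3])
}

atom_index <- function(frame, name) {
  i <- which(frame$atom_names == name)
  if (!length(i)) stop(sprintf("atom '%s' not found in frame", name))
  i[1]
}

#' Tilt angle of an atom-pair vector to the membrane normal
#'
#' Angle between the vector from `atom_a` to `atom_b` and the membrane
#' normal (+z), in degrees. The default range is `[0, 180]`; with
#' `fold = TRUE` the angle is folded to `[0, 90]` (direction-free tilt).
#'
#' @inheritParams assign_leaflets
#' @param atom_a,atom_b Atom names (defaults: the N2-N3 chromophore pair).
#' @param fold Fold to `[0, 90]` degrees.
#' @return Angle in degrees.
#' @export
tilt_angle <- function(frame, atom_a = "N2", atom_b = "N3", fold = FALSE) {
  stopifnot(inherits(frame, "BilayerFrame"))
  v <- frame$coordinates[atom_index(frame, atom_b), ] -
    frame$coordinates[atom_index(frame, atom_a), ]
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("tilt atoms are coincident")
  ang <- acos(max(-1, min(1, v[3] / nv))) * 180 / pi
  if (fold && ang > 90) ang <- 180 - ang
  ang
}

# Kabsch optimal rotation: returns R such that moving %*% R best matches
# reference (both n x 3 with rows as atoms, already centred); proper
# rotation enforced via the determinant sign correction.
kabsch_rotation <- function(moving, reference) {
  h <- crossprod(moving, reference)
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Heavy-atom RMSD of the dye after optimal superposition
#'
#' RMSD over the dye's heavy atoms after optimal rigid-body superposition
#' (translation + Kabsch rotation) of the dye onto the reference frame's
#' dye, so global rigid motion contributes nothing.
#'
#' @param frame,reference `BilayerFrame`s with identical
#'   `dye_heavy_indices`.
#' @return RMSD in Angstrom.
#' @export
heavy_atom_rmsd <- function(frame, reference) {
  stopifnot(inherits(frame, "BilayerFrame"),
            inherits(reference, "BilayerFrame"))
  if (!identical(frame$dye_heavy_indices, reference$dye_heavy_indices))
    stop("frames have different dye heavy-atom selections")
  idx <- frame$dye_heavy_indices
  if (length(idx) < 3L)
    stop("superposition needs at least 3 heavy atoms")
  a <- frame$coordinates[idx, , drop = FALSE]
  b <- reference$coordinates[idx, , drop = FALSE]
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  rot <- kabsch_rotation(a, b)
  sqrt(mean(rowSums((a %*% rot - b)^2)))
}

# Proximal leaflet of the dye: the leaflet whose P-plane mean z is
# nearest the headgroup edge atom. Fixed from the first frame per
# trajectory by depth_series (the dye does not flip).
proximal_leaflet <- function(frame, edge_atom = "N2") {
  lf <- assign_leaflets(frame)
  ez <- frame$coordinates[atom_index(frame, edge_atom), 3]
  zt <- mean(frame$coordinates[lf$top, 3])
  zb <- mean(frame$coordinates[lf$bottom, 3])
  if (abs(zt - ez) <= abs(zb - ez)) "top" else "bottom"
}

#' Signed distance of an atom below the proximal phosphate plane
#'
#' Distance from the mean z of the proximal leaflet's phosphates (the
#' membrane-water interface) to the atom, signed positive when the atom
#' lies on the bilayer-centre side of the plane.
#'
#' @inheritParams assign_leaflets
#' @param atom Atom name.
#' @param proximal `"top"`, `"bottom"`, or `NULL` to determine the
#'   proximal leaflet from this frame's headgroup edge atom.
#' @param edge_atom Atom used to pick the proximal leaflet when
#'   `proximal` is `NULL`.
#' @return Signed distance in Angstrom.
#' @export
interface_distance <- function(frame, atom, proximal = NULL,
                               edge_atom = "N2") {
  stopifnot(inherits(frame, "BilayerFrame"))
  if (is.null(proximal)) proximal <- proximal_leaflet(frame, edge_atom)
  lf <- assign_leaflets(frame)
  plane_z <- mean(frame$coordinates[lf[[proximal]], 3])
  az <- frame$coordinates[atom_index(frame, atom), 3]
  if (proximal == "top") plane_z - az else az - plane_z
}

#' Per-frame geometry series of a bilayer trajectory
#'
#' Applies [membrane_thickness()], [tilt_angle()], [heavy_atom_rmsd()]
#' (against the first analyzed frame, superposing on the dye heavy atoms)
#' and [interface_distance()] for both chromophore edge atoms to every
#' frame. The proximal leaflet is fixed from the first frame.
#'
#' @param trajectory A `BilayerTrajectory`.
#' @param tilt_pair Atom names for the tilt vector.
#' @param edge_atoms Atom names of the two chromophore edge atoms whose
#'   interface distances are followed.
#' @param fold_tilt Fold tilt to `[0, 90]` degrees.
#' @return A data frame of class `DepthSeries` with columns `time` (ns),
#'   `thickness`, `tilt`, `rmsd`, `dist_edge1`, `dist_edge2` (Angstrom /
#'   degrees); attribute `proximal` records the leaflet used.
#' @export
depth_series <- function(trajectory, tilt_pair = c("N2", "N3"),
                         edge_atoms = c("N2", "C23"), fold_tilt = FALSE) {
  stopifnot(inherits(trajectory, "BilayerTrajectory"))
  nf <- length(trajectory$times)
  ref <- bilayer_frame(trajectory, 1L)
  proximal <- proximal_leaflet(ref, edge_atoms[1])
  out <- matrix(NA_real_, nf, 5)
  for (f in seq_len(nf)) {
    fr <- bilayer_frame(trajectory, f)
    res <- tryCatch(
      c(membrane_thickness(fr),
        tilt_angle(fr, tilt_pair[1], tilt_pair[2], fold = fold_tilt),
        heavy_atom_rmsd(fr, ref),
        interface_distance(fr, edge_atoms[1], proximal = proximal),
        interface_distance(fr, edge_atoms[2], proximal = proximal)),
      error = function(e)
        stop(sprintf("frame %d: %s", f, conditionMessage(e)), call. = FALSE))
    out[f, ] <- res
  }
  ds <- data.frame(time = trajectory$times, thickness = out[, 1],
                   tilt = out[, 2], rmsd = out[, 3],
                   dist_edge1 = out[, 4], dist_edge2 = out[, 5])
  class(ds) <- c("DepthSeries", "data.frame")
  attr(ds, "proximal") <- proximal
  ds
}

#' Window averages of a depth series
#'
#' Means and SDs over the trailing `window_ns` of the trajectory
#' (frames with `time >= t_end - window_ns`, inclusive). The chromophore
#' midpoint is the mean of the two edge-atom interface distances.
#'
#' @param series A [depth_series()] result.
#' @param window_ns Window length in ns (<= trajectory span).
#' @return An object of class `DepthSummary`: `window` (ns interval),
#'   `mean_dist_edge1`, `mean_dist_edge2`, `mean_midpoint`, matching
#'   `sd_*` fields, `sem_midpoint` (autocorrelation-corrected standard
#'   error of the windowed midpoint mean, by batch means), `n_frames`.
#' @export
window_average <- function(series, window_ns = 100) {
  stopifnot(inherits(series, "DepthSeries"))
  t_end <- max(series$time)
  t0 <- t_end - window_ns
  if (t0 < min(series$time))
    stop("window_ns exceeds the trajectory span")
  w <- series[series$time >= t0, ]
  if (nrow(w) < 2L) stop("fewer than 2 frames in the window")
  mid <- (w$dist_edge1 + w$dist_edge2) / 2
  # batch-means SE: 20 batches absorb the OU autocorrelation
  nb <- min(20L, nrow(w) %/% 2L)
  bm <- tapply(mid, cut(seq_along(mid), nb), mean)
  sem <- stats::sd(bm) / sqrt(nb)
  structure(list(window = c(t0, t_end),
                 mean_dist_edge1 = mean(w$dist_edge1),
                 mean_dist_edge2 = mean(w$dist_edge2),
                 mean_midpoint = mean(mid),
                 sd_dist_edge1 = stats::sd(w$dist_edge1),
                 sd_dist_edge2 = stats::sd(w$dist_edge2),
                 sd_midpoint = stats::sd(mid),
                 sem_midpoint = sem,
                 n_frames = nrow(w)),
            class = "DepthSummary")
}

#' @export
print.DepthSummary <- function(x, ...) {
  cat(sprintf(
    "Window %.1f-%.1f ns (%d frames): midpoint depth %.2f +/- %.2f A (SD)\n",
    x$window[1], x$window[2], x$n_frames, x$mean_midpoint, x$sd_midpoint))
  cat(sprintf("  edge atoms: %.2f / %.2f A; SEM(midpoint) %.3f A\n",
              x$mean_dist_edge1, x$mean_dist_edge2, x$sem_midpoint))
  invisible(x)
}

#' Convergence time of two independently started trajectories
#'
#' For two depth series (e.g. two embedding models started 5 Angstrom
#' apart), computes the running mean of each chromophore-midpoint
#' distance and returns the earliest time t at which the two running
#' means differ by less than `tolerance` for every time in
#' `[t, t + hold]`. Series on different time grids are resampled onto
#' their common grid by linear interpolation.
#'
#' @param series_a,series_b [depth_series()] results.
#' @param tolerance Convergence tolerance in Angstrom.
#' @param hold Time (ns) the criterion must hold.
#' @return Convergence time in ns, or `NA` (with message) if the
#'   criterion is never met.
#' @export
convergence_time <- function(series_a, series_b, tolerance = 1, hold = 20) {
  stopifnot(inherits(series_a, "DepthSeries"),
            inherits(series_b, "DepthSeries"))
  mid_a <- (series_a$dist_edge1 + series_a$dist_edge2) / 2
  mid_b <- (series_b$dist_edge1 + series_b$dist_edge2) / 2
  if (!isTRUE(all.equal(series_a$time, series_b$time))) {
    lo <- max(min(series_a$time), min(series_b$time))
    hi <- min(max(series_a$time), max(series_b$time))
    tm <- sort(unique(c(series_a$time[series_a$time >= lo &
                                        series_a$time <= hi],
                        series_b$time[series_b$time >= lo &
                                        series_b$time <= hi])))
    mid_a <- stats::approx(series_a$time, mid_a, xout = tm)$y
    mid_b <- stats::approx(series_b$time, mid_b, xout = tm)$y
  } else tm <- series_a$time
  run_a <- cumsum(mid_a) / seq_along(mid_a)
  run_b <- cumsum(mid_b) / seq_along(mid_b)
  close <- abs(run_a - run_b) < tolerance
  t_end <- max(tm)
  # earliest t with the criterion holding over [t, t + hold]
  for (i in seq_along(tm)) {
    if (tm[i] + hold > t_end) break
    j <- which(tm >= tm[i] & tm <= tm[i] + hold)
    if (all(close[j])) return(tm[i])
  }
  message("running means never stay within tolerance over a full hold window")
  NA_real_
}
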
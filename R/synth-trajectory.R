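#' Packaged probe insertion-depth presets
#'
#' Mean distance (Angstrom) of each probe's chromophore/sensor moiety
#' below the proximal phosphate plane, as established for identical
#' simulation conditions: di-4-ANEPPDHQ sits superficially (4.4 A),
#' close to di-8-ANEPPS (3.7 A), while Laurdan sits deep (10.6 A).
#' All presets use a 30 degree mean tilt to the membrane normal.
#'
#' @format Named numeric vector of depths in Angstrom.
#' @export
dye_depth_presets <- c("di4-ANEPPDHQ" = 4.4,
                       "di8-ANEPPS" = 3.7,
                       "Laurdan" = 10.6)

#' Specification for a synthetic bilayer-plus-dye trajectory
#'
#' A kinematic stand-in for an equilibrated dye-in-POPC simulation: two
#' phosphate planes at `+/- thickness/2` with per-frame Gaussian jitter,
#' and a rigid-rod dye in the top leaflet whose chromophore-midpoint depth
#' below the proximal phosphate plane and whose tilt to the membrane
#' normal both follow stationary Ornstein-Uhlenbeck (mean-reverting)
#' processes, so their stationary mean and SD are known in closed form.
#' `initial_depth_offset` starts the depth away from its mean (decaying
#' with `depth_relaxation_time`), emulating a second embedding model
#' shifted toward the bilayer center.
#'
#' @param thickness Phosphate-plane separation (Angstrom).
#' @param n_lipids_per_leaflet Phosphate atoms per leaflet.
#' @param p_jitter_sd Per-atom, per-frame Gaussian z-jitter of the
#'   phosphate atoms (Angstrom).
#' @param dye_depth Stationary mean depth of the chromophore midpoint
#'   below the proximal phosphate plane (Angstrom), or a preset name from
#'   [dye_depth_presets].
#' @param depth_sd Stationary SD of the depth process (Angstrom).
#' @param depth_relaxation_time OU relaxation time (ns) shared by the
#'   depth and tilt processes.
#' @param tilt_mean,tilt_sd Stationary mean and SD of the tilt angle to
#'   the membrane normal (degrees).
#' @param rod_length Dye rod length (Angstrom); must not exceed
#'   `thickness`.
#' @param n_dye_atoms Atoms along the rod (>= 2). The edge atoms carry the
#'   chromophore-boundary names "N2" (deep edge) and "C23" (shallow edge);
#'   the atom next to N2 is named "N3" so the tilt pair N2-N3 lies along
#'   the rod axis.
#' @param duration,frame_interval Trajectory length and frame spacing (ns).
#' @param initial_depth_offset Added to the depth at t = 0 (Angstrom);
#'   use 5 for the deeper-start embedding model.
#' @param seed Integer RNG seed.
#' @return An object of class `TrajectorySpec`.
#' @export
trajectory_spec <- function(thickness = 40, n_lipids_per_leaflet = 36,
                            p_jitter_sd = 1, dye_depth = "di4-ANEPPDHQ",
                            depth_sd = 1.5, depth_relaxation_time = 10,
                            tilt_mean = 30, tilt_sd = 5,
                            rod_length = 10, n_dye_atoms = 10L,
                            duration = 300, frame_interval = 0.1,
                            initial_depth_offset = 0, seed = 1L) {
  if (is.character(dye_depth)) {
    dye_depth <- dye_depth_presets[[match.arg(dye_depth,
                                              names(dye_depth_presets))]]
  }
  if (thickness <= 0) stop("thickness must be positive")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (duration < frame_interval) stop("duration must be >= frame_interval")
  if (n_dye_atoms < 2L) stop("the dye rod needs at least 2 atoms")
  if (rod_length > thickness)
    stop("rod_length exceeds the bilayer thickness")
  structure(list(thickness = thickness,
                 n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 p_jitter_sd = p_jitter_sd, dye_depth = dye_depth,
                 depth_sd = depth_sd,
                 depth_relaxation_time = depth_relaxation_time,
                 tilt_mean = tilt_mean, tilt_sd = tilt_sd,
                 rod_length = rod_length, n_dye_atoms = as.integer(n_dye_atoms),
                 duration = duration, frame_interval = frame_interval,
                 initial_depth_offset = initial_depth_offset,
                 seed = as.integer(seed)),
            class = "TrajectorySpec")
}

# Exact OU discretization: x_{k+1} = mu + (x_k - mu) phi + sd sqrt(1-phi^2) Z
ou_path <- function(n, mu, sd, tau, dt, x0) {
  x <- numeric(n)
  x[1] <- x0
  if (n == 1L) return(x)
  phi <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - phi^2)
  z <- stats::rnorm(n - 1L)
  for (k in seq_len(n - 1L))
    x[k + 1L] <- mu + (x[k] - mu) * phi + innov_sd * z[k]
  x
}

# Edge atoms carry the chromophore-boundary names N2/C23 and the tilt
# partner N3; interior rod atoms get neutral CX<i> names.
dye_atom_names <- function(n) {
  if (n == 2L) return(c("N2", "C23"))
  c("N2", "N3", if (n > 3L) paste0("CX", seq_len(n - 3L) + 2L), "C23")
}

#' Generate a synthetic bilayer trajectory with known depth and tilt
#'
#' @param spec A [trajectory_spec()].
#' @return A list with
#'   \describe{
#'     \item{trajectory}{A `BilayerTrajectory`: `times` (ns), `coords`
#'       (`n_atoms x 3 x n_frames` array, Angstrom), `atom_names`,
#'       `p_atom_indices`, `dye_atom_indices`, `dye_heavy_indices` (all
#'       rod atoms; the rod has no hydrogens), `box`.}
#'     \item{truth}{`depth_series` and `tilt_series` (the simulated OU
#'       paths), plus `times`.}
#'   }
#' @export
make_trajectory <- function(spec) {
  stopifnot(inherits(spec, "TrajectorySpec"))
  set.seed(spec$seed)
  times <- seq(0, spec$duration, by = spec$frame_interval)
  nf <- length(times)
  nlip <- spec$n_lipids_per_leaflet
  # phosphates on a square grid, 8 A spacing, leaflet planes at +/- t/2
  side <- ceiling(sqrt(nlip))
  gx <- ((seq_len(nlip) - 1L) %% side) * 8
  gy <- ((seq_len(nlip) - 1L) %/% side) * 8
  box <- c(side * 8, side * 8, 2 * spec$thickness)

  depth <- ou_path(nf, spec$dye_depth, spec$depth_sd,
                   spec$depth_relaxation_time, spec$frame_interval,
                   spec$dye_depth + spec$initial_depth_offset)
  tilt <- ou_path(nf, spec$tilt_mean, spec$tilt_sd,
                  spec$depth_relaxation_time, spec$frame_interval,
                  spec$tilt_mean)

  n_p <- 2L * nlip
  n_dye <- spec$n_dye_atoms
  n_atoms <- n_p + n_dye
  coords <- array(NA_real_, c(n_atoms, 3, nf))
  cx <- box[1] / 2; cy <- box[2] / 2
  # rod atom offsets along the axis: N2 (first) at -L/2, C23 (last) at +L/2
  s <- seq(-spec$rod_length / 2, spec$rod_length / 2,
           length.out = n_dye)
  for (f in seq_len(nf)) {
    zj_top <- spec$thickness / 2 +
      stats::rnorm(nlip, sd = spec$p_jitter_sd)
    zj_bot <- -spec$thickness / 2 +
      stats::rnorm(nlip, sd = spec$p_jitter_sd)
    coords[seq_len(nlip), , f] <- cbind(gx, gy, zj_top)
    coords[nlip + seq_len(nlip), , f] <- cbind(gx, gy, zj_bot)
    th <- tilt[f] * pi / 180
    axis <- c(sin(th), 0, cos(th))
    mid <- c(cx, cy, spec$thickness / 2 - depth[f])
    coords[n_p + seq_len(n_dye), , f] <-
      cbind(mid[1] + s * axis[1], mid[2] + s * axis[2], mid[3] + s * axis[3])
  }
  atom_names <- c(rep("P", n_p), dye_atom_names(n_dye))
  traj <- structure(
    list(times = times, coords = coords, atom_names = atom_names,
         p_atom_indices = seq_len(n_p),
         dye_atom_indices = n_p + seq_len(n_dye),
         dye_heavy_indices = n_p + seq_len(n_dye),
         box = box),
    class = "BilayerTrajectory")
  list(trajectory = traj,
       truth = list(times = times, depth_series = depth, tilt_series = tilt))
}

#' @export
print.BilayerTrajectory <- function(x, ...) {
  cat(sprintf(
    "BilayerTrajectory: %d frames (%.1f-%.1f ns), %d atoms (%d P, %d dye)\n",
    length(x$times), min(x$times), max(x$times), length(x$atom_names),
    length(x$p_atom_indices), length(x$dye_atom_indices)))
  invisible(x)
}

#' Extract one frame of a trajectory
#'
#' @param trajectory A `BilayerTrajectory`.
#' @param i Frame index (1-based).
#' @return An object of class `BilayerFrame` holding that frame's time,
#'   coordinate matrix (`n_atoms x 3`, Angstrom) and atom bookkeeping.
#' @export
bilayer_frame <- function(trajectory, i) {
  stopifnot(inherits(trajectory, "BilayerTrajectory"))
  if (i < 1L || i > length(trajectory$times))
    stop(sprintf("frame %d outside 1..%d", i, length(trajectory$times)))
  structure(list(time = trajectory$times[i],
                 coordinates = trajectory$coords[, , i, drop = TRUE],
                 atom_names = trajectory$atom_names,
                 p_atom_indices = trajectory$p_atom_indices,
                 dye_atom_indices = trajectory$dye_atom_indices,
                 dye_heavy_indices = trajectory$dye_heavy_indices,
                 box = trajectory$box),
            class = "BilayerFrame")
}
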
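test_that("leaflet assignment splits planes and applies the tie rule", {
  fr <- flat_frame()
  lf <- assign_leaflets(fr)
  expect_equal(sort(lf$top), 1:4)
  expect_equal(sort(lf$bottom), 5:8)
  # odd atom exactly at the median goes to the bottom leaflet
  fr2 <- flat_frame()
  fr2$coordinates <- rbind(fr2$coordinates, c(0, 0, 0))
  fr2$atom_names <- c(fr2$atom_names, "P")
  fr2$p_atom_indices <- c(fr2$p_atom_indices, nrow(fr2$coordinates))
  lf2 <- assign_leaflets(fr2)
  expect_true(nrow(fr2$coordinates) %in% lf2$bottom)
  # degenerate: all phosphates coplanar
  fr3 <- flat_frame(thickness = 0)
  expect_error(assign_leaflets(fr3), "no bilayer")
  # jittered generator frame: assignment matches generation leaflets
  tj <- make_trajectory(tiny_traj_spec(p_jitter_sd = 2, thickness = 40,
                                       seed = 31))
  frj <- bilayer_frame(tj$trajectory, 3)
  lfj <- assign_leaflets(frj)
  expect_setequal(lfj$top, 1:16)       # generator fills top leaflet first
  expect_setequal(lfj$bottom, 17:32)
})

test_that("membrane thickness equals the P-plane mean gap, invariantly", {
  fr <- flat_frame(thickness = 40)
  expect_equal(membrane_thickness(fr), 40)
  # jittered planes vs brute-force mean difference
  set.seed(32)
  fr$coordinates[fr$p_atom_indices, 3] <-
    fr$coordinates[fr$p_atom_indices, 3] + rnorm(8, sd = 1.5)
  z <- fr$coordinates[fr$p_atom_indices, 3]
  brute <- mean(z[z > median(z)]) - mean(z[z <= median(z)])
  expect_equal(membrane_thickness(fr), brute, tolerance = 1e-12)
  # translation invariance
  fr7 <- fr
  fr7$coordinates[, 3] <- fr7$coordinates[, 3] + 7
  expect_equal(membrane_thickness(fr7), membrane_thickness(fr),
               tolerance = 1e-12)
})

test_that("tilt angle measures against the +z membrane normal", {
  up <- flat_frame(dye = rbind(c(0, 0, 10), c(0, 0, 14), c(0, 0, 6)))
  expect_equal(tilt_angle(up), 0)
  flat <- flat_frame(dye = rbind(c(0, 0, 10), c(4, 0, 10), c(8, 0, 10)))
  expect_equal(tilt_angle(flat), 90)
  down <- flat_frame(dye = rbind(c(0, 0, 14), c(0, 0, 10), c(0, 0, 6)))
  expect_equal(tilt_angle(down), 180)
  expect_equal(tilt_angle(down, fold = TRUE), 0)
  same <- flat_frame(dye = rbind(c(0, 0, 10), c(0, 0, 10), c(0, 0, 6)))
  expect_error(tilt_angle(same), "coincident")
  expect_error(tilt_angle(up, "N2", "QQ"), "not found")
  # generator round trip: a rod generated at 30 degrees reads back 30
  tj <- make_trajectory(tiny_traj_spec(tilt_mean = 30, tilt_sd = 0,
                                       seed = 33))
  expect_equal(tilt_angle(bilayer_frame(tj$trajectory, 5)), 30,
               tolerance = 1e-9)
})

test_that("heavy-atom RMSD removes rigid motion and matches bio3d", {
  set.seed(34)
  dye <- matrix(rnorm(15, sd = 3), 5)
  fr <- flat_frame(dye = dye, dye_names = c("N2", "N3", "C4", "C5", "C23"))
  expect_equal(heavy_atom_rmsd(fr, fr), 0)
  # pure rigid motion of the dye -> 0
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  fr2 <- fr
  fr2$coordinates[fr$dye_atom_indices, ] <-
    dye %*% t(rot) + matrix(c(3, -2, 5), 5, 3, byrow = TRUE)
  expect_lt(heavy_atom_rmsd(fr2, fr), 1e-9)
  # random perturbation vs bio3d superposition oracle
  fr3 <- fr
  fr3$coordinates[fr$dye_atom_indices, ] <- dye + rnorm(15, sd = 0.5)
  ours <- heavy_atom_rmsd(fr3, fr)
  fixed <- as.vector(t(dye))
  mobile <- rbind(as.vector(t(fr3$coordinates[fr$dye_atom_indices, ])))
  fitted <- bio3d::fit.xyz(fixed, mobile, fixed.inds = 1:15,
                           mobile.inds = 1:15)
  oracle <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) -
                                 dye)^2)))
  expect_equal(ours, oracle, tolerance = 1e-9)
  # underdetermined superposition rejected
  fr4 <- flat_frame(dye = dye[1:2, ], dye_names = c("N2", "C23"))
  expect_error(heavy_atom_rmsd(fr4, fr4), "3 heavy atoms")
})

test_that("interface distance is signed toward the bilayer center", {
  # atom at z = 15 below a plane whose mean z is 19 -> +4
  fr <- flat_frame(thickness = 38,
                   dye = rbind(c(0, 0, 15), c(0, 0, 13), c(0, 0, 11)))
  expect_equal(interface_distance(fr, "N2"), 4)
  expect_equal(interface_distance(fr, "C23"), 8)
  # atom exactly on the plane -> 0
  fr0 <- flat_frame(thickness = 38,
                    dye = rbind(c(0, 0, 19), c(0, 0, 13), c(0, 0, 11)))
  expect_equal(interface_distance(fr0, "N2"), 0)
  # bottom-leaflet dye: sign still points into the bilayer
  frb <- flat_frame(thickness = 38,
                    dye = rbind(c(0, 0, -15), c(0, 0, -13), c(0, 0, -11)))
  expect_equal(interface_distance(frb, "N2"), 4)
})

test_that("depth_series composes the per-frame operations", {
  tj <- make_trajectory(tiny_traj_spec(seed = 35))
  ds <- depth_series(tj$trajectory)
  expect_equal(nrow(ds), length(tj$trajectory$times))
  expect_true(all(diff(ds$time) > 0))
  # spot-check frames against single-frame calls
  ref <- bilayer_frame(tj$trajectory, 1)
  for (f in c(1L, 7L, nrow(ds))) {
    fr <- bilayer_frame(tj$trajectory, f)
    expect_equal(ds$thickness[f], membrane_thickness(fr))
    expect_equal(ds$tilt[f], tilt_angle(fr))
    expect_equal(ds$rmsd[f], heavy_atom_rmsd(fr, ref))
    expect_equal(ds$dist_edge1[f],
                 interface_distance(fr, "N2", proximal = "top"))
    expect_equal(ds$dist_edge2[f],
                 interface_distance(fr, "C23", proximal = "top"))
  }
  # constant trajectory -> all series constant
  tc <- make_trajectory(tiny_traj_spec(depth_sd = 0, tilt_sd = 0,
                                       p_jitter_sd = 0, seed = 36))
  dc <- depth_series(tc$trajectory)
  expect_equal(diff(range(dc$thickness)), 0)
  expect_equal(diff(range(dc$tilt)), 0)
  expect_lt(max(dc$rmsd), 1e-9)
})

test_that("window averages use the trailing closed window", {
  tj <- make_trajectory(trajectory_spec(n_lipids_per_leaflet = 16,
                                        duration = 300, frame_interval = 1,
                                        seed = 37))
  ds <- depth_series(tj$trajectory)
  wa <- window_average(ds, 100)
  expect_equal(wa$window, c(200, 300))
  expect_equal(wa$n_frames, sum(ds$time >= 200))
  manual <- mean((ds$dist_edge1[ds$time >= 200] +
                    ds$dist_edge2[ds$time >= 200]) / 2)
  expect_equal(wa$mean_midpoint, manual)
  expect_equal(wa$mean_midpoint,
               (wa$mean_dist_edge1 + wa$mean_dist_edge2) / 2)
  # constant series -> that constant
  tc <- make_trajectory(tiny_traj_spec(depth_sd = 0, tilt_sd = 0,
                                       p_jitter_sd = 0, dye_depth = 4.4,
                                       seed = 38))
  wc <- window_average(depth_series(tc$trajectory), 5)
  expect_equal(wc$mean_midpoint, 4.4)
  expect_error(window_average(ds, 1000), "span")
})

test_that("windowed means recover OU preset depths at the expected rate", {
  hits <- vapply(1:40, function(i) {
    tj <- make_trajectory(trajectory_spec(
      n_lipids_per_leaflet = 16, duration = 60, frame_interval = 0.2,
      dye_depth = 4.4, depth_sd = 1.5, depth_relaxation_time = 2,
      seed = 500 + i))
    ds <- depth_series(tj$trajectory)
    wa <- window_average(ds, 30)
    n_eff <- 30 / (2 * 2)
    abs(wa$mean_midpoint - 4.4) < 3 * 1.5 / sqrt(n_eff)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("recovered Laurdan depth exceeds di-4-ANEPPDHQ depth by > 5 A", {
  depth_of <- function(preset, seed) {
    tj <- make_trajectory(trajectory_spec(
      n_lipids_per_leaflet = 16, dye_depth = preset,
      duration = 150, frame_interval = 0.25, seed = seed))
    window_average(depth_series(tj$trajectory), 50)$mean_midpoint
  }
  for (s in 1:3) {
    gap <- depth_of("Laurdan", 600 + s) - depth_of("di4-ANEPPDHQ", 700 + s)
    expect_gt(gap, 5)
  }
})

test_that("convergence time detects matching running means", {
  tj <- make_trajectory(tiny_traj_spec(seed = 39))
  ds <- depth_series(tj$trajectory)
  expect_equal(convergence_time(ds, ds, tolerance = 0.5, hold = 5), 0)
  # constructed step case: series equal after t0, far apart before
  mk <- function(mid) {
    d <- data.frame(time = seq(0, 100, by = 1), thickness = 40, tilt = 30,
                    rmsd = 0, dist_edge1 = mid, dist_edge2 = mid)
    class(d) <- c("DepthSeries", "data.frame")
    d
  }
  a <- mk(rep(4.4, 101))
  bvals <- c(rep(10, 11), rep(4.4, 90))   # running mean decays after t=10
  b <- mk(bvals)
  ct <- convergence_time(a, b, tolerance = 1, hold = 10)
  run_b <- cumsum(bvals) / seq_along(bvals)
  t0 <- min(which(abs(run_b - 4.4) < 1)) - 1
  expect_equal(ct, t0)
  expect_gt(ct, 10)
  # never converging pair signals NA
  c_far <- mk(rep(30, 101))
  expect_message(ctna <- convergence_time(a, c_far, tolerance = 1,
                                          hold = 10),
                 "never")
  expect_true(is.na(ctna))
})

test_that("two-start trajectories converge finitely and reproducibly", {
  run_pair <- function() {
    m1 <- make_trajectory(trajectory_spec(
      n_lipids_per_leaflet = 16, duration = 300, frame_interval = 0.25,
      depth_relaxation_time = 20, seed = 801))
    m2 <- make_trajectory(trajectory_spec(
      n_lipids_per_leaflet = 16, duration = 300, frame_interval = 0.25,
      depth_relaxation_time = 20, initial_depth_offset = 5, seed = 802))
    convergence_time(depth_series(m1$trajectory),
                     depth_series(m2$trajectory),
                     tolerance = 1, hold = 20)
  }
  ct <- run_pair()
  expect_true(is.finite(ct))
  expect_gte(ct, 0)
  expect_identical(run_pair(), ct)
})
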
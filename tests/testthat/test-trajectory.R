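# Trajectory IO and the MD-analysis procedures, validated on constructed and
# generated fixtures.

make_traj <- function(frames, atoms = NULL, dt = 0.1) {
  nf <- length(frames)
  nat <- nrow(frames[[1]])
  xyz <- array(0, c(nf, nat, 3))
  for (k in seq_len(nf)) xyz[k, , ] <- frames[[k]]
  if (is.null(atoms))
    atoms <- data.frame(elety = paste0("A", seq_len(nat)), resid = "MOL",
                        resno = 1L, stringsAsFactors = FALSE)
  smolrate:::new_trajectory(dt * (seq_len(nf) - 1), xyz, atoms)
}

test_that("XYZ round trip preserves frames, names and times", {
  tr <- make_traj(list(matrix(1:15, 5, 3), matrix(15:1, 5, 3),
                       matrix(0, 5, 3)))
  td <- withr::local_tempdir()
  path <- file.path(td, "t.xyz")
  write_xyz(tr, path)
  tr2 <- read_trajectory(path)
  expect_equal(n_frames(tr2), 3)
  expect_equal(dim(tr2$xyz), c(3, 5, 3))
  expect_equal(tr2$xyz, tr$xyz, tolerance = 1e-6)
  expect_equal(tr2$times, tr$times, tolerance = 1e-9)
  expect_equal(tr2$atoms$elety, tr$atoms$elety)
  # truncated file names the offending frame
  txt <- readLines(path)
  writeLines(txt[1:(length(txt) - 2)], path)
  expect_error(read_trajectory(path), "frame 3")
})

test_that("single-model PDB reads as a one-frame trajectory", {
  td <- withr::local_tempdir()
  path <- file.path(td, "m.pdb")
  writeLines(c(
    "ATOM      1  CA  ARG A 372      11.000  12.000  13.000  1.00  0.00           C",
    "ATOM      2  CZ  ARG A 372      14.000  12.000  13.000  1.00  0.00           C",
    "END"), path)
  tr <- read_trajectory(path)
  expect_equal(n_frames(tr), 1)
  expect_equal(tr$atoms$elety, c("CA", "CZ"))
  expect_equal(tr$xyz[1, 1, ], c(11, 12, 13))
})

test_that("swing angle recovers constructed rotations and alignment removes rigid motion", {
  gen <- generate_telegraph_trajectory(rate = 0, duration = 10, dt = 1,
                                       jitter_sd = 0, pose_internal = 0,
                                       seed = 1)
  ref <- gen$reference
  # the reference against itself gives zero
  s0 <- swing_angle(ref, ref, resno = 372)
  expect_equal(s0$theta, 0, tolerance = 1e-9)
  # a 90-degree pose reads back as 90
  gen90 <- generate_telegraph_trajectory(rate = 0, duration = 10, dt = 1,
                                         jitter_sd = 0, pose_internal = 90,
                                         seed = 1)
  s90 <- swing_angle(gen90$trajectory, ref, resno = 372)
  expect_equal(s90$theta, rep(90, n_frames(gen90$trajectory)),
               tolerance = 1e-9)
  # rigid-body motion of whole frames is removed by backbone alignment
  gen2 <- generate_telegraph_trajectory(rate = 1.7, duration = 400, seed = 4)
  th_ref <- swing_angle(gen2$trajectory, ref, resno = 372)$theta
  moved <- gen2$trajectory
  set.seed(99)
  for (k in seq_len(n_frames(moved))) {
    ang <- stats::runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
                c(0, sin(ang[1]), cos(ang[1])))
    Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
                c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
    shift <- stats::rnorm(3, 0, 5)
    moved$xyz[k, , ] <- sweep(moved$xyz[k, , ] %*% (Rx %*% Rz), 2, shift, `+`)
  }
  th_moved <- swing_angle(moved, ref, resno = 372, align = 1:3)$theta
  expect_equal(th_moved, th_ref, tolerance = 1e-6)
  expect_error(swing_angle(gen2$trajectory, ref, resno = 1), "selection error")
})

test_that("hysteresis transition detection counts, filters and alternates", {
  # constant series: no transitions
  s <- swing_series(seq(0, 99, by = 1), rep(30, 100))
  s <- detect_transitions(s, min_dwell = 5)
  expect_equal(nrow(s$transitions), 0)
  expect_equal(s$rate, 0)
  # inverted thresholds rejected
  expect_error(detect_transitions(s, theta_internal = 100,
                                  theta_external = 60), "parameter error")
  # a single chattering spike below min_dwell is discarded
  th <- rep(30, 100); th[50] <- 130
  s2 <- detect_transitions(swing_series(seq(0, 99), th), min_dwell = 5)
  expect_equal(nrow(s2$transitions), 0)
  # the same spike with min_dwell below the frame interval is two transitions
  s3 <- detect_transitions(swing_series(seq(0, 99), th), min_dwell = 0.5)
  expect_equal(nrow(s3$transitions), 2)
  expect_equal(s3$transitions$direction, c("to_external", "to_internal"))
  # a clean two-state square wave: alternating directions
  th4 <- rep(c(30, 130), each = 25, times = 2)
  s4 <- detect_transitions(swing_series(seq_along(th4) - 1, th4),
                           min_dwell = 5)
  expect_equal(nrow(s4$transitions), 3)
  expect_true(all(s4$transitions$direction[c(1, 3)] == "to_external"))
  # intermediate angles between the thresholds keep the previous state
  th5 <- c(rep(30, 20), rep(80, 20), rep(30, 20))
  s5 <- detect_transitions(swing_series(seq_along(th5) - 1, th5))
  expect_equal(nrow(s5$transitions), 0)
  expect_true(all(s5$states == "internal"))
})

test_that("occupancy maps rasterize atoms and fractions correctly", {
  # one static atom: voxels inside its radius at occupancy 1, volume ~ sphere
  tr <- make_traj(list(matrix(c(0, 0, 0), 1), matrix(c(0, 0, 0), 1)))
  occ <- occupancy_map(tr, 1, voxel_size = 0.5, radius = 1.9)
  expect_true(all(occ$occupancy %in% c(0, 1)))
  expect_equal(visited_volume(occ, 0.5), 4 / 3 * pi * 1.9^3,
               tolerance = 0.1)
  # atom present in a voxel in one of two frames: occupancy 0.5
  tr2 <- make_traj(list(matrix(c(0, 0, 0), 1), matrix(c(30, 0, 0), 1)))
  occ2 <- occupancy_map(tr2, 1, voxel_size = 1, radius = 0.4)
  expect_equal(sort(unique(as.vector(occ2$occupancy))), c(0, 0.5))
  # threshold 1 excludes half-occupied voxels
  expect_equal(visited_volume(occ2, 1), 0)
  expect_gt(visited_volume(occ2, 0.5), 0)
  # visited volume is monotone as the threshold decreases
  v <- vapply(c(1, 0.6, 0.3, 0.01), function(t) visited_volume(occ2, t), 0)
  expect_true(all(diff(v) >= 0))
  expect_error(occupancy_map(tr, integer(0)), "empty")
  expect_error(occupancy_map(tr, 1, voxel_size = -1), "parameter error")
})

test_that("ligand displacement and orientation track constructed poses", {
  lig <- matrix(c(0, 0, 0, 2, 0, 0, 0, 1.5, 0), 3, 3, byrow = TRUE)
  ref <- make_traj(list(lig))
  # identity
  r0 <- com_orientation(make_traj(list(lig)), 1:3, ref)
  expect_equal(r0$displacement, 0, tolerance = 1e-9)
  expect_equal(r0$orientation, 0, tolerance = 1e-4)
  # pure translation: displacement without rotation
  r1 <- com_orientation(make_traj(list(sweep(lig, 2, c(3, 0, 0), `+`))),
                        1:3, ref)
  expect_equal(r1$displacement, 3, tolerance = 1e-9)
  expect_equal(r1$orientation, 0, tolerance = 1e-4)
  # a flip of nearly 180 degrees about x
  Rx <- rbind(c(1, 0, 0), c(0, -1, 0), c(0, 0, -1))
  r2 <- com_orientation(make_traj(list(lig %*% Rx)), 1:3, ref)
  expect_equal(r2$orientation, 180, tolerance = 1e-4)
  expect_error(com_orientation(make_traj(list(lig)), 1:2, ref), "3 atoms")
})

test_that("distance series and contact episodes are exact on fixtures", {
  # two atoms at a fixed 4 A separation
  fr <- lapply(1:5, function(i) matrix(c(0, 0, 0, 4, 0, 0), 2, 3,
                                       byrow = TRUE))
  tr <- make_traj(fr)
  ds <- distance_series(tr, 1, 2, cutoff = 3.5)
  expect_equal(ds$series$distance, rep(4, 5))
  expect_equal(nrow(ds$episodes), 0)
  # scheduled contact of 190 ns is recovered exactly
  fx <- generate_contact_fixture(data.frame(start = 10, end = 200),
                                 duration = 400, dt = 0.1)
  ds2 <- distance_series(fx, 1, 2, cutoff = 3.5)
  expect_equal(nrow(ds2$episodes), 1)
  expect_equal(ds2$episodes$duration, 190, tolerance = 1e-9)
  # two episodes separated by a single frame stay distinct
  fx3 <- generate_contact_fixture(
    data.frame(start = c(0, 10.1), end = c(10, 20)), duration = 30, dt = 0.1)
  ds3 <- distance_series(fx3, 1, 2, cutoff = 3.5)
  expect_equal(nrow(ds3$episodes), 2)
  # cutoff below the minimum distance: no episodes
  ds4 <- distance_series(fx, 1, 2, cutoff = 1)
  expect_equal(nrow(ds4$episodes), 0)
  # ambiguous selection errors
  expect_error(distance_series(fx, list(resid = "ARG"), list(elety = "ZZ")),
               "ambiguous|resolves")
})
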
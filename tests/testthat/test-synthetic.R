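# Synthetic-trajectory generators: determinism, ground-truth consistency and
# the statistical properties the estimators rely on.

test_that("telegraph generator is deterministic and self-consistent", {
  g1 <- generate_telegraph_trajectory(rate = 1.7, duration = 2000, seed = 7)
  g2 <- generate_telegraph_trajectory(rate = 1.7, duration = 2000, seed = 7)
  expect_identical(g1$trajectory$xyz, g2$trajectory$xyz)
  expect_identical(g1$ground_truth$transition_times,
                   g2$ground_truth$transition_times)
  g3 <- generate_telegraph_trajectory(rate = 1.7, duration = 2000, seed = 8)
  expect_false(identical(g1$trajectory$xyz, g3$trajectory$xyz))
  # emitted event list matches the counted transitions exactly
  expect_identical(g1$ground_truth$n_transitions,
                   length(g1$ground_truth$transition_times))
  # dwells partition the duration
  expect_equal(sum(g1$ground_truth$dwell_times), 2000, tolerance = 1e-9)
  # zero rate: constant pose, no transitions
  g0 <- generate_telegraph_trajectory(rate = 0, duration = 100, jitter_sd = 0,
                                      seed = 1)
  expect_equal(g0$ground_truth$n_transitions, 0L)
  expect_equal(length(unique(g0$trajectory$xyz[, 4, 1])), 1L)
})

test_that("telegraph transition counts have the Poisson mean rate * T", {
  n <- vapply(1:100, function(i)
    generate_telegraph_trajectory(rate = 1.7, duration = 2000,
                                  seed = 100 + i)$ground_truth$n_transitions,
    0L)
  # expected 1.7/us * 2 us = 3.4 per trajectory
  expect_equal(mean(n), 3.4, tolerance = 0.15)
})

test_that("telegraph dwell times are exponential", {
  gen <- generate_telegraph_trajectory(rate = 50, duration = 25000, seed = 3)
  dw <- gen$ground_truth$dwell_times
  dw <- dw[-length(dw)] # last dwell is censored by the end of the run
  expect_gt(length(dw), 1000)
  ks <- stats::ks.test(dw, stats::pexp, rate = 50 * 1e-3)
  expect_gt(ks$p.value, 0.01)
})

test_that("undersampled switching warns", {
  expect_warning(generate_telegraph_trajectory(rate = 1000, duration = 10,
                                               dt = 0.24, seed = 1),
                 "undersamples")
})

test_that("random-walk generator stays in the box and is seeded", {
  gen <- generate_random_walk_ligand(n_steps = 5000, seed = 2)
  p <- gen$trajectory$xyz[, 1, ]
  expect_true(all(p >= 0 & p <= 10))
  gen2 <- generate_random_walk_ligand(n_steps = 5000, seed = 2)
  expect_identical(gen$trajectory$xyz, gen2$trajectory$xyz)
  # zero steps: a single-point trajectory
  g0 <- generate_random_walk_ligand(n_steps = 0, seed = 1)
  expect_equal(n_frames(g0$trajectory), 1)
  expect_error(generate_random_walk_ligand(step_sd = 12), "parameter error")
})

test_that("long confined walk visits the whole box volume", {
  gen <- generate_random_walk_ligand(box = c(10, 10, 10), n_steps = 60000,
                                     seed = 5)
  occ <- occupancy_map(gen$trajectory, 1, voxel_size = 1, radius = 0)
  v <- visited_volume(occ, threshold = 1 / n_frames(gen$trajectory))
  expect_equal(v, gen$ground_truth$volume, tolerance = 0.03)
})

test_that("contact fixture follows its schedule and rejects overlaps", {
  fx <- generate_contact_fixture(data.frame(start = numeric(0),
                                            end = numeric(0)),
                                 duration = 10, dt = 0.1)
  ds <- distance_series(fx, 1, 2, cutoff = 3.5)
  expect_equal(nrow(ds$episodes), 0)
  expect_error(generate_contact_fixture(
    data.frame(start = c(0, 5), end = c(6, 9)), duration = 10),
    "overlap")
})

test_that("generated fixtures round-trip through files with their sidecar", {
  td <- withr::local_tempdir()
  gen <- generate_telegraph_trajectory(rate = 1.7, duration = 100, seed = 7)
  path <- file.path(td, "tele.xyz")
  write_generated(gen, path)
  back <- read_trajectory(path)
  expect_equal(back$xyz, gen$trajectory$xyz, tolerance = 1e-5)
  gt <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(gt$seed, 7)
  expect_equal(gt$n_transitions, gen$ground_truth$n_transitions)
})
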
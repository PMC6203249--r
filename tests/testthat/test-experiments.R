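# Scan orchestration and site splitting (coarse grids; the headline
# quantities are exercised at full resolution in test-acceptance.R).

test_that("affinity scan is monotone, deterministic, and zero at dG_b = 0", {
  fix <- coarse_base()
  s <- place_site(fix$geom, d = 3, r_b = 1.8, dG_b = -2)
  sc <- do.call(scan_affinity,
                c(list(fix$geom, s, c(0, -1, -2, -3), default_params), coarse))
  expect_identical(sc$delta_k[1], 0)
  expect_true(all(diff(sc$delta_k) > 0))
  sc2 <- do.call(scan_affinity,
                 c(list(fix$geom, s, c(0, -1, -2, -3), default_params), coarse))
  expect_identical(sc$delta_k, sc2$delta_k)
  expect_error(scan_affinity(fix$geom, s, c(-1, 2), default_params), "<= 0")
})

test_that("volume scan grows with V_b and reports a linear fit", {
  fix <- coarse_base()
  s <- place_site(fix$geom, d = 3, r_b = 1.8, dG_b = -2)
  sc <- do.call(scan_volume,
                c(list(fix$geom, s, s$V_b * c(0.5, 1, 1.5, 2), default_params),
                  coarse))
  expect_true(all(diff(sc$delta_k) > 0))
  expect_equal(sc$fit$model, "linear")
  expect_gt(sc$fit$r_squared, 0.9)
  # infeasibly large site reports the feasible range
  expect_error(do.call(scan_volume,
                       c(list(fix$geom, s, s$V_b * c(1, 300), default_params),
                         coarse)),
               "feasible")
})

test_that("reactivity scan: k0 grows with alpha and delta_k with k0", {
  fix <- coarse_base()
  s <- place_site(fix$geom, d = 3, r_b = 1.8, dG_b = -2)
  sc <- do.call(scan_reactivity,
                c(list(fix$geom, s, c(0.05, 0.5, 5, Inf), default_params),
                  coarse))
  expect_true(all(diff(sc$k0_M1s1) > 0))
  expect_true(all(diff(sc$delta_k) > -1e-9))
  # weakly reactive limit: rate and enhancement both vanish
  expect_lt(sc$k0_M1s1[1], 5e6)
  expect_lt(sc$delta_k[1], 0.5)
})

test_that("elongation scan shrinks delta_k and truncates infeasible points", {
  fix <- coarse_base()
  s <- place_site(fix$geom, d = 3, r_b = 2, dG_b = -2)
  sc <- do.call(scan_elongation,
                c(list(fix$geom, s, c(9, 13.5, 18), default_params), coarse))
  expect_equal(sc$values, c(9, 13.5, 18))
  expect_true(all(diff(sc$delta_k) < 0))
  # single-point scan: one value, no fit
  sc1 <- do.call(scan_elongation,
                 c(list(fix$geom, s, 9, default_params), coarse))
  expect_length(sc1$delta_k, 1)
  expect_null(sc1$fit)
  # a height so large the lumen is narrower than the site
  expect_warning(
    sct <- do.call(scan_elongation,
                   c(list(fix$geom, s, c(9, 100), default_params), coarse)),
    "infeasible")
  expect_equal(sct$values, 9)
})

test_that("split configurations preserve volume, avoid overlap, and seed", {
  g <- build_cylinder_model()
  single <- place_site(g, d = 3, r_b = 2, dG_b = -2)
  cfg <- generate_split_configurations(g, single, n_sites = 3, n_configs = 4,
                                       seed = 1, n_candidates = 300)
  expect_length(cfg, 4)
  for (cf in cfg) {
    expect_length(cf$sites, 3)
    # equal radii r_b / 3^(1/3) and total volume within 1%
    expect_equal(cf$sites[[1]]$r_b, 2 / 3^(1 / 3), tolerance = 1e-12)
    expect_equal(sum(vapply(cf$sites, `[[`, 0, "V_b")), single$V_b,
                 tolerance = 0.01)
    ctrs <- t(vapply(cf$sites, `[[`, numeric(3), "center"))
    dd <- as.matrix(stats::dist(ctrs))
    expect_true(all(dd[upper.tri(dd)] >= 2 * cf$sites[[1]]$r_b - 1e-9))
  }
  # scores sorted ascending; best configurations have small distribution gap
  scores <- vapply(cfg, `[[`, 0, "d_distance")
  expect_true(all(diff(scores) >= 0))
  cfg_b <- generate_split_configurations(g, single, n_sites = 3, n_configs = 4,
                                         seed = 1, n_candidates = 300)
  expect_identical(lapply(cfg, `[[`, "sites"), lapply(cfg_b, `[[`, "sites"))
  cfg_c <- generate_split_configurations(g, single, n_sites = 3, n_configs = 4,
                                         seed = 2, n_candidates = 300)
  expect_false(identical(lapply(cfg, `[[`, "sites"),
                         lapply(cfg_c, `[[`, "sites")))
  # n_sites = 1 returns the site itself at distance zero
  one <- generate_split_configurations(g, single, n_sites = 1)
  expect_identical(one[[1]]$sites[[1]], single)
  expect_identical(one[[1]]$d_distance, 0)
})

test_that("splitting a vanishing well leaves the rate exactly unchanged", {
  g <- build_cylinder_model()
  single <- place_site(g, d = 3, r_b = 2, dG_b = 0)
  ex <- do.call(split_site_experiment,
                c(list(g, single, n_sites = 3, n_configs = 3, seed = 1,
                       params = default_params, n_candidates = 100), coarse))
  expect_identical(unname(ex$delta_k_configs), rep(0, 3))
  expect_identical(ex$sd_delta_k, 0)
  expect_identical(ex$delta_k_single, 0)
})

test_that("the Wasserstein distance metric behaves like a metric", {
  a <- c(1, 2, 3)
  expect_equal(smolrate:::wasserstein1d(a, a), 0)
  b <- a + 1
  expect_equal(smolrate:::wasserstein1d(a, b), 1, tolerance = 0.3)
  expect_gte(smolrate:::wasserstein1d(a, a + 3),
             smolrate:::wasserstein1d(a, b))
})
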
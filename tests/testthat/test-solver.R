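# Solver verification against closed-form diffusion-reaction results.

test_that("isolated absorbing sphere reproduces the Smoluchowski limit", {
  sp <- build_sphere_model(radius = 2, bulk_radius = 150, resolution = 0.3)
  f <- solve_ssse(sp, NULL, transport_params())
  k <- compute_rate(f)
  expect_equal(k$k_A3ns, 4 * pi * 78 * 2, tolerance = 0.03)
  # exact unit conversion: 4 pi D a at D = 50, a = 2 is 1256.6 A^3/ns,
  # i.e. 7.568e8 /M/s
  expect_equal(rate_to_molar(4 * pi * 50 * 2), 7.56766e8, tolerance = 1e-5)
  expect_lt(k$flux_conservation, 0.005)
  # concentration profile rho(r) = c (1 - a/r)
  for (r in c(3, 5, 10)) {
    x <- r / sqrt(3)
    expect_equal(field_density(f, c(x, x, x)), 1 - 2 / r, tolerance = 0.15)
  }
})

test_that("finite reactivity follows the Collins-Kimball closed form", {
  sp <- build_sphere_model(radius = 2, bulk_radius = 150, resolution = 0.3)
  for (ada in c(0.1, 1, 10)) {
    alpha <- ada * 78 / 2
    k <- compute_rate(solve_ssse(sp, NULL, transport_params(alpha = alpha)))
    expect_equal(k$k_A3ns, 4 * pi * 78 * 2 / (1 + 78 / (alpha * 2)),
                 tolerance = 0.03)
  }
  # alpha a / D = 1 halves the diffusion limit
  kh <- compute_rate(solve_ssse(sp, NULL, transport_params(alpha = 78 / 2)))
  expect_equal(kh$k_A3ns, 2 * pi * 78 * 2, tolerance = 0.03)
})

test_that("rate converges under grid refinement", {
  p <- transport_params()
  k1 <- compute_rate(solve_ssse(build_sphere_model(
    radius = 2, bulk_radius = 60, resolution = 0.3), NULL, p))$k_A3ns
  k2 <- compute_rate(solve_ssse(build_sphere_model(
    radius = 2, bulk_radius = 60, resolution = 0.15), NULL, p))$k_A3ns
  expect_lt(abs(k1 - k2) / k2, 0.02)
})

test_that("no reactivity means equilibrium: Boltzmann density and zero rate", {
  g <- build_cylinder_model()
  s <- place_site(g, d = 3, r_b = 1.8, dG_b = -2)
  f <- solve_ssse(g, s, transport_params(alpha = 0),
                  resolution = 0.4, bulk_radius = 24)
  k <- compute_rate(f)
  expect_equal(k$k_A3ns, 0)
  rho_in <- field_density(f, s$center)
  rho_bulk <- field_density(f, c(0, 0, 20))
  # e^{2 / kBT} with kBT = 0.59616 kcal/mol at 300 K
  expect_equal(rho_in / rho_bulk, exp(2 / (0.0019872 * 300)),
               tolerance = 1e-6)
})

test_that("flux is conserved and bounded by the maximum principle", {
  fix <- coarse_base()
  s <- place_site(fix$geom, d = 3, r_b = 1.8, dG_b = -3)
  f <- smolrate:::solve_on_grid(fix$base$grid, s, default_params)
  expect_lt(abs(f$flux_cat - f$flux_bulk) / f$flux_cat, 0.005)
  expect_gte(min(f$u), -1e-10)
  expect_lte(max(f$u), default_params$c_bulk + 1e-10)
  expect_lt(f$residual, 1e-8)
})

test_that("rate is linear in bulk concentration and diffusion coefficient", {
  g <- build_cylinder_model()
  s <- place_site(g, d = 3, r_b = 1.8, dG_b = -2)
  k1 <- compute_rate(solve_ssse(g, s, transport_params(c_bulk = 1),
                                resolution = 0.8, bulk_radius = 24))
  k2 <- compute_rate(solve_ssse(g, s, transport_params(c_bulk = 2),
                                resolution = 0.8, bulk_radius = 24))
  expect_equal(k1$k_A3ns, k2$k_A3ns, tolerance = 1e-10)
  r1 <- compute_delta_k(g, s, transport_params(D = 78),
                        resolution = 0.8, bulk_radius = 24)
  r2 <- compute_delta_k(g, s, transport_params(D = 156),
                        resolution = 0.8, bulk_radius = 24)
  expect_equal(r2$k_A3ns / r1$k_A3ns, 2, tolerance = 1e-10)
  expect_equal(r2$delta_k, r1$delta_k, tolerance = 1e-10)
})

test_that("delta_k is exactly zero for a vanishing well", {
  fix <- coarse_base()
  s <- place_site(fix$geom, d = 3, r_b = 1.8, dG_b = 0)
  r <- delta_k_at(fix, s)
  expect_identical(r$delta_k, 0)
})

test_that("paired solves refuse a base field from a different problem", {
  fix <- coarse_base()
  s <- place_site(fix$geom, d = 3, r_b = 1.8, dG_b = -2)
  g_other <- elongate_at_constant_volume(fix$geom, 18)
  s_other <- place_site(g_other, d = 3, r_b = 1.8, dG_b = -2)
  expect_error(compute_delta_k(g_other, s_other, default_params,
                               base_field = fix$base),
               "mismatch")
  # and a base solved with a site is not a base
  with_site <- smolrate:::solve_on_grid(fix$base$grid, s, default_params)
  expect_error(compute_delta_k(fix$geom, s, default_params,
                               base_field = with_site),
               "site-free")
})

test_that("rate responds monotonically to reactivity, affinity, size, distance", {
  fix <- coarse_base()
  g <- fix$geom
  # k non-decreasing in alpha
  ks <- vapply(c(1, 10, Inf), function(a) {
    f <- smolrate:::solve_on_grid(fix$base$grid, NULL,
                                  transport_params(alpha = a))
    f$flux_cat
  }, 0)
  expect_true(all(diff(ks) > 0))
  # delta_k non-decreasing in |dG_b|
  dk_g <- vapply(c(-1, -2, -3), function(dg)
    delta_k_at(fix, place_site(g, 3, 1.8, dg))$delta_k, 0)
  expect_true(all(diff(dk_g) > 0))
  # delta_k non-decreasing in V_b
  dk_v <- vapply(c(1.4, 1.8, 2.2), function(rb)
    delta_k_at(fix, place_site(g, 3, rb, -2))$delta_k, 0)
  expect_true(all(diff(dk_v) > 0))
  # delta_k non-increasing in d
  dk_d <- vapply(c(3, 4, 5), function(d)
    delta_k_at(fix, place_site(g, d, 1.8, -2))$delta_k, 0)
  expect_true(all(diff(dk_d) < 0))
})

test_that("binding sites smaller than the grid are rejected", {
  g <- build_cylinder_model()
  s <- place_site(g, d = 3, r_b = 1.8, dG_b = -2)
  tiny <- binding_site(c(0, 0, 3), 0.2, -2)
  expect_error(solve_ssse(g, tiny, default_params,
                          resolution = 0.8, bulk_radius = 24),
               "refinement error")
})
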
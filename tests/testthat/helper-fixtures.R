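# Shared fixtures. Coarse discretization options keep the many-solve property
# tests fast; the acceptance suite uses the default resolution.

coarse <- list(resolution = 0.8, bulk_radius = 24)

default_params <- transport_params()

# memoized expensive fixtures shared across test files
.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# base solve of the default cylinder at default resolution (used by the
# full-resolution scientific checks)
acceptance_base <- function() {
  memo("acceptance_base", {
    geom <- build_cylinder_model()
    grid <- smolrate:::discretize(geom)
    list(geom = geom,
         base = smolrate:::solve_on_grid(grid, NULL, default_params))
  })
}

# coarse-grid base solve for property tests
coarse_base <- function() {
  memo("coarse_base", {
    geom <- build_cylinder_model()
    grid <- smolrate:::discretize(geom, resolution = coarse$resolution,
                                  bulk_radius = coarse$bulk_radius)
    list(geom = geom,
         base = smolrate:::solve_on_grid(grid, NULL, default_params))
  })
}

delta_k_at <- function(fix, site) {
  compute_delta_k(fix$geom, site, default_params, base_field = fix$base)
}

# minimal closed tetrahedron mesh (outward-oriented)
tetra_mesh <- function() {
  list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
       faces = rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
}
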
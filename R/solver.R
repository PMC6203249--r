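# Steady-state Smoluchowski solver.
#
# The substrate density rho(x) obeys  div( D e^{-U/kBT} grad( e^{U/kBT} rho ) ) = 0
# with rho = c_bulk on the far-field boundary, zero normal flux on reflecting
# walls, and the radiation condition J.n = alpha rho on the catalytic surface
# (alpha = Inf imposed as rho = 0 there). In the transformed variable
# u = e^{U/kBT} rho the equation is a pure conduction problem with mobility
# sigma = D e^{-U/kBT}; the finite-volume scheme combines the two half-cell
# mobilities harmonically across each face, which keeps the flux continuous
# across the square-well boundary. The symmetric positive-definite system is
# solved by sparse Cholesky factorization (deterministic, bit-reproducible).

site_potential <- function(grid, sites) {
  U <- numeric(prod(grid$dims))
  for (s in sites) {
    inside <- (grid$cx - s$center[1])^2 + (grid$cy - s$center[2])^2 +
      (grid$cz - s$center[3])^2 < s$r_b^2
    if (!any(inside))
      stop("refinement error: binding site at (",
           paste(signif(s$center, 4), collapse = ", "),
           ") contains no grid cells; reduce the resolution below r_b = ", s$r_b)
    U[inside] <- U[inside] + s$dG_b
  }
  U
}

as_site_list <- function(sites) {
  if (is.null(sites)) return(list())
  if (inherits(sites, "binding_site")) return(list(sites))
  stopifnot(all(vapply(sites, inherits, TRUE, "binding_site")))
  sites
}

# Assemble and solve on a prepared grid; internal work-horse shared by all
# user-facing entry points.
solve_on_grid <- function(grid, sites, params) {
  sites <- as_site_list(sites)
  U <- if (length(sites)) site_potential(grid, sites) else
    numeric(prod(grid$dims))
  sigma <- params$D * exp(-U / params$kBT)
  n <- grid$n
  g <- grid$fA / (grid$fdP / sigma[grid$fcp] + grid$fdQ / sigma[grid$fcq])
  gb <- grid$bA / (grid$bdP / sigma[grid$bcp] + grid$bdQ / params$D)
  alpha_eff <- grid$gamma * params$alpha
  gc_ <- if (is.infinite(params$alpha))
    grid$ct_A * sigma[grid$ct_cell] / grid$ct_d
  else if (params$alpha == 0) numeric(length(grid$ct_A))
  else grid$ct_A / (grid$ct_d / sigma[grid$ct_cell] + 1 / alpha_eff)

  diag_v <- numeric(n)
  add <- function(d, ix, val) {
    rs <- rowsum(val, ix)
    d[as.integer(rownames(rs))] <- d[as.integer(rownames(rs))] + rs[, 1]
    d
  }
  diag_v <- add(diag_v, grid$fp, g)
  diag_v <- add(diag_v, grid$fq, g)
  if (length(grid$bp)) diag_v <- add(diag_v, grid$bp, gb)
  if (length(grid$ct_p) && any(gc_ > 0)) diag_v <- add(diag_v, grid$ct_p, gc_)
  rhs <- numeric(n)
  if (length(grid$bp)) rhs <- add(rhs, grid$bp, gb * params$c_bulk)

  # solvent numbering grows with the linear cell index, so fp < fq: the
  # triplets below are exactly the upper triangle plus the diagonal
  A <- Matrix::sparseMatrix(
    i = c(grid$fp, seq_len(n)),
    j = c(grid$fq, seq_len(n)),
    x = c(-g, diag_v), dims = c(n, n), symmetric = TRUE)
  u <- as.numeric(Matrix::solve(A, rhs))

  res <- sqrt(sum((as.numeric(A %*% u) - rhs)^2)) /
    max(sqrt(sum(rhs^2)), .Machine$double.eps)
  flux_cat <- sum(gc_ * u[grid$ct_p]) * grid$mult
  flux_bulk <- sum(gb * (params$c_bulk - u[grid$bp])) * grid$mult

  structure(list(
    u = u, rho = u * exp(-U[grid$sol] / params$kBT),
    grid = grid, params = params, sites = sites,
    U_sol = U[grid$sol],
    flux_cat = flux_cat, flux_bulk = flux_bulk,
    residual = res,
    u_range = range(u)
  ), class = "concentration_field")
}

#' Solve the steady-state Smoluchowski equation
#'
#' Discretizes the geometry (if not already supplied as a grid) and solves for
#' the steady-state substrate density under the square-well potential of the
#' given binding sites.
#'
#' @param geom An `enzyme_geometry`.
#' @param sites A `binding_site`, a list of them, or `NULL` for no site.
#' @param params A `transport_params` object.
#' @param resolution,bulk_radius,grade_ratio Optional discretization
#'   overrides of the geometry's defaults.
#' @return A `concentration_field` with the solution, the integrated fluxes
#'   through the catalytic and bulk boundaries, and the residual norm of the
#'   discrete system.
#' @examples
#' \donttest{
#' geom <- build_cylinder_model()
#' f <- solve_ssse(geom, NULL, transport_params())
#' compute_rate(f)
#' }
#' @export
solve_ssse <- function(geom, sites = NULL, params = transport_params(),
                       resolution = NULL, bulk_radius = NULL,
                       grade_ratio = 1.35) {
  stopifnot(inherits(geom, "enzyme_geometry"),
            inherits(params, "transport_params"))
  grid <- discretize(geom, resolution = resolution, bulk_radius = bulk_radius,
                     grade_ratio = grade_ratio)
  solve_on_grid(grid, sites, params)
}

#' @export
print.concentration_field <- function(x, ...) {
  cat("Steady-state Smoluchowski solution\n")
  cat(sprintf("  cells: %d solvent, residual %.2e\n", x$grid$n, x$residual))
  cat(sprintf("  flux: catalytic %.6g, bulk %.6g (A^3/ns per c_bulk)\n",
              x$flux_cat, x$flux_bulk))
  invisible(x)
}

#' Probe the substrate density at points
#'
#' Returns the solved density rho (in units of `c_bulk`) at the solvent cells
#' containing the query points (`NA` outside the solvent domain).
#'
#' @param field A `concentration_field`.
#' @param points Numeric matrix (n x 3) of coordinates (A).
#' @return Numeric vector of densities.
#' @export
field_density <- function(field, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  g <- field$grid
  ix <- findInterval(points[, 1], g$xe, all.inside = TRUE)
  iy <- findInterval(points[, 2], g$ye, all.inside = TRUE)
  iz <- findInterval(points[, 3], g$ze, all.inside = TRUE)
  cell <- ix + (iy - 1L) * g$dims[1] + (iz - 1L) * prod(g$dims[1:2])
  solk <- g$idx[cell]
  out <- rep(NA_real_, nrow(points))
  has <- solk > 0
  out[has] <- field$rho[solk[has]]
  out
}

#' Reaction rate from the integrated catalytic flux
#'
#' The bimolecular rate constant is the substrate flux integrated over the
#' catalytic surface divided by the bulk concentration,
#' `k = (1/c_bulk) * integral_cat J.n dS`, reported both in A^3/ns and in
#' M^-1 s^-1 (exact factor 6.022140857e5).
#'
#' @param field A converged `concentration_field`.
#' @param params Transport parameters (defaults to those used in the solve).
#' @return A `rate_result` with elements `k_A3ns`, `k_M1s1`,
#'   `flux_conservation` (relative mismatch of catalytic vs bulk flux) and
#'   `residual`.
#' @export
compute_rate <- function(field, params = field$params) {
  k <- field$flux_cat / params$c_bulk
  if (k < -1e-8 * abs(field$flux_bulk))
    stop("discretization error: integrated catalytic flux is negative")
  structure(list(
    k_A3ns = k, k_M1s1 = rate_to_molar(k),
    flux_conservation = if (k > 0)
      abs(field$flux_cat - field$flux_bulk) / abs(field$flux_cat) else 0,
    residual = field$residual, params = params
  ), class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("k = %.6g A^3/ns = %.4g M^-1 s^-1\n", x$k_A3ns, x$k_M1s1))
  if (!is.null(x$k0_A3ns)) {
    cat(sprintf("k0 = %.6g A^3/ns = %.4g M^-1 s^-1 (no binding site)\n",
                x$k0_A3ns, x$k0_M1s1))
    cat(sprintf("delta_k = %+.4g %%\n", x$delta_k))
  }
  invisible(x)
}

#' Relative rate change from off-center binding
#'
#' Solves the steady-state Smoluchowski equation twice on the identical
#' discretization -- first without, then with the binding site(s) -- and
#' reports the base rate `k0`, the rate `k`, and the relative change
#' `delta_k = 100 (k - k0) / k0` in percent. Using one shared grid makes the
#' discretization error largely cancel in `delta_k`.
#'
#' @param geom An `enzyme_geometry`.
#' @param sites A `binding_site` or list of binding sites.
#' @param params A `transport_params`.
#' @param resolution,bulk_radius,grade_ratio Discretization overrides.
#' @param base_field Optional: a `concentration_field` from a previous
#'   site-free solve on the same geometry/discretization, to be reused as the
#'   `k0` solve.
#' @return A `rate_result` with `k`, `k0` (both unit systems) and `delta_k` (%).
#' @examples
#' \donttest{
#' geom <- build_cylinder_model()
#' site <- place_site(geom, d = 3, r_b = 1.8, dG_b = -2)
#' compute_delta_k(geom, site, transport_params())
#' }
#' @export
compute_delta_k <- function(geom, sites, params = transport_params(),
                            resolution = NULL, bulk_radius = NULL,
                            grade_ratio = 1.35, base_field = NULL) {
  if (!is.null(base_field)) {
    key <- c("kind", "lumen_height", "lumen_radius", "catalytic_radius",
             "radius", "source")
    if (!identical(base_field$grid$geom[key], geom[key]) ||
        !identical(base_field$params$alpha, params$alpha) ||
        !identical(base_field$params$D, params$D))
      stop("grid mismatch: the base field was solved on a different ",
           "geometry or transport setting; paired solves must share one grid")
    if (length(base_field$sites))
      stop("the base field must be a site-free solve")
  }
  grid <- if (!is.null(base_field)) base_field$grid else
    discretize(geom, resolution = resolution, bulk_radius = bulk_radius,
               grade_ratio = grade_ratio)
  f0 <- base_field %||% solve_on_grid(grid, NULL, params)
  f1 <- solve_on_grid(grid, sites, params)
  k0 <- f0$flux_cat / params$c_bulk
  k1 <- f1$flux_cat / params$c_bulk
  structure(list(
    k_A3ns = k1, k_M1s1 = rate_to_molar(k1),
    k0_A3ns = k0, k0_M1s1 = rate_to_molar(k0),
    delta_k = if (k0 > 0) 100 * (k1 - k0) / k0 else 0,
    flux_conservation = abs(f1$flux_cat - f1$flux_bulk) /
      max(abs(f1$flux_cat), .Machine$double.eps),
    residual = max(f0$residual, f1$residual),
    params = params, sites = as_site_list(sites),
    base_field = f0
  ), class = "rate_result")
}
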
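# Computational domains: parameterized cylindrical enzyme model, isolated
# reactive sphere, and imported molecular surface meshes, plus placement and
# validation of off-center binding sites.
#
# Coordinate convention (fixed for reproducible site placement): right-handed
# Cartesian, lengths in Angstrom, cylinder axis = z, catalytic base plane at
# z = 0, lumen opening toward +z.

#' Build the cylindrical enzyme model
#'
#' Constructs a generic enzyme as a cylindrical cavity (lumen) of height
#' `H_in` and base radius `r_in` carved into a reflecting body, open at the
#' top into a bulk region terminated by a hemispherical far-field boundary on
#' which the substrate concentration is held at its bulk value. The catalytic
#' center is a disk of radius `r_c` at the center of the cavity base, carrying
#' a radiation (partial-absorption) boundary condition; every other surface
#' reflects.
#'
#' With the default `H_in = 9`, `r_in = 6` the lumen volume is
#' `pi * 36 * 9 = 1017.9` A^3, matching a typical enzyme cavity volume of
#' about 1000 A^3.
#'
#' The catalytic patch radius is the one geometric parameter of the model that
#' is not fixed by the lumen dimensions. The default `r_c = 2.5` A is
#' calibrated so that the diffusion-limited base rate of the default model
#' (`alpha = Inf`, default `D`) lies on the order of 1e8 M^-1 s^-1, the
#' accepted scale of diffusion-limited enzyme-substrate association.
#'
#' @param H_in Lumen height (A).
#' @param r_in Lumen base radius (A).
#' @param r_c Catalytic patch (disk) radius (A); must not exceed `r_in`.
#' @param resolution Default grid spacing of the fine region used when the
#'   model is discretized (A). Must resolve the catalytic patch
#'   (`resolution < r_c`).
#' @param wall_thickness Thickness of the reflecting body around the lumen (A);
#'   geometric bookkeeping only (the body reflects regardless of thickness).
#' @param bulk_radius Radius (A) of the hemispherical far-field boundary,
#'   centered at the lumen opening. Default `3 * max(H_in, 2 * r_in) +
#'   wall_thickness`; doubling it is the standard truncation-error check.
#' @return An `enzyme_geometry` object.
#' @examples
#' geom <- build_cylinder_model()
#' lumen_volume(geom)
#' @export
build_cylinder_model <- function(H_in = 9, r_in = 6, r_c = 2.5,
                                 resolution = 0.4, wall_thickness = 3,
                                 bulk_radius = NULL) {
  stopifnot(H_in > 0, r_in > 0, r_c > 0, resolution > 0, wall_thickness > 0)
  if (r_c > r_in)
    stop("geometry error: catalytic radius r_c = ", r_c,
         " exceeds lumen radius r_in = ", r_in)
  if (resolution >= r_c)
    stop("resolution ", resolution, " A is coarser than the catalytic patch ",
         "(r_c = ", r_c, " A): patch would be unresolved")
  if (is.null(bulk_radius)) bulk_radius <- 3 * max(H_in, 2 * r_in) + wall_thickness
  stopifnot(bulk_radius > H_in + r_in)
  structure(list(
    kind = "cylinder",
    lumen_height = H_in,
    lumen_radius = r_in,
    catalytic_radius = r_c,
    wall_thickness = wall_thickness,
    body_extent = r_in + wall_thickness,
    bulk_radius = bulk_radius,
    resolution = resolution,
    cat_center = c(0, 0, 0),
    source = "cylinder"
  ), class = "enzyme_geometry")
}

#' Elongate a cylindrical model at constant lumen volume
#'
#' Returns a cylinder of height `new_H_in` whose lumen volume equals that of
#' `geom`, i.e. `r_in` is rescaled to `sqrt(V / (pi * new_H_in))`. Used to
#' study how the rate enhancement from an off-center site decays as the lumen
#' narrows into a tunnel.
#'
#' @param geom A cylindrical `enzyme_geometry`.
#' @param new_H_in New lumen height (A).
#' @return A new `enzyme_geometry` with identical volume.
#' @examples
#' g <- build_cylinder_model(H_in = 9, r_in = 6)
#' elongate_at_constant_volume(g, 36)$lumen_radius # exactly 3
#' @export
elongate_at_constant_volume <- function(geom, new_H_in) {
  stopifnot(inherits(geom, "enzyme_geometry"))
  if (geom$kind != "cylinder")
    stop("unsupported geometry: elongation is defined for cylinder models only")
  stopifnot(new_H_in > 0)
  V <- lumen_volume(geom)
  new_r <- sqrt(V / (pi * new_H_in))
  build_cylinder_model(
    H_in = new_H_in, r_in = new_r,
    r_c = min(geom$catalytic_radius, 0.999 * new_r),
    resolution = geom$resolution, wall_thickness = geom$wall_thickness
  )
}

#' Isolated reactive sphere in free solution
#'
#' The textbook validation geometry: a single sphere of radius `a` whose whole
#' surface carries the radiation condition, suspended in unbounded solvent.
#' The steady-state rate constant has the Collins-Kimball closed form
#' `k = 4 pi D a / (1 + D / (alpha a))`, reducing to the Smoluchowski limit
#' `4 pi D a` for a perfect absorber.
#'
#' The problem is symmetric in all three coordinate planes, so by default only
#' one octant is discretized (the symmetry planes are natural reflecting
#' boundaries of the finite-volume scheme) and the integrated flux is
#' multiplied by 8.
#'
#' @param radius Sphere radius `a` (A).
#' @param bulk_radius Radius of the spherical far-field boundary (A).
#' @param resolution Fine-region grid spacing (A).
#' @param octant Discretize one octant only (default) or the full domain.
#' @return An `enzyme_geometry` object of kind `"sphere"`.
#' @export
build_sphere_model <- function(radius = 2, bulk_radius = 150,
                               resolution = 0.3, octant = TRUE) {
  stopifnot(radius > 0, bulk_radius > 3 * radius, resolution < radius)
  structure(list(
    kind = "sphere",
    radius = radius,
    catalytic_radius = radius,
    bulk_radius = bulk_radius,
    resolution = resolution,
    octant = isTRUE(octant),
    source = "sphere"
  ), class = "enzyme_geometry")
}

#' @export
print.enzyme_geometry <- function(x, ...) {
  cat("Enzyme geometry [", x$kind, "]\n", sep = "")
  if (x$kind == "cylinder") {
    cat(sprintf("  lumen: H_in = %g A, r_in = %g A (volume %.1f A^3)\n",
                x$lumen_height, x$lumen_radius, lumen_volume(x)))
    cat(sprintf("  catalytic disk: r_c = %g A at the base center\n",
                x$catalytic_radius))
  } else if (x$kind == "sphere") {
    cat(sprintf("  reactive sphere: a = %g A%s\n", x$radius,
                if (x$octant) " (octant symmetry)" else ""))
  } else if (x$kind == "mesh") {
    cat(sprintf("  mesh: %d vertices, %d faces (%d catalytic)\n",
                nrow(x$mesh$vertices), nrow(x$mesh$faces),
                sum(x$mesh$label == "catalytic")))
  }
  cat(sprintf("  bulk boundary at %g A, fine resolution %g A\n",
              x$bulk_radius, x$resolution))
  invisible(x)
}

#' Lumen volume of a cylindrical model
#'
#' @param geom A cylindrical `enzyme_geometry`.
#' @return Volume `pi * r_in^2 * H_in` in A^3.
#' @export
lumen_volume <- function(geom) {
  stopifnot(inherits(geom, "enzyme_geometry"), geom$kind == "cylinder")
  pi * geom$lumen_radius^2 * geom$lumen_height
}

#' Analytic surface partition areas
#'
#' Areas of the three boundary partitions of the solvent domain: the reactive
#' catalytic patch, the reflecting walls and the fixed-concentration bulk
#' boundary. For the parametric cylinder these are closed forms; for a mesh
#' geometry the catalytic and wall areas are sums over tagged faces and the
#' bulk area is the enclosing sphere.
#'
#' @param geom An `enzyme_geometry`.
#' @return Named list with `catalytic`, `wall`, `bulk` and `total` (A^2).
#' @export
geometry_areas <- function(geom) {
  stopifnot(inherits(geom, "enzyme_geometry"))
  if (geom$kind == "cylinder") {
    a_cat <- pi * geom$catalytic_radius^2
    a_wall <- pi * (geom$lumen_radius^2 - geom$catalytic_radius^2) +
      2 * pi * geom$lumen_radius * geom$lumen_height +
      pi * (geom$bulk_radius^2 - geom$lumen_radius^2)
    a_bulk <- 2 * pi * geom$bulk_radius^2
  } else if (geom$kind == "sphere") {
    a_cat <- 4 * pi * geom$radius^2
    a_wall <- 0
    a_bulk <- 4 * pi * geom$bulk_radius^2
  } else {
    ar <- mesh_face_areas(geom$mesh)
    a_cat <- sum(ar[geom$mesh$label == "catalytic"])
    a_wall <- sum(ar[geom$mesh$label == "wall"])
    a_bulk <- if (any(geom$mesh$label == "bulk"))
      sum(ar[geom$mesh$label == "bulk"]) else 4 * pi * geom$bulk_radius^2
  }
  list(catalytic = a_cat, wall = a_wall, bulk = a_bulk,
       total = a_cat + a_wall + a_bulk)
}

#' Construct a binding site from an explicit center
#'
#' An off-center binding site is a spherical square well: the substrate
#' potential is `dG_b` (kcal/mol, non-positive) inside the sphere and zero
#' outside. The derived volume `V_b = 4/3 pi r_b^3` and the distance `d` from
#' the site center to the center of the catalytic patch are stored.
#'
#' @param center Numeric 3-vector, site center (A).
#' @param r_b Site radius (A).
#' @param dG_b Well depth (kcal/mol, `<= 0`).
#' @param geom Optional `enzyme_geometry`; if given, the site is validated to
#'   lie entirely inside the solvent domain.
#' @return A `binding_site` object.
#' @export
binding_site <- function(center, r_b, dG_b, geom = NULL) {
  stopifnot(is.numeric(center), length(center) == 3, r_b > 0)
  if (dG_b > 0) stop("dG_b must be <= 0 (a binding site attracts)")
  cat_ctr <- if (!is.null(geom) && !is.null(geom$cat_center))
    geom$cat_center else c(0, 0, 0)
  site <- structure(list(
    center = as.numeric(center), r_b = r_b, dG_b = dG_b,
    V_b = 4 / 3 * pi * r_b^3,
    d = sqrt(sum((center - cat_ctr)^2))
  ), class = "binding_site")
  if (!is.null(geom) && geom$kind == "cylinder") {
    cl <- site_clearance(geom, site)
    if (min(cl) < -1e-9) {
      bad <- which.min(cl)
      stop("placement error: site violates ", names(cl)[bad],
           " clearance by ", format(-cl[bad], digits = 3), " A")
    }
  }
  site
}

#' @export
print.binding_site <- function(x, ...) {
  cat(sprintf(
    "Binding site: r_b = %g A (V_b = %.2f A^3), dG_b = %g kcal/mol, d = %.3f A\n",
    x$r_b, x$V_b, x$dG_b, x$d))
  invisible(x)
}

# Clearances (in A, >= 0 means valid) of a site sphere against the solvent
# boundaries of a cylinder geometry. The catalytic disk is the set
# {z = 0, r_xy <= r_c}; the distance from a point to it is z if the point is
# over the disk, otherwise the distance to its rim.
site_clearance <- function(geom, site) {
  stopifnot(geom$kind == "cylinder")
  ctr <- site$center
  r_xy <- sqrt(ctr[1]^2 + ctr[2]^2)
  z <- ctr[3]
  dist_disk <- if (r_xy <= geom$catalytic_radius) z else
    sqrt((r_xy - geom$catalytic_radius)^2 + z^2)
  c(catalytic = dist_disk - site$r_b,
    wall_base = z - site$r_b,
    wall_side = geom$lumen_radius - r_xy - site$r_b,
    lumen_top = geom$lumen_height - z - site$r_b)
}

#' Place an off-center binding site at distance d from the catalytic center
#'
#' Places the site center at distance `d` from the center of the catalytic
#' patch. By default the center sits on the cavity axis directly above the
#' patch (the shortest-distance placement for a site that must clear the base
#' plane); a nonzero `tilt` moves it off-axis along the direction given by
#' `azimuth`, with the center at
#' `d * (sin(tilt) cos(azimuth), sin(tilt) sin(azimuth), cos(tilt))`.
#' The sphere must fit entirely inside the lumen without touching the walls or
#' the catalytic patch.
#'
#' @param geom A cylindrical `enzyme_geometry`.
#' @param d Distance from the site center to the catalytic center (A).
#' @param r_b Site radius (A).
#' @param dG_b Well depth (kcal/mol, `<= 0`).
#' @param azimuth Azimuthal placement angle (radians), used when `tilt > 0`.
#' @param tilt Polar angle from the cavity axis (radians); 0 = on-axis.
#' @return A validated `binding_site` with `d` equal to the request.
#' @examples
#' g <- build_cylinder_model()
#' place_site(g, d = 3, r_b = 1.8, dG_b = -2)
#' @export
place_site <- function(geom, d, r_b, dG_b, azimuth = 0, tilt = 0) {
  stopifnot(inherits(geom, "enzyme_geometry"), geom$kind == "cylinder",
            d > 0, r_b > 0)
  ctr <- d * c(sin(tilt) * cos(azimuth), sin(tilt) * sin(azimuth), cos(tilt))
  binding_site(ctr, r_b, dG_b, geom = geom)
}
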
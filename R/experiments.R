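# Parameter-scan and site-splitting experiments built on the solver: how the
# rate enhancement delta_k depends on the site's affinity, volume, the enzyme
# reactivity, lumen elongation, and on splitting one site into several with
# the same total volume.

new_scan <- function(variable, values, results, fixed, fit = NULL,
                     alt_fit = NULL) {
  structure(list(
    variable = variable, values = values,
    delta_k = vapply(results, `[[`, 0, "delta_k"),
    k_A3ns = vapply(results, `[[`, 0, "k_A3ns"),
    k0_A3ns = vapply(results, `[[`, 0, "k0_A3ns"),
    k0_M1s1 = vapply(results, `[[`, 0, "k0_M1s1"),
    fixed = fixed, fit = fit, alt_fit = alt_fit
  ), class = "ssse_scan")
}

#' @export
print.ssse_scan <- function(x, ...) {
  cat("Scan over", x$variable, "\n")
  print(data.frame(value = x$values, delta_k = x$delta_k,
                   k0_M1s1 = x$k0_M1s1))
  if (!is.null(x$fit))
    cat(sprintf("  %s fit: R^2 = %.4f\n", x$fit$model, x$fit$r_squared))
  invisible(x)
}

#' @export
as.data.frame.ssse_scan <- function(x, ...) {
  data.frame(variable = x$variable, value = x$values, delta_k = x$delta_k,
             k_A3ns = x$k_A3ns, k0_A3ns = x$k0_A3ns, k0_M1s1 = x$k0_M1s1)
}

fit_linear <- function(x, y) {
  fm <- stats::lm(y ~ x)
  list(model = "linear",
       intercept = unname(stats::coef(fm)[1]),
       slope = unname(stats::coef(fm)[2]),
       r_squared = summary(fm)$r.squared,
       sse = sum(stats::residuals(fm)^2),
       predict = function(x0) unname(stats::coef(fm)[1] + stats::coef(fm)[2] * x0))
}

# Exponential law y = A exp(x / b), fitted on log(y); points with y <= 0 are
# excluded from the log fit. SSE is reported on the original scale so the two
# model families can be compared directly.
fit_exponential <- function(x, y) {
  ok <- y > 0
  if (sum(ok) < 2)
    return(list(model = "exponential", A = NA, b = NA, r_squared = NA, sse = NA))
  fm <- stats::lm(log(y[ok]) ~ x[ok])
  A <- exp(unname(stats::coef(fm)[1]))
  invb <- unname(stats::coef(fm)[2])
  pred <- A * exp(invb * x)
  list(model = "exponential", A = A, b = 1 / invb,
       r_squared = summary(fm)$r.squared,
       sse = sum((y - pred)^2),
       predict = function(x0) A * exp(invb * x0))
}

run_scan_point <- function(geom, site, params, grid_opts, base_field) {
  do.call(compute_delta_k, c(list(geom = geom, sites = site, params = params,
                                  base_field = base_field), grid_opts))
}

#' Scan the binding-site affinity
#'
#' Solves for `delta_k` at each well depth in `dG_b_values`, holding the site
#' geometry fixed, and fits the exponential law
#' `delta_k = A exp(-dG_b / b)` on the log scale (a linear fit is also
#' reported for model discrimination). Note that for well depths beyond about
#' one kBT the response saturates -- the site behaves as a high-mobility
#' inclusion whose effect no longer grows with the Boltzmann factor -- so the
#' exponential law is only a rough description over wide affinity ranges.
#'
#' @param geom Cylindrical `enzyme_geometry`.
#' @param site_template A `binding_site` whose center/radius are used at every
#'   scan point.
#' @param dG_b_values Well depths (kcal/mol, all `<= 0`), at least 4 for a fit.
#' @param params `transport_params`.
#' @param ... Discretization overrides (`resolution`, `bulk_radius`,
#'   `grade_ratio`).
#' @return An `ssse_scan` with one `delta_k` per affinity and the fits.
#' @export
scan_affinity <- function(geom, site_template, dG_b_values,
                          params = transport_params(), ...) {
  stopifnot(all(dG_b_values <= 0))
  grid_opts <- list(...)
  grid <- do.call(discretize, c(list(geom = geom), grid_opts))
  base <- solve_on_grid(grid, NULL, params)
  res <- lapply(dG_b_values, function(dg) {
    site <- binding_site(site_template$center, site_template$r_b, dg)
    compute_delta_k(geom, site, params, base_field = base)
  })
  dk <- vapply(res, `[[`, 0, "delta_k")
  new_scan("dG_b", dG_b_values, res,
           fixed = list(site = site_template, params = params),
           fit = if (length(dk) >= 4) fit_exponential(-dG_b_values, dk),
           alt_fit = if (length(dk) >= 4) fit_linear(-dG_b_values, dk))
}

#' Scan the binding-site volume
#'
#' Varies the site volume `V_b` at fixed center, affinity and reactivity, and
#' fits `delta_k` linearly in `V_b`. An exponential fit is also reported for
#' model discrimination.
#'
#' @param geom Cylindrical `enzyme_geometry`.
#' @param site_template `binding_site` providing center and affinity.
#' @param V_b_values Site volumes (A^3); each radius `(3 V / 4 pi)^(1/3)` must
#'   fit at the template center.
#' @param params `transport_params`.
#' @param ... Discretization overrides.
#' @return An `ssse_scan`.
#' @export
scan_volume <- function(geom, site_template, V_b_values,
                        params = transport_params(), ...) {
  radii <- (3 * V_b_values / (4 * pi))^(1 / 3)
  sites <- vector("list", length(radii))
  for (i in seq_along(radii)) {
    sites[[i]] <- tryCatch(
      binding_site(site_template$center, radii[i], site_template$dG_b,
                   geom = geom),
      error = function(e) {
        feas <- V_b_values[vapply(radii, function(r) !inherits(tryCatch(
          binding_site(site_template$center, r, site_template$dG_b, geom = geom),
          error = identity), "error"), TRUE)]
        stop("placement failed at V_b = ", signif(V_b_values[i], 4),
             " A^3; feasible volumes at this center: ",
             paste(signif(feas, 4), collapse = ", "), call. = FALSE)
      })
  }
  grid_opts <- list(...)
  grid <- do.call(discretize, c(list(geom = geom), grid_opts))
  base <- solve_on_grid(grid, NULL, params)
  res <- lapply(sites, function(s)
    compute_delta_k(geom, s, params, base_field = base))
  dk <- vapply(res, `[[`, 0, "delta_k")
  new_scan("V_b", V_b_values, res,
           fixed = list(site = site_template, params = params),
           fit = if (length(dk) >= 3) fit_linear(V_b_values, dk),
           alt_fit = if (length(dk) >= 3) fit_exponential(V_b_values, dk))
}

#' Scan the intrinsic reactivity
#'
#' For each reactivity `alpha` the base rate `k0(alpha)` and the rate change
#' `delta_k(alpha)` are computed; `delta_k` is reported against `k0` because
#' the enhancement from off-center binding only becomes significant once the
#' reaction is heavily influenced by diffusion (`k0 > 1e7` per M s).
#'
#' @param geom Cylindrical `enzyme_geometry`.
#' @param site A `binding_site`.
#' @param alpha_values Reactivities (A/ns), positive or `Inf`.
#' @param params `transport_params` (its `alpha` is overridden per point).
#' @param ... Discretization overrides.
#' @return An `ssse_scan` whose `values` are the alphas; `k0_M1s1` gives the
#'   matching base rates.
#' @export
scan_reactivity <- function(geom, site, alpha_values,
                            params = transport_params(), ...) {
  stopifnot(all(alpha_values > 0 | is.infinite(alpha_values)))
  grid_opts <- list(...)
  grid <- do.call(discretize, c(list(geom = geom), grid_opts))
  res <- lapply(alpha_values, function(a) {
    p <- transport_params(D = params$D, alpha = a, c_bulk = params$c_bulk,
                          temperature = params$temperature)
    base <- solve_on_grid(grid, NULL, p)
    compute_delta_k(geom, site, p, base_field = base)
  })
  new_scan("alpha", alpha_values, res,
           fixed = list(site = site, params = params))
}

#' Scan lumen elongation at constant volume
#'
#' Elongates the cylinder to each height in `H_in_values` (holding the lumen
#' volume constant) and recomputes `delta_k` for a site placed at the same
#' `(d, r_b, dG_b)` in every geometry. The enhancement decays as the lumen
#' narrows into a tunnel.
#'
#' @param geom Reference cylindrical `enzyme_geometry`.
#' @param site Reference `binding_site` (placement parameters reused).
#' @param H_in_values Lumen heights (A).
#' @param params `transport_params`.
#' @param ... Discretization overrides.
#' @return An `ssse_scan`; infeasible placements at narrow radii truncate the
#'   scan with a warning.
#' @export
scan_elongation <- function(geom, site, H_in_values,
                            params = transport_params(), ...) {
  grid_opts <- list(...)
  vals <- numeric(0); res <- list()
  for (H in H_in_values) {
    g <- elongate_at_constant_volume(geom, H)
    s <- tryCatch(place_site(g, d = site$d, r_b = site$r_b, dG_b = site$dG_b),
                  error = function(e) NULL)
    if (is.null(s)) {
      warning("site (d = ", site$d, ", r_b = ", site$r_b,
              ") infeasible at H_in = ", H, "; scan truncated")
      next
    }
    res[[length(res) + 1]] <- do.call(compute_delta_k,
                                      c(list(geom = g, sites = s, params = params), grid_opts))
    vals <- c(vals, H)
  }
  new_scan("H_in", vals, res, fixed = list(site = site, params = params))
}

# 1-Wasserstein distance between two samples, on a common histogram with the
# given bin width (distances here are in A).
wasserstein1d <- function(a, b, bin = 0.25) {
  nb <- ceiling(max(a, b) / bin) + 1L
  ca <- cumsum(tabulate(pmin(floor(a / bin) + 1L, nb), nbins = nb)) / length(a)
  cb <- cumsum(tabulate(pmin(floor(b / bin) + 1L, nb), nbins = nb)) / length(b)
  sum(abs(ca - cb)) * bin
}

# Lattice points (spacing `by`) inside a sphere; used to build d-distributions.
sphere_lattice <- function(center, r, by = 0.25) {
  ax <- seq(-r, r, by = by)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  g <- g[rowSums(g^2) <= r^2, , drop = FALSE]
  sweep(g, 2, center, `+`)
}

site_d_distribution <- function(sites, by = 0.25) {
  pts <- do.call(rbind, lapply(sites, function(s)
    sphere_lattice(s$center, s$r_b, by = by)))
  sqrt(rowSums(pts^2))
}

#' Randomly split a binding site into several with matched d-distribution
#'
#' Draws candidate configurations of `n_sites` equal-radius, non-overlapping
#' spheres (total volume equal to the single site's) uniformly inside the
#' lumen, scores each by the 1-Wasserstein distance between its distribution
#' of distances-to-catalytic-center (over interior lattice points) and the
#' single site's, and returns the `n_configs` best-scoring configurations.
#'
#' @param geom Cylindrical `enzyme_geometry`.
#' @param single_site The reference `binding_site`.
#' @param n_sites Number of split sites (>= 2; 1 returns the site itself).
#' @param n_configs Number of configurations to keep.
#' @param seed RNG seed (recorded in the output).
#' @param n_candidates Candidate sampling budget.
#' @param bin Histogram bin width (A) for the distance distributions.
#' @return A list of `split_configuration`s, each with `sites` (list of
#'   `binding_site`), `d_distance` (Wasserstein score) and `seed`.
#' @export
generate_split_configurations <- function(geom, single_site, n_sites = 3,
                                          n_configs = 8, seed = 1,
                                          n_candidates = 10000, bin = 0.25) {
  stopifnot(geom$kind == "cylinder", n_sites >= 1, n_configs >= 1)
  if (n_sites == 1)
    return(list(structure(list(sites = list(single_site), d_distance = 0,
                               seed = seed), class = "split_configuration")))
  r_s <- single_site$r_b / n_sites^(1 / 3)
  ref_d <- site_d_distribution(list(single_site), by = bin)
  r_in <- geom$lumen_radius; H <- geom$lumen_height; r_c <- geom$catalytic_radius
  if (r_in - r_s <= 0 || H - 2 * r_s <= 0)
    stop("feasibility error: split spheres of radius ", signif(r_s, 4),
         " do not fit in the lumen")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  draw_center <- function() {
    repeat {
      x <- stats::runif(1, -r_in + r_s, r_in - r_s)
      y <- stats::runif(1, -r_in + r_s, r_in - r_s)
      z <- stats::runif(1, r_s, H - r_s)
      r_xy <- sqrt(x^2 + y^2)
      if (r_xy > r_in - r_s) next
      dist_disk <- if (r_xy <= r_c) z else sqrt((r_xy - r_c)^2 + z^2)
      if (dist_disk <= r_s) next
      return(c(x, y, z))
    }
  }
  cands <- vector("list", n_candidates)
  scores <- rep(Inf, n_candidates)
  for (i in seq_len(n_candidates)) {
    centers <- list(); attempts <- 0L
    while (length(centers) < n_sites) {
      attempts <- attempts + 1L
      if (attempts > 1000L)
        stop("feasibility error: could not place ", n_sites,
             " non-overlapping spheres after 1000 attempts")
      ctr <- draw_center()
      clash <- any(vapply(centers, function(c0)
        sum((c0 - ctr)^2) < (2 * r_s)^2, TRUE))
      if (!clash) centers[[length(centers) + 1]] <- ctr
    }
    sites <- lapply(centers, function(c0)
      binding_site(c0, r_s, single_site$dG_b))
    cands[[i]] <- sites
    scores[i] <- wasserstein1d(site_d_distribution(sites, by = bin), ref_d,
                               bin = bin)
  }
  keep <- order(scores)[seq_len(n_configs)]
  lapply(keep, function(i)
    structure(list(sites = cands[[i]], d_distance = scores[i], seed = seed),
              class = "split_configuration"))
}

#' Site-splitting experiment
#'
#' Compares `delta_k` from one off-center site against the mean over randomly
#' placed configurations of `n_sites` sites with the same total volume and
#' matched distance-to-catalytic-center distributions. All solves share one
#' discretization and one base solve.
#'
#' @param geom Cylindrical `enzyme_geometry`.
#' @param single_site The reference `binding_site`.
#' @param n_sites Sites per split configuration.
#' @param n_configs Number of configurations.
#' @param seed RNG seed for configuration sampling.
#' @param params `transport_params`.
#' @param n_candidates Candidate budget for configuration selection.
#' @param ... Discretization overrides.
#' @return A `split_experiment`: per-configuration `delta_k`, their mean and
#'   standard deviation, the single-site `delta_k`, and the configurations.
#' @export
split_site_experiment <- function(geom, single_site, n_sites = 3,
                                  n_configs = 8, seed = 1,
                                  params = transport_params(),
                                  n_candidates = 10000, ...) {
  configs <- generate_split_configurations(geom, single_site, n_sites,
                                           n_configs, seed,
                                           n_candidates = n_candidates)
  grid_opts <- list(...)
  grid <- do.call(discretize, c(list(geom = geom), grid_opts))
  base <- solve_on_grid(grid, NULL, params)
  single <- compute_delta_k(geom, single_site, params, base_field = base)
  dk <- vapply(configs, function(cf)
    compute_delta_k(geom, cf$sites, params, base_field = base)$delta_k, 0)
  structure(list(
    delta_k_configs = dk,
    mean_delta_k = mean(dk),
    sd_delta_k = stats::sd(dk),
    delta_k_single = single$delta_k,
    k0_M1s1 = single$k0_M1s1,
    configs = configs, seed = seed
  ), class = "split_experiment")
}

#' @export
print.split_experiment <- function(x, ...) {
  cat(sprintf("Split-site experiment (%d configs): delta_k = %.3f +/- %.3f %%\n",
              length(x$delta_k_configs), x$mean_delta_k, x$sd_delta_k))
  cat(sprintf("Single site: delta_k = %.3f %%\n", x$delta_k_single))
  invisible(x)
}
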
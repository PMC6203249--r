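# Physical constants and transport parameters.

# Boltzmann constant in kcal/(mol K)
.kB_kcal <- 0.0019872

# Exact conversion of a bimolecular rate constant from A^3/ns to M^-1 s^-1:
# 1 A^3 = 1e-27 L, 1 ns = 1e-9 s, times Avogadro's number.
.A3NS_TO_M1S1 <- 6.022140857e5

#' Transport parameters for the steady-state Smoluchowski equation
#'
#' Bundles the physical parameters of the diffusing substrate: its diffusion
#' coefficient, the intrinsic reactivity of the catalytic surface, the bulk
#' reference concentration and the temperature. The thermal energy
#' `kBT = 0.0019872 * T` kcal/mol is derived and stored.
#'
#' The reactivity `alpha` enters through the radiation (Collins-Kimball)
#' boundary condition on the catalytic surface, `J.n = alpha * rho`;
#' `alpha = Inf` is the perfectly absorbing (diffusion-limited) surface and is
#' imposed as `rho = 0` there. `alpha = 0` switches the reaction off.
#'
#' @param D Diffusion coefficient in A^2/ns. The default, 78 A^2/ns
#'   (7.8e-6 cm^2/s), is typical for a small aromatic solute in water at room
#'   temperature.
#' @param alpha Intrinsic surface reactivity in A/ns; `Inf` allowed.
#' @param c_bulk Far-field substrate concentration (dimensionless reference
#'   scale; the rate constant is independent of it).
#' @param temperature Temperature in K.
#' @return An object of class `transport_params`.
#' @examples
#' transport_params()
#' transport_params(alpha = 10)
#' @export
transport_params <- function(D = 78, alpha = Inf, c_bulk = 1, temperature = 300) {
  stopifnot(is.numeric(D), length(D) == 1, D > 0)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0)
  stopifnot(is.numeric(c_bulk), length(c_bulk) == 1, c_bulk > 0)
  stopifnot(is.numeric(temperature), length(temperature) == 1, temperature > 0)
  structure(list(
    D = D, alpha = alpha, c_bulk = c_bulk, temperature = temperature,
    kBT = .kB_kcal * temperature
  ), class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat("Transport parameters:\n")
  cat(sprintf("  D      = %g A^2/ns\n", x$D))
  cat(sprintf("  alpha  = %g A/ns\n", x$alpha))
  cat(sprintf("  c_bulk = %g\n", x$c_bulk))
  cat(sprintf("  T      = %g K (kBT = %.5f kcal/mol)\n", x$temperature, x$kBT))
  invisible(x)
}

#' Convert a rate constant from A^3/ns to M^-1 s^-1
#'
#' Applies the exact factor 6.022140857e5 (Avogadro's number times the
#' volume and time unit conversions).
#'
#' @param k_A3ns Rate constant(s) in A^3/ns.
#' @return Rate constant(s) in M^-1 s^-1.
#' @examples
#' rate_to_molar(4 * pi * 78 * 2) # diffusion-limited 2-A absorber, D = 78
#' @export
rate_to_molar <- function(k_A3ns) k_A3ns * .A3NS_TO_M1S1
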
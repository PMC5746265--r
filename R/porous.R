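#' Coil packing density
#'
#' Fraction of the aneurysm dome volume occupied by coil material,
#' expressed as a percentage: `100 * CV / DV`.
#'
#' @param CV total coil volume (mm^3), `0 <= CV <= DV`.
#' @param DV dome volume (mm^3), strictly positive.
#' @return packing density in percent, in `[0, 100]`.
#' @examples
#' packing_density(21.21, 54.8) # ~38.7 %
#' @export
packing_density <- function(CV, DV) {
  if (!is.numeric(CV) || !is.numeric(DV)) stop("CV and DV must be numeric")
  if (any(DV <= 0)) stop("dome volume DV must be positive")
  if (any(CV < 0)) stop("coil volume CV must be nonnegative")
  if (any(CV > DV)) stop("over-packing: coil volume CV exceeds dome volume DV")
  100 * CV / DV
}

#' Porosity of the coiled dome
#'
#' Void fraction `kappa = 1 - packing/100` of the coil mass treated as a
#' homogeneous porous medium.
#'
#' @param packing packing density in percent, in `[0, 100]`.
#' @return porosity in `[0, 1]`.
#' @export
porosity <- function(packing) {
  if (!is.numeric(packing)) stop("packing density must be numeric")
  if (any(packing < 0 | packing > 100))
    stop("packing density must lie in [0, 100] percent")
  1 - packing / 100
}

#' Ergun resistance coefficients
#'
#' Packed-bed inertial and viscous resistance coefficients for a bed of
#' uniform particles of diameter `D_P` at porosity `kappa`:
#' `alpha = 1.75 * rho * (1 - kappa) / (kappa^3 * D_P)` (kg m^-4) and
#' `beta = 150 * mu * (1 - kappa)^2 / (kappa^3 * D_P^2)` (Pa s m^-2).
#' At `kappa = 1` (no coil) both vanish exactly; both diverge as the bed
#' closes (`kappa -> 0`).
#'
#' @param kappa porosity, `0 < kappa <= 1`.
#' @param D_P particle diameter in metres (default 0.010 in = 2.54e-4 m,
#'   the primary diameter of a bare platinum coil).
#' @param rho fluid density (kg/m^3), default blood.
#' @param mu dynamic viscosity (Pa s), default blood.
#' @return list with elements `alpha` and `beta`.
#' @export
ergun_coefficients <- function(kappa, D_P = COIL_D_P_M, rho = BLOOD_RHO,
                               mu = BLOOD_MU) {
  if (!is.numeric(kappa)) stop("kappa must be numeric")
  if (any(kappa <= 0)) stop("kappa = 0 implies infinite resistance")
  if (any(kappa > 1)) stop("porosity kappa cannot exceed 1")
  if (D_P <= 0) stop("particle diameter D_P must be positive")
  list(alpha = 1.75 * rho * (1 - kappa) / (kappa^3 * D_P),
       beta  = 150 * mu * (1 - kappa)^2 / (kappa^3 * D_P^2))
}

#' Porous resistance coefficient set
#'
#' Bundles porosity, particle diameter, fluid properties and the derived
#' Ergun coefficients into the resistance law `K(|v|) = alpha |v| + beta`
#' applied in the coiled dome.  Supply either `kappa` directly or a
#' `packing` density in percent.
#'
#' @param kappa porosity in `(0, 1]`; overrides `packing` when given.
#' @param packing packing density in percent.
#' @param D_P particle diameter (m).
#' @param rho,mu fluid density and viscosity (SI).
#' @return object of class `porous_coefficients`.
#' @export
porous_coefficients <- function(kappa = NULL, packing = NULL,
                                D_P = COIL_D_P_M, rho = BLOOD_RHO,
                                mu = BLOOD_MU) {
  if (is.null(kappa)) {
    if (is.null(packing)) stop("supply either kappa or packing")
    kappa <- porosity(packing)
  }
  if (length(kappa) != 1L) stop("kappa must be a single value")
  co <- ergun_coefficients(kappa, D_P = D_P, rho = rho, mu = mu)
  structure(list(kappa = kappa, D_P = D_P, rho = rho, mu = mu,
                 alpha = co$alpha, beta = co$beta),
            class = "porous_coefficients")
}

#' @export
print.porous_coefficients <- function(x, ...) {
  cat(sprintf(
    "Porous coil model: kappa = %.4f (packing %.1f%%), D_P = %.3e m\n",
    x$kappa, 100 * (1 - x$kappa), x$D_P))
  cat(sprintf("  alpha = %.4e kg m^-4, beta = %.4e Pa s m^-2\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Darcy resistance at a given speed
#'
#' Quasilinear resistance `K = alpha * |v| + beta` balancing the local
#' pressure gradient in the coiled region (`0 = -grad p - K v`).
#'
#' @param coeffs a [porous_coefficients()] object (or any list with
#'   `alpha` and `beta`).
#' @param speed flow speed magnitude (m/s), nonnegative; vectorized.
#' @return resistance K in Pa s m^-2.
#' @export
darcy_resistance <- function(coeffs, speed) {
  if (!is.numeric(speed)) stop("speed must be numeric")
  if (any(speed < 0)) stop("speed must be nonnegative")
  coeffs$alpha * speed + coeffs$beta
}
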
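# Priestley-Taylor potential evaporation for soil and canopy, and the
# residual potential transpiration after interception consumption.

#' Slope of the saturation vapour-pressure curve
#'
#' FAO-56 closed form
#' \eqn{\Delta = 4098 \cdot 0.6108 e^{17.27 T / (T + 237.3)} / (T + 237.3)^2}
#' (kPa per degree C). Strictly increasing over the physical range.
#'
#' @param ta air temperature (degrees C), in (-60, 60).
#' @return slope Delta (kPa per degree C).
#' @export
svp_slope <- function(ta) {
  if (any(ta <= -60 | ta >= 60)) stop("ta outside physical range (-60, 60) C")
  4098 * (0.6108 * exp(17.27 * ta / (ta + 237.3))) / (ta + 237.3)^2
}

#' Latent heat of vaporization
#'
#' Harrison linear form \eqn{\lambda = 2.501 - 0.002361 T} (MJ kg-1).
#'
#' @param ta air temperature (degrees C), in (-60, 60).
#' @return latent heat (MJ kg-1); 2.501 at 0 C, decreasing with temperature.
#' @export
latent_heat <- function(ta) {
  if (any(ta <= -60 | ta >= 60)) stop("ta outside physical range (-60, 60) C")
  2.501 - 0.002361 * ta
}

#' Psychrometric constant
#'
#' Fixed at 0.066 kPa per degree C by default; optionally pressure-adjusted
#' via the FAO-56 relation \eqn{\gamma = 0.000665 \cdot p_a}.
#'
#' @param pa air pressure (kPa), used only when `pressure_adjusted = TRUE`.
#' @param pressure_adjusted logical; default `FALSE` returns the fixed value.
#' @return psychrometric constant (kPa per degree C).
#' @export
psychrometric_constant <- function(pa = 101.325, pressure_adjusted = FALSE) {
  if (pressure_adjusted) 0.000665 * pa else 0.066
}

#' Priestley-Taylor potential evaporation from available energy
#' @keywords internal
.priestley_taylor <- function(energy, delta, gamma, lambda_, alpha) {
  pmax(0, alpha * (delta / (delta + gamma)) * energy / lambda_)
}

#' Potential soil evaporation (Priestley-Taylor)
#'
#' \eqn{E_{ps} = \alpha \frac{\Delta}{\Delta+\gamma} \frac{R_{ns}-G}{\lambda}}.
#' Negative available energy clamps the potential at zero (the model has no
#' dew pathway).
#'
#' @param rns soil-allocated net radiation (MJ m-2 d-1).
#' @param g ground heat flux (MJ m-2 d-1), default 0 at daily scale.
#' @param delta slope of the saturation vapour-pressure curve (kPa C-1).
#' @param gamma psychrometric constant (kPa C-1).
#' @param lambda_ latent heat of vaporization (MJ kg-1), > 0.
#' @param alpha Priestley-Taylor coefficient (default 1.26).
#' @return potential soil evaporation (mm d-1).
#' @export
potential_soil_evaporation <- function(rns, g = 0, delta, gamma = 0.066,
                                       lambda_, alpha = 1.26) {
  if (any(lambda_ <= 0)) stop("lambda_ must be positive")
  .priestley_taylor(rns - g, delta, gamma, lambda_, alpha)
}

#' Potential canopy evaporation and potential transpiration
#'
#' Canopy potential evaporation by the Priestley-Taylor form on the
#' canopy-allocated net radiation; potential transpiration is the residual
#' after interception consumption, \eqn{T_p = (1 - f_{wet}) E_{pc}}.
#'
#' @param rnc canopy-allocated net radiation (MJ m-2 d-1).
#' @param f_wet relative canopy surface wetness, in \[0, 1\].
#' @inheritParams potential_soil_evaporation
#' @return list with `e_pc` and `t_p` (mm d-1).
#' @export
potential_canopy_and_transpiration <- function(rnc, f_wet, delta, gamma = 0.066,
                                               lambda_, alpha = 1.26) {
  if (any(lambda_ <= 0)) stop("lambda_ must be positive")
  if (any(f_wet < 0 | f_wet > 1)) stop("f_wet must be in [0, 1]")
  e_pc <- .priestley_taylor(rnc, delta, gamma, lambda_, alpha)
  list(e_pc = e_pc, t_p = (1 - f_wet) * e_pc)
}
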
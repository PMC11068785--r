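# Daily surface radiation budget: blue-sky albedo, upward longwave,
# four-component net radiation, and Beer-law canopy/soil partition.

#' Stefan-Boltzmann constant (W m-2 K-4)
#' @keywords internal
.SIGMA_SB <- 5.670374419e-8

#' Conversion factor from W m-2 (mean daily) to MJ m-2 d-1
#' @keywords internal
.WM2_TO_MJ_DAY <- 0.0864

#' Blue-sky albedo from black-sky and white-sky albedo
#'
#' The actual (blue-sky) surface albedo is a linear blend of the black-sky
#' (direct beam) and white-sky (diffuse) albedos, weighted by the fraction of
#' downward shortwave radiation arriving as direct beam.
#'
#' @param albedo_black black-sky albedo, in \[0, 1\].
#' @param albedo_white white-sky albedo, in \[0, 1\].
#' @param direct_fraction fraction of shortwave that is direct beam, in \[0, 1\].
#' @return blue-sky albedo, bounded by the two input albedos.
#' @export
#' @examples
#' blue_sky_albedo(0.1, 0.3, 0.5) # 0.2
blue_sky_albedo <- function(albedo_black, albedo_white, direct_fraction) {
  .check_unit_interval(albedo_black, "albedo_black")
  .check_unit_interval(albedo_white, "albedo_white")
  .check_unit_interval(direct_fraction, "direct_fraction")
  direct_fraction * albedo_black + (1 - direct_fraction) * albedo_white
}

#' Upward longwave radiation from skin temperature and emissivity
#'
#' Grey-body emission plus reflection of the downward longwave flux:
#' \eqn{L_u = \epsilon \sigma T_s^4 + (1-\epsilon) L_d}, converted to daily
#' MJ m-2.
#'
#' @param emissivity broadband surface emissivity, in (0, 1].
#' @param tskin skin temperature (K), > 0.
#' @param lwd downward longwave radiation (MJ m-2 d-1).
#' @return upward longwave radiation (MJ m-2 d-1).
#' @export
upward_longwave <- function(emissivity, tskin, lwd) {
  if (any(emissivity <= 0) || any(emissivity > 1)) {
    stop("emissivity must be in (0, 1]")
  }
  if (any(tskin <= 0)) stop("tskin must be positive (K)")
  emissivity * .SIGMA_SB * tskin^4 * .WM2_TO_MJ_DAY + (1 - emissivity) * lwd
}

#' Net radiation from the four-component balance
#'
#' \eqn{R_n = S_d (1 - \alpha_{blue}) + L_d - L_u}.
#'
#' @param swd downward shortwave radiation (MJ m-2 d-1), >= 0.
#' @param albedo_blue blue-sky albedo, in \[0, 1\].
#' @param lwd downward longwave radiation (MJ m-2 d-1).
#' @param lwu upward longwave radiation (MJ m-2 d-1).
#' @return net radiation (MJ m-2 d-1).
#' @export
net_radiation <- function(swd, albedo_blue, lwd, lwu) {
  if (any(swd < 0)) stop("swd must be non-negative")
  .check_unit_interval(albedo_blue, "albedo_blue")
  swd * (1 - albedo_blue) + lwd - lwu
}

#' Partition net radiation between bare soil and canopy
#'
#' Beer-law extinction through the canopy: the soil receives
#' \eqn{R_{ns} = e^{-k_{Rn} LAI} R_n} and the canopy the complement
#' \eqn{R_{nc} = R_n - R_{ns}}, so closure is exact by construction.
#'
#' @param rn net radiation (MJ m-2 d-1).
#' @param lai leaf area index (m2 m-2), >= 0.
#' @param k_rn canopy extinction coefficient for net radiation (default 0.6).
#' @return list with `rns` (soil) and `rnc` (canopy), both MJ m-2 d-1.
#' @export
partition_radiation <- function(rn, lai, k_rn = 0.6) {
  if (any(lai < 0)) stop("lai must be non-negative")
  rns <- exp(-k_rn * lai) * rn
  list(rns = rns, rnc = rn - rns)
}

#' @keywords internal
.check_unit_interval <- function(x, name) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop(sprintf("%s must be in [0, 1]", name))
  }
  invisible(TRUE)
}
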
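# Multiplicative stress constraints on potential evaporation and
# transpiration, and the dynamic critical soil-moisture threshold.

#' Canopy surface wetness fraction
#'
#' \eqn{f_{wet} = \min(\chi S_c / E_{pc}, 1)}, where the canopy storage
#' \eqn{S_c} is the product of precipitation and LAI and \eqn{\chi} is the
#' fraction of interception occurring during daytime. Evaluated against the
#' potential canopy evaporation, which removes the implicit dependence of
#' wetness on the transpiration it modulates. When there is no canopy energy
#' (`e_pc == 0`) a wetted canopy is fully wet (1) and a dry one dry (0).
#'
#' @param s_c canopy water storage (mm), >= 0.
#' @param e_pc potential canopy evaporation (mm d-1), >= 0.
#' @param chi daytime interception fraction, in (0, 1]; default 0.7.
#' @return wetness fraction in \[0, 1\].
#' @export
canopy_wetness <- function(s_c, e_pc, chi = 0.7) {
  if (any(s_c < 0)) stop("canopy storage s_c must be non-negative")
  if (any(chi <= 0 | chi > 1)) stop("chi must be in (0, 1]")
  ifelse(e_pc > 0, pmin(chi * s_c / e_pc, 1), as.numeric(s_c > 0))
}

#' Soil-moisture constraint on bare-soil evaporation
#'
#' Linear ramp between the wilting point and field capacity:
#' 0 below \eqn{\theta_{wp}}, \eqn{(\theta-\theta_{wp})/(\theta_{fc}-\theta_{wp})}
#' between, 1 above \eqn{\theta_{fc}}.
#'
#' @param theta surface-layer soil moisture (m3 m-3).
#' @param theta_fc field capacity (m3 m-3).
#' @param theta_wp wilting point (m3 m-3), strictly below `theta_fc`.
#' @return constraint in \[0, 1\].
#' @export
soil_evap_stress <- function(theta, theta_fc, theta_wp) {
  if (any(theta_wp >= theta_fc)) {
    stop("theta_wp must be strictly below theta_fc")
  }
  pmin(1, pmax(0, (theta - theta_wp) / (theta_fc - theta_wp)))
}

#' Temperature constraint on plant activity
#'
#' \eqn{f_t = \exp\{-[(T_a - T_{opt})/T_{opt}]^2\}}, maximal (1) at the
#' optimum growth temperature. Undefined for non-positive optima; such a
#' configuration is rejected rather than silently patched.
#'
#' @param ta air temperature (degrees C).
#' @param t_opt optimum plant growth temperature (degrees C), > 0.
#' @return constraint in (0, 1].
#' @export
temperature_stress <- function(ta, t_opt) {
  if (any(t_opt <= 0)) {
    stop("t_opt must be positive; the temperature constraint is undefined ",
         "for non-positive optimum temperatures")
  }
  exp(-((ta - t_opt) / t_opt)^2)
}

#' Vegetation water-content constraint from VOD
#'
#' \eqn{f_v = \sqrt{VOD / VOD_{max}}} with the record maximum of the VOD
#' series as reference; VOD above the reference clamps the constraint at 1.
#'
#' @param vod vegetation optical depth (unitless), >= 0.
#' @param vod_max reference maximum VOD, > 0.
#' @return constraint in \[0, 1\].
#' @export
vegetation_stress <- function(vod, vod_max) {
  if (any(vod_max <= 0)) stop("vod_max must be positive")
  if (any(vod < 0)) stop("vod must be non-negative")
  sqrt(pmin(vod / vod_max, 1))
}

#' Optimum plant growth temperature from a forcing climatology
#'
#' The optimum temperature is taken as the air temperature on the day where
#' the product LAI x Rn x Ta is largest over the climatology; it is a plant
#' trait, computed once per site and held fixed.
#'
#' @param ta air temperature series (degrees C).
#' @param lai leaf area index series.
#' @param rn net radiation series (MJ m-2 d-1).
#' @return optimum temperature (degrees C).
#' @export
optimum_temperature <- function(ta, lai, rn) {
  n <- length(ta)
  if (length(lai) != n || length(rn) != n) {
    stop("ta, lai and rn must have equal length")
  }
  if (n < 365) stop("need at least one full year (365 days) of forcing")
  prod <- lai * rn * ta
  if (all(prod < 0)) {
    stop("configuration error: LAI x Rn x Ta is negative for every day; ",
         "no optimum temperature can be derived")
  }
  ta[which.max(prod)]
}

#' Dynamic critical soil moisture for transpiration stress
#'
#' The critical threshold \eqn{\theta_c} below which transpiration becomes
#' water-limited depends on evaporative demand and plant stature:
#' \deqn{k = \sqrt{H_c}, \quad \theta_{wp}^h = \theta_{wp}/k,}
#' \deqn{p = \frac{1}{1+E_p} - \frac{w}{1+H_c}, \quad
#'       \theta_c = (1-p)(\theta_{fc} - \theta_{wp}^h) + \theta_{wp}^h,}
#' with the result clamped into \eqn{[\theta_{wp}^h, \theta_{fc}]}.
#'
#' @param theta_fc field capacity (m3 m-3).
#' @param theta_wp wilting point (m3 m-3).
#' @param e_p potential evapotranspiration demand (mm d-1), >= 0, used
#'   dimensionlessly inside 1/(1+E_p).
#' @param h_c canopy height (m), at or above `h_c_min`.
#' @param w weight of canopy height on the threshold (default 0.1).
#' @param h_c_min lower bound on canopy height (default 0.1 m); the
#'   height-adjusted wilting point is singular at zero height.
#' @return list with `theta_c`, `theta_wp_h`, `p`, `k`.
#' @export
critical_moisture <- function(theta_fc, theta_wp, e_p, h_c, w = 0.1,
                              h_c_min = 0.1) {
  if (any(h_c < h_c_min)) {
    stop(sprintf("h_c below the configured floor of %g m", h_c_min))
  }
  if (any(e_p < 0)) stop("e_p must be non-negative")
  k <- sqrt(h_c)
  theta_wp_h <- theta_wp / k
  p <- 1 / (1 + e_p) - w / (1 + h_c)
  theta_c <- (1 - p) * (theta_fc - theta_wp_h) + theta_wp_h
  theta_c <- pmin(pmax(theta_c, theta_wp_h), theta_fc)
  list(theta_c = theta_c, theta_wp_h = theta_wp_h, p = p, k = k)
}

#' Soil-moisture constraint on transpiration for one layer
#'
#' Piecewise: 0 at or below the height-adjusted wilting point, 1 at or above
#' the critical moisture, and
#' \eqn{1 - [(\theta_c - \theta)/(\theta_c - \theta_{wp}^h)]^k} in between.
#'
#' @param theta layer soil moisture (m3 m-3).
#' @param theta_c critical soil moisture (m3 m-3).
#' @param theta_wp_h height-adjusted wilting point, strictly below `theta_c`.
#' @param k sensitivity index (sqrt of canopy height), > 0.
#' @return constraint in \[0, 1\].
#' @export
transpiration_stress <- function(theta, theta_c, theta_wp_h, k) {
  if (any(theta_wp_h >= theta_c)) {
    stop("degenerate interval: theta_wp_h must be strictly below theta_c")
  }
  frac <- pmin(pmax((theta_c - theta) / (theta_c - theta_wp_h), 0), 1)
  1 - frac^k
}
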
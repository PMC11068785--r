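# Vertical root distribution (linear dose-response profile), allocation of
# potential transpiration across soil layers, and its split between the
# unsaturated and saturated zones given the groundwater table depth.
#
# Depth convention: all depths are positive downward in cm, measured from the
# surface; z_m are layer bottom depths with z_m0 = 0.

#' Shape parameter of the linear dose-response root profile
#'
#' The cumulative root fraction above depth z is
#' \eqn{F(z) = 1/(1 + (z/D_{50})^c)} with \eqn{c < 0}. `root_shape` returns
#' the unique c for which F reaches 0.95 at `d95` given F(`d50`) = 0.5:
#' \eqn{c = \log_{10}(1/19) / \log_{10}(D_{95}/D_{50})}.
#'
#' @param d50 depth above which half of the root mass lies (cm), > 0.
#' @param d95 depth above which 95\% of the root mass lies (cm), > `d50`.
#' @return shape parameter c (negative).
#' @export
#' @examples
#' root_shape(10, 100) # -1.27875
root_shape <- function(d50, d95) {
  if (any(d50 <= 0) || any(d95 <= d50)) {
    stop("require d95 > d50 > 0")
  }
  log10(1 / 0.95 - 1) / log10(d95 / d50)
}

#' Cumulative root fraction above depth z
#' @keywords internal
.root_cdf <- function(z, d50, c) {
  ifelse(z <= 0, 0, 1 / (1 + (z / d50)^c))
}

#' Per-layer root fractions from the dose-response profile
#'
#' \eqn{r_i = F(z_{m,i}) - F(z_{m,i-1})} over the three layer bottoms. Root
#' mass below the deepest layer (fraction `1 - F(z_m3)`) is not renormalized:
#' the transpiration allocation normalizes over the three layers itself.
#'
#' @param z_bottom increasing vector of layer bottom depths (cm).
#' @param d50,d95 root depth parameters (cm), `d95 > d50 > 0`.
#' @return list with `r` (per-layer fractions), `c` (shape), and `cdf`
#'   (the cumulative fraction at each layer bottom).
#' @export
root_fractions <- function(z_bottom, d50, d95) {
  if (any(diff(c(0, z_bottom)) <= 0)) {
    stop("z_bottom must be strictly increasing and positive")
  }
  c_shape <- root_shape(d50, d95)
  cdf <- .root_cdf(z_bottom, d50, c_shape)
  r <- diff(c(0, cdf))
  list(r = r, c = c_shape, cdf = cdf)
}

#' Allocate potential transpiration across layers
#'
#' Weights combine root density and relative layer wetness:
#' \deqn{T_{p,i} = T_p \frac{r_i (\bar\theta_i/\theta_s)^b}
#'   {\sum_j r_j (\bar\theta_j/\theta_s)^b}.}
#' When every weight is zero (completely dry profile) all layers receive
#' zero, i.e. transpiration is fully suppressed downstream.
#'
#' @param t_p potential transpiration (mm d-1).
#' @param r per-layer root fractions.
#' @param theta_bar per-layer mean wetness (m3 m-3), saturated-zone aware.
#' @param theta_s saturated water content (m3 m-3).
#' @param b dimensionless soil wetness exponent.
#' @return per-layer potential transpiration summing to `t_p` (or all zero).
#' @export
allocate_transpiration <- function(t_p, r, theta_bar, theta_s, b) {
  w <- r * (theta_bar / theta_s)^b
  s <- sum(w)
  if (!is.finite(s) || s <= 0) {
    return(rep(0, length(r)))
  }
  t_p * w / s
}

#' Mean layer wetness accounting for the saturated fraction
#'
#' Thickness-weighted mean of the prognostic moisture over the unsaturated
#' part of the layer and of the saturated water content over the part below
#' the water table.
#'
#' @param theta per-layer prognostic soil moisture (m3 m-3).
#' @param z_top,z_bottom per-layer top and bottom depths (cm).
#' @param z_gw groundwater table depth (cm), >= 0.
#' @param theta_s saturated water content (m3 m-3).
#' @return per-layer mean wetness.
#' @export
layer_mean_wetness <- function(theta, z_top, z_bottom, z_gw, theta_s) {
  if (any(z_gw < 0)) stop("z_gw must be non-negative (depth below surface)")
  unsat <- pmin(pmax(z_gw - z_top, 0), z_bottom - z_top)
  sat <- (z_bottom - z_top) - unsat
  (unsat * theta + sat * theta_s) / (z_bottom - z_top)
}

#' Split layer transpiration between unsaturated and saturated zones
#'
#' Three cases on the water-table position relative to the layer: entirely
#' saturated (`z_gw <= z_top`) sends everything to the saturated zone;
#' entirely unsaturated (`z_gw >= z_bottom`) to the unsaturated zone; a
#' table inside the layer splits in proportion to
#' \eqn{(z_{gw}-z_{top})\theta_i} and \eqn{(z_{bot}-z_{gw})\theta_s}.
#' The two parts always sum exactly to the layer demand, and the split is
#' continuous in `z_gw` at both case boundaries.
#'
#' @param t_p_i per-layer potential transpiration (mm d-1), >= 0.
#' @param z_gw groundwater table depth (cm), >= 0.
#' @param z_top,z_bottom per-layer top and bottom depths (cm).
#' @param theta per-layer soil moisture (m3 m-3).
#' @param theta_s saturated water content (m3 m-3).
#' @return list with `t_ps` (unsaturated) and `t_pg` (saturated), mm d-1.
#' @export
split_saturation <- function(t_p_i, z_gw, z_top, z_bottom, theta, theta_s) {
  if (any(z_gw < 0)) stop("z_gw must be non-negative (depth below surface)")
  if (any(t_p_i < 0)) stop("t_p_i must be non-negative")
  if (any(z_top >= z_bottom)) stop("require z_top < z_bottom")
  w_unsat <- pmin(pmax(z_gw - z_top, 0), z_bottom - z_top) * theta
  w_sat <- pmin(pmax(z_bottom - z_gw, 0), z_bottom - z_top) * theta_s
  tot <- w_unsat + w_sat
  frac_unsat <- ifelse(z_gw >= z_bottom, 1,
                ifelse(z_gw <= z_top, 0,
                       ifelse(tot > 0, w_unsat / tot, 0)))
  t_ps <- frac_unsat * t_p_i
  list(t_ps = t_ps, t_pg = t_p_i - t_ps)
}
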
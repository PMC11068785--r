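# One-day advance of the prognostic state: interception, actual fluxes,
# bucket infiltration/drainage capped by saturated conductivity, groundwater
# recharge and water-table update, with exact mass accounting.
#
# Within-day ordering (explicit scheme, every equation evaluated from the
# beginning-of-day state): interception -> evaporation/transpiration demand
# on beginning-of-day moisture -> infiltration/drainage -> groundwater.

#' Canopy interception of rainfall
#'
#' Canopy storage is the product of precipitation and LAI
#' (\eqn{S_c = P \cdot LAI}). Interception evaporation is energy- and
#' supply-limited: \eqn{E_i = \min(\chi S_c, E_{pc}, P)}, which keeps
#' throughfall non-negative; the wetness fraction is recovered as
#' \eqn{f_{wet} = E_i / E_{pc}} so the identity \eqn{E_i = f_{wet} E_{pc}}
#' holds exactly.
#'
#' @param precip precipitation (mm d-1), >= 0.
#' @param lai leaf area index (m2 m-2), >= 0.
#' @param e_pc potential canopy evaporation (mm d-1), >= 0.
#' @param chi daytime interception fraction, default 0.7.
#' @return list with `e_i`, `throughfall`, `f_wet`, `s_c`.
#' @export
interception <- function(precip, lai, e_pc, chi = 0.7) {
  if (any(precip < 0) || any(lai < 0) || any(e_pc < 0)) {
    stop("precip, lai and e_pc must be non-negative")
  }
  s_c <- precip * lai
  e_i <- pmin(chi * s_c, e_pc, precip)
  f_wet <- ifelse(e_pc > 0, e_i / e_pc, as.numeric(s_c > 0))
  list(e_i = e_i, throughfall = precip - e_i, f_wet = f_wet, s_c = s_c)
}

#' Actual fluxes from potentials and stresses
#'
#' \eqn{E_s = f_{sm} E_{ps}};
#' \eqn{T_r = f_v f_t [\sum_i f_{smv,i} T_{ps,i} + \sum_i T_{pg,i}]} --- the
#' saturated-zone demand is exempt from the per-layer soil-moisture stress;
#' \eqn{ET = E_i + E_s + T_r}.
#'
#' @param e_i interception evaporation (mm d-1).
#' @param e_ps potential soil evaporation (mm d-1).
#' @param f_sm soil-evaporation moisture constraint.
#' @param f_v,f_t vegetation water-content and temperature constraints.
#' @param f_smv per-layer transpiration moisture constraints (length 3).
#' @param t_ps,t_pg per-layer unsaturated/saturated potential transpiration.
#' @return list with `et`, `e_s`, `t_r`, and the per-layer actual
#'   transpiration split `t_r_unsat`, `t_r_sat`.
#' @export
actual_fluxes <- function(e_i, e_ps, f_sm, f_v, f_t, f_smv, t_ps, t_pg) {
  e_s <- f_sm * e_ps
  t_r_unsat <- f_v * f_t * f_smv * t_ps
  t_r_sat <- f_v * f_t * t_pg
  t_r <- sum(t_r_unsat) + sum(t_r_sat)
  list(et = e_i + e_s + t_r, e_s = e_s, t_r = t_r,
       t_r_unsat = t_r_unsat, t_r_sat = t_r_sat)
}

#' One-day soil water bucket update
#'
#' Sequential top-down scheme: throughfall infiltrates into layer 1;
#' extraction (soil evaporation from layer 1, per-layer unsaturated
#' transpiration) is removed; water above saturation spills instantly as
#' saturation-excess runoff; water above field capacity drains to the next
#' layer at a rate capped by the layer's saturated conductivity and by the
#' receiving layer's remaining capacity; drainage out of layer 3 is
#' groundwater recharge. Extraction must have been clipped to available
#' storage by the caller ([sith_step()] does this); a negative resulting
#' storage is an internal error and fails hard.
#'
#' @param theta beginning-of-day per-layer soil moisture (m3 m-3).
#' @param throughfall infiltrating water (mm).
#' @param e_s soil evaporation drawn from layer 1 (mm).
#' @param t_r_unsat per-layer unsaturated-zone transpiration (mm).
#' @param params a `sith_params` list (layer geometry and hydraulics).
#' @return list with updated `theta`, `runoff` (mm), `recharge` (mm,
#'   gravity drainage out of layer 3).
#' @export
soil_water_update <- function(theta, throughfall, e_s, t_r_unsat, params) {
  cap <- params$thickness * 10          # mm of water per unit theta
  ks <- rep(params$k_sat, length.out = 3)
  w <- theta * cap                      # layer storages in mm
  w[1] <- w[1] + throughfall
  extract <- c(e_s + t_r_unsat[1], t_r_unsat[2], t_r_unsat[3])
  w <- w - extract
  if (any(w < -1e-9)) {
    stop("internal error: negative layer storage after extraction; ",
         "demand was not clipped to available water")
  }
  w <- pmax(w, 0)
  # saturation excess in layer 1 spills as runoff
  runoff <- max(0, w[1] - params$theta_s * cap[1])
  w[1] <- w[1] - runoff
  # gravity drainage cascade, capped by k_sat and receiving capacity
  for (i in 1:2) {
    excess <- max(0, w[i] - params$theta_fc * cap[i])
    drain <- min(excess, ks[i])
    drain <- min(drain, params$theta_s * cap[i + 1] - w[i + 1])
    drain <- max(drain, 0)
    w[i] <- w[i] - drain
    w[i + 1] <- w[i + 1] + drain
  }
  recharge <- min(max(0, w[3] - params$theta_fc * cap[3]), ks[3])
  w[3] <- w[3] - recharge
  list(theta = w / cap, runoff = runoff, recharge = recharge)
}

#' Groundwater table update
#'
#' Net vertical exchange converts to a table movement through the specific
#' yield: \eqn{z_{gw}' = z_{gw} - (R - T_{r,sat})/(10 S_y)} (mm of water to
#' cm of table), floored at the surface and capped at a maximum depth.
#'
#' @param z_gw groundwater table depth (cm).
#' @param recharge gravity recharge from the soil column (mm).
#' @param sat_extraction saturated-zone transpiration drawn from
#'   groundwater (mm).
#' @param specific_yield aquifer specific yield, in (0, 1).
#' @param z_max cap on table depth (cm), default 3000.
#' @return updated table depth (cm).
#' @export
update_groundwater <- function(z_gw, recharge, sat_extraction,
                               specific_yield = 0.05, z_max = 3000) {
  if (specific_yield <= 0 || specific_yield >= 1) {
    stop("specific_yield must be in (0, 1)")
  }
  z_new <- z_gw - (recharge - sat_extraction) / (10 * specific_yield)
  min(max(z_new, 0), z_max)
}

# ---- internal kernels shared by sith_step() and run_point() ----

# State-independent daily quantities, vectorized over forcing rows.
# Requires params$t_opt and params$vod_max to be set.
.forcing_fluxes <- function(forcing, params) {
  direct_frac <- ifelse(forcing$swd > 0, forcing$swd_direct / forcing$swd, 0)
  alb <- blue_sky_albedo(forcing$albedo_black, forcing$albedo_white,
                         direct_frac)
  lwu <- upward_longwave(forcing$emissivity, forcing$tskin, forcing$lwd)
  rn <- net_radiation(forcing$swd, alb, forcing$lwd, lwu)
  part <- partition_radiation(rn, forcing$lai, params$k_rn)
  g <- params$g_fraction * part$rns
  delta <- svp_slope(forcing$ta)
  lambda_ <- latent_heat(forcing$ta)
  gamma <- if (params$pressure_gamma) 0.000665 * forcing$pa else params$gamma
  e_ps <- potential_soil_evaporation(part$rns, g, delta, gamma, lambda_,
                                     params$alpha)
  e_pc <- .priestley_taylor(part$rnc, delta, gamma, lambda_, params$alpha)
  ic <- interception(forcing$precip, forcing$lai, e_pc, params$chi)
  t_p <- (1 - ic$f_wet) * e_pc
  f_t <- temperature_stress(forcing$ta, params$t_opt)
  f_v <- vegetation_stress(forcing$vod, params$vod_max)
  list(precip = forcing$precip, rn = rn, rns = part$rns, rnc = part$rnc,
       g = g, e_ps = e_ps, e_pc = e_pc, e_i = ic$e_i,
       throughfall = ic$throughfall, f_wet = ic$f_wet, t_p = t_p,
       f_t = f_t, f_v = f_v, e_p = e_ps + e_pc)
}

# Names of the per-day flux outputs, in emission order.
.FLUX_NAMES <- c("et", "e_i", "e_s", "t_r", "t_r1", "t_r2", "t_r3",
                 "runoff", "recharge", "balance_residual",
                 "e_ps", "e_pc", "t_p", "rn", "rns", "rnc",
                 "f_wet", "f_sm", "f_t", "f_v")

# Advance the prognostic state with precomputed forcing-only quantities for
# one day (scalar list `ff`). Returns list(theta, z_gw, fluxes).
.step_state <- function(theta, z_gw, ff, params) {
  # stresses on beginning-of-day moisture
  f_sm <- soil_evap_stress(theta[1], params$theta_fc, params$theta_wp)
  cm <- critical_moisture(params$theta_fc, params$theta_wp, ff$e_p,
                          params$h_c, params$w, params$h_c_min)
  f_smv <- transpiration_stress(theta, cm$theta_c, cm$theta_wp_h, cm$k)
  # root-zone allocation and saturation split
  theta_bar <- layer_mean_wetness(theta, params$z_top, params$z_bottom,
                                  z_gw, params$theta_s)
  t_p_i <- allocate_transpiration(ff$t_p, params$root_r, theta_bar,
                                  params$theta_s, params$b)
  sp <- split_saturation(t_p_i, z_gw, params$z_top, params$z_bottom,
                         theta, params$theta_s)
  af <- actual_fluxes(ff$e_i, ff$e_ps, f_sm, ff$f_v, ff$f_t, f_smv,
                      sp$t_ps, sp$t_pg)
  e_s <- af$e_s
  t_r_unsat <- af$t_r_unsat
  # clip extraction to water available above the residual floor
  avail <- pmax(theta - params$theta_residual, 0) * params$thickness * 10
  d1 <- e_s + t_r_unsat[1]
  if (d1 > avail[1]) {
    scale1 <- if (d1 > 0) avail[1] / d1 else 0
    e_s <- e_s * scale1
    t_r_unsat[1] <- t_r_unsat[1] * scale1
  }
  t_r_unsat[2] <- min(t_r_unsat[2], avail[2])
  t_r_unsat[3] <- min(t_r_unsat[3], avail[3])
  t_r_sat <- af$t_r_sat
  t_r <- sum(t_r_unsat) + sum(t_r_sat)
  et <- ff$e_i + e_s + t_r
  # bucket update and groundwater
  upd <- soil_water_update(theta, ff$throughfall, e_s, t_r_unsat, params)
  sat_uptake <- sum(t_r_sat)
  recharge_net <- upd$recharge - sat_uptake
  z_gw_new <- update_groundwater(z_gw, upd$recharge, sat_uptake,
                                 params$specific_yield, params$z_gw_max)
  # exact mass accounting over the three soil layers
  d_storage <- sum((upd$theta - theta) * params$thickness * 10)
  residual <- ff$precip - (et + upd$runoff + recharge_net + d_storage)
  if (abs(residual) > params$balance_tol) {
    stop(sprintf("water balance violated: residual %.3e mm", residual))
  }
  fluxes <- c(et, ff$e_i, e_s, t_r,
              t_r_unsat[1] + t_r_sat[1], t_r_unsat[2] + t_r_sat[2],
              t_r_unsat[3] + t_r_sat[3],
              upd$runoff, recharge_net, residual,
              ff$e_ps, ff$e_pc, ff$t_p, ff$rn, ff$rns, ff$rnc,
              ff$f_wet, f_sm, ff$f_t, ff$f_v)
  names(fluxes) <- .FLUX_NAMES
  list(theta = upd$theta, z_gw = z_gw_new, fluxes = fluxes)
}

#' Advance the model state by one day
#'
#' Orchestrates the full daily chain: radiation assembly and partition,
#' Priestley-Taylor potentials, interception, stress constraints, root-zone
#' allocation, saturation split, actual fluxes, bucket update and
#' groundwater update. Emits the per-day flux vector including the
#' water-balance residual \eqn{P - (ET + Q + R + \Delta S)}, where the
#' reported recharge is net of saturated-zone uptake and \eqn{\Delta S}
#' covers the three soil layers; a residual above the configured tolerance
#' fails hard.
#'
#' @param state a `sith_state` (see [sith_state()]).
#' @param forcing one day of forcing: a one-row data frame or list with the
#'   fields of [generate_forcing()] output.
#' @param params a `sith_params` list with `t_opt` and `vod_max` set.
#' @return list with `state` (updated `sith_state`) and `fluxes` (named
#'   vector; `et`, `e_i`, `e_s`, `t_r`, per-layer transpiration, `runoff`,
#'   `recharge`, `balance_residual`, plus diagnostics).
#' @export
sith_step <- function(state, forcing, params) {
  if (is.null(params$t_opt) || is.null(params$vod_max)) {
    stop("params$t_opt and params$vod_max must be set (site traits); ",
         "run_point() derives them from a forcing climatology")
  }
  ff <- .forcing_fluxes(forcing, params)
  ff1 <- lapply(ff, `[`, 1)
  out <- .step_state(state$theta, state$z_gw, ff1, params)
  list(state = sith_state(out$theta, out$z_gw), fluxes = out$fluxes)
}
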
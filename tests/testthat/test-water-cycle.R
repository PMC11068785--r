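test_that("interception is supply- and energy-limited with exact identity", {
  ic <- interception(0, 2, 3)
  expect_equal(ic$e_i, 0); expect_equal(ic$throughfall, 0)
  ic <- interception(10, 0, 3)
  expect_equal(ic$e_i, 0); expect_equal(ic$throughfall, 10)
  # energy-limited: min(0.7*10*2, 3) = 3
  ic <- interception(10, 2, 3, chi = 0.7)
  expect_equal(ic$e_i, 3); expect_equal(ic$throughfall, 7)
  # storage-limited: min(0.7*1*0.5, 3, 1) = 0.35
  ic <- interception(1, 0.5, 3, chi = 0.7)
  expect_equal(ic$e_i, 0.35)
  # supply-limited: high LAI and energy cannot intercept more than rainfall
  ic <- interception(1, 5, 10, chi = 0.7)
  expect_equal(ic$e_i, 1); expect_equal(ic$throughfall, 0)
  # Ei = f_wet * E_pc holds exactly in all cases
  set.seed(3)
  for (i in 1:100) {
    ic <- interception(rexp(1, 1/5), runif(1, 0, 6), rexp(1, 1/3))
    expect_gte(ic$throughfall, 0)
    expect_true(ic$f_wet >= 0 && ic$f_wet <= 1)
  }
})

test_that("actual fluxes compose the constraint products", {
  # direct substitution of the transpiration double sum:
  # t_r = 1*1 + 0.5*1 + 0*1 + (0 + 0 + 0.5) = 2.0
  af <- actual_fluxes(e_i = 0.2, e_ps = 4, f_sm = 0.5, f_v = 1, f_t = 1,
                      f_smv = c(1, 0.5, 0), t_ps = c(1, 1, 1),
                      t_pg = c(0, 0, 0.5))
  expect_equal(af$t_r, 2.0)
  expect_equal(af$e_s, 2.0)
  expect_equal(af$et, 0.2 + 2 + 2)
  # saturated-zone demand is exempt from the soil-moisture stress
  af2 <- actual_fluxes(0, 0, 0, f_v = 1, f_t = 1, f_smv = c(0, 0, 0),
                       t_ps = c(1, 1, 1), t_pg = c(0.3, 0, 0))
  expect_equal(af2$t_r, 0.3)
  # full stress with no saturated uptake leaves interception only
  af3 <- actual_fluxes(0.7, 5, 0, f_v = 0, f_t = 1, f_smv = c(1, 1, 1),
                       t_ps = c(1, 1, 1), t_pg = c(0, 0, 0))
  expect_equal(af3$et, 0.7)
})

test_that("bucket update conserves water and respects drainage rules", {
  p <- default_test_params()
  # identity step
  upd <- soil_water_update(rep(0.2, 3), 0, 0, rep(0, 3), p)
  expect_equal(upd$theta, rep(0.2, 3))
  expect_equal(upd$runoff, 0); expect_equal(upd$recharge, 0)
  # at field capacity everywhere: no drainage (rule active only above fc)
  upd <- soil_water_update(rep(p$theta_fc, 3), 0, 0, rep(0, 3), p)
  expect_equal(upd$theta, rep(p$theta_fc, 3))
  expect_equal(upd$recharge, 0)
  # saturation excess in layer 1 runs off instantly
  big <- (p$theta_s - 0.2) * p$thickness[1] * 10 + 25
  upd <- soil_water_update(c(0.2, 0.2, 0.2), big, 0, rep(0, 3), p)
  expect_gt(upd$runoff, 0)
  expect_lte(upd$theta[1], p$theta_s + 1e-12)
  # mass closes: inputs - outputs = storage change
  d_storage <- sum((upd$theta - 0.2) * p$thickness * 10)
  expect_equal(big - upd$runoff - upd$recharge, d_storage)
  # unclipped extraction is an internal error, never silent
  expect_error(soil_water_update(c(0.02, 0.2, 0.2), 0, 50, rep(0, 3), p),
               "internal error")
})

test_that("groundwater table moves with net recharge over specific yield", {
  expect_equal(update_groundwater(100, 5, 5, 0.05), 100)
  expect_equal(update_groundwater(100, 5, 0, 0.05), 90)  # 5/(10*0.05) cm rise
  expect_gt(update_groundwater(100, 0, 5, 0.05), 100)
  expect_equal(update_groundwater(2, 50, 0, 0.05), 0)    # floored at surface
  expect_error(update_groundwater(100, 5, 0, 1.5), "specific_yield")
})

test_that("a full step balances water and matches manual composition", {
  f <- one_day_forcing(precip = 8, lai = 2.5)
  p <- resolved_params(generate_forcing("temperate", 1, seed = 5))
  st <- sith_state(c(0.25, 0.25, 0.25), 200)
  out <- sith_step(st, f, p)
  fx <- out$fluxes
  expect_equal(unname(fx["et"]),
               unname(fx["e_i"] + fx["e_s"] + fx["t_r"]))
  expect_lt(abs(fx["balance_residual"]), 1e-6)
  expect_true(all(fx[c("et", "e_i", "e_s", "t_r", "runoff")] >= 0))
  # manual composition of the same day from the individual operations
  dir_frac <- f$swd_direct / f$swd
  alb <- blue_sky_albedo(f$albedo_black, f$albedo_white, dir_frac)
  lwu <- upward_longwave(f$emissivity, f$tskin, f$lwd)
  rn <- net_radiation(f$swd, alb, f$lwd, lwu)
  part <- partition_radiation(rn, f$lai, p$k_rn)
  delta <- svp_slope(f$ta); lam <- latent_heat(f$ta)
  e_ps <- potential_soil_evaporation(part$rns, 0, delta, p$gamma, lam,
                                     p$alpha)
  e_pc <- potential_canopy_and_transpiration(part$rnc, 0, delta, p$gamma,
                                             lam, p$alpha)$e_pc
  expect_equal(unname(fx["rn"]), rn)
  expect_equal(unname(fx["e_ps"]), e_ps)
  expect_equal(unname(fx["e_pc"]), e_pc)
  ic <- interception(f$precip, f$lai, e_pc, p$chi)
  expect_equal(unname(fx["e_i"]), ic$e_i)
  expect_equal(unname(fx["t_p"]), (1 - ic$f_wet) * e_pc)
})

test_that("ET never exceeds the potential ceiling and responds to wetness", {
  forcing <- generate_forcing("temperate", 1, seed = 9)
  p <- resolved_params(forcing)
  run <- run_point(forcing, p)
  ceiling <- run$fluxes$e_i + run$fluxes$e_ps + run$fluxes$t_p
  expect_true(all(run$fluxes$et <= ceiling + 1e-9))
  # monotone wetness response of same-day soil evaporation
  f <- one_day_forcing(precip = 0)
  dry <- sith_step(sith_state(c(0.15, 0.25, 0.25), 300), f, p)
  wet <- sith_step(sith_state(c(0.25, 0.25, 0.25), 300), f, p)
  expect_gte(wet$fluxes["e_s"], dry$fluxes["e_s"])
})
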
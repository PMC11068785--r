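test_that("canopy wetness saturates and handles zero-energy days", {
  expect_equal(canopy_wetness(0, 5), 0)
  expect_equal(canopy_wetness(10, 5, chi = 0.7), 1)  # chi*s_c >= e_pc
  expect_equal(canopy_wetness(2, 7, chi = 0.7), 0.2) # 0.7*2/7
  expect_equal(canopy_wetness(0, 0), 0)
  expect_equal(canopy_wetness(3, 0), 1)
  expect_error(canopy_wetness(-1, 5), "non-negative")
})

test_that("soil-evaporation stress is a clamped linear ramp", {
  expect_equal(soil_evap_stress(0.12, 0.30, 0.12), 0)
  expect_equal(soil_evap_stress(0.21, 0.30, 0.12), 0.5)
  expect_equal(soil_evap_stress(0.35, 0.30, 0.12), 1)
  th <- seq(0, 0.5, by = 0.01)
  f <- soil_evap_stress(th, 0.30, 0.12)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) >= 0))
  expect_error(soil_evap_stress(0.2, 0.2, 0.2), "strictly below")
})

test_that("temperature stress peaks at the optimum with scaled symmetry", {
  expect_equal(temperature_stress(25, 25), 1)
  expect_equal(temperature_stress(0, 20), exp(-1))
  expect_equal(temperature_stress(40, 20), exp(-1)) # symmetric at 2*t_opt
  # symmetric in the scaled deviation around t_opt
  expect_equal(temperature_stress(15, 20), temperature_stress(25, 20))
  expect_error(temperature_stress(10, 0), "t_opt")
  expect_error(temperature_stress(10, -5), "t_opt")
})

test_that("vegetation stress is the square root of relative VOD", {
  expect_equal(vegetation_stress(0.8, 0.8), 1)
  expect_equal(vegetation_stress(0, 0.8), 0)
  expect_equal(vegetation_stress(0.2, 0.8), 0.5)
  expect_equal(vegetation_stress(1.5, 0.8), 1)  # clamp above the record max
  vods <- seq(0, 1, by = 0.05)
  expect_true(all(diff(vegetation_stress(vods, 0.8)) >= 0))
  expect_error(vegetation_stress(0.5, 0), "vod_max")
})

test_that("optimum temperature is the argmax of the LAI*Rn*Ta product", {
  doy <- 1:365
  ta <- 10 + 12 * cos(2 * pi * (doy - 200) / 365)
  expect_equal(optimum_temperature(ta, rep(2, 365), rep(10, 365)), ta[200])
  expect_equal(optimum_temperature(rep(20, 365), rep(2, 365),
                                   rep(10, 365)), 20)
  # crafted series with the product max forced onto day 123
  lai <- rep(1, 365); rn <- rep(5, 365)
  lai[123] <- 10
  prod <- lai * rn * ta
  expect_equal(which.max(prod), 123)  # brute-force argmax oracle
  expect_equal(optimum_temperature(ta, lai, rn), ta[123])
  expect_error(optimum_temperature(ta[1:100], lai[1:100], rn[1:100]),
               "365")
  expect_error(optimum_temperature(rep(-5, 365), rep(1, 365), rep(1, 365)),
               "configuration")
})

test_that("critical moisture follows the demand/height regulation", {
  # direct substitution oracle: e_p = 0, h_c = 1, w = 0.1
  cm <- critical_moisture(0.30, 0.12, e_p = 0, h_c = 1)
  expect_equal(cm$k, 1)
  expect_equal(cm$theta_wp_h, 0.12)
  expect_equal(cm$p, 0.95)
  expect_equal(cm$theta_c, 0.05 * (0.30 - 0.12) + 0.12)
  # high-demand limit: p < 0 and theta_c clamps at field capacity
  cm_hi <- critical_moisture(0.30, 0.12, e_p = 1e6, h_c = 1)
  expect_equal(cm_hi$theta_c, 0.30)
  # square-root height rule
  cm4 <- critical_moisture(0.30, 0.12, e_p = 0, h_c = 4)
  expect_equal(cm4$k, 2)
  expect_equal(cm4$theta_wp_h, 0.06)
  # theta_c decreasing in e_p before clamping (1/(1+E_p) regulation)
  eps <- c(0, 0.5, 1, 2, 4, 8)
  tc <- vapply(eps, function(e)
    critical_moisture(0.30, 0.12, e, h_c = 1)$theta_c, numeric(1))
  expect_true(all(diff(tc) >= 0))  # lower p -> higher theta_c as demand rises
  expect_error(critical_moisture(0.30, 0.12, 1, h_c = 0.01), "floor")
})

test_that("transpiration stress is piecewise with exponent k", {
  expect_equal(transpiration_stress(0.25, 0.25, 0.10, 2), 1)
  expect_equal(transpiration_stress(0.10, 0.25, 0.10, 2), 0)
  expect_equal(transpiration_stress(0.175, 0.25, 0.10, 1), 0.5)
  th <- seq(0, 0.4, by = 0.01)
  f <- transpiration_stress(th, 0.25, 0.10, 3)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) >= 0))
  expect_error(transpiration_stress(0.2, 0.1, 0.1, 2), "degenerate")
})

test_that("stress outputs stay in [0,1] over random valid draws", {
  set.seed(11)
  for (i in 1:200) {
    wp <- runif(1, 0.02, 0.2); fc <- wp + runif(1, 0.05, 0.25)
    hc <- runif(1, 0.1, 30); ep <- rexp(1, 1 / 3)
    cm <- critical_moisture(fc, wp, ep, hc)
    expect_true(cm$theta_c >= cm$theta_wp_h && cm$theta_c <= fc)
    th <- runif(3, 0, 0.5)
    f <- transpiration_stress(th, cm$theta_c, cm$theta_wp_h, cm$k)
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(soil_evap_stress(th, fc, wp) >= 0 &
                      soil_evap_stress(th, fc, wp) <= 1))
  }
})
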
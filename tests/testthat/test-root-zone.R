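test_that("dose-response shape parameter pins the 50% and 95% depths", {
  # log10 ratio = 1 solves 1/(1+(d95/d50)^c) = 0.95 at c = -1.27875
  expect_equal(root_shape(10, 100), -1.2787536, tolerance = 1e-6)
  F <- function(z, d50, c) 1 / (1 + (z / d50)^c)
  for (pair in list(c(10, 100), c(16, 80), c(25, 180))) {
    c_ <- root_shape(pair[1], pair[2])
    expect_lt(c_, 0)
    expect_equal(F(pair[1], pair[1], c_), 0.5)
    expect_equal(F(pair[2], pair[1], c_), 0.95)
  }
  expect_error(root_shape(50, 20), "d95 > d50")
})

test_that("root fractions difference the cumulative profile", {
  d50 <- 20; d95 <- 150
  rf <- root_fractions(c(d50, d95, 300), d50, d95)
  expect_equal(rf$r[1], 0.5)          # F(d50) - F(0)
  expect_equal(rf$r[2], 0.45)         # 0.95 - 0.5
  # independent brute-force evaluation of F at the layer bottoms
  F <- function(z) 1 / (1 + (z / d50)^rf$c)
  expect_equal(rf$r, diff(c(0, F(c(d50, d95, 300)))))
  expect_true(all(rf$r >= 0))
  expect_lt(sum(rf$r), 1)             # mass below layer 3 is ignored
  # monotone non-decreasing cumulative profile with F(0) = 0
  z <- seq(0, 500, by = 5)
  expect_true(all(diff(sithv2:::.root_cdf(z, d50, rf$c)) >= 0))
  expect_equal(sithv2:::.root_cdf(0, d50, rf$c), 0)
})

test_that("transpiration allocation weights roots by relative wetness", {
  # equal wetness cancels: allocation proportional to r
  a <- allocate_transpiration(3, c(0.5, 0.3, 0.2), rep(0.2, 3), 0.4, 5)
  expect_equal(a, 3 * c(0.5, 0.3, 0.2))
  # b = 0 collapses the wetness factor
  a0 <- allocate_transpiration(3, c(0.5, 0.3, 0.2), c(0.1, 0.3, 0.2), 0.4, 0)
  expect_equal(a0, 3 * c(0.5, 0.3, 0.2))
  # arithmetic oracle: weights (0.5, 0.15, 0.025)
  sh <- allocate_transpiration(1, c(0.5, 0.3, 0.1), c(1, 0.5, 0.25) * 0.4,
                               0.4, 1)
  expect_equal(sh, c(0.5, 0.15, 0.025) / 0.675, tolerance = 1e-6)
  expect_equal(sh, c(0.7407407, 0.2222222, 0.0370370), tolerance = 1e-6)
  expect_equal(sum(sh), 1)
  # all-dry profile suppresses allocation entirely
  expect_equal(allocate_transpiration(3, c(0.5, 0.3, 0.2), rep(0, 3), 0.4, 2),
               rep(0, 3))
})

test_that("saturation split covers the three water-table cases exactly", {
  # table below the layer bottom: all unsaturated
  sp <- split_saturation(2, z_gw = 400, z_top = 50, z_bottom = 300,
                         theta = 0.2, theta_s = 0.4)
  expect_equal(sp$t_ps, 2); expect_equal(sp$t_pg, 0)
  # table above the layer top: all saturated
  sp <- split_saturation(2, z_gw = 10, z_top = 50, z_bottom = 300,
                         theta = 0.2, theta_s = 0.4)
  expect_equal(sp$t_ps, 0); expect_equal(sp$t_pg, 2)
  # intermediate: weights (z_gw - z_top)*theta vs (z_bot - z_gw)*theta_s
  sp <- split_saturation(2, z_gw = 100, z_top = 50, z_bottom = 300,
                         theta = 0.2, theta_s = 0.4)
  w_u <- 50 * 0.2; w_s <- 200 * 0.4
  expect_equal(sp$t_ps, 2 * w_u / (w_u + w_s))
  expect_equal(sp$t_ps + sp$t_pg, 2)
  expect_error(split_saturation(1, -5, 0, 5, 0.2, 0.4), "non-negative")
})

test_that("saturation split is continuous in z_gw at layer boundaries", {
  eps <- 1e-9
  for (z_b in c(50, 300)) {
    lo <- split_saturation(1, z_b - eps, 50, 300, 0.2, 0.4)
    hi <- split_saturation(1, z_b + eps, 50, 300, 0.2, 0.4)
    expect_equal(lo$t_ps, hi$t_ps, tolerance = 1e-6)
  }
})

test_that("layer mean wetness blends prognostic and saturated moisture", {
  # fully unsaturated / fully saturated limits
  expect_equal(layer_mean_wetness(0.2, 0, 5, z_gw = 100, 0.4), 0.2)
  expect_equal(layer_mean_wetness(0.2, 50, 300, z_gw = 0, 0.4), 0.4)
  # half-submerged layer
  expect_equal(layer_mean_wetness(0.2, 0, 100, z_gw = 50, 0.4),
               (50 * 0.2 + 50 * 0.4) / 100)
})
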
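test_that("fit metrics recover the standard definitions", {
  obs <- c(1, 2, 3, 4.5, 2.2, 3.3)
  m <- fit_metrics(obs, obs)
  expect_equal(m$r, 1); expect_equal(m$rmse, 0)
  expect_equal(m$nse, 1); expect_equal(m$slope, 1)
  expect_equal(m$intercept, 0)
  # the mean forecast has NSE exactly 0
  m0 <- fit_metrics(rep(mean(obs), length(obs)), obs)
  expect_equal(m0$nse, 0)
  # hand-worked triple: errors all 1, obs deviations sum to 2
  m1 <- fit_metrics(c(2, 3, 4), c(1, 2, 3))
  expect_equal(m1$rmse, 1)
  expect_equal(m1$r, 1)
  expect_equal(m1$nse, -0.5)
  # rmse symmetric under exchange, NSE and slope are not
  a <- c(1, 3, 5, 7); b <- c(2, 3, 7, 6)
  expect_equal(fit_metrics(a, b)$rmse, fit_metrics(b, a)$rmse)
  expect_false(isTRUE(all.equal(fit_metrics(a, b)$nse,
                                fit_metrics(b, a)$nse)))
  # constant observations flag NSE as missing, not zero
  mc <- fit_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_true(is.na(mc$nse))
})

test_that("fit metrics apply pairwise deletion and report the count", {
  m <- fit_metrics(c(1, NA, 3, 4, 5), c(1.1, 2, NA, 4.2, 5.1))
  expect_equal(m$n, 3)
  expect_error(fit_metrics(c(1, NA, NA, 4), c(1, 2, 3, NA)), "at least 3")
})

test_that("water-balance ET is the residual of the basin budget", {
  expect_equal(water_balance_et(800, 200, 0), 600)
  expect_equal(water_balance_et(500, 500, 0), 0)
  expect_equal(water_balance_et(500, 0, 500), 0)
})

test_that("Mann-Kendall S equals exhaustive pair counting", {
  brute_s <- function(x) {
    s <- 0
    n <- length(x)
    for (i in 1:(n - 1)) for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
    s
  }
  # hand series from a near-monotone sequence
  x <- c(1, 3, 2, 4, 6, 5, 7, 9, 8, 10)
  mk <- mann_kendall(x)
  expect_equal(mk$s, brute_s(x))
  # random series of assorted lengths, with and without ties
  set.seed(17)
  for (n in c(5, 8, 12, 20, 30)) {
    y <- sample(1:8, n, replace = TRUE) + round(rnorm(n), 1)
    expect_equal(mann_kendall(y)$s, brute_s(y))
  }
  # strictly increasing: perfect concordance S = n(n-1)/2, tiny p
  inc <- mann_kendall(as.numeric(1:12))
  expect_equal(inc$s, 12 * 11 / 2)
  expect_lt(inc$p_value, 0.01)
  # constant series: S = 0, no trend detected
  cst <- mann_kendall(rep(2, 9))
  expect_equal(cst$s, 0)
  expect_equal(cst$p_value, 1)
})

test_that("Mann-Kendall p-values match the independent Kendall test", {
  # Kendall's tau of x against time is the same test; cor.test is the
  # independent oracle (exact for small untied n, approximate otherwise)
  set.seed(23)
  x <- c(1, 3, 2, 4, 6, 5, 7, 9, 8, 10)
  expect_equal(mann_kendall(x)$p_value,
               cor.test(seq_along(x), x, method = "kendall")$p.value,
               tolerance = 1e-10)
  y <- cumsum(rnorm(25)) + 0.2 * (1:25)
  expect_equal(mann_kendall(y)$p_value,
               cor.test(seq_along(y), y, method = "kendall",
                        exact = FALSE, continuity = TRUE)$p.value,
               tolerance = 1e-8)
})

test_that("linear trend pairs an OLS slope with MK significance", {
  yrs <- 1982:2020
  x <- 500 + 0.53 * (yrs - 1982)
  tr <- linear_trend_mk(x, yrs)
  expect_equal(tr$slope, 0.53)
  expect_equal(tr$sen_slope, 0.53)
  expect_lt(tr$mk_p_value, 0.01)
  expect_error(linear_trend_mk(1:5), "8 years")
})

test_that("ratio to reference is a guarded quotient", {
  expect_equal(ratio_to_reference(600, 600), 1)
  expect_equal(ratio_to_reference(1200, 600), 2)
  expect_equal(ratio_to_reference(588, 600), 0.98)
  expect_error(ratio_to_reference(500, 0), "positive")
})
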
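# Validation computations: fit metrics (Pearson r, RMSE, Nash-Sutcliffe
# efficiency, OLS regression), basin water-balance ET, and annual trend
# analysis with the Mann-Kendall significance test.

#' Fit metrics between simulated and observed series
#'
#' Pearson correlation, RMSE, Nash-Sutcliffe efficiency
#' (\eqn{1 - \sum(sim-obs)^2 / \sum(obs - \bar{obs})^2}), and the ordinary
#' least-squares slope/intercept of sim on obs. Missing values are removed
#' pairwise and the retained count reported. With constant observations the
#' NSE denominator vanishes; NSE (and slope) are then reported as `NA`
#' rather than forced to a number.
#'
#' @param sim simulated series.
#' @param obs observed series, same length.
#' @return list with `r`, `rmse`, `nse`, `slope`, `intercept`, `n`.
#' @export
fit_metrics <- function(sim, obs) {
  if (length(sim) != length(obs)) stop("sim and obs lengths differ")
  ok <- is.finite(sim) & is.finite(obs)
  sim <- sim[ok]; obs <- obs[ok]
  n <- length(sim)
  if (n < 3) stop("need at least 3 paired non-missing values")
  err2 <- sum((sim - obs)^2)
  dev2 <- sum((obs - mean(obs))^2)
  if (dev2 > 0) {
    # Pearson r is undefined for a constant simulation; report NA quietly
    r <- if (stats::sd(sim) > 0) stats::cor(sim, obs) else NA_real_
    nse <- 1 - err2 / dev2
    slope <- stats::cov(sim, obs) / stats::var(obs)
    intercept <- mean(sim) - slope * mean(obs)
  } else {
    r <- NA_real_; nse <- NA_real_; slope <- NA_real_
    intercept <- NA_real_
  }
  list(r = r, rmse = sqrt(err2 / n), nse = nse, slope = slope,
       intercept = intercept, n = n)
}

#' Water-balance evapotranspiration
#'
#' Basin-scale ET inferred as the residual of the water balance:
#' \eqn{ET_{wb} = P - Q - \Delta S} (precipitation minus runoff minus the
#' change in total water storage), all in mm over a common period.
#'
#' @param precip precipitation (mm per period).
#' @param runoff runoff (mm per period).
#' @param d_storage change in total water storage (mm per period).
#' @return water-balance ET (mm per period).
#' @export
water_balance_et <- function(precip, runoff, d_storage) {
  precip - runoff - d_storage
}

# exact null distribution of the Mann-Kendall S statistic for n untied
# values: counts over permutations by convolution (inserting the k-th value
# adds j concordant and k-1-j discordant pairs, j = 0..k-1).
.mk_exact_counts <- function(n) {
  counts <- 1
  for (k in 2:n) {
    m <- length(counts)
    new <- numeric(m + 2 * (k - 1))
    for (j in 0:(k - 1)) {
      new[(1:m) + 2 * j] <- new[(1:m) + 2 * j] + counts
    }
    counts <- new
  }
  counts  # index i corresponds to S = (i - 1) - n(n-1)/2
}

#' Mann-Kendall trend test
#'
#' Two-sided test on the pairwise-concordance statistic
#' \eqn{S = \sum_{i<j} \mathrm{sign}(x_j - x_i)} with tie-corrected
#' variance. For n <= 10 without ties the exact permutation null
#' distribution is used; otherwise the normal approximation with
#' continuity correction.
#'
#' @param x series (e.g. annual values).
#' @return list with `s`, `var_s`, `p_value`.
#' @export
mann_kendall <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 values")
  d <- outer(x, x, "-")
  s <- sum(sign(d[lower.tri(d)]))  # row a > col b gives x_a - x_b, a later
  ties <- table(x)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (n <= 10 && length(ties) == 0) {
    counts <- .mk_exact_counts(n)
    s_vals <- seq_along(counts) - 1 - n * (n - 1) / 2
    p <- sum(counts[abs(s_vals) >= abs(s)]) / sum(counts)
  } else if (var_s == 0) {
    p <- 1
  } else {
    z <- (s - sign(s)) / sqrt(var_s)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(s = s, var_s = var_s, p_value = min(p, 1))
}

#' Linear trend of an annual series with Mann-Kendall significance
#'
#' The trend value is the ordinary least-squares slope in units per year;
#' significance comes from the (distribution-free) Mann-Kendall test.
#' Sen's slope (median of pairwise slopes) is reported alongside as a
#' robust alternative estimator.
#'
#' @param x annual values.
#' @param years year coordinates (default `seq_along(x)`).
#' @return list with `slope` (units yr-1), `intercept`, `sen_slope`,
#'   `mk_s`, `mk_p_value`, `n`.
#' @export
linear_trend_mk <- function(x, years = seq_along(x)) {
  ok <- is.finite(x) & is.finite(years)
  x <- x[ok]; years <- years[ok]
  n <- length(x)
  if (n < 8) stop("need at least 8 years for a trend estimate")
  fit <- stats::lm.fit(cbind(1, years), x)
  mk <- mann_kendall(x)
  ij <- utils::combn(n, 2)
  sen <- stats::median((x[ij[2, ]] - x[ij[1, ]]) /
                         (years[ij[2, ]] - years[ij[1, ]]))
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       sen_slope = sen, mk_s = mk$s, mk_p_value = mk$p_value, n = n)
}

#' Ratio of simulated to reference annual means
#'
#' Used for basin-ratio maps of mean annual ET against the water-balance
#' reference.
#'
#' @param sim_annual_mean simulated mean annual value.
#' @param ref_annual_mean reference mean annual value, > 0.
#' @return the quotient.
#' @export
ratio_to_reference <- function(sim_annual_mean, ref_annual_mean) {
  if (any(ref_annual_mean <= 0)) stop("reference must be positive")
  sim_annual_mean / ref_annual_mean
}
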
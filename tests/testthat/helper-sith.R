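# Shared builders for the test suite: small forcing fixtures and default
# parameter sets, all generated in code.

default_test_params <- function(texture = "loam", pft = "grassland", ...) {
  site_params(texture = texture, pft = pft, ...)
}

# params with site traits resolved from a forcing series
resolved_params <- function(forcing, texture = "loam", pft = "grassland",
                            ...) {
  sithv2:::.resolve_traits(site_params(texture = texture, pft = pft, ...),
                           forcing)
}

# a single plausible mid-season forcing day
one_day_forcing <- function(precip = 0, lai = 2, ta = 18, swd = 18,
                            dir_frac = 0.6, vod = 0.5) {
  data.frame(year = 1, doy = 180, ta = ta, pa = 95, precip = precip,
             swd = swd, swd_direct = dir_frac * swd,
             lwd = 0.8 * 5.670374419e-8 * (ta + 273.15)^4 * 0.0864,
             tskin = ta + 273.15 + 1, albedo_black = 0.15,
             albedo_white = 0.18, emissivity = 0.97, lai = lai, vod = vod)
}

# random-but-valid single-step inputs for conservation sweeps
random_step_inputs <- function(n, seed) {
  set.seed(seed)
  list(
    precip = stats::rexp(n, 1 / 4) * stats::rbinom(n, 1, 0.5),
    lai = stats::runif(n, 0, 6),
    ta = stats::runif(n, -5, 35),
    swd = stats::runif(n, 1, 30),
    dir_frac = stats::runif(n),
    vod = stats::runif(n, 0, 1),
    theta1 = stats::runif(n, 0.02, 0.45),
    theta2 = stats::runif(n, 0.02, 0.45),
    theta3 = stats::runif(n, 0.02, 0.45),
    z_gw = stats::runif(n, 0, 500))
}
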
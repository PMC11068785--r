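# Static site parameters: soil hydraulics resolved from texture class,
# vegetation/root traits resolved from land-cover class, layer geometry,
# and the model's tunable constants.

#' Model configuration constants
#'
#' All tunable constants of the simulator in one list. Defaults follow the
#' model description where a value is prescribed (`alpha` 1.26, `gamma`
#' 0.066 kPa C-1, `chi` 0.7, `k_rn` 0.6, `w` 0.1) and documented plumbing
#' choices elsewhere.
#'
#' @param alpha Priestley-Taylor coefficient.
#' @param gamma psychrometric constant (kPa C-1); ignored when
#'   `pressure_gamma = TRUE`.
#' @param pressure_gamma logical; derive gamma from air pressure instead of
#'   the fixed value.
#' @param chi daytime interception fraction.
#' @param k_rn canopy extinction coefficient for net radiation.
#' @param w weight of canopy height on the critical soil moisture.
#' @param h_c_min canopy-height floor (m) protecting the height-adjusted
#'   wilting point from the singularity at zero height.
#' @param g_fraction ground heat flux as a fraction of soil net radiation;
#'   0 by default (daily G averages near zero).
#' @param specific_yield aquifer specific yield (-) for the water-table
#'   update.
#' @param z_gw_max maximum groundwater table depth (cm).
#' @param theta_residual residual soil moisture floor (m3 m-3) below which
#'   no extraction is allowed.
#' @param balance_tol hard-failure tolerance on the per-step water-balance
#'   residual (mm).
#' @return named list of configuration values.
#' @export
sith_config <- function(alpha = 1.26, gamma = 0.066, pressure_gamma = FALSE,
                        chi = 0.7, k_rn = 0.6, w = 0.1, h_c_min = 0.1,
                        g_fraction = 0, specific_yield = 0.05,
                        z_gw_max = 3000, theta_residual = 0.01,
                        balance_tol = 1e-6) {
  list(alpha = alpha, gamma = gamma, pressure_gamma = pressure_gamma,
       chi = chi, k_rn = k_rn, w = w, h_c_min = h_c_min,
       g_fraction = g_fraction, specific_yield = specific_yield,
       z_gw_max = z_gw_max, theta_residual = theta_residual,
       balance_tol = balance_tol)
}

#' Soil hydraulic parameters for a texture class
#'
#' Looks up the editable table shipped in `inst/extdata/soil_hydraulics.csv`
#' (repository-supplied class means, not prescribed values).
#'
#' @param texture texture class name, e.g. `"loam"`; see
#'   `soil_hydraulics_table()` for available classes.
#' @return list with `theta_s`, `theta_fc`, `theta_wp`, `b`, `k_sat`.
#' @export
soil_hydraulics <- function(texture) {
  tab <- soil_hydraulics_table()
  i <- match(texture, tab$texture)
  if (is.na(i)) {
    stop(sprintf("unknown soil texture '%s'; available: %s", texture,
                 paste(tab$texture, collapse = ", ")))
  }
  as.list(tab[i, -1])
}

#' @rdname soil_hydraulics
#' @export
soil_hydraulics_table <- function() {
  utils::read.csv(system.file("extdata", "soil_hydraulics.csv",
                              package = "sithv2"),
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' Vegetation traits for a plant functional type
#'
#' Canopy height and root-depth quantiles per land-cover class, from the
#' editable table in `inst/extdata/pft_traits.csv`.
#'
#' @param pft plant functional type name, e.g. `"grassland"`.
#' @return list with `h_c` (m), `d50`, `d95` (cm).
#' @export
pft_traits <- function(pft) {
  tab <- pft_traits_table()
  i <- match(pft, tab$pft)
  if (is.na(i)) {
    stop(sprintf("unknown PFT '%s'; available: %s", pft,
                 paste(tab$pft, collapse = ", ")))
  }
  as.list(tab[i, -1])
}

#' @rdname pft_traits
#' @export
pft_traits_table <- function() {
  utils::read.csv(system.file("extdata", "pft_traits.csv",
                              package = "sithv2"),
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' Assemble static site parameters
#'
#' Resolves soil hydraulics from the texture class and vegetation/root traits
#' from the land-cover class, fixes the layer geometry (bottom depths in cm;
#' the first layer is at 5 cm), and precomputes the root fractions. The
#' optimum growth temperature and reference VOD maximum are site traits
#' derived from the forcing climatology; they are filled in by
#' [run_point()]/[spin_up()] when absent, or can be set explicitly.
#'
#' @param texture soil texture class (see [soil_hydraulics_table()]).
#' @param pft plant functional type (see [pft_traits_table()]).
#' @param z_bottom layer bottom depths (cm), default `c(5, 50, 300)`.
#' @param config configuration list from [sith_config()].
#' @param t_opt optional optimum growth temperature (C).
#' @param vod_max optional reference VOD maximum.
#' @return list of class `sith_params`.
#' @export
site_params <- function(texture = "loam", pft = "grassland",
                        z_bottom = c(5, 50, 300), config = sith_config(),
                        t_opt = NULL, vod_max = NULL) {
  if (length(z_bottom) != 3 || any(diff(c(0, z_bottom)) <= 0)) {
    stop("z_bottom must be three strictly increasing positive depths (cm)")
  }
  soil <- soil_hydraulics(texture)
  veg <- pft_traits(pft)
  h_c <- max(veg$h_c, config$h_c_min)
  roots <- root_fractions(z_bottom, veg$d50, veg$d95)
  p <- c(
    list(texture = texture, pft = pft,
         z_bottom = z_bottom, z_top = c(0, z_bottom[1:2]),
         thickness = diff(c(0, z_bottom)),
         h_c = h_c, d50 = veg$d50, d95 = veg$d95,
         root_r = roots$r, root_c = roots$c,
         t_opt = t_opt, vod_max = vod_max),
    soil, config)
  class(p) <- "sith_params"
  p
}

#' Initial prognostic state
#'
#' Soil moisture in all three layers plus the groundwater table depth.
#'
#' @param theta per-layer soil moisture (m3 m-3), length 3.
#' @param z_gw groundwater table depth (cm), >= 0.
#' @return list of class `sith_state`.
#' @export
sith_state <- function(theta, z_gw) {
  if (length(theta) != 3) stop("theta must have length 3")
  if (z_gw < 0) stop("z_gw must be non-negative")
  structure(list(theta = as.numeric(theta), z_gw = as.numeric(z_gw)),
            class = "sith_state")
}

#' Default pre-spin-up state: field capacity everywhere, water table at the
#' bottom of the deepest layer.
#' @param params a `sith_params` list.
#' @return a `sith_state`.
#' @export
default_state <- function(params) {
  sith_state(rep(params$theta_fc, 3), params$z_bottom[3])
}
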
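# Gridded product conventions: 16-bit packed values with a two-decimal
# scale factor, the published filename scheme, and the two preprocessing
# contracts (bilinear regrid, spline temporal gap-fill).

.PRODUCT_VARS <- c("ET", "Tr", "Es", "Ei", "SM1", "SM2", "SM3")
.PRODUCT_INTERVALS <- c("Daily", "Monthly", "Annual")
.NC_FILL_SHORT <- -32767L

#' Pack physical values to 16-bit integers
#'
#' `stored = round(value * scale_factor)` with `scale_factor = 100` for the
#' two-decimal convention; the reader recovers values by multiplying by the
#' reciprocal of the `scale_factor` attribute. `NA` maps to the fill value;
#' values that would overflow the 16-bit range fail hard with the offending
#' cell indices.
#'
#' @param values numeric vector/array in physical units.
#' @param scale_factor positive packing multiplier (default 100).
#' @return integer vector/array of packed values.
#' @export
pack_values <- function(values, scale_factor = 100) {
  if (scale_factor <= 0) stop("scale_factor must be positive")
  stored <- round(values * scale_factor)
  bad <- which(!is.na(stored) & abs(stored) > 32767)
  if (length(bad) > 0) {
    stop(sprintf(
      "packing overflow: %d value(s) outside the 16-bit range (first cells: %s)",
      length(bad), paste(utils::head(bad, 5), collapse = ", ")))
  }
  stored[is.na(stored)] <- .NC_FILL_SHORT
  out <- array(as.integer(stored), dim = dim(values) %||% length(values))
  if (is.null(dim(values))) as.integer(out) else out
}

#' Unpack 16-bit integers to physical values
#'
#' `value = stored * scale_factor^-1` (reciprocal convention); fill values
#' become `NA`. With `convention = "cf"` the CF semantics
#' `value = stored * scale_factor` are applied instead.
#'
#' @param stored integer vector/array of packed values.
#' @param scale_factor the file's `scale_factor` attribute; never guessed.
#' @param fill fill value marking missing data.
#' @param convention `"reciprocal"` (default) or `"cf"`.
#' @return numeric vector/array in physical units.
#' @export
unpack_values <- function(stored, scale_factor, fill = .NC_FILL_SHORT,
                          convention = c("reciprocal", "cf")) {
  convention <- match.arg(convention)
  if (is.null(scale_factor)) {
    stop("missing scale_factor attribute; refusing to guess the packing")
  }
  if (scale_factor <= 0) stop("scale_factor must be positive")
  vals <- ifelse(stored == fill, NA_real_,
                 if (convention == "reciprocal") stored / scale_factor
                 else stored * scale_factor)
  if (!is.null(dim(stored))) array(vals, dim = dim(stored)) else vals
}

#' Product filename for a variable, interval and year
#'
#' `SiTH.v2.<VV>.<XXXX>.<YYYY>.nc`, e.g. `SiTH.v2.ET.Daily.1982.nc`.
#'
#' @param variable one of `ET`, `Tr`, `Es`, `Ei`, `SM1`, `SM2`, `SM3`.
#' @param interval `"Daily"`, `"Monthly"` or `"Annual"`.
#' @param year four-digit year.
#' @return filename string.
#' @export
product_filename <- function(variable, interval, year) {
  variable <- match.arg(variable, .PRODUCT_VARS)
  interval <- match.arg(interval, .PRODUCT_INTERVALS)
  sprintf("SiTH.v2.%s.%s.%04d.nc", variable, interval, as.integer(year))
}

#' Parse a product filename back to its components
#'
#' @param filename a product filename (path allowed).
#' @return list with `variable`, `interval`, `year`.
#' @export
parse_product_filename <- function(filename) {
  bn <- basename(filename)
  m <- regmatches(bn, regexec(
    "^SiTH\\.v2\\.([A-Za-z0-9]+)\\.([A-Za-z]+)\\.([0-9]{4})\\.nc$", bn))[[1]]
  if (length(m) != 4) stop(sprintf("not a product filename: '%s'", bn))
  if (!m[2] %in% .PRODUCT_VARS || !m[3] %in% .PRODUCT_INTERVALS) {
    stop(sprintf("unknown variable/interval in filename '%s'", bn))
  }
  list(variable = m[2], interval = m[3], year = as.integer(m[4]))
}

.PRODUCT_UNITS <- c(ET = "mm d-1", Tr = "mm d-1", Es = "mm d-1",
                    Ei = "mm d-1", SM1 = "m3 m-3", SM2 = "m3 m-3",
                    SM3 = "m3 m-3")

#' Write one year of a gridded variable as a packed NetCDF product
#'
#' Values are packed to 16-bit shorts (two-decimal convention) and written
#' to a NetCDF-3 classic file named by [product_filename()], with
#' coordinates at 0.1-degree cell centers and global attributes recording
#' the variable, interval, units, packing convention and model version.
#' By default the `scale_factor` attribute is the write-time multiplier
#' (the reader divides by it); `cf = TRUE` emits CF semantics
#' (`scale_factor = 1/100`, reader multiplies) instead, and a `packing`
#' attribute names the convention either way.
#'
#' @param values `[time, lat, lon]` array of physical values.
#' @param variable product variable name (`"ET"`, `"Tr"`, `"Es"`, `"Ei"`,
#'   `"SM1"`, `"SM2"`, `"SM3"`).
#' @param interval `"Daily"`, `"Monthly"` or `"Annual"`.
#' @param year four-digit year the file covers.
#' @param out_dir output directory.
#' @param lat,lon coordinate vectors of cell centers (degrees).
#' @param time time coordinate (default `1:ntime`, day/month index).
#' @param scale_factor packing multiplier, default 100.
#' @param cf logical; write a CF-convention `scale_factor` attribute.
#' @param overwrite refuse to clobber an existing file unless `TRUE`.
#' @return path of the file written.
#' @export
write_product <- function(values, variable, interval, year, out_dir,
                          lat, lon, time = NULL, scale_factor = 100,
                          cf = FALSE, overwrite = FALSE) {
  variable <- match.arg(variable, .PRODUCT_VARS)
  interval <- match.arg(interval, .PRODUCT_INTERVALS)
  d <- dim(values)
  if (length(d) != 3) stop("values must be a [time, lat, lon] array")
  if (d[2] != length(lat) || d[3] != length(lon)) {
    stop("lat/lon lengths do not match the values array")
  }
  expected <- c(Daily = 365L, Monthly = 12L, Annual = 1L)[[interval]]
  if (d[1] != expected) {
    stop(sprintf("%s product must have %d time steps, got %d",
                 interval, expected, d[1]))
  }
  if (is.null(time)) time <- seq_len(d[1])
  path <- file.path(out_dir, product_filename(variable, interval, year))
  if (file.exists(path) && !overwrite) {
    stop(sprintf("refusing to overwrite existing file '%s'", path))
  }
  packed <- pack_values(values, scale_factor)
  sf_att <- if (cf) 1 / scale_factor else scale_factor
  vars <- list(
    time = list(dims = "time", data = as.numeric(time), type = "double",
                atts = list(units = sprintf("%s index within %d",
                                            tolower(interval), year))),
    lat = list(dims = "lat", data = as.numeric(lat), type = "double",
               atts = list(units = "degrees_north")),
    lon = list(dims = "lon", data = as.numeric(lon), type = "double",
               atts = list(units = "degrees_east")))
  vars[[variable]] <- list(
    dims = c("time", "lat", "lon"), data = packed, type = "short",
    atts = list(scale_factor = sf_att,
                `_FillValue` = .NC_FILL_SHORT,
                units = .PRODUCT_UNITS[[variable]],
                packing = if (cf) "cf" else "reciprocal"))
  nc3_write(
    path,
    dims = list(time = d[1], lat = d[2], lon = d[3]),
    vars = vars,
    global_atts = list(
      title = sprintf("SiTHv2 %s %s product, %d", variable, interval, year),
      variable = variable, interval = interval, year = as.integer(year),
      units = .PRODUCT_UNITS[[variable]],
      scale_factor_convention = if (cf) "cf (value = stored * scale_factor)"
        else "reciprocal (value = stored / scale_factor)",
      model = "SiTHv2", source = "sithv2 R package"))
  path
}

#' Read a packed product file back to physical values
#'
#' Uses the file's `scale_factor` and `packing` attributes (hard failure if
#' the scale factor is absent) and restores `NA` at fill values.
#'
#' @param path product file path.
#' @return list with `values` (`[time, lat, lon]` array), `lat`, `lon`,
#'   `time`, `variable`, `interval`, `year`.
#' @export
read_product <- function(path) {
  meta <- parse_product_filename(path)
  nc <- nc3_read(path)
  v <- nc$vars[[meta$variable]]
  if (is.null(v)) stop("product variable not found in file")
  sf <- v$atts$scale_factor
  if (is.null(sf)) stop("missing scale_factor attribute in product file")
  convention <- v$atts$packing %||% "reciprocal"
  fill <- v$atts$`_FillValue` %||% .NC_FILL_SHORT
  values <- unpack_values(v$data, sf, fill = fill, convention = convention)
  list(values = values, lat = nc$vars$lat$data, lon = nc$vars$lon$data,
       time = nc$vars$time$data, variable = meta$variable,
       interval = meta$interval, year = meta$year)
}

#' Bilinear regrid of a rectilinear field
#'
#' Standard bilinear interpolation on cell centers; constant fields map to
#' constants, values are bounded by the four surrounding source values, and
#' target points coincident with source points reproduce them exactly.
#' Target points outside the source hull are clamped to the nearest edge
#' (with a warning).
#'
#' @param field matrix `[lat, lon]` at the source resolution.
#' @param src_lat,src_lon source cell-center coordinates (monotone).
#' @param dst_lat,dst_lon target cell-center coordinates.
#' @return matrix `[dst_lat, dst_lon]`.
#' @export
regrid_bilinear <- function(field, src_lat, src_lon, dst_lat, dst_lon) {
  if (is.unsorted(src_lat) ) {
    src_lat <- rev(src_lat)
    field <- field[rev(seq_len(nrow(field))), , drop = FALSE]
  }
  if (is.unsorted(src_lon)) {
    src_lon <- rev(src_lon)
    field <- field[, rev(seq_len(ncol(field))), drop = FALSE]
  }
  out_lat <- dst_lat
  out_lon <- dst_lon
  if (any(dst_lat < min(src_lat) | dst_lat > max(src_lat)) ||
      any(dst_lon < min(src_lon) | dst_lon > max(src_lon))) {
    warning("target grid extends beyond the source hull; ",
            "edge values are used (nearest policy)")
  }
  qlat <- pmin(pmax(out_lat, min(src_lat)), max(src_lat))
  qlon <- pmin(pmax(out_lon, min(src_lon)), max(src_lon))
  g <- expand.grid(lat = qlat, lon = qlon)
  z <- pracma::interp2(x = src_lon, y = src_lat, Z = field,
                       xp = g$lon, yp = g$lat, method = "linear")
  matrix(z, nrow = length(dst_lat), ncol = length(dst_lon))
}

#' Fill a sparse time series to daily resolution by cubic spline
#'
#' Cubic-spline interpolation (Forsythe-Malcolm-Moler end conditions, which
#' reproduce cubic polynomials exactly) through the observation knots,
#' evaluated at daily resolution; knot values are reproduced exactly.
#' Non-negative variables are floored at zero after interpolation. With
#' fewer than 4 knots the method falls back to linear interpolation with a
#' warning.
#'
#' @param t_obs observation times (days), strictly increasing.
#' @param y_obs observed values at `t_obs`.
#' @param t_out output times (default daily steps spanning the knots).
#' @param nonneg floor the result at zero (default `TRUE`).
#' @return numeric vector of length `length(t_out)`.
#' @export
gapfill_spline <- function(t_obs, y_obs, t_out = NULL, nonneg = TRUE) {
  if (length(t_obs) != length(y_obs)) stop("t_obs and y_obs lengths differ")
  if (any(diff(t_obs) <= 0)) stop("t_obs must be strictly increasing")
  if (is.null(t_out)) t_out <- seq(ceiling(min(t_obs)), floor(max(t_obs)))
  y <- if (length(t_obs) < 4) {
    warning("fewer than 4 knots; falling back to linear interpolation")
    stats::approx(t_obs, y_obs, xout = t_out, rule = 2)$y
  } else {
    stats::spline(t_obs, y_obs, xout = t_out, method = "fmm")$y
  }
  if (nonneg) pmax(y, 0) else y
}
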
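# Minimal NetCDF-3 classic (CDF-1) writer and reader in base R.
#
# Supports what the gridded product needs: fixed-size dimensions, variables
# of type short/int/float/double/char, and global/variable attributes. All
# header integers are 4-byte big-endian; names and values are padded to
# 4-byte boundaries as required by the classic format. Record (unlimited)
# dimensions are not used: time is written as a fixed dimension.

.NC_TYPES <- c(byte = 1L, char = 2L, short = 3L, int = 4L, float = 5L,
               double = 6L)
.NC_SIZES <- c(byte = 1L, char = 1L, short = 2L, int = 4L, float = 4L,
               double = 8L)
.NC_DIMENSION <- 10L
.NC_VARIABLE <- 11L
.NC_ATTRIBUTE <- 12L

.pad4 <- function(n) as.integer((4 - n %% 4) %% 4)

.nc3_put_name <- function(con, name) {
  b <- charToRaw(name)
  writeBin(length(b), con, size = 4, endian = "big")
  writeBin(b, con)
  if (.pad4(length(b)) > 0) writeBin(raw(.pad4(length(b))), con)
}

.nc3_put_values <- function(con, values, type) {
  n <- if (type == "char") nchar(values, type = "bytes") else length(values)
  nbytes <- n * .NC_SIZES[[type]]
  switch(type,
    char = writeBin(charToRaw(values), con),
    byte = writeBin(as.integer(values), con, size = 1, endian = "big"),
    short = writeBin(as.integer(values), con, size = 2, endian = "big"),
    int = writeBin(as.integer(values), con, size = 4, endian = "big"),
    float = writeBin(as.numeric(values), con, size = 4, endian = "big"),
    double = writeBin(as.numeric(values), con, size = 8, endian = "big"))
  if (.pad4(nbytes) > 0) writeBin(raw(.pad4(nbytes)), con)
}

# attribute type inferred from the R value
.att_type <- function(v) {
  if (is.character(v)) "char"
  else if (is.integer(v)) "int"
  else "double"
}

.nc3_put_att_list <- function(con, atts) {
  if (length(atts) == 0) {
    writeBin(c(0L, 0L), con, size = 4, endian = "big")
    return(invisible())
  }
  writeBin(c(.NC_ATTRIBUTE, length(atts)), con, size = 4, endian = "big")
  for (nm in names(atts)) {
    v <- atts[[nm]]
    ty <- .att_type(v)
    .nc3_put_name(con, nm)
    writeBin(.NC_TYPES[[ty]], con, size = 4, endian = "big")
    n <- if (ty == "char") nchar(v, type = "bytes") else length(v)
    writeBin(as.integer(n), con, size = 4, endian = "big")
    .nc3_put_values(con, v, ty)
  }
}

.nc3_header <- function(dims, vars, global_atts, begins) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(charToRaw("CDF"), con)
  writeBin(as.raw(1L), con)                      # CDF-1
  writeBin(0L, con, size = 4, endian = "big")    # numrecs (no record vars)
  # dimension list
  writeBin(c(.NC_DIMENSION, length(dims)), con, size = 4, endian = "big")
  for (nm in names(dims)) {
    .nc3_put_name(con, nm)
    writeBin(as.integer(dims[[nm]]), con, size = 4, endian = "big")
  }
  .nc3_put_att_list(con, global_atts)
  # variable list
  writeBin(c(.NC_VARIABLE, length(vars)), con, size = 4, endian = "big")
  for (k in seq_along(vars)) {
    v <- vars[[k]]
    .nc3_put_name(con, names(vars)[k])
    dimids <- match(v$dims, names(dims)) - 1L
    writeBin(length(dimids), con, size = 4, endian = "big")
    if (length(dimids) > 0) {
      writeBin(dimids, con, size = 4, endian = "big")
    }
    .nc3_put_att_list(con, v$atts %||% list())
    writeBin(.NC_TYPES[[v$type]], con, size = 4, endian = "big")
    nelem <- prod(unlist(dims[v$dims]))
    vsize <- nelem * .NC_SIZES[[v$type]]
    vsize <- as.integer(vsize + .pad4(vsize))
    writeBin(vsize, con, size = 4, endian = "big")
    writeBin(as.integer(begins[k]), con, size = 4, endian = "big")
  }
  rawConnectionValue(con)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a NetCDF-3 classic file
#'
#' @param path output file path.
#' @param dims named list of dimension lengths, in definition order.
#' @param vars named list of variables; each a list with `dims` (character
#'   vector of dimension names, slowest varying first), `data` (R array
#'   with dimensions in that same order), `type` (`"short"`, `"int"`,
#'   `"float"`, `"double"` or `"char"`), and optional `atts` (named list).
#' @param global_atts named list of global attributes.
#' @return `path`, invisibly.
#' @export
nc3_write <- function(path, dims, vars, global_atts = list()) {
  for (k in seq_along(vars)) {
    v <- vars[[k]]
    nelem <- prod(unlist(dims[v$dims]))
    if (length(v$data) != nelem) {
      stop(sprintf("variable '%s': data length %d does not match dims (%d)",
                   names(vars)[k], length(v$data), nelem))
    }
  }
  vsizes <- vapply(vars, function(v) {
    s <- prod(unlist(dims[v$dims])) * .NC_SIZES[[v$type]]
    s + .pad4(s)
  }, numeric(1))
  header0 <- .nc3_header(dims, vars, global_atts,
                         begins = rep(0L, length(vars)))
  begins <- length(header0) + cumsum(c(0, vsizes[-length(vsizes)]))
  header <- .nc3_header(dims, vars, global_atts, begins = begins)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  for (v in vars) {
    x <- v$data
    nd <- length(v$dims)
    vec <- if (nd > 1) {
      as.vector(aperm(array(x, dim = unlist(dims[v$dims])),
                      rev(seq_len(nd))))
    } else as.vector(x)
    .nc3_put_values(con, vec, v$type)
  }
  invisible(path)
}

# ---- reader ----

.nc3_cursor <- function(raw_bytes) {
  env <- new.env(parent = emptyenv())
  env$b <- raw_bytes
  env$pos <- 1L
  env
}

.take <- function(cur, n) {
  out <- cur$b[cur$pos:(cur$pos + n - 1L)]
  cur$pos <- cur$pos + as.integer(n)
  out
}

.get_int <- function(cur, n = 1L) {
  readBin(.take(cur, 4L * n), "integer", n = n, size = 4, endian = "big")
}

.get_name <- function(cur) {
  len <- .get_int(cur)
  nm <- rawToChar(.take(cur, len))
  if (.pad4(len) > 0) .take(cur, .pad4(len))
  nm
}

.get_values <- function(cur, type, n) {
  nbytes <- n * .NC_SIZES[[type]]
  bytes <- .take(cur, nbytes)
  if (.pad4(nbytes) > 0) .take(cur, .pad4(nbytes))
  switch(type,
    char = rawToChar(bytes),
    byte = readBin(bytes, "integer", n = n, size = 1, endian = "big"),
    short = readBin(bytes, "integer", n = n, size = 2, signed = TRUE,
                    endian = "big"),
    int = readBin(bytes, "integer", n = n, size = 4, endian = "big"),
    float = readBin(bytes, "double", n = n, size = 4, endian = "big"),
    double = readBin(bytes, "double", n = n, size = 8, endian = "big"))
}

.get_att_list <- function(cur) {
  tag <- .get_int(cur)
  n <- .get_int(cur)
  if (n == 0) return(list())
  if (tag != .NC_ATTRIBUTE) stop("malformed NetCDF header: bad attribute tag")
  atts <- list()
  for (i in seq_len(n)) {
    nm <- .get_name(cur)
    ty <- names(.NC_TYPES)[match(.get_int(cur), .NC_TYPES)]
    nel <- .get_int(cur)
    atts[[nm]] <- .get_values(cur, ty, nel)
  }
  atts
}

#' Read a NetCDF-3 classic file
#'
#' Counterpart to [nc3_write()]. Returns dimension lengths, global
#' attributes, and each variable's data (as an R array with dimensions in
#' the variable's declared order) and attributes.
#'
#' @param path file path.
#' @return list with `dims`, `global_atts`, `vars` (each with `dims`,
#'   `type`, `atts`, `data`).
#' @export
nc3_read <- function(path) {
  raw_bytes <- readBin(path, "raw", n = file.info(path)$size)
  cur <- .nc3_cursor(raw_bytes)
  magic <- rawToChar(.take(cur, 3L))
  version <- as.integer(.take(cur, 1L))
  if (magic != "CDF" || !(version %in% c(1L, 2L))) {
    stop("not a NetCDF-3 classic file")
  }
  .get_int(cur)  # numrecs, unused (no record variables written)
  tag <- .get_int(cur); ndims <- .get_int(cur)
  dims <- list()
  if (ndims > 0) {
    if (tag != .NC_DIMENSION) stop("malformed NetCDF header: bad dim tag")
    for (i in seq_len(ndims)) {
      nm <- .get_name(cur)  # name must be consumed before the length
      dims[[nm]] <- .get_int(cur)
    }
  }
  global_atts <- .get_att_list(cur)
  tag <- .get_int(cur); nvars <- .get_int(cur)
  vars <- list()
  if (nvars > 0) {
    if (tag != .NC_VARIABLE) stop("malformed NetCDF header: bad var tag")
    for (i in seq_len(nvars)) {
      nm <- .get_name(cur)
      nd <- .get_int(cur)
      dimids <- if (nd > 0) .get_int(cur, nd) else integer(0)
      atts <- .get_att_list(cur)
      ty <- names(.NC_TYPES)[match(.get_int(cur), .NC_TYPES)]
      .get_int(cur)  # vsize (recomputed below)
      begin <- if (version == 1L) .get_int(cur) else {
        hi <- .get_int(cur); lo <- .get_int(cur); hi * 2^32 + lo
      }
      vars[[nm]] <- list(dims = names(dims)[dimids + 1L], type = ty,
                         atts = atts, begin = begin)
    }
  }
  for (nm in names(vars)) {
    v <- vars[[nm]]
    dl <- unname(unlist(dims[v$dims]))
    nelem <- if (length(dl) == 0) 1L else prod(dl)
    dcur <- .nc3_cursor(raw_bytes)
    dcur$pos <- as.integer(v$begin) + 1L
    vec <- .get_values(dcur, v$type, nelem)
    if (length(dl) > 1) {
      y <- array(vec, dim = rev(dl))
      vec <- aperm(y, rev(seq_along(dl)))
    }
    vars[[nm]]$data <- vec
    vars[[nm]]$begin <- NULL
  }
  list(dims = dims, global_atts = global_atts, vars = vars)
}
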
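#' Gridded suitability / environmental surface
#'
#' Minimal in-memory raster matching the ESRI ASCII grid model: a value
#' matrix whose first row is the northernmost row, a lower-left corner,
#' a square cell size in decimal degrees (WGS-84), and `NA` for no-data
#' cells. Used both for environmental predictor grids and for niche-model
#' suitability surfaces (non-negative values, normalizable to a
#' probability surface).
#'
#' @param values numeric matrix; row 1 = top (north) row.
#' @param xll,yll longitude/latitude of the lower-left corner of the grid.
#' @param cellsize cell size in decimal degrees.
#' @param crs coordinate-system tag (informational; default `"WGS-84"`).
#' @return Object of class `"suitability_surface"`.
#' @export
suitability_surface <- function(values, xll, yll, cellsize, crs = "WGS-84") {
  values <- as.matrix(values)
  if (any(is.infinite(values)))
    stop("surface values must be finite or NA", call. = FALSE)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, crs = crs),
            class = "suitability_surface")
}

#' @export
print.suitability_surface <- function(x, ...) {
  cat(sprintf("suitability_surface: %d x %d cells, cellsize %g deg, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  cat(sprintf("  values: [%g, %g], %d no-data cells\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              sum(is.na(x$values))))
  invisible(x)
}

#' Cell-center coordinates of a surface
#'
#' @param surface a [suitability_surface()].
#' @return Data frame `lon`, `lat`, `row`, `col`, one row per cell in
#'   column-major order of the value matrix.
#' @export
grid_centers <- function(surface) {
  nr <- nrow(surface$values); nc <- ncol(surface$values)
  lon <- surface$xll + (seq_len(nc) - 0.5) * surface$cellsize
  lat <- surface$yll + (nr - seq_len(nr) + 0.5) * surface$cellsize
  data.frame(lon = rep(lon, each = nr), lat = rep(lat, times = nc),
             row = rep(seq_len(nr), times = nc),
             col = rep(seq_len(nc), each = nr))
}

in_extent <- function(surface, lon, lat) {
  nr <- nrow(surface$values); nc <- ncol(surface$values)
  lon >= surface$xll & lon <= surface$xll + nc * surface$cellsize &
    lat >= surface$yll & lat <= surface$yll + nr * surface$cellsize
}

#' Extract the cell value at a point
#'
#' @param surface a [suitability_surface()].
#' @param lon,lat point coordinates (vectors allowed).
#' @return Cell values (`NA` for no-data cells).
#' @export
extract_value <- function(surface, lon, lat) {
  if (any(!in_extent(surface, lon, lat)))
    stop("point outside raster extent", call. = FALSE)
  nr <- nrow(surface$values); nc <- ncol(surface$values)
  col <- pmin(pmax(ceiling((lon - surface$xll) / surface$cellsize), 1), nc)
  row <- pmin(pmax(nr - ceiling((lat - surface$yll) / surface$cellsize) + 1, 1), nr)
  surface$values[cbind(row, col)]
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard 6-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`; `xllcenter`/`yllcenter` are
#' converted) followed by whitespace-separated rows, north row first.
#' `NODATA_value` cells become `NA`.
#'
#' @param path file path.
#' @return A [suitability_surface()].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    hdr$yllcenter - hdr$cellsize / 2
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has wrong cell count in ", path, call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  suitability_surface(m, xll, yll, hdr$cellsize)
}

#' Write an ESRI ASCII grid
#'
#' @param surface a [suitability_surface()].
#' @param path output file path.
#' @param nodata value written for `NA` cells (default -9999).
#' @export
write_ascii_grid <- function(surface, path, nodata = -9999) {
  stopifnot(inherits(surface, "suitability_surface"))
  m <- surface$values
  m[is.na(m)] <- nodata
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", surface$xll),
    sprintf("yllcorner %.10g", surface$yll),
    sprintf("cellsize %.10g", surface$cellsize),
    sprintf("NODATA_value %g", nodata)), con)
  utils::write.table(format(m, trim = TRUE, scientific = FALSE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mean raster value in a circular buffer around a point
#'
#' Mean of the non-missing cell values whose centers lie within
#' `radius_km` great-circle kilometres of the point. This is the
#' raster-neighbourhood form of extracting environmental values as means
#' over a buffer around imprecisely located collection sites (5 km by
#' default), which smooths coordinate uncertainty.
#'
#' @param surface a [suitability_surface()].
#' @param lon,lat point coordinates (scalar).
#' @param radius_km buffer radius in km (default 5).
#' @return Scalar mean.
#' @export
buffer_mean_extract <- function(surface, lon, lat, radius_km = 5) {
  if (!in_extent(surface, lon, lat))
    stop("point outside raster extent", call. = FALSE)
  ctr <- grid_centers(surface)
  d <- geosphere::distHaversine(cbind(lon, lat), cbind(ctr$lon, ctr$lat),
                                r = 6371.0088)
  v <- surface$values[cbind(ctr$row, ctr$col)][d <= radius_km]
  v <- v[!is.na(v)]
  if (!length(v))
    stop("empty buffer: no valid cells within ", radius_km, " km", call. = FALSE)
  mean(v)
}
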
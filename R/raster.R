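#' Lightweight in-memory single-band raster
#'
#' A minimal raster container used throughout the package: a numeric matrix
#' in row-major map orientation (row 1 = northernmost row) plus an origin
#' and square cell size in projected metres. All package coordinates are in
#' an arbitrary projected metric CRS; no geodesy is performed.
#'
#' @param values numeric matrix, `nrow` = rows (north to south), `ncol` = columns
#'   (west to east).
#' @param xmin,ymin coordinates (m) of the lower-left corner of the grid.
#' @param cellsize square cell edge length (m), > 0.
#' @return an object of class `bruv_raster`.
#' @export
bruv_raster <- function(values, xmin = 0, ymin = 0, cellsize = 100) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize),
    class = "bruv_raster"
  )
}

#' @export
print.bruv_raster <- function(x, ...) {
  cat(sprintf(
    "<bruv_raster> %d x %d cells, cell %g m, origin (%g, %g), range [%g, %g]\n",
    nrow(x$values), ncol(x$values), x$cellsize, x$xmin, x$ymin,
    min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)
  ))
  invisible(x)
}

#' @export
dim.bruv_raster <- function(x) dim(x$values)

#' Cell-center coordinates of every raster cell
#'
#' @param r a [bruv_raster].
#' @return data.frame with `row`, `col`, `x`, `y`, `value`; row 1 is the
#'   northernmost raster row, so `y` decreases with `row`.
#' @export
raster_cells <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  row <- rep(seq_len(nr), times = nc)
  col <- rep(seq_len(nc), each = nr)
  data.frame(
    row = row, col = col,
    x = r$xmin + (col - 0.5) * r$cellsize,
    y = r$ymin + (nr - row + 0.5) * r$cellsize,
    value = as.vector(r$values)
  )
}

#' Extract raster values at point coordinates
#'
#' Nearest-cell (containing-cell) lookup; points outside the grid get `NA`.
#'
#' @param r a [bruv_raster].
#' @param x,y point coordinates (m).
#' @return numeric vector of cell values.
#' @export
raster_extract <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((x - r$xmin) / r$cellsize) + 1
  row <- nr - floor((y - r$ymin) / r$cellsize)
  ok <- col >= 1 & col <= nc & row >= 1 & row <= nr
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

#' Read / write rasters as ESRI ASCII grid
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows north to south); used in
#' place of a binary raster format so that all artifacts stay text.
#'
#' @param r a [bruv_raster].
#' @param path file path.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a [bruv_raster].
#' @export
write_ascii_grid <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$cellsize),
    "NODATA_value -9999"
  ), con)
  vals <- r$values
  vals[is.na(vals)] <- -9999
  write.table(format(vals, trim = TRUE, digits = 10, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(vals) <- NULL
  vals[vals == h[["nodata_value"]]] <- NA
  stopifnot(nrow(vals) == h[["nrows"]], ncol(vals) == h[["ncols"]])
  bruv_raster(vals, xmin = h[["xllcorner"]], ymin = h[["yllcorner"]],
              cellsize = h[["cellsize"]])
}

#' Write point or polygon layers as GeoJSON
#'
#' Minimal GeoJSON writer for the package's vector outputs (island points,
#' hexagonal summary grids). Coordinates are written as-is (projected m).
#'
#' @param df data.frame; must contain `x`, `y` columns (points) or a
#'   list-column `coords` of n x 2 matrices (polygons). Remaining columns
#'   become feature properties.
#' @param path output file.
#' @param geometry `"Point"` or `"Polygon"`.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(df, path, geometry = c("Point", "Polygon")) {
  geometry <- match.arg(geometry)
  feats <- lapply(seq_len(nrow(df)), function(i) {
    if (geometry == "Point") {
      geom <- list(type = "Point", coordinates = c(df$x[i], df$y[i]))
      props <- as.list(df[i, setdiff(names(df), c("x", "y")), drop = FALSE])
    } else {
      ring <- df$coords[[i]]
      if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
      geom <- list(type = "Polygon",
                   coordinates = list(lapply(seq_len(nrow(ring)),
                                             function(j) ring[j, ])))
      props <- as.list(df[i, setdiff(names(df), "coords"), drop = FALSE])
    }
    list(type = "Feature", geometry = geom, properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON point layer
#'
#' @param path GeoJSON file with Point features.
#' @return data.frame with `x`, `y` and any feature properties.
#' @export
read_geojson_points <- function(path) {
  g <- jsonlite::read_json(path)
  stopifnot(identical(g$type, "FeatureCollection"))
  rows <- lapply(g$features, function(f) {
    stopifnot(identical(f$geometry$type, "Point"))
    cc <- unlist(f$geometry$coordinates)
    c(list(x = cc[1], y = cc[2]), f$properties)
  })
  do.call(rbind.data.frame, rows)
}
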
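#' Gridded canopy-height raster
#'
#' A minimal in-memory container for a single-band height grid on a planar,
#' equal-area grid. Values are heights in meters (`NA` = nodata), stored as a
#' matrix whose first row is the northernmost row (row-major, 0-based cell
#' indexing in the file format; cell-center registration).
#'
#' @param values numeric matrix of heights in meters, `NA` for nodata.
#' @param cell_size cell edge length in meters (> 0).
#' @param xll,yll planar coordinates of the lower-left corner of the grid.
#' @return an object of class `height_raster`.
#' @export
height_raster <- function(values, cell_size = 30, xll = 0, yll = 0) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (any(values < 0, na.rm = TRUE))
    stop("heights must be >= 0 where not nodata")
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 xll = as.numeric(xll), yll = as.numeric(yll)),
            class = "height_raster")
}

#' @export
print.height_raster <- function(x, ...) {
  cat(sprintf("<height_raster> %d x %d cells, %.0f m resolution\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  v <- x$values[!is.na(x$values)]
  cat(sprintf("  height range [%.2f, %.2f] m, %.1f%% nodata\n",
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              100 * mean(is.na(x$values))))
  invisible(x)
}

# planar coordinates of all cell centers; row 1 is the top (north) row
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  list(x = r$xll + (seq_len(nc) - 0.5) * cs,
       y = r$yll + (nr - seq_len(nr) + 0.5) * cs)
}

#' Read / write ESRI ASCII grid
#'
#' Plain-text single-band raster exchange format (`ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value` header followed by rows north to south).
#'
#' @param path file path.
#' @return `read_ascii_grid` returns a [height_raster()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("grid body does not match header dims")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  height_raster(m, cell_size = hdr$cellsize,
                xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0)
}

#' @param raster a [height_raster()].
#' @param nodata numeric value written for `NA` cells.
#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  m <- raster$values
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.6f", raster$xll),
           sprintf("yllcorner %.6f", raster$yll),
           sprintf("cellsize %.6f", raster$cell_size),
           sprintf("NODATA_value %g", nodata))
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a circular landscape buffer
#'
#' Clips a circular window of given radius around a center point: cells whose
#' centers lie farther than `radius` from `center` become nodata, and the
#' result is cropped to the circle's bounding box. This is the landscape unit
#' on which all habitat metrics are computed (default radius 19 km, the
#' buffer used to characterize habitat around a survey route centroid,
#' enclosing roughly 1100 km^2).
#'
#' @param raster a [height_raster()].
#' @param center numeric length-2, planar `(x, y)` of the buffer center.
#' @param radius buffer radius in meters.
#' @return a `landscape_window` (inherits `height_raster`) with `center` and
#'   `radius` recorded.
#' @export
extract_buffer <- function(raster, center, radius = 19000) {
  stopifnot(inherits(raster, "height_raster"), length(center) == 2,
            radius > 0)
  cc <- cell_centers(raster)
  dx <- cc$x - center[1]
  dy <- cc$y - center[2]
  keep_col <- which(abs(dx) <= radius)
  keep_row <- which(abs(dy) <= radius)
  if (!length(keep_col) || !length(keep_row))
    stop("buffer outside raster")
  m <- raster$values[keep_row, keep_col, drop = FALSE]
  d2 <- outer(dy[keep_row]^2, dx[keep_col]^2, `+`)
  m[d2 > radius^2] <- NA_real_
  if (all(is.na(m))) stop("buffer outside raster")
  out <- height_raster(m, cell_size = raster$cell_size,
                       xll = raster$xll + (min(keep_col) - 1) * raster$cell_size,
                       yll = raster$yll +
                         (nrow(raster$values) - max(keep_row)) * raster$cell_size)
  out$center <- as.numeric(center)
  out$radius <- as.numeric(radius)
  class(out) <- c("landscape_window", "height_raster")
  out
}

#' Treat a full raster as one landscape window
#'
#' Convenience for computing metrics on a rectangular grid without circular
#' clipping (e.g. synthetic experiments).
#' @param raster a [height_raster()].
#' @export
as_window <- function(raster) {
  stopifnot(inherits(raster, "height_raster"))
  class(raster) <- unique(c("landscape_window", class(raster)))
  raster
}

#' Landscape area of a window
#'
#' Area of the non-nodata cells in m^2 -- the denominator used by all
#' density metrics (edge density, contrast-weighted edge density).
#' @param window a `landscape_window` or `height_raster`.
#' @export
landscape_area_m2 <- function(window) {
  sum(!is.na(window$values)) * window$cell_size^2
}
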
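#' Georeferenced raster grid
#'
#' Lightweight container for the 2-D layers the pipeline exchanges: the RGB
#' orthomosaic (DOM, 8-bit digital numbers), digital surface models (DSM,
#' metres), canopy height models, index layers and binary vegetation masks.
#'
#' The coordinate convention is fixed package-wide: pixels are addressed
#' \code{(row, col)}, 1-based, row 1 at the top; the affine transform maps
#' pixel \emph{centres} to world coordinates,
#' \code{x = x0 + (col-1)*dx}, \code{y = y0 + (row-1)*dy} (north-up grids
#' have \code{dy < 0}).  Only axis-aligned transforms are supported.
#'
#' @param values numeric matrix (single band) or \code{rows x cols x 3}
#'   array (RGB).
#' @param transform numeric length-4 vector \code{c(x0, dx, y0, dy)};
#'   \code{dx} and \code{dy} must be non-zero.
#' @param nodata optional sentinel value; cells equal to it (or \code{NA})
#'   are treated as missing by all per-plot statistics.
#' @param units free-text unit tag, one of \code{"DN8"} (8-bit digital
#'   numbers), \code{"m"}, \code{"index"}, \code{"binary"}.
#' @return an object of class \code{raster_grid}.
#' @export
raster_grid <- function(values, transform = c(0.5, 1, -0.5, -1),
                        nodata = NULL, units = "index") {
  if (!is.numeric(values)) stop("`values` must be numeric")
  d <- dim(values)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] == 3L)))
    stop("`values` must be a matrix or a rows x cols x 3 array")
  if (d[1] < 1L || d[2] < 1L) stop("raster must have positive dimensions")
  transform <- as.numeric(transform)
  if (length(transform) != 4L || any(!is.finite(transform)))
    stop("`transform` must be c(x0, dx, y0, dy), all finite")
  if (transform[2] == 0 || transform[4] == 0)
    stop("degenerate affine: dx and dy must be non-zero")
  if (identical(units, "DN8")) {
    v <- values[is.finite(values)]
    if (length(v) && (min(v) < 0 || max(v) > 255))
      stop("DN8 rasters must lie in [0, 255]")
  }
  if (identical(units, "binary")) {
    v <- values[is.finite(values)]
    if (length(v) && !all(v %in% c(0, 1)))
      stop("binary rasters may only contain 0, 1 and nodata")
  }
  structure(list(values = values, transform = transform,
                 nodata = nodata, units = units),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_grid> %d x %d%s, units '%s'\n", d[1], d[2],
              if (length(d) == 3L) " x 3 bands" else "", x$units))
  cat(sprintf("  transform: x0=%.6g dx=%.6g y0=%.6g dy=%.6g\n",
              x$transform[1], x$transform[2], x$transform[3], x$transform[4]))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

n_bands <- function(grid) if (length(dim(grid$values)) == 3L) 3L else 1L

## World coordinates of all pixel centres along each axis.
pixel_centres <- function(grid) {
  d <- dim(grid$values)
  list(x = grid$transform[1] + (seq_len(d[2]) - 1) * grid$transform[2],
       y = grid$transform[3] + (seq_len(d[1]) - 1) * grid$transform[4])
}

## Replace nodata sentinel by NA in a copy of the values.
values_na <- function(grid) {
  v <- grid$values
  if (!is.null(grid$nodata)) v[v == grid$nodata] <- NA_real_
  v
}

sidecar_paths <- function(path) {
  list(wld = paste0(path, ".wld"), meta = paste0(path, ".json"))
}

#' Write a raster to disk
#'
#' Writes a TIFF image plus an ESRI world file (\code{<path>.wld}) carrying
#' the affine transform and a JSON sidecar (\code{<path>.json}) carrying
#' units, nodata and the value scaling.  \code{"DN8"} and \code{"binary"}
#' layers are stored as 8-bit samples and round-trip bit-exactly; metric and
#' index layers are stored as 32-bit floats rescaled to the unit interval
#' (the scale and offset live in the sidecar), which round-trips to within
#' float precision of the value range.
#'
#' @param grid a \code{\link{raster_grid}}.
#' @param path output path (".tif" recommended).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  na_mask <- !is.finite(v) | (if (!is.null(grid$nodata)) v == grid$nodata else FALSE)
  meta <- list(units = grid$units,
               nodata = if (is.null(grid$nodata)) NULL else grid$nodata,
               has_nodata_cells = any(na_mask))
  if (grid$units %in% c("DN8", "binary")) {
    scaled <- v
    scaled[na_mask] <- 0
    ## binary masks stored as full-scale 0/255 samples, DN8 as-is
    scaled <- if (grid$units == "binary") scaled else scaled / 255
    bits <- 8L
    meta$encoding <- if (grid$units == "binary") "bit" else "dn8"
  } else {
    fin <- v[!na_mask]
    off <- if (length(fin)) min(fin) else 0
    rng <- if (length(fin)) max(fin) - off else 0
    if (rng == 0) rng <- 1
    scaled <- (v - off) / rng
    ## valid data compressed into [0.25, 1]; 0 is the nodata sentinel in-file
    scaled <- 0.25 + 0.75 * scaled
    scaled[na_mask] <- 0
    bits <- 32L
    meta$encoding <- "float_scaled"
    meta$offset <- off
    meta$scale <- rng
  }
  suppressWarnings(tiff::writeTIFF(scaled, path, bits.per.sample = bits))
  sc <- sidecar_paths(path)
  tr <- grid$transform
  writeLines(formatC(c(tr[2], 0, 0, tr[4], tr[1], tr[3]),
                     format = "g", digits = 17), sc$wld)
  jsonlite::write_json(meta, sc$meta, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a raster from disk
#'
#' Reads TIFF (or PNG) rasters written by \code{\link{write_raster}}, or any
#' 8-bit TIFF/PNG accompanied by a world file.  Rotated world files are
#' rejected; DN bands are validated to lie in \code{[0, 255]}.
#'
#' @param path raster path.
#' @return a \code{\link{raster_grid}}.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "png" = png::readPNG(path),
    tryCatch(tiff::readTIFF(path), error = function(e)
      stop("unreadable raster (", conditionMessage(e), ")")))
  d <- dim(raw)
  if (!(length(d) == 2L || (length(d) == 3L && d[3] %in% c(1L, 3L))))
    stop("format error: band count must be 1 or 3, got ",
         if (length(d) == 3L) d[3] else 1L)
  if (length(d) == 3L && d[3] == 1L) { raw <- raw[, , 1]; d <- dim(raw) }

  sc <- sidecar_paths(path)
  if (!file.exists(sc$wld)) stop("format error: missing world file ", sc$wld)
  w <- suppressWarnings(as.numeric(readLines(sc$wld)))
  if (length(w) != 6L || any(!is.finite(w)))
    stop("format error: unreadable affine in ", sc$wld)
  if (w[2] != 0 || w[3] != 0)
    stop("rotated affines are not supported")
  transform <- c(w[5], w[1], w[6], w[4])

  meta <- if (file.exists(sc$meta)) jsonlite::read_json(sc$meta) else
    list(units = if (length(d) == 3L) "DN8" else "index", encoding = "dn8")
  enc <- meta$encoding %||% "dn8"
  if (enc == "float_scaled") {
    v <- raw
    na <- v == 0
    v <- (v - 0.25) / 0.75 * meta$scale + meta$offset
    v[na] <- NA_real_
  } else if (enc == "bit") {
    v <- round(raw)
  } else {
    v <- round(raw * 255)
  }
  raster_grid(v, transform = transform,
              nodata = meta$nodata %||% NULL, units = meta$units %||% "index")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pixels covered by a plot polygon
#'
#' Returns the (row, col) indices of all pixels whose \emph{centre} falls
#' inside the polygon ring — the deterministic centre-point rasterisation
#' rule used by every per-plot statistic in the package.
#'
#' @param polygon two-column matrix of ring vertices in world coordinates
#'   (closed or open; closure is enforced).
#' @param grid a \code{\link{raster_grid}}.
#' @return integer matrix with columns \code{row}, \code{col} (possibly
#'   zero rows, with a warning, when the polygon misses the grid).
#' @export
rasterize_plot <- function(polygon, grid) {
  stopifnot(inherits(grid, "raster_grid"))
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("polygon must be a ring of at least 3 (x, y) vertices")
  if (!all(polygon[1, ] == polygon[nrow(polygon), ]))
    polygon <- rbind(polygon, polygon[1, ])
  ctr <- pixel_centres(grid)
  cand_c <- which(ctr$x >= min(polygon[, 1]) & ctr$x <= max(polygon[, 1]))
  cand_r <- which(ctr$y >= min(polygon[, 2]) & ctr$y <= max(polygon[, 2]))
  empty <- matrix(integer(), 0, 2, dimnames = list(NULL, c("row", "col")))
  if (!length(cand_c) || !length(cand_r)) {
    warning("polygon does not intersect the raster extent")
    return(empty)
  }
  pts <- cbind(rep(ctr$x[cand_c], each = length(cand_r)),
               rep(ctr$y[cand_r], times = length(cand_c)))
  inside <- mgcv::in.out(polygon, pts)
  if (!any(inside)) {
    warning("polygon does not cover any pixel centre")
    return(empty)
  }
  out <- cbind(row = rep(cand_r, times = length(cand_c))[inside],
               col = rep(cand_c, each = length(cand_r))[inside])
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

## Band i of a 3-band array, dimensions preserved even for 1 x n grids.
band <- function(v, i) {
  d <- dim(v)
  out <- v[, , i, drop = FALSE]
  dim(out) <- d[1:2]
  out
}

## Shoelace area of a ring (world units squared).
ring_area <- function(polygon) {
  p <- as.matrix(polygon)
  if (!all(p[1, ] == p[nrow(p), ])) p <- rbind(p, p[1, ])
  x <- p[, 1]; y <- p[, 2]; n <- nrow(p)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}
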
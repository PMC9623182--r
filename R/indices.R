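#' Normalised chromaticity coordinates
#'
#' Converts an 8-bit RGB raster to the brightness-free chromaticity
#' coordinates \code{r = R/(R+G+B)}, \code{g = G/(R+G+B)},
#' \code{b = B/(R+G+B)}.  Pixels with \code{R+G+B = 0} are flagged invalid
#' rather than producing NaN.
#'
#' @param rgb 3-band \code{"DN8"} \code{\link{raster_grid}}.
#' @return list with matrices \code{r}, \code{g}, \code{b} and a logical
#'   \code{valid} matrix; class \code{chromaticity_image}.
#' @export
normalize_chromaticity <- function(rgb) {
  stopifnot(inherits(rgb, "raster_grid"))
  if (n_bands(rgb) != 3L) stop("chromaticity requires a 3-band raster")
  v <- values_na(rgb)
  R <- band(v, 1); G <- band(v, 2); B <- band(v, 3)
  s <- R + G + B
  valid <- is.finite(s) & s > 0
  s[!valid] <- 1
  out <- list(r = R / s, g = G / s, b = B / s, valid = valid)
  out$r[!valid] <- NA_real_; out$g[!valid] <- NA_real_; out$b[!valid] <- NA_real_
  class(out) <- "chromaticity_image"
  out
}

#' The visible-light vegetation index registry
#'
#' The ten indices computed by the pipeline, in their fixed registry order
#' (used for deterministic tie-breaking in feature selection).  \code{R},
#' \code{G}, \code{B} are the raw band digital numbers; the remainder are
#' functions of the normalised chromaticities.  \code{GLA} is implemented
#' exactly as registered, \code{(2g - r + b)/(2g + r + b)}, which differs
#' from \code{GLI} only in the sign of \code{b}; \code{GRRI} is \code{r/g}.
#'
#' @return character vector of index names in registry order.
#' @export
vi_registry <- function() {
  c("R", "G", "B", "GRRI", "GLA", "GLI", "GRVI", "VARI", "EXG", "NDI")
}

index_formula <- function(name, r, g, b) {
  switch(name,
    GRRI = list(v = r / g,                       bad = g == 0),
    GLA  = list(v = (2 * g - r + b) / (2 * g + r + b), bad = (2 * g + r + b) == 0),
    GLI  = list(v = (2 * g - r - b) / (2 * g + r + b), bad = (2 * g + r + b) == 0),
    GRVI = list(v = (g - r) / (g + r),           bad = (g + r) == 0),
    VARI = list(v = (g - r) / (g + r - b),       bad = (g + r - b) == 0),
    EXG  = list(v = 2 * g - b - r,               bad = FALSE),
    NDI  = list(v = (r - g) / (r + g + 0.01),    bad = FALSE),
    stop("unknown index name: ", name))
}

#' Compute one vegetation index layer
#'
#' @param name index name from \code{\link{vi_registry}}.
#' @param rgb 3-band \code{"DN8"} \code{\link{raster_grid}}.
#' @return single-band \code{\link{raster_grid}} (units \code{"index"};
#'   raw-band indices keep \code{"DN8"}); pixels with an undefined value
#'   (zero band sum or zero denominator) are NA.
#' @export
compute_index <- function(name, rgb) {
  if (!name %in% vi_registry()) stop("unknown index name: ", name)
  stopifnot(inherits(rgb, "raster_grid"))
  if (n_bands(rgb) != 3L) stop("vegetation indices require a 3-band raster")
  if (name %in% c("R", "G", "B")) {
    b <- match(name, c("R", "G", "B"))
    return(raster_grid(band(values_na(rgb), b), rgb$transform, units = "DN8"))
  }
  ch <- normalize_chromaticity(rgb)
  f <- index_formula(name, ch$r, ch$g, ch$b)
  v <- f$v
  v[!ch$valid | f$bad] <- NA_real_
  raster_grid(v, rgb$transform, units = "index")
}

#' Plot-level index means
#'
#' Mean index value over every valid pixel of each plot (centre-point
#' rasterisation); optionally restricted to vegetation-mask pixels.  The
#' valid-pixel count is reported alongside each mean.
#'
#' @param index single-band \code{\link{raster_grid}}.
#' @param plots a \code{\link{plot_layer}} co-registered with the raster.
#' @param mask optional binary \code{\link{raster_grid}}; when given, only
#'   pixels with mask value 1 contribute.
#' @return data frame with columns \code{plot_id}, \code{mean},
#'   \code{valid_px}; plots with zero valid pixels get NA and a warning.
#' @export
plot_index_means <- function(index, plots, mask = NULL) {
  stopifnot(inherits(index, "raster_grid"), inherits(plots, "plot_layer"))
  if (!is.null(mask)) {
    if (!all(dim(mask$values)[1:2] == dim(index$values)[1:2]) ||
        max(abs(mask$transform - index$transform)) > 1e-9)
      stop("mask is not co-registered with the index raster")
  }
  v <- values_na(index)
  ids <- plots$records$plot_id
  out <- data.frame(plot_id = ids, mean = NA_real_, valid_px = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    px <- rasterize_plot(plots$polygons[[ids[i]]], index)
    if (!nrow(px)) next
    vals <- v[px]
    if (!is.null(mask)) vals <- vals[mask$values[px] == 1]
    vals <- vals[is.finite(vals)]
    out$valid_px[i] <- length(vals)
    if (length(vals)) out$mean[i] <- mean(vals)
  }
  if (any(out$valid_px == 0L))
    warning("plots with zero valid pixels: ",
            paste(out$plot_id[out$valid_px == 0L], collapse = ", "))
  out
}

#' Per-plot table of all ten vegetation indices
#'
#' Convenience wrapper running \code{\link{compute_index}} and
#' \code{\link{plot_index_means}} for the whole registry.
#'
#' @inheritParams plot_index_means
#' @param rgb 3-band DOM \code{\link{raster_grid}}.
#' @return data frame: \code{plot_id}, one column per registry index, and
#'   \code{valid_px}.
#' @export
plot_vi_table <- function(rgb, plots, mask = NULL) {
  layers <- lapply(vi_registry(), function(nm) values_na(compute_index(nm, rgb)))
  names(layers) <- vi_registry()
  ids <- plots$records$plot_id
  res <- data.frame(plot_id = ids, stringsAsFactors = FALSE)
  for (nm in vi_registry()) res[[nm]] <- NA_real_
  res$valid_px <- 0L
  for (i in seq_along(ids)) {
    px <- rasterize_plot(plots$polygons[[ids[i]]], rgb)
    if (!nrow(px)) next
    keep <- if (!is.null(mask)) mask$values[px] == 1 else TRUE
    for (nm in vi_registry()) {
      vals <- layers[[nm]][px][keep]
      vals <- vals[is.finite(vals)]
      if (length(vals)) res[[nm]][i] <- mean(vals)
      if (nm == "EXG") res$valid_px[i] <- length(vals)
    }
  }
  res
}
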
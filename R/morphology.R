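#' Maximum inter-class variance (Otsu) threshold
#'
#' Builds a 256-bin histogram over the input range and returns the cut
#' value maximising the between-class variance
#' \code{w0 w1 (mu0 - mu1)^2}; on ties the smallest maximising cut wins.
#' Classification convention: \code{value > threshold} is foreground.
#'
#' @param values numeric vector (non-finite values dropped); at least two
#'   distinct values required.
#' @return the threshold, with attributes \code{"separability"} (the
#'   normalised criterion \code{sigma_b^2 / sigma^2} at the optimum) and
#'   \code{"bin"} (the winning cut index, 1--255).
#' @export
otsu_threshold <- function(values) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L)
    stop("degenerate input: Otsu threshold needs at least 2 distinct values")
  lo <- min(v); hi <- max(v)
  breaks <- seq(lo, hi, length.out = 257L)
  idx <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), 256L)
  cnt <- tabulate(idx, nbins = 256L)
  mids <- (breaks[-257L] + breaks[-1L]) / 2
  w <- cumsum(cnt)
  m <- cumsum(cnt * mids)
  n <- w[256L]; mt <- m[256L]
  w0 <- w[1:255]; w1 <- n - w0
  mu0 <- ifelse(w0 > 0, m[1:255] / w0, 0)
  mu1 <- ifelse(w1 > 0, (mt - m[1:255]) / w1, 0)
  bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(bcv)                       # which.max returns the first tie
  thr <- breaks[k + 1L]
  tot_var <- mean((v - mean(v))^2)
  structure(thr, separability = if (tot_var > 0) bcv[k] / tot_var else 0,
            bin = k)
}

#' Segment vegetation on the UAV orthomosaic
#'
#' The excess-green index (\code{EXG = 2g - b - r}) is computed on the
#' normalised chromaticities and thresholded globally with the maximum
#' inter-class variance criterion; pixels above the threshold are
#' vegetation.  A warning flags scenes where the criterion separates the
#' histogram poorly (weak bimodality, e.g. bare soil) or the foreground is
#' nearly empty.
#'
#' @param dom 3-band \code{"DN8"} \code{\link{raster_grid}}.
#' @param min_separability separability below which the scene is flagged
#'   as weakly bimodal.
#' @return binary \code{\link{raster_grid}} with attribute
#'   \code{"threshold"}.
#' @export
segment_vegetation_uav <- function(dom, min_separability = 0.75) {
  exg <- compute_index("EXG", dom)
  v <- exg$values
  thr <- otsu_threshold(v)     # degenerate scenes propagate the error
  m <- matrix(0, nrow(v), ncol(v))
  m[which(v > thr)] <- 1
  sep <- attr(thr, "separability")
  if (sep < min_separability)
    warning(sprintf(paste0("weak bimodality (separability %.2f): the scene",
                           " may contain no vegetation/soil contrast"), sep))
  frac <- mean(m[is.finite(v)])
  if (frac < 0.01) warning("near-empty vegetation mask (foreground ",
                           sprintf("%.2f%%)", 100 * frac))
  out <- raster_grid(m, dom$transform, units = "binary")
  attr(out, "threshold") <- as.numeric(thr)
  out
}

#' RGB to Hue-Saturation-Intensity
#'
#' Geometric HSI conversion on 8-bit DN: \code{I = (R+G+B)/(3*255)},
#' \code{S = 1 - min(R,G,B)/mean(R,G,B)} (0 for black pixels), hue from
#' the arccos formulation in degrees, reflected to (180, 360) when
#' \code{B > G}.  Hue is undefined (NA) where saturation is 0.
#'
#' @param rgb 3-band \code{"DN8"} \code{\link{raster_grid}}.
#' @return list of matrices \code{hue} (degrees), \code{saturation},
#'   \code{intensity}; class \code{hsi_image}.
#' @export
rgb_to_hsi <- function(rgb) {
  stopifnot(inherits(rgb, "raster_grid"))
  if (n_bands(rgb) != 3L) stop("HSI conversion requires a 3-band raster")
  v <- values_na(rgb)
  R <- band(v, 1); G <- band(v, 2); B <- band(v, 3)
  I <- (R + G + B) / (3 * 255)
  mn <- pmin(R, G, B)
  mean_dn <- (R + G + B) / 3
  S <- ifelse(mean_dn > 0, 1 - mn / mean_dn, 0)
  num <- 0.5 * ((R - G) + (R - B))
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  ct <- ifelse(den > 0, pmin(1, pmax(-1, num / den)), NA_real_)
  hue <- acos(ct) * 180 / pi
  hue <- ifelse(B > G, 360 - hue, hue)
  hue[S == 0 | !is.finite(hue)] <- NA_real_
  structure(list(hue = hue, saturation = S, intensity = I),
            class = "hsi_image")
}

#' VCEA parameter set
#'
#' Defaults for the ground-photo vegetation-coverage extraction: green hue
#' window 60--180 degrees, saturation floor 0.1, minimum connected
#' component area 25 px (at ground-photo resolution), and the white-box
#' frame width to exclude.
#'
#' @param hue_lo,hue_hi hue window, degrees.
#' @param sat_floor minimum saturation of candidate pixels.
#' @param min_area smallest surviving component, pixels.
#' @param frame_px border width excluded from the analysis.
#' @return named list.
#' @export
vcea_params <- function(hue_lo = 60, hue_hi = 180, sat_floor = 0.1,
                        min_area = 25L, frame_px = 5L) {
  list(hue_lo = hue_lo, hue_hi = hue_hi, sat_floor = sat_floor,
       min_area = as.integer(min_area), frame_px = as.integer(frame_px))
}

#' Ground-photo vegetation mask (VCEA)
#'
#' Three-stage coverage extraction from a white-box ground photo:
#' an HSI pre-filter keeps pixels with hue in the green window and
#' saturation above the floor; the excess-green index over those
#' candidates is thresholded with the maximum inter-class variance
#' criterion (if the candidate values are all equal, all candidates are
#' kept); finally connected components smaller than the morphological
#' area threshold are removed.  The white frame border is excluded.
#'
#' @param photo 3-band \code{"DN8"} \code{\link{raster_grid}}.
#' @param params \code{\link{vcea_params}}.
#' @return binary \code{\link{raster_grid}} (frame pixels 0).
#' @export
vcea_ground_mask <- function(photo, params = vcea_params()) {
  stopifnot(inherits(photo, "raster_grid"))
  d <- dim(photo$values)
  hsi <- rgb_to_hsi(photo)
  cand <- !is.na(hsi$hue) & hsi$hue >= params$hue_lo &
    hsi$hue <= params$hue_hi & hsi$saturation >= params$sat_floor
  fp <- params$frame_px
  if (fp > 0) {
    border <- matrix(TRUE, d[1], d[2])
    border[(fp + 1):(d[1] - fp), (fp + 1):(d[2] - fp)] <- FALSE
    cand[border] <- FALSE
  }
  m <- matrix(0, d[1], d[2])
  if (!any(cand)) {
    warning("no candidate vegetation pixels in the hue window")
    return(raster_grid(m, photo$transform, units = "binary"))
  }
  ## the vegetation/soil EXG threshold is estimated on the whole frame
  ## interior (where soil keeps the histogram bimodal), then applied to the
  ## HSI candidates; thresholding inside the candidate set alone would
  ## split vegetation against itself once the hue filter has removed soil
  exg <- compute_index("EXG", photo)$values
  inner <- !logical(length(exg)); dim(inner) <- dim(exg)
  if (fp > 0) inner <- !border
  ei <- exg[inner]
  if (length(unique(ei[is.finite(ei)])) >= 2L) {
    thr <- otsu_threshold(ei)
    keep <- cand & !is.na(exg) & exg > thr
    ## degenerate case (frame interior already single-class): keep the
    ## HSI candidates unfiltered
    if (!any(keep)) keep <- cand
  } else {
    keep <- cand
  }
  m[keep] <- 1
  if (params$min_area > 1L) {
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < params$min_area)
    if (length(drop)) m[lab %in% drop] <- 0
  }
  raster_grid(m, photo$transform, units = "binary")
}

#' Canopy coverage from a mask
#'
#' \code{CC} = vegetation pixels / total valid pixels within the region.
#'
#' @param mask binary \code{\link{raster_grid}}.
#' @param region optional (row, col) index matrix (e.g. from
#'   \code{\link{rasterize_plot}}) or a polygon ring; \code{NULL} uses the
#'   whole raster.
#' @return coverage fraction in [0, 1].
#' @export
coverage_from_mask <- function(mask, region = NULL) {
  stopifnot(inherits(mask, "raster_grid"))
  v <- values_na(mask)
  if (!is.null(region)) {
    if (!(is.matrix(region) && is.integer(region)))
      region <- rasterize_plot(region, mask)
    v <- v[region]
  }
  v <- v[is.finite(v)]
  if (!length(v)) stop("zero valid pixels in region")
  mean(v == 1)
}

#' Canopy height model from DSM differencing
#'
#' \code{CHM = DSM_stage - DSM_bare}, negative differences clamped to 0
#' (they are physically meaningless and arise from DSM noise).
#'
#' @param dsm_stage,dsm_bare co-registered metre-unit
#'   \code{\link{raster_grid}}s of identical shape.
#' @return \code{\link{raster_grid}} in metres.
#' @export
canopy_height_model <- function(dsm_stage, dsm_bare) {
  stopifnot(inherits(dsm_stage, "raster_grid"), inherits(dsm_bare, "raster_grid"))
  if (!all(dim(dsm_stage$values) == dim(dsm_bare$values)))
    stop("DSM shape mismatch")
  if (max(abs(dsm_stage$transform - dsm_bare$transform)) > 1e-9)
    stop("DSM transform mismatch")
  chm <- pmax(values_na(dsm_stage) - values_na(dsm_bare), 0)
  raster_grid(chm, dsm_stage$transform, units = "m")
}

#' Plot-level plant height
#'
#' Average of the canopy height model over the vegetation-mask pixels of a
#' plot, reported in centimetres.  Falls back to the all-pixel mean (with a
#' warning) when the mask covers no plot pixel.  \code{stat = "p90"}
#' switches to the 90th percentile for sensitivity analysis.
#'
#' @param chm canopy height model (metres).
#' @param polygon plot ring in world coordinates.
#' @param mask binary vegetation \code{\link{raster_grid}} (or NULL).
#' @param stat \code{"mean"} or \code{"p90"}.
#' @return height in cm.
#' @export
plot_height <- function(chm, polygon, mask = NULL, stat = c("mean", "p90")) {
  stat <- match.arg(stat)
  stopifnot(inherits(chm, "raster_grid"))
  px <- rasterize_plot(polygon, chm)
  if (!nrow(px)) stop("empty plot: polygon covers no pixel")
  v <- values_na(chm)[px]
  if (!is.null(mask)) {
    inveg <- mask$values[px] == 1
    if (any(inveg, na.rm = TRUE)) {
      v <- v[inveg]
    } else {
      warning("vegetation mask empty within plot; using all plot pixels")
    }
  }
  v <- v[is.finite(v)]
  if (!length(v)) stop("empty plot: no valid CHM pixels")
  100 * if (stat == "mean") mean(v) else as.numeric(quantile(v, 0.9, names = FALSE))
}

#' Canopy volume
#'
#' The coverage-weighted height \code{CV = CC * H} (cm): a one-number
#' summary of canopy size in both the horizontal and vertical dimension.
#'
#' @param CC canopy coverage fraction in [0, 1].
#' @param H plant height, cm, non-negative.
#' @return canopy volume in cm.
#' @export
canopy_volume <- function(CC, H) {
  if (any(!is.finite(CC)) || any(CC < 0 | CC > 1))
    stop("CC must lie in [0, 1]")
  if (any(!is.finite(H)) || any(H < 0)) stop("H must be non-negative")
  CC * H
}

#' Per-plot morphological features from rendered or real layers
#'
#' Runs the UAV morphology chain for one stage: vegetation segmentation on
#' the DOM, CHM from DSM differencing, then per-plot H (cm), CC and
#' CV = CC * H.
#'
#' @param dom 3-band orthomosaic.
#' @param dsm_stage,dsm_bare stage and bare-soil DSMs (metres).
#' @param plots a \code{\link{plot_layer}}.
#' @param stage stage label copied into the output.
#' @param height_stat passed to \code{\link{plot_height}}.
#' @return data frame \code{plot_id, stage, H, CC, CV}.
#' @export
extract_morphology <- function(dom, dsm_stage, dsm_bare, plots,
                               stage = NA_character_,
                               height_stat = "mean") {
  mask <- segment_vegetation_uav(dom)
  chm <- canopy_height_model(dsm_stage, dsm_bare)
  ids <- plots$records$plot_id
  out <- data.frame(plot_id = ids, stage = stage, H = NA_real_,
                    CC = NA_real_, CV = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    px <- rasterize_plot(plots$polygons[[ids[i]]], dom)
    if (!nrow(px)) next
    out$CC[i] <- coverage_from_mask(mask, px)
    out$H[i] <- plot_height(chm, plots$polygons[[ids[i]]], mask,
                            stat = height_stat)
    out$CV[i] <- canopy_volume(out$CC[i], out$H[i])
  }
  out
}
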
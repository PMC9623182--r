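#' Trial design configuration
#'
#' Describes the three-zone potato trial the generator reproduces: a plant
#' density zone (3 levels x 2 varieties x 3 replicates = 18 plots), a
#' nitrogen zone (4 levels x 2 varieties x 3 replicates = 24 plots) and a
#' potassium zone (2 extra levels x 1 variety x 3 replicates = 6 plots),
#' 48 plots of 32.5 m2 in total, laid out on a regular grid with aisles.
#'
#' @param density,nitrogen,potassium per-zone lists with elements
#'   \code{codes}, \code{varieties}, \code{reps}.
#' @param plot_w,plot_h plot footprint in metres (default 6.5 x 5 = 32.5 m2).
#' @param gap aisle width between plots, metres.
#' @param layout_cols number of plot columns in the field layout.
#' @param gsd ground sampling distance of the rendered orthomosaic,
#'   metres per pixel.
#' @param seed master seed recorded with the design.
#' @return a \code{design_config} list.
#' @export
design_config <- function(
    density   = list(codes = c("T0", "T1", "T2"),
                     varieties = c("Z3", "Z5"), reps = 3L),
    nitrogen  = list(codes = c("N0", "N1", "N2", "N3"),
                     varieties = c("Z3", "Z5"), reps = 3L),
    potassium = list(codes = c("K0", "K2"),
                     varieties = "Z3", reps = 3L),
    plot_w = 6.5, plot_h = 5, gap = 1, layout_cols = 8L,
    gsd = 0.05, seed = 20190418L) {
  cfg <- list(density = density, nitrogen = nitrogen, potassium = potassium,
              plot_w = plot_w, plot_h = plot_h, gap = gap,
              layout_cols = as.integer(layout_cols), gsd = gsd,
              seed = as.integer(seed))
  class(cfg) <- "design_config"
  cfg
}

zone_grid <- function(zone, spec) {
  if (!length(spec$codes) || spec$reps < 1L) return(NULL)
  g <- expand.grid(replication = seq_len(spec$reps),
                   variety = spec$varieties, level = spec$codes,
                   stringsAsFactors = FALSE)
  data.frame(zone = zone, level = g$level, variety = g$variety,
             replication = as.integer(g$replication),
             stringsAsFactors = FALSE)
}

#' Generate the experimental design
#'
#' Lays the configured treatment structure out on a rectangular field grid
#' and returns one record and one rectangular polygon per plot.  Fully
#' deterministic: the same configuration always yields the same layer.
#'
#' @param config a \code{\link{design_config}}.
#' @return a \code{\link{plot_layer}} with attribute \code{"config"}.
#' @export
generate_design <- function(config = design_config()) {
  recs <- rbind(zone_grid("density", config$density),
                zone_grid("nitrogen", config$nitrogen),
                zone_grid("potassium", config$potassium))
  n <- nrow(recs)
  recs$plot_id <- sprintf("p%02d", seq_len(n))
  ncol_l <- config$layout_cols
  nrow_l <- ceiling(n / ncol_l)
  field_h <- nrow_l * config$plot_h + (nrow_l + 1) * config$gap
  polys <- vector("list", n); names(polys) <- recs$plot_id
  for (i in seq_len(n)) {
    r <- (i - 1) %/% ncol_l + 1
    c <- (i - 1) %% ncol_l + 1
    x0 <- config$gap + (c - 1) * (config$plot_w + config$gap)
    y1 <- field_h - (config$gap + (r - 1) * (config$plot_h + config$gap))
    y0 <- y1 - config$plot_h
    polys[[i]] <- cbind(c(x0, x0 + config$plot_w, x0 + config$plot_w, x0, x0),
                        c(y0, y0, y1, y1, y0))
  }
  out <- plot_layer(recs[, c("plot_id", "zone", "level", "variety",
                             "replication")], polys)
  attr(out, "config") <- config
  out
}

#' Per-stage calibration envelopes for the generator
#'
#' Target ranges and moments for plant height (cm), canopy coverage
#' (fraction) and plant nitrogen content (% dry mass) at the three imaged
#' growth stages of the emulated potato trial: S1 tuber formation, S2 tuber
#' growth, S3 starch accumulation.  Sampled ground truth is kept inside the
#' \code{[min, max]} envelope of its stage.
#'
#' @return data frame with columns \code{stage}, \code{var}, \code{min},
#'   \code{max}, \code{mean}, \code{sd}.
#' @export
stage_calibration <- function() {
  data.frame(
    stage = rep(c("S1", "S2", "S3"), each = 3L),
    var   = rep(c("H", "PNC", "CC"), times = 3L),
    min   = c(20.38, 2.09, 0.60,  20.42, 1.61, 0.40,  15.12, 1.86, 0.40),
    max   = c(40.50, 4.50, 0.80,  40.88, 4.00, 0.80,  40.35, 3.74, 0.80),
    mean  = c(30.29, 3.21, 0.70,  27.72, 2.69, 0.60,  25.78, 2.94, 0.58),
    sd    = c(4.76,  0.61, 0.05,  5.20,  0.58, 0.10,  5.15,  0.46, 0.10),
    stringsAsFactors = FALSE)
}

#' Stage-dependent PNC coupling defaults
#'
#' The generator ties morphology and canopy colour to plant nitrogen
#' content with stage-specific strength: the PNC -> H and PNC -> CC
#' correlation target \code{r} weakens from 0.7 at tuber formation to 0.5
#' at starch accumulation (morphology saturates late in the season), while
#' the green chromaticity of vegetation pixels rises affinely with PNC
#' (\code{g_base + g_slope * (PNC - stage mean)}).  \code{senescent_frac}
#' is the per-pixel probability of a yellowed (senescent) leaf pixel,
#' non-zero late in the season.  \code{g_plot_sd} (default 0) adds a
#' per-plot greenness offset unrelated to PNC — a nuisance channel for
#' realism experiments; the default keeps the canopy colour a pure affine
#' function of PNC so the vegetation-index signal is recoverable by
#' construction.
#'
#' @return data frame, one row per stage.
#' @export
default_coupling <- function() {
  data.frame(stage = c("S1", "S2", "S3"),
             r = c(0.70, 0.60, 0.50),
             g_base = c(0.50, 0.50, 0.48),
             g_slope = 0.035,
             g_plot_sd = 0,
             senescent_frac = c(0, 0.04, 0.12),
             stringsAsFactors = FALSE)
}

## Affine shrink of x about `centre` so every value fits [lo, hi].
## Affine maps preserve Pearson correlation exactly, so coupling targets
## survive the range enforcement.
shrink_to_range <- function(x, lo, hi, centre) {
  dev_hi <- max(x - centre, 0)
  dev_lo <- max(centre - x, 0)
  s <- min(1, if (dev_hi > 0) (hi - centre) / dev_hi else 1,
              if (dev_lo > 0) (centre - lo) / dev_lo else 1)
  centre + s * (x - centre)
}

cal_row <- function(stage, var) {
  cal <- stage_calibration()
  cal[cal$stage == stage & cal$var == var, ]
}

#' Sample per-plot ground truth for one growth stage
#'
#' Draws true PNC from treatment-level means (monotone in nitrogen level,
#' mildly decreasing in planting density) plus Gaussian plot noise, then
#' generates true plant height and canopy coverage as linear functions of
#' the standardised PNC with the stage's target correlation plus
#' independent noise.  All three variables are affinely shrunk into their
#' stage calibration envelope, which preserves the correlation structure.
#'
#' @param design a \code{\link{plot_layer}} from \code{\link{generate_design}}.
#' @param stage one of \code{"S1"}, \code{"S2"}, \code{"S3"}.
#' @param coupling data frame as \code{\link{default_coupling}}.
#' @param seed integer seed; identical seeds give identical truth.
#' @return a \code{scene_truth} object: the design, the stage, coupling
#'   parameters and a per-plot data frame of \code{true_PNC} (% dry mass),
#'   \code{true_H} (cm) and \code{true_CC} (fraction).
#' @export
sample_truth <- function(design, stage, coupling = default_coupling(),
                         seed = 20190418L) {
  stopifnot(inherits(design, "plot_layer"))
  if (!stage %in% c("S1", "S2", "S3"))
    stop("stage must be S1, S2 or S3 (use empty_truth() for bare soil)")
  cp <- coupling[coupling$stage == stage, ]
  if (nrow(cp) != 1L) stop("coupling must contain one row for stage ", stage)
  if (abs(cp$r) >= 1 + 1e-12 || cp$r <= -1)
    stop("coupling correlation must lie in (-1, 1]")
  rec <- design$records
  n <- nrow(rec)
  set.seed(as.integer(seed))

  ## treatment effects in units of the stage PNC standard deviation
  eff_n <- c(N0 = -1.00, N1 = -0.35, N2 = 0.35, N3 = 0.95)
  eff_t <- c(T0 = 0.30, T1 = 0.00, T2 = -0.30)
  eff_v <- c(Z3 = 0.10, Z5 = -0.10)
  eff <- ifelse(rec$zone == "nitrogen", eff_n[rec$level],
         ifelse(rec$zone == "density", eff_t[rec$level], 0)) +
         eff_v[rec$variety]

  cpn <- cal_row(stage, "PNC")
  pnc <- cpn$mean + cpn$sd * (eff + 0.5 * rnorm(n))
  pnc <- shrink_to_range(pnc, cpn$min, cpn$max, cpn$mean)

  zq <- if (n >= 2 && sd(pnc) > 0) as.numeric(scale(pnc)) else rep(0, n)
  r <- cp$r
  couple <- function(var) {
    cc <- cal_row(stage, var)
    x <- cc$mean + cc$sd * (r * zq + sqrt(max(0, 1 - r^2)) * rnorm(n))
    shrink_to_range(x, cc$min, cc$max, cc$mean)
  }
  truth <- data.frame(plot_id = rec$plot_id,
                      true_PNC = pnc, true_H = couple("H"),
                      true_CC = couple("CC"),
                      stringsAsFactors = FALSE)
  structure(list(stage = stage, design = design, coupling = cp,
                 plots = truth, seed = as.integer(seed)),
            class = "scene_truth")
}

#' Empty (bare-soil) truth for stage S0
#' @param design a \code{\link{plot_layer}}.
#' @return a \code{scene_truth} with no vegetation.
#' @export
empty_truth <- function(design) {
  structure(list(stage = "S0", design = design, coupling = NULL,
                 plots = data.frame(plot_id = design$records$plot_id,
                                    true_PNC = NA_real_, true_H = 0,
                                    true_CC = 0, stringsAsFactors = FALSE),
                 seed = NA_integer_),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> stage %s, %d plots\n", x$stage, nrow(x$plots)))
  invisible(x)
}

#' Renderer parameter set
#'
#' Defaults emulate a low-altitude UAV survey of the trial: 5 cm orthophoto
#' ground sampling distance, 8 DN channel jitter, 1 cm DSM noise, 20 cm
#' plant disk radius.  Soil is a brown digital-number anchor (R > G > B),
#' vegetation a green chromaticity anchor whose green share carries the
#' PNC signal; senescent pixels use a yellow anchor.
#'
#' @param gsd orthophoto resolution, m/px.
#' @param dn_jitter per-channel Gaussian DN noise SD (0 = noise-free).
#' @param dsm_noise per-pixel DSM noise SD in metres.
#' @param plant_radius_m nominal plant disk radius, metres.
#' @param radius_jitter relative radius spread (uniform +/- fraction).
#' @param soil_dn length-3 soil anchor DN.
#' @param veg_dn_sum total DN (R+G+B) of vegetation pixels.
#' @param yellow_chroma chromaticity of senescent pixels.
#' @param soil_elev base terrain elevation, metres.
#' @param weeds logical; add weed blobs in aisles and small specks inside
#'   plots (they are \emph{not} part of the truth mask).
#' @param photo_scale resolution multiplier of ground photos vs the DOM.
#' @param frame_px white-box frame width of ground photos, pixels.
#' @return named list of parameters.
#' @export
render_params <- function(gsd = 0.05, dn_jitter = 8, dsm_noise = 0.01,
                          plant_radius_m = 0.20, radius_jitter = 0.25,
                          soil_dn = c(140, 95, 75), veg_dn_sum = 270,
                          yellow_chroma = c(0.42, 0.37, 0.21),
                          soil_elev = 36, weeds = FALSE,
                          photo_scale = 4L, frame_px = 5L) {
  list(gsd = gsd, dn_jitter = dn_jitter, dsm_noise = dsm_noise,
       plant_radius_m = plant_radius_m, radius_jitter = radius_jitter,
       soil_dn = soil_dn, veg_dn_sum = veg_dn_sum,
       yellow_chroma = yellow_chroma, soil_elev = soil_elev,
       weeds = weeds, photo_scale = as.integer(photo_scale),
       frame_px = as.integer(frame_px))
}

## Smooth deterministic bare-soil surface (metres) at world (x, y).
soil_surface <- function(x, y, base) {
  base + 0.003 * x + 0.04 * sin(x / 5) + 0.04 * cos(y / 4)
}

clip_dn <- function(x) pmin(255, pmax(0, round(x)))

## Vegetation chromaticity for a plot: the green share carries the PNC
## signal plus a per-plot nuisance offset (illumination/moisture variation
## a camera sees but nitrogen does not explain).
veg_chroma <- function(pnc, stage, coupling, g_offset = 0) {
  cp <- coupling[coupling$stage == stage, ]
  g <- cp$g_base + cp$g_slope * (pnc - cal_row(stage, "PNC")$mean) + g_offset
  g <- min(0.62, max(0.40, g))
  c(0.55 * (1 - g), g, 0.45 * (1 - g))
}

## Place random disks into an nr x nc logical block until exactly n_target
## pixels are set; the last disk is trimmed (outermost pixels first) so the
## count is met exactly.  Returns the mask and the placed disk geometry.
place_disks <- function(nr, nc, n_target, rad_px, rad_jit) {
  m <- matrix(FALSE, nr, nc)
  count <- 0L
  plants <- list()
  guard <- 0L
  while (count < n_target) {
    guard <- guard + 1L
    if (guard > 1e5) stop("disk packing failed to converge")
    cx <- runif(1, 0.5, nc + 0.5)
    cy <- runif(1, 0.5, nr + 0.5)
    rad <- rad_px * runif(1, 1 - rad_jit, 1 + rad_jit)
    rows <- max(1L, floor(cy - rad)):min(nr, ceiling(cy + rad))
    cols <- max(1L, floor(cx - rad)):min(nc, ceiling(cx + rad))
    dd <- outer((rows - cy)^2, (cols - cx)^2, "+")
    sel <- which(dd <= rad^2 & !m[rows, cols, drop = FALSE], arr.ind = TRUE)
    if (!nrow(sel)) next
    need <- n_target - count
    if (nrow(sel) > need) {
      ord <- order(dd[sel])          # innermost pixels kept when trimming
      sel <- sel[ord[seq_len(need)], , drop = FALSE]
    }
    m[cbind(rows[sel[, 1]], cols[sel[, 2]])] <- TRUE
    count <- count + nrow(sel)
    plants[[length(plants) + 1L]] <- c(cx = cx, cy = cy, rad = rad)
  }
  list(mask = m, plants = do.call(rbind, plants))
}

## Integer pixel block (rows, cols) of an axis-aligned plot polygon.
plot_block <- function(polygon, grid) {
  ctr <- pixel_centres(grid)
  list(rows = which(ctr$y > min(polygon[, 2]) & ctr$y < max(polygon[, 2])),
       cols = which(ctr$x > min(polygon[, 1]) & ctr$x < max(polygon[, 1])))
}

#' Render a synthetic UAV scene
#'
#' Renders the orthomosaic (DOM), digital surface model (DSM) and the
#' renderer's own vegetation truth mask for one growth stage.  Soil pixels
#' are drawn around a brown DN anchor; plants are overlapping green disks
#' whose green chromaticity increases with the plot's true PNC; disks are
#' placed (and the last one trimmed) until the plot's vegetation pixel
#' count equals \code{round(true_CC * plot pixels)} exactly, after which
#' \code{true_CC} is back-filled from the final mask so mask and truth
#' agree to the pixel.  The DSM is a smooth bare-soil surface plus the
#' plot's true height (cm -> m) over vegetation pixels, plus optional
#' per-pixel noise.  Stage \code{"S0"} renders bare soil.
#'
#' @param truth a \code{scene_truth} (see \code{\link{sample_truth}},
#'   \code{\link{empty_truth}}).
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @param params \code{\link{render_params}}.
#' @return list with elements \code{dom}, \code{dsm}, \code{mask}
#'   (\code{\link{raster_grid}}s) and \code{truth} (back-filled, with a
#'   \code{plants} geometry table).
#' @export
render_scene <- function(truth, seed = 1L, params = render_params()) {
  stopifnot(inherits(truth, "scene_truth"))
  design <- truth$design
  cfg <- attr(design, "config")
  if (is.null(cfg)) stop("design carries no layout config")
  set.seed(as.integer(seed))

  ncol_l <- cfg$layout_cols
  nrow_l <- ceiling(nrow(design$records) / ncol_l)
  field_w <- ncol_l * cfg$plot_w + (ncol_l + 1) * cfg$gap
  field_h <- nrow_l * cfg$plot_h + (nrow_l + 1) * cfg$gap
  nc <- round(field_w / params$gsd)
  nr <- round(field_h / params$gsd)
  transform <- c(params$gsd / 2, params$gsd, field_h - params$gsd / 2,
                 -params$gsd)

  dom <- array(0, c(nr, nc, 3L))
  for (b in 1:3)
    dom[, , b] <- clip_dn(params$soil_dn[b] +
                          if (params$dn_jitter > 0)
                            rnorm(nr * nc, 0, params$dn_jitter) else 0)
  ctr <- list(x = transform[1] + (seq_len(nc) - 1) * transform[2],
              y = transform[3] + (seq_len(nr) - 1) * transform[4])
  z0 <- outer(ctr$y, ctr$x, function(y, x) soil_surface(x, y, params$soil_elev))
  dsm <- z0 + if (params$dsm_noise > 0) matrix(rnorm(nr * nc, 0, params$dsm_noise), nr, nc) else 0
  mask <- matrix(0, nr, nc)

  plants_all <- list()
  tp <- truth$plots
  if (truth$stage != "S0") {
    grid_ref <- raster_grid(mask, transform, units = "binary")
    for (i in seq_len(nrow(tp))) {
      id <- tp$plot_id[i]
      blk <- plot_block(design$polygons[[id]], grid_ref)
      bnr <- length(blk$rows); bnc <- length(blk$cols)
      npx <- bnr * bnc
      if (tp$true_CC[i] > 0.99)
        stop("infeasible packing: plot ", id, " requests CC > 0.99")
      n_target <- round(tp$true_CC[i] * npx)
      if (n_target == 0) { tp$true_CC[i] <- 0; next }
      pd <- place_disks(bnr, bnc, n_target,
                        params$plant_radius_m / params$gsd,
                        params$radius_jitter)
      sel <- which(pd$mask, arr.ind = TRUE)
      rows <- blk$rows[sel[, 1]]; cols <- blk$cols[sel[, 2]]
      nveg <- nrow(sel)

      g_off <- rnorm(1, 0, truth$coupling$g_plot_sd)
      chroma <- veg_chroma(tp$true_PNC[i], truth$stage, truth$coupling, g_off)
      sen_frac <- truth$coupling$senescent_frac
      sen <- if (sen_frac > 0) runif(nveg) < sen_frac else rep(FALSE, nveg)
      for (b in 1:3) {
        dn <- ifelse(sen, params$yellow_chroma[b], chroma[b]) *
          params$veg_dn_sum +
          if (params$dn_jitter > 0) rnorm(nveg, 0, params$dn_jitter) else 0
        dom[cbind(rows, cols, b)] <- clip_dn(dn)
      }
      dsm[cbind(rows, cols)] <- dsm[cbind(rows, cols)] + tp$true_H[i] / 100
      mask[cbind(rows, cols)] <- 1
      tp$true_CC[i] <- nveg / npx
      if (!is.null(pd$plants))
        plants_all[[id]] <- data.frame(
          plot_id = id,
          x = transform[1] + (blk$cols[1] - 1 + pd$plants[, "cx"] - 1) * params$gsd,
          y = transform[3] - (blk$rows[1] - 1 + pd$plants[, "cy"] - 1) * params$gsd,
          radius_m = pd$plants[, "rad"] * params$gsd,
          stringsAsFactors = FALSE)
    }
    if (params$weeds) {
      n_weed <- 3L * nrow_l
      for (w in seq_len(n_weed)) {
        wr <- sample.int(nr, 1); wc <- sample.int(nc, 1)
        if (mask[wr, wc] == 1) next
        rad <- 0.15 / params$gsd
        rows <- max(1L, floor(wr - rad)):min(nr, ceiling(wr + rad))
        cols <- max(1L, floor(wc - rad)):min(nc, ceiling(wc + rad))
        dd <- outer((rows - wr)^2, (cols - wc)^2, "+")
        sel <- which(dd <= rad^2, arr.ind = TRUE)
        for (b in 1:3)
          dom[cbind(rows[sel[, 1]], cols[sel[, 2]], b)] <-
            clip_dn(c(0.28, 0.50, 0.22)[b] * params$veg_dn_sum +
                    rnorm(nrow(sel), 0, max(params$dn_jitter, 1)))
      }
    }
  }

  truth$plots <- tp
  truth$plants <- if (length(plants_all)) do.call(rbind, plants_all) else NULL
  list(dom = raster_grid(dom, transform, units = "DN8"),
       dsm = raster_grid(dsm, transform, units = "m"),
       mask = raster_grid(mask, transform, units = "binary"),
       truth = truth)
}

#' Render a nadir ground photo of one plot
#'
#' Emulates the white-box ground photos used as coverage reference: a
#' 1.3 m x 1.3 m frame interior rendered with the same soil/vegetation
#' colour model as \code{\link{render_scene}} at \code{photo_scale} times
#' the orthophoto resolution, surrounded by a white frame.  Disks are
#' placed and trimmed so the interior vegetation fraction equals
#' \code{round(true_CC * interior pixels) / interior pixels}.
#'
#' @param truth a \code{scene_truth}.
#' @param plot_id plot to photograph.
#' @param seed integer seed.
#' @param params \code{\link{render_params}}.
#' @return list with \code{photo} (RGB \code{raster_grid}), \code{mask}
#'   (truth mask, frame pixels 0), \code{frame_px} and the achieved
#'   interior coverage \code{cc}.
#' @export
render_ground_photo <- function(truth, plot_id, seed = 1L,
                                params = render_params()) {
  stopifnot(inherits(truth, "scene_truth"))
  i <- match(plot_id, truth$plots$plot_id)
  if (is.na(i)) stop("unknown plot_id: ", plot_id)
  set.seed(as.integer(seed))
  gsd <- params$gsd / params$photo_scale
  side <- round(1.3 / gsd)
  fp <- params$frame_px
  full <- side + 2L * fp
  transform <- c(gsd / 2, gsd, full * gsd - gsd / 2, -gsd)

  img <- array(255, c(full, full, 3L))   # white frame
  interior <- (fp + 1L):(fp + side)
  for (b in 1:3)
    img[interior, interior, b] <-
      clip_dn(params$soil_dn[b] +
              if (params$dn_jitter > 0) rnorm(side * side, 0, params$dn_jitter) else 0)

  mask <- matrix(0, full, full)
  cc <- truth$plots$true_CC[i]
  if (cc > 0 && truth$stage != "S0") {
    if (cc > 0.99) stop("infeasible packing: CC > 0.99")
    n_target <- round(cc * side * side)
    pd <- place_disks(side, side, n_target,
                      params$plant_radius_m / gsd, params$radius_jitter)
    sel <- which(pd$mask, arr.ind = TRUE)
    rows <- interior[sel[, 1]]; cols <- interior[sel[, 2]]
    nveg <- nrow(sel)
    chroma <- veg_chroma(truth$plots$true_PNC[i], truth$stage, truth$coupling,
                         rnorm(1, 0, truth$coupling$g_plot_sd))
    sen_frac <- truth$coupling$senescent_frac
    sen <- if (sen_frac > 0) runif(nveg) < sen_frac else rep(FALSE, nveg)
    for (b in 1:3)
      img[cbind(rows, cols, b)] <-
        clip_dn(ifelse(sen, params$yellow_chroma[b], chroma[b]) *
                params$veg_dn_sum +
                if (params$dn_jitter > 0) rnorm(nveg, 0, params$dn_jitter) else 0)
    mask[cbind(rows, cols)] <- 1
    if (params$weeds) {
      ## small green specks: too small to be plants, removed by the
      ## morphological (component-area) filter downstream
      for (s in seq_len(10L)) {
        sr <- sample(interior, 1); sc <- sample(interior, 1)
        off <- rbind(c(0, 0), c(0, 1), c(1, 0), c(0, -1), c(-1, 0))
        pr <- pmin(pmax(sr + off[, 1], interior[1]), interior[side])
        pc <- pmin(pmax(sc + off[, 2], interior[1]), interior[side])
        for (b in 1:3)
          img[cbind(pr, pc, b)] <- clip_dn(c(0.28, 0.50, 0.22)[b] *
                                           params$veg_dn_sum)
      }
    }
  }
  list(photo = raster_grid(img, transform, units = "DN8"),
       mask = raster_grid(mask, transform, units = "binary"),
       frame_px = fp,
       cc = sum(mask) / (side * side))
}
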
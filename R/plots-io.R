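#' Experimental plot layer
#'
#' A plot layer couples one record per experimental plot (treatment zone,
#' level, variety, replication and any ground measurements) with its
#' polygon in world coordinates.
#'
#' @param records data frame with columns \code{plot_id}, \code{zone}
#'   (\code{density}/\code{nitrogen}/\code{potassium}), \code{level},
#'   \code{variety}, \code{replication} (1--3) and optional
#'   \code{measured_H} (cm), \code{measured_CC} (fraction in [0,1]),
#'   \code{measured_PNC} (% dry mass, positive).
#' @param polygons named list (by \code{plot_id}) of two-column vertex
#'   matrices, each a simple closed ring of positive area.
#' @return an object of class \code{plot_layer}.
#' @export
plot_layer <- function(records, polygons) {
  records <- as.data.frame(records)
  req <- c("plot_id", "zone", "level", "variety", "replication")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing required plot properties: ",
                         paste(miss, collapse = ", "))
  for (m in c("measured_H", "measured_CC", "measured_PNC"))
    if (!m %in% names(records)) records[[m]] <- NA_real_
  if (anyDuplicated(records$plot_id))
    stop("duplicate plot_id in plot layer")
  if (!all(records$zone %in% c("density", "nitrogen", "potassium")))
    stop("zone must be one of density/nitrogen/potassium")
  if (!all(records$replication %in% 1:3))
    stop("replication must be 1, 2 or 3")
  cc <- records$measured_CC
  if (any(!is.na(cc) & (cc < 0 | cc > 1)))
    stop("measured_CC must lie in [0, 1]")
  pnc <- records$measured_PNC
  if (any(!is.na(pnc) & pnc <= 0))
    stop("measured_PNC must be positive when present")
  if (!setequal(names(polygons), records$plot_id))
    stop("polygons must be named by plot_id, one per record")
  for (id in records$plot_id) {
    a <- ring_area(polygons[[id]])
    if (!is.finite(a) || a <= 0) stop("plot ", id, " has non-positive area")
  }
  structure(list(records = records, polygons = polygons[records$plot_id]),
            class = "plot_layer")
}

#' @export
print.plot_layer <- function(x, ...) {
  cat(sprintf("<plot_layer> %d plots (%s)\n", nrow(x$records),
              paste(sprintf("%s: %d", names(table(x$records$zone)),
                            table(x$records$zone)), collapse = ", ")))
  invisible(x)
}

#' Plot polygon areas in square metres
#' @param plots a \code{\link{plot_layer}}.
#' @return named numeric vector of ring areas.
#' @export
plot_areas <- function(plots) {
  vapply(plots$polygons, ring_area, numeric(1))
}

#' Write a plot layer as GeoJSON
#'
#' @param plots a \code{\link{plot_layer}}.
#' @param path output path (".geojson").
#' @return `path`, invisibly.
#' @export
write_plots <- function(plots, path) {
  stopifnot(inherits(plots, "plot_layer"))
  feats <- lapply(seq_len(nrow(plots$records)), function(i) {
    rec <- plots$records[i, ]
    ring <- as.matrix(plots$polygons[[rec$plot_id]])
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    props <- list(plot_id = rec$plot_id, zone = rec$zone, level = rec$level,
                  variety = rec$variety, replication = rec$replication)
    for (m in c("measured_H", "measured_CC", "measured_PNC"))
      if (!is.na(rec[[m]])) props[[m]] <- rec[[m]]
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a plot layer from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features with the properties
#' listed under \code{\link{plot_layer}}; all invariants (unique ids, valid
#' replication, CC in [0,1], positive PNC, simple positive-area rings) are
#' enforced on read.
#'
#' @param path GeoJSON path.
#' @return a \code{\link{plot_layer}}.
#' @export
read_plots <- function(path) {
  if (!file.exists(path)) stop("plot file not found: ", path)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("format error: not a GeoJSON FeatureCollection")
  rows <- list(); polys <- list()
  for (ft in gj$features) {
    pr <- ft$properties
    req <- c("plot_id", "zone", "level", "variety", "replication")
    miss <- setdiff(req, names(pr))
    if (length(miss)) stop("feature missing required property: ",
                           paste(miss, collapse = ", "))
    if (!identical(ft$geometry$type, "Polygon"))
      stop("format error: geometry must be Polygon")
    ring <- do.call(rbind, lapply(ft$geometry$coordinates[[1]],
                                  function(p) as.numeric(unlist(p))))
    rows[[length(rows) + 1L]] <- data.frame(
      plot_id = as.character(pr$plot_id), zone = as.character(pr$zone),
      level = as.character(pr$level), variety = as.character(pr$variety),
      replication = as.integer(pr$replication),
      measured_H = as.numeric(pr$measured_H %||% NA),
      measured_CC = as.numeric(pr$measured_CC %||% NA),
      measured_PNC = as.numeric(pr$measured_PNC %||% NA),
      stringsAsFactors = FALSE)
    polys[[as.character(pr$plot_id)]] <- ring
  }
  plot_layer(do.call(rbind, rows), polys)
}
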
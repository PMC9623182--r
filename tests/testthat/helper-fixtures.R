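# Shared fixtures and independent oracles.

# Single-plot (or few-plot) trial configuration for fast rendering tests.
mini_config <- function(codes = "T0", varieties = "Z3", reps = 1L,
                        layout_cols = 1L) {
  design_config(
    density = list(codes = codes, varieties = varieties, reps = reps),
    nitrogen = list(codes = character(0), varieties = character(0), reps = 0L),
    potassium = list(codes = character(0), varieties = character(0), reps = 0L),
    layout_cols = layout_cols)
}

# Small 3-band DN raster from explicit channel matrices.
rgb_raster <- function(R, G, B, transform = c(0.5, 1, -0.5, -1)) {
  a <- array(0, c(nrow(R), ncol(R), 3))
  a[, , 1] <- R; a[, , 2] <- G; a[, , 3] <- B
  raster_grid(a, transform, units = "DN8")
}

# Uniform-colour raster: every pixel has DN (r, g, b).
flat_rgb <- function(dn, nr = 4, nc = 4) {
  rgb_raster(matrix(dn[1], nr, nc), matrix(dn[2], nr, nc),
             matrix(dn[3], nr, nc))
}

# Ray-casting point-in-polygon, written independently of mgcv::in.out.
# Even-odd rule on the half-open ray to +x.
pip_oracle <- function(px, py, ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  n <- nrow(ring) - 1L
  inside <- FALSE
  for (k in seq_len(n)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]
    x2 <- ring[k + 1, 1]; y2 <- ring[k + 1, 2]
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

# Exhaustive pixel-centre rasterisation using the ray-casting oracle.
rasterize_oracle <- function(ring, grid) {
  d <- dim(grid$values)
  tr <- grid$transform
  hits <- NULL
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    x <- tr[1] + (c - 1) * tr[2]
    y <- tr[3] + (r - 1) * tr[4]
    if (pip_oracle(x, y, ring)) hits <- rbind(hits, c(r, c))
  }
  if (is.null(hits)) matrix(integer(), 0, 2) else hits
}

# Brute-force maximum inter-class variance threshold: same 256-bin
# histogram contract, evaluated cut by cut with naive summation.
otsu_oracle <- function(values) {
  v <- values[is.finite(values)]
  breaks <- seq(min(v), max(v), length.out = 257)
  idx <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), 256L)
  cnt <- tabulate(idx, nbins = 256)
  mids <- (breaks[-257] + breaks[-1]) / 2
  n <- length(v)
  best <- -Inf; best_k <- NA_integer_
  for (k in 1:255) {
    n0 <- sum(cnt[1:k]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(cnt[1:k] * mids[1:k]) / n0
    mu1 <- sum(cnt[(k + 1):256] * mids[(k + 1):256]) / n1
    bcv <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (bcv > best + 1e-15) { best <- bcv; best_k <- k }
  }
  breaks[best_k + 1]
}

# Two orthogonal standardised vectors -> a pair with exact sample
# correlation `rho`.
pair_with_cor <- function(n, rho, seed = 1) {
  set.seed(seed)
  z1 <- as.numeric(scale(rnorm(n)))
  e <- rnorm(n)
  e <- e - z1 * sum(e * z1) / sum(z1 * z1)
  z2 <- as.numeric(scale(e))
  list(x = z1, y = rho * z1 + sqrt(1 - rho^2) * z2)
}
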
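# Shared fixtures: everything is generated in code at test time.

# quarter-resolution geometry with the default band layout (same physical
# extents as the packaged cohort geometry, 4x fewer pixels) for fast tests
small_geometry <- function() {
  geometry_spec(image_size = c(512L, 512L), pixel_size = 1.3)
}

# one rendered animal on the small geometry (cached per session)
.small_sim_cache <- new.env()
small_sim <- function(noiseless = FALSE, seed = 7L) {
  key <- paste0("s", noiseless, seed)
  if (is.null(.small_sim_cache[[key]])) {
    map <- build_geometry(small_geometry())
    .small_sim_cache[[key]] <- list(
      map = map,
      sim = render_channels(map, effect_config(), "control", 3,
                            seed = seed, noiseless = noiseless))
  }
  .small_sim_cache[[key]]
}

# single-region geometry of ~1 mm^2 (one CA band labelled CA1_SR)
one_region_geometry <- function() {
  geometry_spec(
    image_size = c(900L, 900L), pixel_size = 1.25,
    bands = data.frame(subfield = "CA", lamina = "SR", thickness_um = 1000),
    margin_um = 60, curvature_um = 0, ca1_fraction = 0.999)
}

# paint an axis-aligned rectangle of foreground (used to plant particles of
# exact pixel area)
plant_rect <- function(img, r0, c0, h, w, value = 200) {
  img[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- value
  img
}

# independent brute-force Triangle oracle: explicit point-to-line distance,
# exhaustive over candidate bins, mirror convention as documented
triangle_oracle <- function(counts) {
  n <- length(counts)
  nz <- which(counts > 0)
  peak <- which.max(counts)
  lo <- nz[1]; hi <- nz[length(nz)]
  flip <- (peak - lo) > (hi - peak)
  if (flip) {
    counts <- rev(counts)
    peak <- n - peak + 1L
    hi <- n - lo + 1L
  }
  p1 <- c(peak, counts[peak]); p2 <- c(hi, 0)
  v <- p2 - p1
  dist_to_line <- function(b) {
    w <- c(b, counts[b]) - p1
    (v[1] * w[2] - v[2] * w[1]) / sqrt(sum(v^2))  # signed; below-line < 0
  }
  cand <- peak:hi
  d <- -vapply(cand, dist_to_line, numeric(1))
  best <- cand[which.max(d)]          # which.max takes the first tie = nearest peak
  if (flip) best <- n - best + 1L
  best - 1L
}

# random plausible histogram: background peak + optional second mode + noise
random_histogram <- function() {
  n <- 256
  x <- seq_len(n)
  h <- stats::dnorm(x, mean = stats::runif(1, 5, 80), sd = stats::runif(1, 2, 25)) *
    stats::runif(1, 1e4, 1e6)
  if (stats::runif(1) < 0.7)
    h <- h + stats::dnorm(x, mean = stats::runif(1, 100, 250),
                          sd = stats::runif(1, 2, 30)) * stats::runif(1, 1e2, 1e5)
  h <- round(h + stats::runif(n) * stats::runif(1, 0, 50))
  if (sum(h > 0) < 2) h[c(10, 200)] <- c(100, 50)
  h
}
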
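# Plaque masking and per-region burden measurement: Zack/ImageJ Triangle
# auto-threshold on a 256-bin histogram, 8-connected particle analysis with a
# strict > 10 um^2 size filter, and pixel-pooled area fractions per region.

#' Zack/ImageJ Triangle threshold of a histogram
#'
#' Locates the histogram peak, picks the longer tail (ties broken toward the
#' right tail), draws the line from (peak, peak height) to (tail end, 0) and
#' returns the bin maximizing the perpendicular distance between histogram and
#' line; among tied bins the one nearest the peak wins. When the left tail is
#' longer the histogram is flipped, scanned, and the result mirrored back.
#'
#' @param counts numeric vector of non-negative bin counts (typically 256).
#' @return 0-based threshold bin index.
#' @export
triangle_threshold <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0), length(counts) >= 2)
  nz <- which(counts > 0)
  if (length(nz) < 2) stop_config("degenerate histogram: fewer than two non-zero bins")
  n <- length(counts)
  peak <- which.max(counts)           # first max (ImageJ convention)
  lo <- nz[1]; hi <- nz[length(nz)]
  flipped <- (peak - lo) > (hi - peak)   # longer left tail -> flip
  if (flipped) {
    counts <- rev(counts)
    peak <- n - peak + 1L
    hi <- n - lo + 1L
  }
  # line from (peak, h_peak) to (hi, 0); scan bins peak..hi, strict > keeps
  # the first (nearest-the-peak) maximum
  hp <- counts[peak]
  dx <- hi - peak; dy <- hp
  nrm <- sqrt(dx^2 + dy^2)
  best <- peak; bestd <- -Inf
  for (b in peak:hi) {
    d <- (dy * (hi - b) - dx * counts[b]) / nrm  # height of chord minus histogram
    if (d > bestd) { bestd <- d; best <- b }
  }
  if (flipped) best <- n - best + 1L
  best - 1L
}

# 256-bin histogram following the ImageJ 8-bit convention: images already on
# the integer 0..255 scale are binned as-is (as ImageJ does for an 8-bit
# export); anything else is linearly rescaled to 0..255 first. Rescaling
# integer data would scatter empty gap bins through the histogram and distort
# the Triangle geometry.
hist256 <- function(channel) {
  r <- range(channel)
  if (diff(r) == 0) stop_config("degenerate histogram: channel intensity is constant")
  eightbit <- r[1] >= 0 && r[2] <= 255 && all(channel == round(channel))
  if (eightbit) {
    bins <- channel
    lo <- 0; hi <- 255
  } else {
    bins <- pmin(pmax(round((channel - r[1]) / (r[2] - r[1]) * 255), 0), 255)
    lo <- r[1]; hi <- r[2]
  }
  list(counts = tabulate(bins + 1L, nbins = 256L), min = lo, max = hi,
       bins = bins)
}

#' Build the plaque mask from an Abeta channel
#'
#' Binarizes at the Triangle threshold of the 256-bin rescaled histogram
#' (bright side is foreground), labels 8-connected particles, and discards
#' every particle whose physical area is not strictly greater than
#' `min_area_um2`. Particles touching the image border are retained.
#'
#' @param abeta 2-D intensity matrix.
#' @param pixel_size microns per pixel (> 0).
#' @param min_area_um2 strict lower area cutoff; the workflow default is 10.
#' @return `plaque_mask`: list with `mask` (logical), `particles`
#'   (data.frame id, area_um2, centroid_x/y in pixel coordinates, bounding
#'   box), `threshold` (intensity units), `threshold_bin`, `pixel_size`. An
#'   empty mask (no surviving particle) is a valid result.
#' @export
make_plaque_mask <- function(abeta, pixel_size, min_area_um2 = 10) {
  stopifnot(is.matrix(abeta), all(is.finite(abeta)), pixel_size > 0)
  hh <- hist256(abeta)
  tb <- triangle_threshold(hh$counts)
  fg <- hh$bins > tb
  lab <- label_components8(fg)
  particles <- data.frame(id = integer(), area_um2 = numeric(),
                          centroid_x = numeric(), centroid_y = numeric(),
                          xmin = integer(), xmax = integer(),
                          ymin = integer(), ymax = integer())
  mask <- matrix(FALSE, nrow(abeta), ncol(abeta))
  if (max(lab) > 0L) {
    px_counts <- tabulate(lab[lab > 0L])
    areas <- px_counts * pixel_size^2
    keep <- which(areas > min_area_um2)
    if (length(keep)) {
      idx <- which(lab > 0L)
      l <- lab[idx]
      sel <- l %in% keep
      idx <- idx[sel]; l <- l[sel]
      rr <- (idx - 1L) %% nrow(abeta) + 1L
      cc <- (idx - 1L) %/% nrow(abeta) + 1L
      mask[idx] <- TRUE
      ord <- order(l)
      l <- l[ord]; rr <- rr[ord]; cc <- cc[ord]
      particles <- data.frame(
        id = seq_along(keep),
        area_um2 = areas[keep],
        centroid_x = as.numeric(tapply(cc, l, mean)),
        centroid_y = as.numeric(tapply(rr, l, mean)),
        xmin = as.integer(tapply(cc, l, min)),
        xmax = as.integer(tapply(cc, l, max)),
        ymin = as.integer(tapply(rr, l, min)),
        ymax = as.integer(tapply(rr, l, max))
      )
    }
  }
  structure(list(mask = mask, particles = particles,
                 threshold = hh$min + tb / 255 * (hh$max - hh$min),
                 threshold_bin = tb, pixel_size = pixel_size),
            class = "plaque_mask")
}

#' Measure per-region plaque burden
#'
#' For every region of the label map (and the pixel-pooled aggregates CA1,
#' CA2/3, DG and whole hippocampus): region area, plaque area (overlap of the
#' plaque mask with the region) and the area fraction in percent. Aggregates
#' pool pixels, they never average fractions.
#'
#' @param map `lamina_map`.
#' @param mask `plaque_mask` (or a bare logical matrix of the same shape).
#' @return data.frame region / area_um2 / plaque_area_um2 / area_fraction_pct.
#' @export
measure_regions <- function(map, mask) {
  m <- if (inherits(mask, "plaque_mask")) mask$mask else mask
  if (!all(dim(m) == dim(map$labels)))
    stop_config("label map (%d x %d) and plaque mask (%d x %d) differ in shape",
                nrow(map$labels), ncol(map$labels), nrow(m), ncol(m))
  if (inherits(mask, "plaque_mask") &&
      abs(mask$pixel_size - map$pixel_size) > 1e-9)
    stop_config("label map and plaque mask disagree on pixel size")
  pxa <- map$pixel_size^2
  nb <- max(map$codes$label)
  tot <- tabulate(map$labels, nbins = nb)
  hit <- tabulate(map$labels[m], nbins = nb)
  rows <- lapply(c(map$codes$region, AGGREGATE_CODES), function(rg) {
    labs <- tryCatch(region_labels(map, rg), error = function(e) integer())
    if (!length(labs)) return(NULL)
    a <- sum(tot[labs]) * pxa
    p <- sum(hit[labs]) * pxa
    data.frame(region = rg, area_um2 = a, plaque_area_um2 = p,
               area_fraction_pct = if (a > 0) 100 * p / a else NA_real_)
  })
  do.call(rbind, rows)
}

#' Quantify one image: segmentation map + plaque mask + measurements
#'
#' @param image `mc_image` with an ABETA channel.
#' @param map `lamina_map` (e.g. from [segment_image()]).
#' @param min_area_um2 particle filter cutoff.
#' @return list(mask, measurements).
#' @export
quantify_image <- function(image, map, min_area_um2 = 10) {
  mask <- make_plaque_mask(get_channel(image, "ABETA"), image$pixel_size,
                           min_area_um2)
  list(mask = mask, measurements = measure_regions(map, mask))
}
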
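#' Hippocampal region codes
#'
#' The 11 (subfield, lamina) regions used throughout the package, in canonical
#' label order: CA1 and CA2/3 each carry SO, SP, SR, SLM; the dentate gyrus
#' carries MO, SG and the hilus (H). Region codes are strings of the form
#' `"CA1_SP"`, `"DG_MO"`, ...; the aggregate codes `"CA1"`, `"CA23"`, `"DG"`
#' and `"HIPP"` denote pixel-pooled groupings.
#'
#' @format character vector of length 11.
#' @export
REGION_CODES <- c("CA1_SO", "CA1_SP", "CA1_SR", "CA1_SLM",
                  "CA23_SO", "CA23_SP", "CA23_SR", "CA23_SLM",
                  "DG_MO", "DG_SG", "DG_H")

#' Aggregate region codes
#' @format character vector.
#' @export
AGGREGATE_CODES <- c("CA1", "CA23", "DG", "HIPP")

# laminae with cell bodies (dark in the VGLUT1-like neuropil channel)
CELL_BODY_LAMINAE <- c("SP", "SG")

#' Schematic geometry of a hippocampal section
#'
#' Describes the synthetic section as a stack of curved laminar bands: the CA
#' bands (SO, SP, SR, SLM, outer side first) on top of the DG bands (MO, SG,
#' H), mirroring the apposition of SLM and the DG molecular layer in a real
#' coronal section. CA bands are split into CA1 (left) and CA2/3 (right) at a
#' fixed fraction of the tissue width. The geometry is schematic, not
#' anatomically warped: every downstream measurement depends only on region
#' membership.
#'
#' @param image_size integer c(height, width) in pixels.
#' @param pixel_size microns per pixel.
#' @param bands data.frame with columns `subfield` ("CA" or "DG"), `lamina`,
#'   and `thickness_um`, in stacking order (top to bottom). The default is a
#'   plausible mouse-hippocampus layout.
#' @param margin_um background margin left on every side, microns.
#' @param curvature_um amplitude of the arc the bands follow, microns.
#' @param ca1_fraction fraction of the tissue width assigned to CA1.
#' @return object of class `geometry_spec`.
#' @export
geometry_spec <- function(image_size = c(1024L, 1024L),
                          pixel_size = 0.65,
                          bands = default_bands(),
                          margin_um = 55,
                          curvature_um = 10,
                          ca1_fraction = 0.55) {
  stopifnot(length(image_size) == 2L, all(image_size >= 16L), pixel_size > 0,
            margin_um >= 0, curvature_um >= 0,
            ca1_fraction > 0, ca1_fraction < 1)
  req <- c("subfield", "lamina", "thickness_um")
  if (!all(req %in% names(bands))) stop_config("bands must have columns %s",
                                               paste(req, collapse = ", "))
  if (any(bands$thickness_um <= 0))
    stop_config("band thickness must be positive (offending lamina: %s)",
                bands$lamina[which(bands$thickness_um <= 0)[1]])
  # SP / SG must be flanked by laminae of their own subfield
  for (sub in unique(bands$subfield)) {
    idx <- which(bands$subfield == sub)
    for (cb in intersect(CELL_BODY_LAMINAE, bands$lamina[idx])) {
      pos <- which(bands$lamina[idx] == cb)
      if (pos == 1L || pos == length(idx))
        stop_config("%s band of %s must be flanked by other %s laminae",
                    cb, sub, sub)
    }
  }
  height_um <- image_size[1] * pixel_size
  cum <- margin_um + cumsum(bands$thickness_um)
  over <- which(cum + margin_um + curvature_um > height_um)
  if (length(over))
    stop_config("band '%s %s' exceeds the image extent (%.0f of %.0f um used)",
                bands$subfield[over[1]], bands$lamina[over[1]],
                cum[over[1]] + margin_um + curvature_um, height_um)
  structure(list(image_size = as.integer(image_size), pixel_size = pixel_size,
                 bands = bands, margin_um = margin_um,
                 curvature_um = curvature_um, ca1_fraction = ca1_fraction),
            class = "geometry_spec")
}

#' @rdname geometry_spec
#' @export
default_bands <- function() {
  data.frame(
    subfield = c("CA", "CA", "CA", "CA", "DG", "DG", "DG"),
    lamina = c("SO", "SP", "SR", "SLM", "MO", "SG", "H"),
    thickness_um = c(60, 70, 110, 85, 90, 50, 70)
  )
}

#' CA1-only geometry for colocalization sections
#'
#' Single-subfield variant used for the interneuron-marker experiments, which
#' the source study restricted to CA1: thicker SR/SLM so the 40 um SR/SLM
#' border band has room for many somata.
#'
#' @inheritParams geometry_spec
#' @export
geometry_spec_ca1 <- function(image_size = c(768L, 1024L), pixel_size = 0.65) {
  geometry_spec(
    image_size = image_size, pixel_size = pixel_size,
    bands = data.frame(subfield = "CA",
                       lamina = c("SO", "SP", "SR", "SLM"),
                       thickness_um = c(60, 70, 140, 110)),
    ca1_fraction = 0.999, curvature_um = 8
  )
}

#' Rasterize a geometry into a lamina label map
#'
#' Every pixel is assigned to background (0) or exactly one (subfield, lamina)
#' region. CA bands are split into CA1/CA2-3 at `ca1_fraction` of the tissue
#' width; bands follow a sinusoidal arc of amplitude `curvature_um`.
#'
#' @param spec a [geometry_spec()].
#' @return a `lamina_map`: list with `labels` (integer matrix), `codes`
#'   (data.frame label/subfield/lamina/region) and `pixel_size`.
#' @export
build_geometry <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]; px <- spec$pixel_size
  xs <- (seq_len(w) - 0.5) * px            # pixel-centre x, um
  ys <- (seq_len(h) - 0.5) * px
  x0 <- spec$margin_um
  x1 <- w * px - spec$margin_um
  tfrac <- pmin(pmax((xs - x0) / (x1 - x0), 0), 1)
  offset <- spec$curvature_um * sin(pi * tfrac)

  edges <- spec$margin_um + c(0, cumsum(spec$bands$thickness_um))
  ylocal <- outer(ys, offset, "-")         # h x w
  band <- matrix(findInterval(ylocal, edges), h, w)
  band[band > nrow(spec$bands)] <- 0L
  incol <- matrix(rep(xs >= x0 & xs <= x1, each = h), h, w)
  band[!incol] <- 0L

  # map stacked band index -> region label, CA bands split by column
  has_ca <- any(spec$bands$subfield == "CA")
  xb <- x0 + spec$ca1_fraction * (x1 - x0)
  ca1col <- matrix(rep(xs < xb, each = h), h, w)
  labels <- matrix(0L, h, w)
  codes <- data.frame(label = integer(), subfield = character(),
                      lamina = character(), region = character())
  nxt <- 1L
  add_code <- function(sub, lam) {
    codes <<- rbind(codes, data.frame(label = nxt, subfield = sub,
                                      lamina = lam,
                                      region = paste(sub, lam, sep = "_")))
    nxt <<- nxt + 1L
    nxt - 1L
  }
  for (i in seq_len(nrow(spec$bands))) {
    sub <- spec$bands$subfield[i]; lam <- spec$bands$lamina[i]
    inband <- band == i
    if (sub == "CA") {
      l1 <- add_code("CA1", lam)
      labels[inband & ca1col] <- l1
      if (spec$ca1_fraction < 0.99) {
        l2 <- add_code("CA23", lam)
        labels[inband & !ca1col] <- l2
      }
    } else {
      labels[inband] <- add_code(sub, lam)
    }
  }
  new_lamina_map(labels, codes, px)
}

#' Construct a lamina map from raw parts
#' @param labels integer matrix (0 = background).
#' @param codes data.frame with columns label, subfield, lamina, region.
#' @param pixel_size microns per pixel.
#' @export
new_lamina_map <- function(labels, codes, pixel_size) {
  stopifnot(is.matrix(labels), pixel_size > 0)
  labs <- sort(unique(labels[labels > 0]))
  if (!all(labs %in% codes$label))
    stop_config("label map contains labels missing from the code table: %s",
                paste(setdiff(labs, codes$label), collapse = ", "))
  structure(list(labels = labels, codes = codes, pixel_size = pixel_size),
            class = "lamina_map")
}

#' @export
print.lamina_map <- function(x, ...) {
  cat(sprintf("<lamina_map> %d x %d px @ %.3g um/px, %d regions\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size, nrow(x$codes)))
  invisible(x)
}

# logical mask of one region (by region code) or aggregate code
region_mask <- function(map, region) {
  labs <- region_labels(map, region)
  matrix(map$labels %in% labs, nrow(map$labels), ncol(map$labels))
}

region_labels <- function(map, region) {
  cd <- map$codes
  switch(region,
         HIPP = cd$label,
         CA1 = cd$label[cd$subfield == "CA1"],
         CA23 = cd$label[cd$subfield == "CA23"],
         CA = cd$label[cd$subfield %in% c("CA", "CA1", "CA23")],
         DG = cd$label[cd$subfield == "DG"],
         {
           l <- cd$label[cd$region == region]
           if (!length(l)) stop_config("unknown region code '%s'", region)
           l
         })
}

#' Region areas of a lamina map
#'
#' @param map a `lamina_map`.
#' @return data.frame with region code and area in square microns (pixel
#'   counts times pixel area), one row per region plus the pixel-pooled
#'   aggregates CA1, CA23, DG and HIPP where present.
#' @export
region_areas <- function(map) {
  pxa <- map$pixel_size^2
  counts <- tabulate(map$labels, nbins = max(map$codes$label))
  out <- data.frame(region = map$codes$region,
                    area_um2 = counts[map$codes$label] * pxa)
  for (agg in AGGREGATE_CODES) {
    labs <- tryCatch(region_labels(map, agg), error = function(e) integer())
    if (length(labs))
      out <- rbind(out, data.frame(region = agg,
                                   area_um2 = sum(counts[labs]) * pxa))
  }
  out
}
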
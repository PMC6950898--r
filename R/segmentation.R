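# Automated replacement of the manual layer-drawing workflow: find the whole
# hippocampus and the dark SP/SG cell-body bands on the VGLUT1-like channel,
# partition the remaining tissue into laminae by signed distance bands, and
# split CA into CA1 / CA2-3 on the WFS1-like channel.

#' Segmentation parameters
#'
#' @param vglut1_threshold "otsu" for automatic thresholding of the neuropil
#'   channel, or a fixed intensity (reproduces the manual-threshold workflow).
#' @param band_threshold threshold separating the dark cell-body bands from
#'   neuropil *within* the hippocampus mask; "otsu" or fixed.
#' @param wfs1_threshold threshold on the along-band WFS1 profile; "otsu" or
#'   fixed.
#' @param min_band_area_um2 smallest connected component accepted as a
#'   cell-body band.
#' @param close_radius_um closing radius cleaning the hippocampus tissue mask
#'   (fills noise holes; the dark cell-body bands are already captured by the
#'   two-pass threshold, see [delineate_hippocampus()]).
#' @param band_close_um closing radius applied to the band masks.
#' @param srslm_fraction position of the SR-SLM boundary as a fraction of the
#'   normalized distance from SP to the far (DG or background) side. The
#'   source workflow drew this boundary by hand; here it is an explicit knob.
#' @param ca_dg_fraction position of the CA/DG (SLM-MO) boundary as a
#'   fraction of the normalized distance from SP to SG; the default matches
#'   laminar bands of typical proportions, (SR+SLM)/(SR+SLM+MO).
#' @export
seg_params <- function(vglut1_threshold = "otsu",
                       band_threshold = "otsu",
                       wfs1_threshold = "otsu",
                       min_band_area_um2 = 2000,
                       close_radius_um = 4,
                       band_close_um = 3,
                       srslm_fraction = 0.56,
                       ca_dg_fraction = 0.68) {
  stopifnot(min_band_area_um2 > 0, close_radius_um >= 0, band_close_um >= 0,
            srslm_fraction > 0, srslm_fraction < 1,
            ca_dg_fraction > 0, ca_dg_fraction < 1)
  structure(list(vglut1_threshold = vglut1_threshold,
                 band_threshold = band_threshold,
                 wfs1_threshold = wfs1_threshold,
                 min_band_area_um2 = min_band_area_um2,
                 close_radius_um = close_radius_um,
                 band_close_um = band_close_um,
                 srslm_fraction = srslm_fraction,
                 ca_dg_fraction = ca_dg_fraction),
            class = "seg_params")
}

resolve_threshold <- function(policy, values) {
  if (identical(policy, "otsu")) otsu_threshold(values) else as.numeric(policy)
}

#' Delineate the whole hippocampus on the neuropil channel
#'
#' Two-pass threshold: the first (Otsu or fixed) separates bright neuropil
#' from everything darker; a second Otsu pass restricted to the sub-threshold
#' intensities finds the floor between true background and the dark SP/SG
#' cell-body bands, so the bands belong to the tissue from the start. The
#' mask is the largest 8-connected component after a small closing, holes
#' filled. Falls back to the first threshold when the dark side is uniform
#' (e.g. noiseless backgrounds).
#'
#' @param vglut1 2-D intensity matrix.
#' @param params [seg_params()].
#' @param pixel_size microns per pixel.
#' @return logical mask.
#' @export
delineate_hippocampus <- function(vglut1, params = seg_params(), pixel_size) {
  stopifnot(is.matrix(vglut1), all(is.finite(vglut1)))
  thr1 <- resolve_threshold(params$vglut1_threshold, vglut1)
  low <- vglut1[vglut1 <= thr1]
  floor_thr <- tryCatch(otsu_threshold(low), error = function(e) thr1)
  fg <- vglut1 > floor_thr
  if (!any(fg)) stop_config("hippocampus delineation failed: no pixel above threshold %.3g", floor_thr)
  # largest raw component first (closing up front would let background noise
  # speckle percolate into the mask), then smooth and fill
  lab <- label_components8(fg)
  big <- which.max(tabulate(lab[lab > 0L]))
  mask <- close_mask(lab == big, params$close_radius_um / pixel_size)
  as.matrix(EBImage::fillHull(EBImage::Image(mask))) > 0
}

#' Segment the SP and SG cell-body bands
#'
#' The cell-body layers are the low-intensity elongated components inside the
#' hippocampus mask. The component overlapping the WFS1-positive (CA-side)
#' territory is SP, the other SG; without a usable WFS1 channel the
#' disambiguation is refused rather than guessed.
#'
#' @param vglut1 neuropil channel.
#' @param hippo_mask logical hippocampus mask.
#' @param params [seg_params()].
#' @param pixel_size microns per pixel.
#' @param wfs1 optional subfield channel used to tell SP from SG.
#' @param expect_sg set FALSE for single-subfield (CA-only) sections.
#' @return list(sp = mask, sg = mask or NULL, threshold).
#' @export
segment_cell_body_layers <- function(vglut1, hippo_mask, params = seg_params(),
                                     pixel_size, wfs1 = NULL, expect_sg = TRUE) {
  stopifnot(is.matrix(vglut1), all(is.finite(vglut1)))
  inside <- vglut1[hippo_mask]
  thr <- tryCatch(resolve_threshold(params$band_threshold, inside),
                  error = function(e) stop_config("no candidate band: %s", conditionMessage(e)))
  # search inside a slightly eroded core: the mask boundary carries a thin
  # dark fringe of background-level pixels that would bridge the bands
  cut <- params$band_close_um / pixel_size + 3
  core <- hippo_mask & dist_to(!hippo_mask) > cut
  dark <- core & vglut1 < thr
  dark <- close_mask(dark, params$band_close_um / pixel_size) & core
  lab <- label_components8(dark)
  if (max(lab) == 0L)
    stop_config("no candidate band found below threshold %.3g (histogram range %.3g-%.3g)",
                thr, min(inside), max(inside))
  sizes <- tabulate(lab[lab > 0L]) * pixel_size^2
  keep <- which(sizes >= params$min_band_area_um2)
  if (!length(keep))
    stop_config("no candidate band: all %d dark components below %.0f um^2",
                length(sizes), params$min_band_area_um2)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  n_expected <- if (expect_sg) 2L else 1L
  if (length(keep) < n_expected)
    stop_config("expected %d cell-body bands, found %d", n_expected, length(keep))
  keep <- keep[seq_len(n_expected)]
  # grow each band back through the raw dark mask so its tips reach the
  # tissue boundary the core erosion trimmed away
  raw_dark <- hippo_mask & vglut1 < thr
  extend_band <- function(band) {
    cand <- raw_dark & (dist_to(band) <= cut + 3)
    lab2 <- label_components8(cand)
    hits <- setdiff(unique(lab2[band]), 0L)
    matrix(lab2 %in% hits, nrow(band), ncol(band))
  }
  comps <- lapply(keep, function(k) extend_band(lab == k))
  if (!expect_sg)
    return(list(sp = comps[[1]], sg = NULL, threshold = thr))
  if (is.null(wfs1))
    stop_config("cannot tell SP from SG without a WFS1 channel or explicit assignment")
  mw <- vapply(comps, function(m) mean(wfs1[m]), numeric(1))
  if (max(mw) < 1.2 * min(mw))
    stop_config("ambiguous SP/SG assignment: WFS1 contrast between candidate bands is only %.2f",
                max(mw) / min(mw))
  list(sp = comps[[which.max(mw)]], sg = comps[[which.min(mw)]], threshold = thr)
}

#' Partition the hippocampus into laminae
#'
#' Pixels outside SP/SG are assigned by signed distance bands anchored on the
#' detected cell-body layers: tissue nearer SP than SG is CA, the rest DG; on
#' the CA side the component farther from SG than SP itself is SO, the other
#' is SR + SLM, split at `srslm_fraction` of the normalized distance between
#' SP and the DG (or background) side; on the DG side the component nearer CA
#' is MO, the other the hilus. If `imported` is supplied it is returned
#' verbatim (bit-faithful import path).
#'
#' @param hippo_mask logical hippocampus mask.
#' @param sp_mask,sg_mask cell-body band masks (`sg_mask` NULL for CA-only
#'   sections).
#' @param params [seg_params()].
#' @param pixel_size microns per pixel.
#' @param imported optional pre-drawn `lamina_map`, returned unchanged.
#' @return `lamina_map` with subfield "CA" undivided (see
#'   [split_subfields()]) or imported regions verbatim.
#' @export
partition_laminae <- function(hippo_mask, sp_mask, sg_mask = NULL,
                              params = seg_params(), pixel_size,
                              imported = NULL) {
  if (!is.null(imported)) {
    stopifnot(inherits(imported, "lamina_map"))
    return(imported)
  }
  if (any(sp_mask & !hippo_mask) || (!is.null(sg_mask) && any(sg_mask & !hippo_mask)))
    stop_config("cell-body band masks must lie inside the hippocampus mask")
  h <- nrow(hippo_mask); w <- ncol(hippo_mask)
  dSP <- dist_to(sp_mask)
  has_dg <- !is.null(sg_mask) && any(sg_mask)
  dSG <- if (has_dg) dist_to(sg_mask) else matrix(Inf, h, w)
  # CA/DG territory boundary at ca_dg_fraction of the SP -> SG distance (the
  # SLM-MO interface is not visible in the neuropil channel)
  ca_terr <- hippo_mask &
    (if (has_dg) dSP / (dSP + dSG) < params$ca_dg_fraction else !logical(length(dSP)))
  dg_terr <- hippo_mask & !ca_terr

  labels <- matrix(0L, h, w)
  codes <- data.frame(label = 1:7,
                      subfield = c("CA", "CA", "CA", "CA", "DG", "DG", "DG"),
                      lamina = c("SO", "SP", "SR", "SLM", "MO", "SG", "H"))
  codes$region <- paste(codes$subfield, codes$lamina, sep = "_")
  labels[sp_mask] <- 2L
  if (has_dg) labels[sg_mask] <- 6L

  # CA side: classify each non-SP component as SO (the side away from SG;
  # without a DG the thin component is SO) or SR/SLM, split by normalized
  # distance between SP and the far side
  rest <- ca_terr & !sp_mask
  if (any(rest)) {
    comp <- label_components8(rest)
    sizes <- tabulate(comp[comp > 0L])
    ref <- if (has_dg) mean(dSG[sp_mask]) else NA_real_
    dFar <- if (has_dg) dist_to(dg_terr) else dist_to(!hippo_mask)
    for (k in seq_len(max(comp))) {
      m <- comp == k
      so_side <- if (has_dg) mean(dSG[m]) > ref else k != which.max(sizes)
      if (so_side) {
        labels[m] <- 1L
      } else {
        tnorm <- dSP[m] / (dSP[m] + dFar[m])
        labels[m] <- ifelse(tnorm < params$srslm_fraction, 3L, 4L)
      }
    }
  }

  # DG side: MO is the component adjacent to CA (near SP), hilus the far one
  if (has_dg) {
    restdg <- dg_terr & !sg_mask
    if (any(restdg)) {
      comp <- label_components8(restdg)
      refdg <- mean(dSP[sg_mask])
      for (k in seq_len(max(comp))) {
        m <- comp == k
        labels[m] <- if (mean(dSP[m]) < refdg) 5L else 7L
      }
    }
  }

  expected <- if (has_dg) 1:7 else 1:4
  empty <- setdiff(expected, unique(labels[labels > 0L]))
  if (length(empty))
    warning(sprintf("empty laminae after partitioning: %s",
                    paste(codes$region[empty], collapse = ", ")))
  new_lamina_map(labels, codes, pixel_size)
}

#' Split undivided CA laminae into CA1 and CA2/3
#'
#' The along-band mean WFS1 profile (per image column, averaged over the CA
#' territory) is thresholded; the single split position minimizing
#' misclassification against a step profile defines the boundary, and the
#' WFS1-high side becomes CA1.
#'
#' @param map `lamina_map` containing undivided "CA" labels.
#' @param wfs1 subfield channel.
#' @param params [seg_params()].
#' @return `lamina_map` with CA1_*/CA23_* regions.
#' @export
split_subfields <- function(map, wfs1, params = seg_params()) {
  cd <- map$codes
  ca_lab <- cd$label[cd$subfield == "CA"]
  if (!length(ca_lab)) return(map)
  h <- nrow(map$labels); w <- ncol(map$labels)
  ca <- matrix(map$labels %in% ca_lab, h, w)
  prof <- vapply(seq_len(w), function(j) {
    v <- wfs1[ca[, j], j]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  ok <- which(!is.na(prof))
  pv <- prof[ok]
  # short running-mean smoothing of the profile
  if (length(pv) > 7) {
    sm <- as.numeric(stats::filter(pv, rep(1 / 7, 7), sides = 2))
    pv <- ifelse(is.na(sm), pv, sm)
  }
  flat <- diff(range(pv)) <= 1e-6 * (abs(mean(pv)) + 1)  # numerically constant
  thr <- if (flat) NA_real_ else
    tryCatch(resolve_threshold(params$wfs1_threshold, pv),
             error = function(e) NA_real_)
  high <- if (is.na(thr)) rep(TRUE, length(pv)) else pv > thr
  if (all(high) || !any(high)) {
    warning(sprintf("WFS1 profile uniformly %s: the whole CA assigned to %s",
                    if (all(high)) "high" else "low",
                    if (all(high)) "CA1" else "CA2/3"))
    ca1_col <- rep(all(high), w)
  } else {
    # single change point minimizing misclassification against a step, tried
    # in both orientations; b = size of the left block
    n <- length(high)
    cum <- c(0L, cumsum(high))
    nhigh <- cum[n + 1L]
    err_high_left <- vapply(0:n, function(b) (b - cum[b + 1L]) +
                              (nhigh - cum[b + 1L]), numeric(1))
    err_low_left <- vapply(0:n, function(b) cum[b + 1L] +
                             ((n - b) - (nhigh - cum[b + 1L])), numeric(1))
    side <- logical(n)   # TRUE = CA1 (WFS1-high)
    if (min(err_high_left) <= min(err_low_left)) {
      b <- which.min(err_high_left) - 1L
      side[seq_len(b)] <- TRUE
    } else {
      b <- which.min(err_low_left) - 1L
      if (b < n) side[(b + 1L):n] <- TRUE
    }
    ca1_col <- rep(FALSE, w)
    ca1_col[ok] <- side
    # extend the decided sides over the unprofiled outer columns
    first_ca1 <- side[1L]
    if (min(ok) > 1L) ca1_col[seq_len(min(ok) - 1L)] <- first_ca1
    if (max(ok) < w) ca1_col[(max(ok) + 1L):w] <- side[n]
  }

  labels <- map$labels
  newcodes <- cd[cd$subfield != "CA", ]
  nxt <- max(cd$label)
  ca1mat <- matrix(rep(ca1_col, each = h), h, w)
  for (l in ca_lab) {
    lam <- cd$lamina[cd$label == l]
    for (sub in c("CA1", "CA23")) {
      sel <- (map$labels == l) & (if (sub == "CA1") ca1mat else !ca1mat)
      if (!any(sel)) next
      nxt <- nxt + 1L
      labels[sel] <- nxt
      newcodes <- rbind(newcodes,
                        data.frame(label = nxt, subfield = sub, lamina = lam,
                                   region = paste(sub, lam, sep = "_")))
    }
  }
  new_lamina_map(labels, newcodes, map$pixel_size)
}

#' Segment a full multi-channel image into a lamina label map
#'
#' Convenience driver chaining [delineate_hippocampus()],
#' [segment_cell_body_layers()], [partition_laminae()] and
#' [split_subfields()].
#'
#' @param image `mc_image` with VGLUT1 and WFS1 channels.
#' @param params [seg_params()].
#' @param imported optional pre-drawn `lamina_map` (passed through verbatim).
#' @param expect_sg FALSE for CA-only sections.
#' @return `lamina_map`.
#' @export
segment_image <- function(image, params = seg_params(), imported = NULL,
                          expect_sg = TRUE) {
  if (!is.null(imported)) return(partition_laminae(NULL, NULL, imported = imported,
                                                   pixel_size = image$pixel_size))
  v <- get_channel(image, "VGLUT1")
  wfs1 <- get_channel(image, "WFS1")
  hip <- delineate_hippocampus(v, params, image$pixel_size)
  bands <- segment_cell_body_layers(v, hip, params, image$pixel_size,
                                    wfs1 = wfs1, expect_sg = expect_sg)
  map <- partition_laminae(hip, bands$sp, bands$sg, params, image$pixel_size)
  split_subfields(map, wfs1, params)
}
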
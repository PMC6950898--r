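# Soma detection, cross-channel cell identity, laminar assignment and
# directional colocalization percentages.

#' Detect immunopositive somata on one marker channel
#'
#' Threshold (fixed value, or Otsu), 8-connected components, keep components
#' whose physical area lies in the soma range, intensity-weighted centroids.
#'
#' @param channel 2-D intensity matrix.
#' @param pixel_size microns per pixel.
#' @param threshold numeric fixed threshold or "otsu".
#' @param soma_area_range_um2 c(min, max) accepted soma area.
#' @return list with `cells` (data.frame id, x, y, area_um2; x/y in pixel
#'   coordinates) and `labels` (integer matrix of the accepted somata). An
#'   empty result is valid.
#' @export
detect_positive_cells <- function(channel, pixel_size, threshold = "otsu",
                                  soma_area_range_um2 = c(20, 300)) {
  stopifnot(is.matrix(channel), all(is.finite(channel)), pixel_size > 0)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(channel) else
    as.numeric(threshold)
  fg <- channel > thr
  lab <- label_components8(fg)
  empty <- list(cells = data.frame(id = integer(), x = numeric(),
                                   y = numeric(), area_um2 = numeric()),
                labels = matrix(0L, nrow(channel), ncol(channel)))
  if (max(lab) == 0L) return(empty)
  areas <- tabulate(lab[lab > 0L]) * pixel_size^2
  keep <- which(areas >= soma_area_range_um2[1] & areas <= soma_area_range_um2[2])
  if (!length(keep)) return(empty)
  idx <- which(lab > 0L)
  l <- lab[idx]
  sel <- l %in% keep
  idx <- idx[sel]; l <- l[sel]
  rr <- (idx - 1L) %% nrow(channel) + 1L
  cc <- (idx - 1L) %/% nrow(channel) + 1L
  wgt <- channel[idx]
  ord <- order(l)
  l <- l[ord]; rr <- rr[ord]; cc <- cc[ord]; wgt <- wgt[ord]
  sw <- as.numeric(tapply(wgt, l, sum))
  cells <- data.frame(
    id = seq_along(keep),
    x = as.numeric(tapply(cc * wgt, l, sum)) / sw,
    y = as.numeric(tapply(rr * wgt, l, sum)) / sw,
    area_um2 = areas[keep]
  )
  out <- matrix(0L, nrow(channel), ncol(channel))
  out[idx] <- match(lab[idx], keep)   # relabel survivors 1..n
  list(cells = cells, labels = out)
}

# Pairwise Dice overlaps between two soma label images. Returns a data.frame
# (a, b, dice) for every overlapping pair.
dice_pairs <- function(labA, labB) {
  both <- labA > 0L & labB > 0L
  if (!any(both)) return(data.frame(a = integer(), b = integer(), dice = numeric()))
  ov <- table(labA[both], labB[both])
  nA <- tabulate(labA[labA > 0L])
  nB <- tabulate(labB[labB > 0L])
  df <- as.data.frame(ov, stringsAsFactors = FALSE)
  names(df) <- c("a", "b", "n")
  df <- df[df$n > 0, ]
  df$a <- as.integer(df$a); df$b <- as.integer(df$b)
  df$dice <- 2 * df$n / (nA[df$a] + nB[df$b])
  df[, c("a", "b", "dice")]
}

#' Merge per-channel detections into a cell table
#'
#' Two detections from different channels are the same cell when their soma
#' masks overlap with Dice >= `dice_min`; matching is greedy by descending
#' Dice and one-to-one per channel pair, so it is symmetric and independent of
#' cell order. Each resulting cell carries one logical positivity column per
#' marker.
#'
#' @param detections named list of [detect_positive_cells()] results, one per
#'   marker.
#' @param dice_min Dice cutoff for cross-channel identity.
#' @return data.frame: id, x, y, area_um2, one logical column per marker.
#' @export
merge_detections <- function(detections, dice_min = 0.5) {
  markers <- names(detections)
  stopifnot(length(markers) >= 1)
  ref <- NULL      # running reference: cells + label matrix
  for (m in markers) {
    det <- detections[[m]]
    k <- nrow(det$cells)
    if (is.null(ref)) {
      cells <- det$cells[, c("x", "y", "area_um2"), drop = FALSE]
      cells[[m]] <- rep(TRUE, k)
      ref <- list(cells = cells, labels = det$labels)
      next
    }
    ref$cells[[m]] <- rep(FALSE, nrow(ref$cells))
    if (k == 0) next
    pr <- dice_pairs(ref$labels, det$labels)
    pr <- pr[pr$dice >= dice_min, ]
    pr <- pr[order(-pr$dice, pr$a, pr$b), ]
    usedA <- logical(nrow(ref$cells)); usedB <- logical(k)
    for (i in seq_len(nrow(pr))) {
      a <- pr$a[i]; b <- pr$b[i]
      if (usedA[a] || usedB[b]) next
      usedA[a] <- TRUE; usedB[b] <- TRUE
      ref$cells[[m]][a] <- TRUE
    }
    newb <- which(!usedB)
    if (length(newb)) {
      add <- det$cells[newb, c("x", "y", "area_um2"), drop = FALSE]
      for (mm in setdiff(names(ref$cells), c("x", "y", "area_um2")))
        add[[mm]] <- mm == m
      base <- nrow(ref$cells)
      ref$cells <- rbind(ref$cells, add)
      # paint the new somata into the reference label image
      for (j in seq_along(newb))
        ref$labels[det$labels == newb[j]] <- base + j
    }
  }
  cells <- ref$cells
  cells <- cbind(id = seq_len(nrow(cells)), cells)
  rownames(cells) <- NULL
  cells
}

#' Assign detected cells to laminae and scopes
#'
#' The lamina is the label under the centroid pixel ("outside" off the map or
#' over background). The derived "SR/SLM" border scope collects cells whose
#' centroid lies within `border_width_um` of the SR-SLM boundary (boundary
#' pixels themselves included); remaining cells keep their lamina as scope.
#'
#' @param cells cell table (needs x, y in pixel coordinates).
#' @param map `lamina_map`.
#' @param border_width_um border scope half-width, microns.
#' @return `cells` with added `lamina` and `scope` columns.
#' @export
assign_laminae <- function(cells, map, border_width_um = 20) {
  h <- nrow(map$labels); w <- ncol(map$labels)
  r <- round(cells$y); c <- round(cells$x)
  inside <- r >= 1 & r <= h & c >= 1 & c <= w
  lam <- rep("outside", nrow(cells))
  lab <- rep(0L, nrow(cells))
  lab[inside] <- map$labels[cbind(r[inside], c[inside])]
  hit <- lab > 0L
  lam[hit] <- map$codes$lamina[match(lab[hit], map$codes$label)]
  cells$lamina <- lam

  px <- map$pixel_size
  srlabs <- map$codes$label[map$codes$lamina == "SR"]
  slmlabs <- map$codes$label[map$codes$lamina == "SLM"]
  scope <- lam
  if (length(srlabs) && length(slmlabs)) {
    sr <- matrix(map$labels %in% srlabs, h, w)
    slm <- matrix(map$labels %in% slmlabs, h, w)
    dslm <- dist_to(slm); dsr <- dist_to(sr)
    border <- (sr & dslm * px <= border_width_um) |
      (slm & dsr * px <= border_width_um)
    onb <- inside & hit
    isb <- logical(nrow(cells))
    isb[onb] <- border[cbind(r[onb], c[onb])]
    scope[isb] <- "SR/SLM"
  }
  cells$scope <- scope
  cells
}

#' Directional colocalization percentage
#'
#' Fraction of A-positive cells that are also B-positive, within a scope.
#' With no A-positive cell in scope the percentage is undefined (NA, flagged)
#' rather than zero.
#'
#' @param cells cell table with logical marker columns (and `scope` if a
#'   scope is requested).
#' @param a,b marker names (direction: share of A+ that are B+).
#' @param scope "all", a lamina code, or "SR/SLM".
#' @return data.frame a, b, scope, n_a, n_ab, pct, undefined.
#' @export
coloc_percentages <- function(cells, a, b, scope = "all") {
  for (m in c(a, b))
    if (!m %in% names(cells)) stop_config("marker '%s' not in cell table", m)
  sel <- if (identical(scope, "all")) rep(TRUE, nrow(cells)) else
    cells$scope == scope
  apos <- sel & cells[[a]]
  n_a <- sum(apos)
  n_ab <- sum(apos & cells[[b]])
  data.frame(a = a, b = b, scope = scope, n_a = n_a, n_ab = n_ab,
             pct = if (n_a > 0) 100 * n_ab / n_a else NA_real_,
             undefined = n_a == 0)
}

#' Laminar distribution of a marker-positive population
#'
#' Percentages of marker-positive cells per scope, over the configured scope
#' list; cells outside the listed scopes are dropped before normalizing, so
#' the percentages sum to 100 (up to rounding).
#'
#' @param cells cell table with `scope` and the marker column.
#' @param marker marker name.
#' @param scopes scope codes to tabulate over.
#' @return data.frame scope, n, pct (NA and flagged when no positive cell).
#' @export
laminar_distribution <- function(cells, marker,
                                 scopes = c("SO", "SP", "SR/SLM", "SR", "SLM")) {
  pos <- cells[cells[[marker]] & cells$scope %in% scopes, , drop = FALSE]
  n <- vapply(scopes, function(s) sum(pos$scope == s), numeric(1))
  tot <- sum(n)
  data.frame(scope = scopes, n = as.integer(n),
             pct = if (tot > 0) 100 * n / tot else rep(NA_real_, length(scopes)),
             undefined = tot == 0)
}

#' Detect somata on every marker channel and build the cell table
#'
#' @param image `mc_image` of marker channels.
#' @param ccfg [coloc_config()] (thresholds, soma range, border width).
#' @param map `lamina_map` for laminar assignment.
#' @param markers channels to use (default: all channels of the image).
#' @return cell table with positivity, lamina and scope columns.
#' @export
detect_cells_image <- function(image, ccfg, map, markers = NULL) {
  markers <- markers %||% names(image$channels)
  dets <- lapply(markers, function(m)
    detect_positive_cells(get_channel(image, m), image$pixel_size,
                          threshold = ccfg$threshold,
                          soma_area_range_um2 = ccfg$soma_area_range_um2))
  names(dets) <- markers
  cells <- merge_detections(dets)
  assign_laminae(cells, map, ccfg$border_width_um)
}
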
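# Synthetic interneuron maps: hard-core soma placement, per-scope marker
# joint tables, rendering of one channel per marker.

#' Marker panel used by the colocalization experiments
#' @format character vector; APP plus seven interneuron markers.
#' @export
MARKER_PANEL <- c("APP", "GABABR1", "PV", "SST", "CCK", "RELN", "CALB", "CALR")

#' Colocalization (cell-map) configuration
#'
#' Marker joint tables are parameterized per placement scope by the APP-
#' positive base rate `a` and, per marker M, the pair q = P(M | APP+) and the
#' target conditional c = P(APP+ | M). The complementary rate
#' P(M | APP-) = a q (1 - c) / (c (1 - a)) is derived so both directional
#' conditionals hold simultaneously; infeasible pairs are rejected here, at
#' load time. When c = 0 (marker never co-expressed with APP), q must be 0 and
#' `p_neg` gives P(M | APP-) directly.
#'
#' @param scopes data.frame with columns `scope`, `weight` (relative cell
#'   count) and `app_rate` (= a).
#' @param markers data.frame with columns `scope`, `marker`, `q`, `c`,
#'   `p_neg` (NA unless c is 0 or NA).
#' @param soma_radius_um soma disc radius.
#' @param min_separation_um hard-core minimum centre-to-centre distance
#'   (>= one soma diameter so discs never merge within a channel).
#' @param border_width_um half-width of the SR/SLM border scope (distance from
#'   the SR-SLM boundary on either side).
#' @param cells_per_section total somata placed per synthetic section.
#' @param threshold fixed intensity threshold for soma detection (the source
#'   workflow thresholded manually).
#' @param soma_area_range_um2 area acceptance window for detected somata.
#' @return object of class `coloc_config`.
#' @export
coloc_config <- function(scopes, markers,
                         soma_radius_um = 4,
                         min_separation_um = 10,
                         border_width_um = 20,
                         cells_per_section = 204L,
                         threshold = 90,
                         soma_area_range_um2 = c(20, 300)) {
  stopifnot(all(c("scope", "weight", "app_rate") %in% names(scopes)),
            all(c("scope", "marker", "q", "c") %in% names(markers)),
            soma_radius_um > 0,
            min_separation_um >= 2 * soma_radius_um,
            border_width_um > 0)
  if (any(scopes$app_rate <= 0 | scopes$app_rate >= 1))
    stop_config("APP base rates must lie strictly in (0, 1)")
  if (!"p_neg" %in% names(markers)) markers$p_neg <- NA_real_
  markers$p_neg_eff <- NA_real_
  for (i in seq_len(nrow(markers))) {
    a <- scopes$app_rate[match(markers$scope[i], scopes$scope)]
    q <- markers$q[i]; cc <- markers$c[i]
    if (is.na(a)) stop_config("marker row %d refers to unknown scope '%s'",
                              i, markers$scope[i])
    if (!is.na(cc) && cc == 0) {
      if (q != 0)
        stop_config("infeasible conditionals for %s in %s: P(APP|M)=0 requires P(M|APP+)=0",
                    markers$marker[i], markers$scope[i])
      markers$p_neg_eff[i] <- if (is.na(markers$p_neg[i])) 0 else markers$p_neg[i]
    } else if (is.na(cc)) {
      markers$p_neg_eff[i] <- if (is.na(markers$p_neg[i])) q else markers$p_neg[i]
    } else {
      pn <- a * q * (1 - cc) / (cc * (1 - a))
      if (pn > 1 + 1e-12)
        stop_config("infeasible conditional pair for %s in %s: derived P(M|APP-) = %.3f > 1",
                    markers$marker[i], markers$scope[i], pn)
      markers$p_neg_eff[i] <- pn
    }
  }
  structure(list(scopes = scopes, markers = markers,
                 soma_radius_um = soma_radius_um,
                 min_separation_um = min_separation_um,
                 border_width_um = border_width_um,
                 cells_per_section = as.integer(cells_per_section),
                 threshold = threshold,
                 soma_area_range_um2 = soma_area_range_um2),
            class = "coloc_config")
}

#' Packaged CA1 interneuron configuration
#'
#' Joint tables transcribed from the directional overlap percentages of the
#' reference experiment (APP with GABA_B_R1, Reelin, CCK, Calbindin,
#' Calretinin, Parvalbumin, Somatostatin in CA1), with the laminar placement
#' weights chosen so the APP-positive population splits 60 / 20 / 2 / 8 / 10
#' percent over SR-SLM border / SO / SP / SR interior / SLM interior.
#'
#' @return a [coloc_config()].
#' @export
coloc_config_fig1 <- function() {
  scopes <- data.frame(
    scope = c("SR/SLM", "SO", "SP", "SR", "SLM"),
    # weight = APP+ share / app_rate, so APP+ cells split 60/20/2/8/10
    weight = c(0.60 / 0.5, 0.20 / 0.25, 0.02 / 0.10, 0.08 / 0.15, 0.10 / 0.15),
    app_rate = c(0.50, 0.25, 0.10, 0.15, 0.15)
  )
  mk <- function(scope, marker, q, c, p_neg = NA_real_)
    data.frame(scope = scope, marker = marker, q = q, c = c, p_neg = p_neg)
  srslm <- function(scope, g_c)
    rbind(mk(scope, "GABABR1", 1.00, g_c),
          mk(scope, "RELN", 0.47, 0.35),
          mk(scope, "CCK", 0.32, 0.95),
          mk(scope, "CALB", 0.27, 0.61),
          mk(scope, "CALR", 0.00, 0.00, 0.10),
          mk(scope, "PV", 0.05, 0.30),
          mk(scope, "SST", 0.03, 0.15))
  markers <- rbind(
    srslm("SR/SLM", 0.97),
    srslm("SR", 0.90),
    srslm("SLM", 0.90),
    rbind(mk("SO", "GABABR1", 1.00, 0.70),
          mk("SO", "PV", 0.41, 0.53),
          mk("SO", "SST", 0.05, 0.08),
          mk("SO", "RELN", 0.10, 0.30),
          mk("SO", "CCK", 0.32, 0.95),
          mk("SO", "CALB", 0.10, 0.50),
          mk("SO", "CALR", 0.00, 0.00, 0.05)),
    rbind(mk("SP", "GABABR1", 1.00, 0.80),
          mk("SP", "PV", 0.30, 0.50),
          mk("SP", "SST", 0.05, 0.20),
          mk("SP", "RELN", 0.05, 0.30),
          mk("SP", "CCK", 0.32, 0.95),
          mk("SP", "CALB", 0.05, 0.50),
          mk("SP", "CALR", 0.00, 0.00, 0.05))
  )
  coloc_config(scopes, markers)
}

# Scope rasters on a CA1 lamina map: the SR/SLM border band (within
# border_width_um of the SR-SLM boundary) plus SO, SP and the SR/SLM
# interiors. Returns a named list of logical masks.
scope_masks <- function(map, border_width_um) {
  px <- map$pixel_size
  sr <- region_mask(map, grep("_SR$", map$codes$region, value = TRUE)[1])
  slm <- region_mask(map, grep("_SLM$", map$codes$region, value = TRUE)[1])
  border <- (sr & dist_to(slm) * px <= border_width_um) |
    (slm & dist_to(sr) * px <= border_width_um)
  list("SR/SLM" = border,
       "SO" = region_mask(map, grep("_SO$", map$codes$region, value = TRUE)[1]),
       "SP" = region_mask(map, grep("_SP$", map$codes$region, value = TRUE)[1]),
       "SR" = sr & !border,
       "SLM" = slm & !border)
}

# Hard-core (dart-throwing) placement of n points over the TRUE pixels of
# `mask`, at least min_sep_um from every previously accepted point (across
# scopes). `occupied` is a running list(x, y) in um shared between calls.
place_hardcore <- function(mask, n, px, min_sep_um, occupied, max_tries = 200L) {
  idx <- which(mask)
  if (!length(idx) && n > 0)
    stop_config("scope raster is empty; cannot place cells")
  h <- nrow(mask)
  cell <- min_sep_um
  gx <- occupied$x; gy <- occupied$y
  grid <- new.env(parent = emptyenv())
  gkey <- function(x, y) paste(floor(x / cell), floor(y / cell))
  for (i in seq_along(gx)) {
    k <- gkey(gx[i], gy[i])
    grid[[k]] <- c(grid[[k]], i)
  }
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  while (placed < n) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      p <- idx[sample.int(length(idx), 1L)]
      x <- (((p - 1L) %/% h) + stats::runif(1)) * px
      y <- (((p - 1L) %% h) + stats::runif(1)) * px
      clash <- FALSE
      for (dx in -1:1) for (dy in -1:1) {
        k <- paste(floor(x / cell) + dx, floor(y / cell) + dy)
        for (j in grid[[k]])
          if ((gx[j] - x)^2 + (gy[j] - y)^2 < min_sep_um^2) { clash <- TRUE; break }
        if (clash) break
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok)
      stop_config("could not satisfy the hard-core constraint after %d tries; reduce the cell density or the minimum separation", max_tries)
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y
    gx <- c(gx, x); gy <- c(gy, y)
    k <- gkey(x, y)
    grid[[k]] <- c(grid[[k]], length(gx))
  }
  list(x = xs, y = ys, all_x = gx, all_y = gy)
}

#' Sample an interneuron map and render the marker channels
#'
#' Somata are placed scope-by-scope by a hard-core point process; each cell's
#' APP status is Bernoulli(scope APP rate) and each marker is drawn from the
#' scope's joint table conditioned on APP status. Every positive marker is
#' rendered as a soma-sized disc in that marker's channel.
#'
#' @param map CA1 lamina_map (e.g. from [geometry_spec_ca1()]).
#' @param ccfg a [coloc_config()].
#' @param cfg an [effect_config()] (noise block only).
#' @param seed integer seed for this section.
#' @param noiseless if TRUE skip the noise model.
#' @return list with `image` (mc_image, one channel per marker) and `cells`
#'   (ground-truth table: id, x_um, y_um, scope, one logical column per
#'   marker).
#' @export
sample_cells <- function(map, ccfg, cfg = effect_config(), seed = 1L,
                         noiseless = FALSE) {
  stopifnot(inherits(ccfg, "coloc_config"))
  set.seed(seed)
  px <- map$pixel_size
  masks <- scope_masks(map, ccfg$border_width_um)
  sc <- ccfg$scopes
  n_scope <- round(ccfg$cells_per_section * sc$weight / sum(sc$weight))
  occupied <- list(x = numeric(), y = numeric())
  rows <- vector("list", nrow(sc))
  for (i in seq_len(nrow(sc))) {
    msk <- masks[[sc$scope[i]]]
    if (is.null(msk)) stop_config("no raster for scope '%s'", sc$scope[i])
    pl <- place_hardcore(msk, n_scope[i], px, ccfg$min_separation_um, occupied)
    occupied <- list(x = pl$all_x, y = pl$all_y)
    if (n_scope[i] == 0L) next
    app <- stats::runif(n_scope[i]) < sc$app_rate[i]
    df <- data.frame(x_um = pl$x, y_um = pl$y, scope = sc$scope[i], APP = app)
    mrk <- ccfg$markers[ccfg$markers$scope == sc$scope[i], ]
    for (m in setdiff(MARKER_PANEL, "APP")) {
      row <- mrk[mrk$marker == m, ]
      if (nrow(row) == 0) { df[[m]] <- FALSE; next }
      p <- ifelse(app, row$q, row$p_neg_eff)
      df[[m]] <- stats::runif(n_scope[i]) < p
    }
    rows[[i]] <- df
  }
  cells <- do.call(rbind, rows)
  cells <- cbind(id = seq_len(nrow(cells)), cells)
  rownames(cells) <- NULL

  nz <- cfg$noise
  h <- nrow(map$labels); w <- ncol(map$labels)
  chans <- stats::setNames(vector("list", length(MARKER_PANEL)), MARKER_PANEL)
  for (m in MARKER_PANEL) {
    img <- matrix(nz$background, h, w)
    pos <- which(cells[[m]])
    if (length(pos))
      img <- render_discs(img, cells$x_um[pos], cells$y_um[pos],
                          rep(ccfg$soma_radius_um, length(pos)), px,
                          nz$soma_peak)$img
    if (!noiseless)
      img <- apply_noise(img, nz, derive_seed(seed, 40L + match(m, MARKER_PANEL)))
    chans[[m]] <- img
  }
  list(image = new_mc_image(chans, px), cells = cells)
}
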
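# Synthetic cohort generator: plaque fields, staining channels, noise.
#
# The generator plants known ground truth (region geometry, per-region plaque
# density and size, per-animal variability, ELISA-style concentrations) so
# that every downstream stage can be validated by parameter recovery.

#' Effect configuration for a synthetic two-arm cohort
#'
#' Declarative description of the generative model: per-region baseline plaque
#' densities, multiplicative cKO density ratios, a log-normal plaque radius
#' distribution, age scaling, ELISA means, and the noise model. Densities are
#' plaques per square millimetre of region at the reference age (3 months).
#'
#' @param baseline_density named numeric, region code -> plaques/mm^2.
#' @param cko_density_ratio named numeric in \[0, 1\], region code ->
#'   multiplicative density factor in the conditional-knockout arm.
#' @param radius_meanlog,radius_sdlog log-normal parameters of the plaque
#'   radius in microns. The defaults put ~17% of plaques below the 10 um^2
#'   particle cutoff so the size filter is genuinely exercised.
#' @param age_scaling named numeric, months -> global density multiplier.
#' @param animal_cv coefficient of variation of the per-animal log-normal
#'   density multiplier (mouse-to-mouse variability).
#' @param elisa list(control_mean, reduction, cv): soluble Abeta42 in pg/mg,
#'   planted fractional reduction in the cKO arm, per-animal CV.
#' @param noise list of rendering intensities (8-bit scale) and noise terms:
#'   `background`, `vglut1_neuropil`, `vglut1_band` (dark SP/SG bands;
#'   neuropil:band contrast >= 3:1 holds for the defaults), `wfs1_high`
#'   (over CA1), `wfs1_low`, `plaque_peak`, `soma_peak`, `read_sigma`
#'   (additive Gaussian sd) and `shot_coef` (sd contribution
#'   `shot_coef * sqrt(intensity)`, a Gaussian stand-in for shot noise).
#' @return object of class `effect_config`.
#' @export
effect_config <- function(baseline_density = default_densities(),
                          cko_density_ratio = NULL,
                          radius_meanlog = log(2.6),
                          radius_sdlog = 0.4,
                          age_scaling = c("2" = 0.3, "3" = 1, "4" = 1.9, "6" = 3.2),
                          animal_cv = 0.15,
                          elisa = list(control_mean = 50, reduction = 0.17, cv = 0.10),
                          noise = default_noise()) {
  if (is.null(cko_density_ratio))
    cko_density_ratio <- stats::setNames(rep(1, length(baseline_density)),
                                         names(baseline_density))
  unknown <- setdiff(c(names(baseline_density), names(cko_density_ratio)),
                     REGION_CODES)
  if (length(unknown))
    stop_config("unknown region code in config: %s", paste(unknown, collapse = ", "))
  if (any(baseline_density < 0)) stop_config("densities must be >= 0")
  if (any(cko_density_ratio < 0 | cko_density_ratio > 1))
    stop_config("cko density ratios must lie in [0, 1]")
  if (any(unlist(age_scaling) < 0)) stop_config("age scaling must be >= 0")
  stopifnot(radius_sdlog > 0, animal_cv >= 0, elisa$cv > 0,
            elisa$control_mean > 0, elisa$reduction >= 0, elisa$reduction <= 1)
  structure(list(baseline_density = baseline_density,
                 cko_density_ratio = cko_density_ratio,
                 radius_meanlog = radius_meanlog, radius_sdlog = radius_sdlog,
                 age_scaling = age_scaling, animal_cv = animal_cv,
                 elisa = elisa, noise = noise),
            class = "effect_config")
}

#' @rdname effect_config
#' @export
default_densities <- function() {
  c(CA1_SO = 2900, CA1_SP = 2800, CA1_SR = 2000, CA1_SLM = 3600,
    CA23_SO = 1500, CA23_SP = 1100, CA23_SR = 1500, CA23_SLM = 2400,
    DG_MO = 900, DG_SG = 500, DG_H = 650)
}

#' @rdname effect_config
#' @export
default_noise <- function() {
  # background sits well above the 8-bit clip so read noise stays symmetric
  list(background = 25, vglut1_neuropil = 140, vglut1_band = 45,
       wfs1_high = 130, wfs1_low = 35, plaque_peak = 180, soma_peak = 180,
       read_sigma = 6, shot_coef = 0.6)
}

# density multiplier for one arm/region vector
arm_density <- function(cfg, arm, age_months) {
  am <- as.character(age_months)
  age_mult <- if (am %in% names(cfg$age_scaling)) cfg$age_scaling[[am]] else 1
  d <- cfg$baseline_density * age_mult
  if (arm == "cko") d <- d * cfg$cko_density_ratio[names(cfg$baseline_density)]
  d
}

#' Sample a plaque field over a lamina map
#'
#' Plaques are a Poisson process per region: counts ~ Poisson(area x density x
#' age scaling x animal multiplier), centres uniform over the region's pixels,
#' radii log-normal. For the cKO arm either the densities are thinned directly
#' (`paired_with = NULL`) or an existing control field is binomially thinned
#' per region (common-random-number pairing).
#'
#' @param map lamina_map.
#' @param cfg effect_config.
#' @param arm "control" or "cko".
#' @param age_months age of the simulated animal.
#' @param animal_mult per-animal density multiplier (log-normal, drawn by the
#'   cohort driver; both arms of a matched pair share it).
#' @param seed integer seed for this field.
#' @param paired_with optional control plaque table to thin instead of
#'   sampling fresh (used when `arm = "cko"` and the cohort is paired).
#' @return data.frame x_um, y_um, r_um, area_um2, region.
#' @export
sample_plaques <- function(map, cfg, arm = "control", age_months = 3,
                           animal_mult = 1, seed = 1L, paired_with = NULL) {
  stopifnot(inherits(map, "lamina_map"), inherits(cfg, "effect_config"))
  set.seed(seed)
  if (!is.null(paired_with)) {
    stopifnot(arm == "cko")
    ratio <- cfg$cko_density_ratio[paired_with$region]
    keep <- stats::runif(nrow(paired_with)) < ratio
    return(paired_with[keep, , drop = FALSE])
  }
  dens <- arm_density(cfg, arm, age_months) * animal_mult
  px <- map$pixel_size
  out <- vector("list", length(dens))
  h <- nrow(map$labels)
  for (i in seq_along(dens)) {
    region <- names(dens)[i]
    labs <- region_labels(map, region)
    idx <- which(map$labels %in% labs)
    if (!length(idx)) next
    area_mm2 <- length(idx) * px^2 / 1e6
    n <- stats::rpois(1L, area_mm2 * dens[i])
    if (n == 0L) next
    pick <- idx[sample.int(length(idx), n, replace = TRUE)]
    r0 <- (pick - 1L) %% h + 1L
    c0 <- (pick - 1L) %/% h + 1L
    x <- (c0 - stats::runif(n)) * px
    y <- (r0 - stats::runif(n)) * px
    r <- stats::rlnorm(n, cfg$radius_meanlog, cfg$radius_sdlog)
    out[[i]] <- data.frame(x_um = x, y_um = y, r_um = r,
                           area_um2 = pi * r^2, region = region)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(x_um = numeric(), y_um = numeric(), r_um = numeric(),
                      area_um2 = numeric(), region = character())
  rownames(res) <- NULL
  res
}

# Paint discs into an intensity matrix (saturating at `peak`), and optionally
# into a logical hit raster. Returns list(img, hits).
render_discs <- function(img, x_um, y_um, r_um, px, peak, hits = NULL) {
  h <- nrow(img); w <- ncol(img)
  track <- !is.null(hits)
  for (k in seq_along(x_um)) {
    r_px <- r_um[k] / px
    cc <- x_um[k] / px + 0.5   # pixel-centre coordinates (pixel i centre = i - 0.5)
    rr <- y_um[k] / px + 0.5
    c_lo <- max(1L, floor(cc - r_px)); c_hi <- min(w, ceiling(cc + r_px))
    r_lo <- max(1L, floor(rr - r_px)); r_hi <- min(h, ceiling(rr + r_px))
    if (c_lo > c_hi || r_lo > r_hi) next
    rs <- r_lo:r_hi; cs <- c_lo:c_hi
    d2 <- outer((rs - rr)^2, (cs - cc)^2, "+")
    inside <- d2 <= r_px^2
    if (!any(inside)) next
    sub <- img[rs, cs, drop = FALSE]
    sub[inside] <- pmax(sub[inside], peak)
    img[rs, cs] <- sub
    if (track) {
      hsub <- hits[rs, cs, drop = FALSE]
      hsub[inside] <- TRUE
      hits[rs, cs] <- hsub
    }
  }
  list(img = img, hits = hits)
}

# Additive Gaussian read noise plus intensity-scaled Gaussian shot noise,
# quantized to 8-bit (the study exported 8-bit TIFFs).
apply_noise <- function(img, noise, seed) {
  set.seed(seed)
  sd_px <- sqrt(noise$read_sigma^2 + noise$shot_coef^2 * pmax(img, 0))
  out <- img + stats::rnorm(length(img)) * sd_px
  matrix(as.numeric(pmin(pmax(round(out), 0), 255)), nrow(img), ncol(img))
}

#' Render the staining channels of one synthetic animal
#'
#' Produces the three structural channels the quantification workflow needs:
#' a VGLUT1-like neuropil channel (bright neuropil, dark SP/SG cell-body
#' bands), a WFS1-like channel elevated only over CA1, and an Abeta/6E10-like
#' channel carrying the plaque field; plus the full ground truth.
#'
#' @inheritParams sample_plaques
#' @param noiseless if TRUE skip the noise model (used by oracle tests).
#' @return list with `image` (class `mc_image`: named channel list +
#'   pixel_size) and `truth` (lamina map, plaque table, per-region planted
#'   plaque pixel area before noise).
#' @export
render_channels <- function(map, cfg, arm = "control", age_months = 3,
                            animal_mult = 1, seed = 1L, paired_with = NULL,
                            noiseless = FALSE) {
  nz <- cfg$noise
  h <- nrow(map$labels); w <- ncol(map$labels)
  hipp <- map$labels > 0L
  bandlab <- map$codes$label[map$codes$lamina %in% CELL_BODY_LAMINAE]
  dark <- matrix(map$labels %in% bandlab, h, w)

  vglut1 <- matrix(nz$background, h, w)
  vglut1[hipp] <- nz$vglut1_neuropil
  vglut1[dark] <- nz$vglut1_band

  wfs1 <- matrix(nz$background, h, w)
  wfs1[hipp] <- nz$wfs1_low
  ca1lab <- map$codes$label[map$codes$subfield == "CA1"]
  if (length(ca1lab)) wfs1[matrix(map$labels %in% ca1lab, h, w)] <- nz$wfs1_high

  plq <- sample_plaques(map, cfg, arm, age_months, animal_mult,
                        seed = derive_seed(seed, 11L), paired_with = paired_with)
  abeta <- matrix(nz$background, h, w)
  hit <- matrix(FALSE, h, w)
  rd <- render_discs(abeta, plq$x_um, plq$y_um, plq$r_um, map$pixel_size,
                     nz$plaque_peak, hits = hit)
  abeta <- rd$img; hit <- rd$hits

  planted <- tabulate(map$labels[hit], nbins = max(map$codes$label))
  planted_area <- data.frame(region = map$codes$region,
                             planted_area_um2 = planted[map$codes$label] *
                               map$pixel_size^2)

  chans <- list(VGLUT1 = vglut1, WFS1 = wfs1, ABETA = abeta)
  if (!noiseless)
    chans <- lapply(seq_along(chans), function(i)
      apply_noise(chans[[i]], nz, derive_seed(seed, 20L + i)))
  names(chans) <- c("VGLUT1", "WFS1", "ABETA")

  list(image = new_mc_image(chans, map$pixel_size),
       truth = list(map = map, plaques = plq, planted_area = planted_area,
                    arm = arm, age_months = age_months,
                    animal_mult = animal_mult, seed = seed))
}

#' Multi-channel image container
#' @param channels named list of equally sized numeric matrices.
#' @param pixel_size microns per pixel.
#' @export
new_mc_image <- function(channels, pixel_size) {
  stopifnot(is.list(channels), length(names(channels)) == length(channels),
            pixel_size > 0)
  dims <- vapply(channels, dim, integer(2))
  if (length(channels) > 1 && any(dims != dims[, 1]))
    stop_config("all channels must share the same dimensions")
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "mc_image")
}

#' Extract a channel by name
#' @param image an `mc_image`.
#' @param name channel name.
#' @export
get_channel <- function(image, name) {
  if (!name %in% names(image$channels))
    stop_config("channel '%s' not found; available: %s", name,
                paste(names(image$channels), collapse = ", "))
  image$channels[[name]]
}

#' Sample per-animal ELISA-style Abeta42 concentrations
#'
#' Values are log-normal with the configured arm mean and CV; the cKO mean is
#' the control mean times (1 - planted reduction).
#'
#' @param cfg effect_config (uses the `elisa` block).
#' @param arm "control" or "cko".
#' @param n_animals number of animals (>= 2).
#' @param seed integer seed.
#' @return numeric vector of concentrations (pg/mg).
#' @export
sample_elisa <- function(cfg, arm = "control", n_animals = 12L, seed = 1L) {
  stopifnot(inherits(cfg, "effect_config"), n_animals >= 2L)
  m <- cfg$elisa$control_mean
  if (arm == "cko") m <- m * (1 - cfg$elisa$reduction)
  cv <- cfg$elisa$cv
  sdlog <- sqrt(log(1 + cv^2))
  set.seed(seed)
  stats::rlnorm(n_animals, log(m) - sdlog^2 / 2, sdlog)
}
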
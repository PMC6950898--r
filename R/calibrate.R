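# Calibration of per-lamina cKO density ratios.
#
# Whole-hippocampus and subfield-aggregate reductions are emergent: they are
# area- and density-weighted mixtures of the per-lamina ratios, further
# blurred by plaques whose footprint straddles a lamina boundary (pixel-wise
# attribution) and by overlap between plaques. The calibration therefore
# works on the *expected measured coverage*:
#
#   mu(p) = sum_regions density_r * (indicator_r (x) survival kernel)(p)
#   P(p covered) = 1 - exp(-mu(p))        (Boolean disc model)
#
# where the survival kernel K(d) = P(plaque radius > d) is evaluated by FFT
# convolution. Per-lamina ratios are then solved (damped Newton on the 5x5
# system) so that the expected measured aggregate reductions equal the
# targets. Deterministic; cached per session.

.calib_cache <- new.env(parent = emptyenv())

# expected coverage field per ratio group (unit animal multiplier)
coverage_fields <- function(map, cfg, groups) {
  h <- nrow(map$labels); w <- ncol(map$labels); px <- map$pixel_size
  # survival kernel on the pixel grid, wrapped for circular convolution
  ri <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1)) * px
  ci <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1)) * px
  d <- sqrt(outer(ri^2, ci^2, "+"))
  kern <- 1 - stats::plnorm(d, cfg$radius_meanlog, cfg$radius_sdlog)
  fk <- stats::fft(kern)
  lapply(groups, function(regions) {
    lam <- matrix(0, h, w)
    for (rg in regions) {
      labs <- region_labels(map, rg)
      lam[map$labels %in% labs] <- cfg$baseline_density[rg] * px^2 / 1e6
    }
    f <- Re(stats::fft(stats::fft(lam) * fk, inverse = TRUE)) / (h * w)
    pmax(f, 0)
  })
}

#' Calibrate cKO density ratios to target aggregate reductions
#'
#' Solves for the per-lamina density ratios of the conditional-knockout arm so
#' that the *expected measured* percent reductions (pixel-pooled area
#' fractions, boundary spill and plaque overlap included) equal the requested
#' targets: SP of CA1, the CA1 aggregate, the whole hippocampus, MO, and the
#' DG aggregate. Laminae within a tied group share one ratio: \{CA1 SO, SR,
#' SLM\}, \{all CA2/3 laminae\} and \{SG, H\} are each tied, SP of CA1 and MO
#' are free.
#'
#' @param map lamina_map of the cohort geometry.
#' @param cfg effect_config carrying baseline densities and the radius
#'   distribution.
#' @param targets named numeric of fractional reductions, names `SP_CA1`,
#'   `CA1`, `HIPP`, `MO`, `DG`.
#' @return named numeric of ratios over all 11 region codes.
#' @export
calibrate_ratios <- function(map, cfg,
                             targets = c(SP_CA1 = 0.75, CA1 = 0.24,
                                         HIPP = 0.31, MO = 0.50, DG = 0.50)) {
  key <- paste(c(dim(map$labels), map$pixel_size, cfg$baseline_density,
                 cfg$radius_meanlog, cfg$radius_sdlog, targets), collapse = "|")
  hit <- .calib_cache[[digest_key(key)]]
  if (!is.null(hit)) return(hit)

  groups <- list(SP_CA1 = "CA1_SP",
                 CA1_other = c("CA1_SO", "CA1_SR", "CA1_SLM"),
                 CA23 = c("CA23_SO", "CA23_SP", "CA23_SR", "CA23_SLM"),
                 MO = "DG_MO",
                 DG_other = c("DG_SG", "DG_H"))
  G <- coverage_fields(map, cfg, groups)
  aggs <- list(SP_CA1 = region_mask(map, "CA1_SP"),
               CA1 = region_mask(map, "CA1"),
               HIPP = region_mask(map, "HIPP"),
               MO = region_mask(map, "DG_MO"),
               DG = region_mask(map, "DG"))
  mu0 <- Reduce(`+`, G)
  ctrl <- vapply(aggs, function(m) sum(1 - exp(-mu0[m])), numeric(1))

  resid <- function(rho) {
    mu <- rho[1] * G[[1]] + rho[2] * G[[2]] + rho[3] * G[[3]] +
      rho[4] * G[[4]] + rho[5] * G[[5]]
    cko <- vapply(aggs, function(m) sum(1 - exp(-mu[m])), numeric(1))
    (1 - cko / ctrl) - targets[names(aggs)]
  }

  # linear (no-overlap) start: M %*% rho = (1 - target) * ctrl_linear
  M <- sapply(seq_along(G), function(g)
    vapply(aggs, function(m) sum(G[[g]][m]), numeric(1)))
  rho <- as.numeric(solve(M, (1 - targets[names(aggs)]) * rowSums(M)))
  for (iter in 1:8) {
    r0 <- resid(rho)
    if (max(abs(r0)) < 1e-6) break
    J <- matrix(0, 5, 5)
    for (g in 1:5) {
      dr <- rho; dr[g] <- dr[g] + 1e-4
      J[, g] <- (resid(dr) - r0) / 1e-4
    }
    rho <- rho - as.numeric(solve(J, r0))
    rho <- pmin(pmax(rho, 0), 1)
  }
  out <- stats::setNames(numeric(length(REGION_CODES)), REGION_CODES)
  for (g in names(groups)) out[groups[[g]]] <- rho[match(g, names(groups))]
  .calib_cache[[digest_key(key)]] <- out
  out
}

digest_key <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}
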
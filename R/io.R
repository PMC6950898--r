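# Formats and orchestration: multi-channel TIFF with sidecar metadata, label
# maps, polygon region import, YAML run configuration, end-to-end pipeline.
#
# Channel names and pixel size travel in a plain-text sidecar ("<image>.meta")
# because baseline TIFF tags round-trip unreliably across writers; a config
# override always wins.

meta_path <- function(path) paste0(path, ".meta")

#' Write a multi-channel image as multi-page 8-bit TIFF
#'
#' @param image `mc_image` (intensities on the 0..255 scale).
#' @param path output file; a `<path>.meta` sidecar records channel names and
#'   pixel size.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "mc_image"))
  pages <- lapply(image$channels, function(ch) pmin(pmax(ch, 0), 255) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "LZW")
  writeLines(c(sprintf("pixel_size_um=%.10g", image$pixel_size),
               sprintf("channels=%s", paste(names(image$channels), collapse = ","))),
             meta_path(path))
  invisible(path)
}

#' Read a multi-channel TIFF
#'
#' Channels are resolved by name from the sidecar metadata or from the
#' `channels` argument (required when no sidecar exists); same for the pixel
#' size.
#'
#' @param path TIFF file.
#' @param channels optional channel-name override (config order).
#' @param pixel_size optional pixel-size override, microns per pixel.
#' @return `mc_image` on the 0..255 intensity scale.
#' @export
read_image <- function(path, channels = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop_config("image file '%s' does not exist", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # tolerate grey-written-as-RGB
    round(p * 255)
  })
  meta <- list()
  if (file.exists(meta_path(path))) {
    kv <- strsplit(readLines(meta_path(path)), "=", fixed = TRUE)
    meta <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  }
  nm <- channels %||% (if (!is.null(meta$channels))
    strsplit(meta$channels, ",", fixed = TRUE)[[1]] else NULL)
  if (is.null(nm))
    stop_config("no channel names for '%s': supply `channels` or a sidecar", path)
  if (length(nm) != length(pages))
    stop_config("'%s' has %d pages but %d channel names (%s)", path,
                length(pages), length(nm), paste(nm, collapse = ", "))
  ps <- pixel_size %||% (if (!is.null(meta$pixel_size_um))
    as.numeric(meta$pixel_size_um) else NULL)
  if (is.null(ps) || !is.finite(ps))
    stop_config("no pixel size for '%s': supply `pixel_size` or a sidecar", path)
  new_mc_image(stats::setNames(pages, nm), ps)
}

#' Write a lamina label map (label TIFF + code-table CSV)
#' @param map `lamina_map`.
#' @param path output TIFF; codes go to `<path>.codes.csv`, pixel size to the
#'   sidecar.
#' @export
write_label_map <- function(map, path) {
  tiff::writeTIFF(map$labels / 65535, path, bits.per.sample = 16L)
  utils::write.csv(map$codes, paste0(path, ".codes.csv"), row.names = FALSE)
  writeLines(sprintf("pixel_size_um=%.10g", map$pixel_size), meta_path(path))
  invisible(path)
}

#' Read a lamina label map written by [write_label_map()]
#' @param path label TIFF.
#' @param pixel_size override, microns per pixel.
#' @export
read_label_map <- function(path, pixel_size = NULL) {
  labs <- round(tiff::readTIFF(path) * 65535)
  storage.mode(labs) <- "integer"
  codes <- utils::read.csv(paste0(path, ".codes.csv"), stringsAsFactors = FALSE)
  ps <- pixel_size
  if (is.null(ps) && file.exists(meta_path(path))) {
    kv <- strsplit(readLines(meta_path(path)), "=", fixed = TRUE)
    meta <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
    ps <- as.numeric(meta$pixel_size_um)
  }
  if (is.null(ps) || !is.finite(ps))
    stop_config("no pixel size for label map '%s'", path)
  new_lamina_map(labs, codes, ps)
}

#' Import regions from a polygon file
#'
#' JSON file: list of objects with `region`, `subfield`, `lamina` and `xy`
#' (flat \[x1, y1, x2, y2, ...\] polygon in pixel coordinates, 0-based,
#' row-major raster convention). A pixel belongs to a polygon if its centre is
#' inside under the even-odd rule.
#'
#' @param path JSON polygon file.
#' @param dim image dimensions c(rows, cols).
#' @param pixel_size microns per pixel.
#' @return `lamina_map`.
#' @export
read_polygon_regions <- function(path, dim, pixel_size) {
  polys <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- matrix(0L, dim[1], dim[2])
  codes <- data.frame(label = integer(), subfield = character(),
                      lamina = character(), region = character())
  # pixel centres, 0-based convention: pixel (i, j) centre at (j + 0.5, i + 0.5)
  cx <- rep(seq_len(dim[2]) - 0.5, each = dim[1])
  cy <- rep(seq_len(dim[1]) - 0.5, times = dim[2])
  for (i in seq_len(nrow(polys))) {
    xy <- matrix(unlist(polys$xy[i]), ncol = 2, byrow = TRUE)
    inside <- point_in_polygon(cx, cy, xy[, 1], xy[, 2])
    labels[inside] <- i
    codes <- rbind(codes, data.frame(label = i, subfield = polys$subfield[i],
                                     lamina = polys$lamina[i],
                                     region = polys$region[i]))
  }
  new_lamina_map(labels, codes, pixel_size)
}

# even-odd ray-casting test, vectorized over query points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read and validate a run configuration (YAML)
#'
#' Single structured file driving the whole experiment; unknown keys are
#' rejected before any computation.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("seed", "out_dir", "n_per_arm", "age_months", "paired",
               "pixel_size", "image_size", "min_area_um2", "segmentation",
               "elisa_n", "overwrite")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop_config("unknown config keys: %s", paste(unknown, collapse = ", "))
  seg_allowed <- c("vglut1_threshold", "band_threshold", "wfs1_threshold",
                   "min_band_area_um2", "close_radius_um", "band_close_um",
                   "srslm_fraction")
  if (!is.null(cfg$segmentation)) {
    bad <- setdiff(names(cfg$segmentation), seg_allowed)
    if (length(bad))
      stop_config("unknown segmentation keys: %s", paste(bad, collapse = ", "))
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$n_per_arm <- as.integer(cfg$n_per_arm %||% 8L)
  cfg
}

#' Run the full pipeline from a configuration
#'
#' simulate -> segment -> quantify -> stats, writing every table as CSV under
#' the output directory plus a manifest with the configuration hash and seed.
#' Reruns with the same configuration are bit-identical on tables.
#'
#' @param config path to a YAML config or a list from [read_run_config()].
#' @param out_dir output directory (overrides the config's).
#' @return list of result tables (invisibly also written to disk).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  out <- out_dir %||% cfg$out_dir %||% stop_config("no output directory configured")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  geom <- geometry_spec(
    image_size = cfg$image_size %||% c(1024L, 1024L),
    pixel_size = cfg$pixel_size %||% 0.65)
  cc <- cohort_config_fig3(geom)
  cc$n_per_arm <- cfg$n_per_arm
  if (!is.null(cfg$paired)) cc$paired <- cfg$paired
  sp <- do.call(seg_params, cfg$segmentation %||% list())

  res <- withCallingHandlers(
    run_recovery_experiment(cc, seed = cfg$seed, params = sp),
    error = function(e) stop_config("pipeline stage 'segment/quantify' failed: %s",
                                    conditionMessage(e)))
  eln <- as.integer(cfg$elisa_n %||% 12L)
  elisa <- data.frame(
    arm = rep(c("control", "cko"), each = eln),
    abeta42 = c(sample_elisa(cc$cfg, "control", eln, derive_seed(cfg$seed, 901L)),
                sample_elisa(cc$cfg, "cko", eln, derive_seed(cfg$seed, 902L))))
  elred <- percent_reduction(elisa$abeta42[elisa$arm == "control"],
                             elisa$abeta42[elisa$arm == "cko"])
  eltt <- t_test_arms(elisa$abeta42[elisa$arm == "control"],
                      elisa$abeta42[elisa$arm == "cko"])

  utils::write.csv(res$measurements, file.path(out, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(res$reductions, file.path(out, "reductions.csv"),
                   row.names = FALSE)
  utils::write.csv(res$anova, file.path(out, "anova.csv"), row.names = FALSE)
  utils::write.csv(cbind(elred, t = eltt$statistic, p = eltt$p_value),
                   file.path(out, "elisa.csv"), row.names = FALSE)

  cfg_file <- file.path(out, "config.yaml")
  yaml::write_yaml(cfg, cfg_file)
  writeLines(c(sprintf("seed=%d", cfg$seed),
               sprintf("config_md5=%s", unname(tools::md5sum(cfg_file))),
               sprintf("package_version=%s",
                       as.character(utils::packageVersion("laminaq")))),
             file.path(out, "manifest.txt"))
  invisible(list(measurements = res$measurements, reductions = res$reductions,
                 anova = res$anova, elisa = elisa,
                 elisa_reduction = elred, elisa_test = eltt))
}
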
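# Cohort-level drivers: packaged study configurations, in-memory cohort
# generation, on-disk bundles, and the end-to-end recovery experiment.

#' Packaged two-arm (control vs GABAergic-BACE1-cKO) cohort configuration
#'
#' Baseline densities follow the reference laminar pattern (CA1 enriched, SLM
#' the highest CA lamina, DG relatively spared); the cKO density ratios are
#' calibrated with [calibrate_ratios()] so the expected measured aggregate
#' reductions are 31% (hippocampus), 24% (CA1), 75% (SP of CA1), 50% (MO) and
#' 50% (DG). Arms are matched pairs by common random numbers.
#'
#' @param geometry [geometry_spec()] of the cohort sections.
#' @return list: geometry, map, cfg (effect_config with calibrated ratios),
#'   n_per_arm, age_months, paired.
#' @export
cohort_config_fig3 <- function(geometry = geometry_spec()) {
  map <- build_geometry(geometry)
  cfg <- effect_config()
  cfg$cko_density_ratio <- calibrate_ratios(map, cfg)
  list(geometry = geometry, map = map, cfg = cfg, n_per_arm = 8L,
       age_months = 3, paired = TRUE,
       planted = c(HIPP = 31, CA1 = 24, CA1_SP = 75, DG = 50, DG_MO = 50))
}

#' Packaged time-course cohort configuration (2/3/4/6 months, one arm)
#' @inheritParams cohort_config_fig3
#' @export
cohort_config_fig2 <- function(geometry = geometry_spec()) {
  list(geometry = geometry, map = build_geometry(geometry),
       cfg = effect_config(), n_per_age = 5L, ages = c(2, 3, 4, 6))
}

#' Simulate one animal: channels + ground truth
#'
#' @param cc cohort config (e.g. [cohort_config_fig3()]).
#' @param arm "control" or "cko".
#' @param index animal index within the arm.
#' @param seed master seed of the cohort.
#' @param age_months age (defaults to the config's).
#' @return [render_channels()] result.
#' @export
simulate_animal <- function(cc, arm, index, seed, age_months = NULL) {
  age <- age_months %||% cc$age_months
  aseed <- derive_seed(seed, index)
  sdlog <- sqrt(log(1 + cc$cfg$animal_cv^2))
  set.seed(derive_seed(aseed, 1L))
  mult <- stats::rlnorm(1, -sdlog^2 / 2, sdlog)
  paired <- isTRUE(cc$paired)
  if (arm == "cko" && paired) {
    ctrl <- sample_plaques(cc$map, cc$cfg, "control", age, mult,
                           seed = derive_seed(aseed, 11L))
    render_channels(cc$map, cc$cfg, "cko", age, mult,
                    seed = derive_seed(aseed, 2L), paired_with = ctrl)
  } else {
    base <- if (arm == "control") aseed else derive_seed(aseed, 7L)
    if (arm == "cko") {  # unpaired cKO: independent stream and multiplier
      set.seed(derive_seed(base, 1L))
      mult <- stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    }
    render_channels(cc$map, cc$cfg, arm, age, mult, seed = base)
  }
}

#' Run the full recovery experiment: simulate, segment, quantify, reduce
#'
#' Generates both arms of the packaged two-arm cohort, runs the measurement
#' pipeline (hippocampus delineation, SP/SG segmentation, laminar
#' partitioning, subfield split, Triangle plaque mask, per-region
#' measurement) on every animal, and assembles the per-region reduction and
#' ANOVA tables.
#'
#' @param cc cohort config from [cohort_config_fig3()].
#' @param seed master seed.
#' @param params [seg_params()].
#' @param use_truth_map use the generator's label map instead of segmenting
#'   (isolates measurement from segmentation in diagnostics).
#' @return list: measurements (animal table incl. aggregates), reductions,
#'   anova, seg_quality (per-animal hippocampus Jaccard vs truth).
#' @export
run_recovery_experiment <- function(cc, seed = 1L, params = seg_params(),
                                    use_truth_map = FALSE) {
  rows <- list(); jc <- c()
  for (arm in c("control", "cko")) {
    for (i in seq_len(cc$n_per_arm)) {
      sim <- simulate_animal(cc, arm, i, seed)
      map <- if (use_truth_map) cc$map else segment_image(sim$image, params)
      q <- quantify_image(sim$image, map)
      m <- q$measurements
      m$animal <- paste0(arm, "_", i)
      m$arm <- arm
      rows[[length(rows) + 1L]] <- m
      jc <- c(jc, jaccard(map$labels > 0, cc$map$labels > 0))
    }
  }
  meas <- do.call(rbind, rows)
  meas <- meas[, c("animal", "arm", "region", "area_um2", "plaque_area_um2",
                   "area_fraction_pct")]
  red <- reduction_table(meas)
  lam <- meas[meas$region %in% REGION_CODES, ]
  list(measurements = meas, reductions = red,
       anova = two_way_anova(lam), seg_quality = jc)
}

#' Generate an on-disk cohort bundle
#'
#' One multi-page TIFF (+ sidecar metadata) per animal plus ground-truth CSV
#' tables (regions, plaque particles, ELISA values) and a plain-text manifest
#' listing every file with the seed that produced it. Deterministic given the
#' master seed.
#'
#' @param cc cohort config.
#' @param out_dir output directory.
#' @param seed master seed.
#' @param overwrite allow writing into an existing bundle directory.
#' @return invisibly, the manifest path.
#' @export
generate_cohort <- function(cc, out_dir, seed = 1L, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop_config("output directory '%s' already contains a bundle; use overwrite = TRUE",
                out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(sprintf("master_seed=%d", seed),
                sprintf("package_version=%s",
                        as.character(utils::packageVersion("laminaq"))))
  truth_rows <- list(); plq_rows <- list()
  for (arm in c("control", "cko")) {
    for (i in seq_len(cc$n_per_arm)) {
      sim <- simulate_animal(cc, arm, i, seed)
      id <- sprintf("%s_%02d", arm, i)
      f <- file.path(out_dir, paste0(id, ".tif"))
      write_image(sim$image, f)
      manifest <- c(manifest, sprintf("image=%s seed=%d arm=%s",
                                      basename(f), derive_seed(seed, i), arm))
      ta <- sim$truth$planted_area
      ta$animal <- id; ta$arm <- arm
      truth_rows[[id]] <- ta
      if (nrow(sim$truth$plaques)) {
        tp <- sim$truth$plaques
        tp$animal <- id
        plq_rows[[id]] <- tp
      }
    }
  }
  utils::write.csv(do.call(rbind, truth_rows),
                   file.path(out_dir, "truth_regions.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, plq_rows),
                   file.path(out_dir, "truth_particles.csv"), row.names = FALSE)
  el <- rbind(
    data.frame(arm = "control",
               abeta42 = sample_elisa(cc$cfg, "control", 12L, derive_seed(seed, 901L))),
    data.frame(arm = "cko",
               abeta42 = sample_elisa(cc$cfg, "cko", 12L, derive_seed(seed, 902L))))
  utils::write.csv(el, file.path(out_dir, "truth_elisa.csv"), row.names = FALSE)
  write_label_map(cc$map, file.path(out_dir, "truth_labels.tif"))
  mf <- file.path(out_dir, "manifest.txt")
  writeLines(manifest, mf)
  invisible(mf)
}

#' Pooled colocalization cohort: simulate sections until enough APP+ cells
#'
#' Renders CA1 sections from the packaged interneuron configuration, runs
#' detection + laminar assignment on each, and pools the recovered cell
#' tables (the reference analysis pools cells across sections and animals).
#'
#' @param n_app_min stop once at least this many APP+ cells are recovered.
#' @param ccfg [coloc_config()].
#' @param seed master seed.
#' @param max_sections hard cap on the number of sections.
#' @param use_truth return the generator's truth tables instead of running
#'   detection (for generator-level tests).
#' @return list: cells (pooled recovered table), truth (pooled ground truth),
#'   n_sections.
#' @export
coloc_cohort <- function(n_app_min = 1000L, ccfg = coloc_config_fig1(),
                         seed = 1L, max_sections = 40L, use_truth = FALSE) {
  map <- build_geometry(geometry_spec_ca1())
  cfg <- effect_config()
  pooled <- list(); truth <- list()
  napp <- 0L; k <- 0L
  while (napp < n_app_min && k < max_sections) {
    k <- k + 1L
    sim <- sample_cells(map, ccfg, cfg, seed = derive_seed(seed, 500L + k))
    tr <- sim$cells
    tr$section <- k
    truth[[k]] <- tr
    if (use_truth) {
      cells <- tr
      cells$scope_truth <- cells$scope
      cells <- assign_truth_scope(cells, map, ccfg$border_width_um)
    } else {
      cells <- detect_cells_image(sim$image, ccfg, map)
    }
    cells$section <- k
    pooled[[k]] <- cells
    napp <- napp + sum(cells$APP)
  }
  cells <- do.call(rbind, pooled)
  cells$id <- seq_len(nrow(cells))
  list(cells = cells, truth = do.call(rbind, truth), n_sections = k)
}

# scope of ground-truth cells from their true coordinates (um)
assign_truth_scope <- function(cells, map, border_width_um) {
  px <- map$pixel_size
  tmp <- cells
  tmp$x <- cells$x_um / px + 0.5
  tmp$y <- cells$y_um / px + 0.5
  assign_laminae(tmp, map, border_width_um)
}
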
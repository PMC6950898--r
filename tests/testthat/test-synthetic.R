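test_that("plaque counts follow the configured Poisson density", {
  map <- build_geometry(one_region_geometry())
  cfg <- effect_config(baseline_density = c(CA1_SR = 50),
                       cko_density_ratio = c(CA1_SR = 1))
  area_mm2 <- region_areas(map)$area_um2[1] / 1e6
  counts <- vapply(1:200, function(s)
    nrow(sample_plaques(map, cfg, seed = s)), numeric(1))
  expected <- 50 * area_mm2
  se <- sqrt(expected / 200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("paired cKO thinning keeps the configured fraction of plaques", {
  map <- build_geometry(one_region_geometry())
  cfg <- effect_config(baseline_density = c(CA1_SR = 120),
                       cko_density_ratio = c(CA1_SR = 0.25))
  kept <- total <- 0
  for (s in 1:60) {
    ctl <- sample_plaques(map, cfg, "control", seed = s)
    cko <- sample_plaques(map, cfg, "cko", seed = s + 1000, paired_with = ctl)
    kept <- kept + nrow(cko); total <- total + nrow(ctl)
  }
  se <- sqrt(0.25 * 0.75 / total)
  expect_lt(abs(kept / total - 0.25), 3 * se)
})

test_that("a null cKO arm reproduces the control plaque field exactly", {
  map <- build_geometry(small_geometry())
  cfg <- effect_config()   # all ratios default to 1
  ctl <- sample_plaques(map, cfg, "control", seed = 5)
  cko <- sample_plaques(map, cfg, "cko", seed = 99, paired_with = ctl)
  expect_identical(cko, ctl)
})

test_that("rendering is deterministic in the seed and varies across seeds", {
  map <- build_geometry(small_geometry())
  cfg <- effect_config()
  a <- render_channels(map, cfg, seed = 3)
  b <- render_channels(map, cfg, seed = 3)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$plaques, b$truth$plaques)
  c <- render_channels(map, cfg, seed = 4)
  expect_false(identical(a$truth$plaques, c$truth$plaques))
})

test_that("planted per-region area equals the rendered pre-noise footprint", {
  fx <- small_sim(noiseless = TRUE)
  ab <- get_channel(fx$sim$image, "ABETA")
  hit <- ab > effect_config()$noise$background
  nb <- max(fx$map$codes$label)
  by_region <- tabulate(fx$map$labels[hit], nbins = nb) * fx$map$pixel_size^2
  expect_equal(fx$sim$truth$planted_area$planted_area_um2,
               by_region[fx$map$codes$label])
})

test_that("noiseless neuropil-to-band contrast meets the 3:1 floor", {
  fx <- small_sim(noiseless = TRUE)
  v <- get_channel(fx$sim$image, "VGLUT1")
  sp <- fx$map$labels == fx$map$codes$label[fx$map$codes$region == "CA1_SP"]
  sr <- fx$map$labels == fx$map$codes$label[fx$map$codes$region == "CA1_SR"]
  expect_gte(mean(v[sr]) / mean(v[sp]), 3)
  # WFS1 elevated only over CA1
  w <- get_channel(fx$sim$image, "WFS1")
  ca1 <- laminaq:::region_mask(fx$map, "CA1")
  ca23 <- laminaq:::region_mask(fx$map, "CA23")
  expect_gt(mean(w[ca1]), 2 * mean(w[ca23]))
})

test_that("unknown region codes in the effect config are rejected", {
  expect_error(effect_config(baseline_density = c(CA9_XX = 10)), "unknown region")
  expect_error(effect_config(cko_density_ratio = c(CA1_SP = 1.2)), "\\[0, 1\\]")
})

test_that("ELISA sampling matches the configured means and reduction", {
  cfg <- effect_config(elisa = list(control_mean = 80, reduction = 0, cv = 0.1))
  m <- replicate(200, mean(sample_elisa(cfg, "control", 12,
                                        sample.int(1e6, 1))))
  expect_lt(abs(mean(m) - 80), 3 * 80 * 0.1 / sqrt(200 * 12))
  # cv -> 0 degenerates to the configured mean
  cfg0 <- effect_config(elisa = list(control_mean = 80, reduction = 0.17, cv = 1e-6))
  expect_equal(mean(sample_elisa(cfg0, "cko", 5, 1)), 80 * 0.83, tolerance = 1e-4)
})

test_that("marker joint sampling matches the configured conditionals", {
  map <- build_geometry(geometry_spec_ca1(image_size = c(384L, 512L),
                                          pixel_size = 1.3))
  ccfg <- coloc_config_fig1()
  pooled <- list()
  for (s in 1:6)
    pooled[[s]] <- sample_cells(map, ccfg, seed = s, noiseless = TRUE)$cells
  cells <- do.call(rbind, pooled)
  border <- cells[cells$scope == "SR/SLM", ]
  # forced co-expression holds exactly
  expect_true(all(border$GABABR1[border$APP]))
  # planted conditional 0.47 within 3 binomial SE at this n
  n_app <- sum(border$APP)
  p_hat <- mean(border$RELN[border$APP])
  expect_lt(abs(p_hat - 0.47), 3 * sqrt(0.47 * 0.53 / n_app))
  # empirical max deviation shrinks roughly as n^(-1/2): compare quarter
  # sample vs full sample deviation from the planted table
  dev <- function(d) abs(mean(d$RELN[d$APP]) - 0.47)
  quarter <- border[seq_len(nrow(border) %/% 4), ]
  expect_lt(dev(border), dev(quarter) + 3 * sqrt(0.25 / n_app))
})

test_that("infeasible conditional pairs are rejected at load time", {
  sc <- data.frame(scope = "SO", weight = 1, app_rate = 0.9)
  mk <- data.frame(scope = "SO", marker = "PV", q = 1.0, c = 0.1,
                   p_neg = NA_real_)
  expect_error(coloc_config(sc, mk), "infeasible")
  mk2 <- data.frame(scope = "SO", marker = "CALR", q = 0.2, c = 0,
                    p_neg = 0.1)
  expect_error(coloc_config(sc, mk2), "infeasible")
})

test_that("hard-core placement respects the minimum separation", {
  map <- build_geometry(geometry_spec_ca1(image_size = c(384L, 512L),
                                          pixel_size = 1.3))
  ccfg <- coloc_config_fig1()
  cells <- sample_cells(map, ccfg, seed = 2, noiseless = TRUE)$cells
  d <- as.matrix(stats::dist(cells[, c("x_um", "y_um")]))
  diag(d) <- Inf
  expect_gte(min(d), ccfg$min_separation_um)
})

test_that("cohort bundles are deterministic and refuse accidental overwrite", {
  cc <- cohort_config_fig3(small_geometry())
  cc$n_per_arm <- 1L
  d1 <- tempfile(); d2 <- tempfile()
  generate_cohort(cc, d1, seed = 11)
  generate_cohort(cc, d2, seed = 11)
  expect_identical(readLines(file.path(d1, "truth_regions.csv")),
                   readLines(file.path(d2, "truth_regions.csv")))
  expect_identical(unname(tools::md5sum(file.path(d1, "control_01.tif"))),
                   unname(tools::md5sum(file.path(d2, "control_01.tif"))))
  expect_error(generate_cohort(cc, d1, seed = 12), "overwrite")
  d3 <- tempfile()
  generate_cohort(cc, d3, seed = 12)
  expect_false(identical(readLines(file.path(d1, "truth_particles.csv")),
                         readLines(file.path(d3, "truth_particles.csv"))))
  expect_length(dir(d1, pattern = "\\.tif$"), 3)  # 2 animals + label map
  unlink(c(d1, d2, d3), recursive = TRUE)
})
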
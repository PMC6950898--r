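# fixture: one CA1 section with rendered marker channels (cached)
.coloc_fix <- new.env()
coloc_fix <- function(noiseless = FALSE) {
  key <- paste0("k", noiseless)
  if (is.null(.coloc_fix[[key]])) {
    map <- build_geometry(geometry_spec_ca1(image_size = c(384L, 512L),
                                            pixel_size = 1.3))
    sim <- sample_cells(map, coloc_config_fig1(), seed = 31,
                        noiseless = noiseless)
    .coloc_fix[[key]] <- list(map = map, sim = sim)
  }
  .coloc_fix[[key]]
}

test_that("noiseless detection recovers every planted soma exactly", {
  # full-resolution section: the hard-core separation guarantees pixelized
  # discs never touch at this pixel size
  map <- build_geometry(geometry_spec_ca1())
  ccfg <- coloc_config_fig1()
  sim <- sample_cells(map, ccfg, seed = 31, noiseless = TRUE)
  app <- get_channel(sim$image, "APP")
  det <- detect_positive_cells(app, map$pixel_size, ccfg$threshold,
                               ccfg$soma_area_range_um2)
  expect_identical(nrow(det$cells), sum(sim$cells$APP))
  blank <- matrix(5, 64, 64)
  det0 <- detect_positive_cells(blank + 0.01 * matrix(rnorm(64^2), 64), 1,
                                threshold = 90)
  expect_identical(nrow(det0$cells), 0L)
})

test_that("detection under default noise reaches F1 >= 0.95 against ground truth", {
  fx <- coloc_fix()
  ccfg <- coloc_config_fig1()
  px <- fx$map$pixel_size
  truth <- fx$sim$cells[fx$sim$cells$APP, ]
  det <- detect_positive_cells(get_channel(fx$sim$image, "APP"), px,
                               ccfg$threshold, ccfg$soma_area_range_um2)$cells
  match_r <- ccfg$soma_radius_um
  d <- outer(det$x * px, truth$x_um + 0.5 * px, "-")^2 +
    outer(det$y * px, truth$y_um + 0.5 * px, "-")^2
  tp <- sum(apply(d, 2, min) <= match_r^2)
  f1 <- 2 * tp / (nrow(det) + nrow(truth))
  expect_gte(f1, 0.95)
})

test_that("laminar assignment follows the centroid and the border rule", {
  fx <- coloc_fix(noiseless = TRUE)
  map <- fx$map
  # constructed centroids: deep SO, exact SR/SLM boundary pixel, off-image
  so <- which(laminaq:::region_mask(map, "CA1_SO") &
                laminaq:::dist_to(!laminaq:::region_mask(map, "CA1_SO")) > 5,
              arr.ind = TRUE)[1, ]
  sr <- laminaq:::region_mask(map, "CA1_SR")
  slm <- laminaq:::region_mask(map, "CA1_SLM")
  bnd <- which(sr & laminaq:::dist_to(slm) <= 1, arr.ind = TRUE)[1, ]
  cells <- data.frame(id = 1:3,
                      x = c(so[2], bnd[2], -5),
                      y = c(so[1], bnd[1], 4))
  cells$APP <- TRUE
  out <- assign_laminae(cells, map, border_width_um = 20)
  expect_identical(out$scope, c("SO", "SR/SLM", "outside"))
  expect_identical(out$lamina[3], "outside")
})

test_that("recovered laminar assignment is perfect away from boundaries", {
  fx <- coloc_fix()
  cells <- detect_cells_image(fx$sim$image, coloc_config_fig1(), fx$map)
  truth <- laminaq:::assign_truth_scope(fx$sim$cells, fx$map, 20)
  # match recovered to truth by nearest centroid
  px <- fx$map$pixel_size
  d <- outer(cells$x, truth$x, "-")^2 + outer(cells$y, truth$y, "-")^2
  nearest <- apply(d, 1, which.min)
  ok <- sqrt(d[cbind(seq_len(nrow(cells)), nearest)]) * px < 4
  # judge only cells deeper than 20 um inside their own scope raster, where
  # assignment must be perfect
  masks <- laminaq:::scope_masks(fx$map, 20)
  deep <- vapply(seq_len(nrow(truth)), function(i) {
    m <- masks[[truth$scope[i]]]
    if (is.null(m)) return(FALSE)
    r <- round(truth$y[i]); c <- round(truth$x[i])
    m[r, c] && laminaq:::dist_to(!m)[r, c] * px > 20
  }, logical(1))
  sel <- ok & deep[nearest]
  expect_gt(sum(sel), 20)
  expect_identical(cells$scope[sel], truth$scope[nearest[sel]])
})

test_that("directional colocalization percentages behave as counts dictate", {
  cells <- data.frame(id = 1:10, scope = rep("SO", 10),
                      A = c(rep(TRUE, 6), rep(FALSE, 4)),
                      B = c(rep(TRUE, 3), rep(FALSE, 7)))
  r <- coloc_percentages(cells, "A", "B", "SO")
  expect_equal(r$pct, 50)
  expect_identical(r$n_ab, 3L)
  # same matched count in both directions
  r2 <- coloc_percentages(cells, "B", "A", "SO")
  expect_identical(r2$n_ab, r$n_ab)
  # disjoint populations give 0, empty A-set is flagged undefined (not 0)
  cells$C <- !cells$A
  expect_equal(coloc_percentages(cells, "A", "C")$pct, 0)
  cells$D <- FALSE
  u <- coloc_percentages(cells, "D", "A")
  expect_true(u$undefined)
  expect_true(is.na(u$pct))
})

test_that("cell identity across channels is one-to-one and order-invariant", {
  fx <- coloc_fix()
  ccfg <- coloc_config_fig1()
  img <- fx$sim$image
  dets <- lapply(c(APP = "APP", GABABR1 = "GABABR1", CCK = "CCK"), function(m)
    detect_positive_cells(get_channel(img, m), fx$map$pixel_size,
                          ccfg$threshold, ccfg$soma_area_range_um2))
  merged <- merge_detections(dets)
  merged_rev <- merge_detections(rev(dets))
  # same number of cells and same per-marker totals regardless of order
  expect_identical(nrow(merged), nrow(merged_rev))
  for (m in names(dets))
    expect_identical(sum(merged[[m]]), sum(merged_rev[[m]]))
  # one-to-one: no detection double-assigned, so marker totals match inputs
  for (m in names(dets))
    expect_identical(sum(merged[[m]]), nrow(dets[[m]]$cells))
})

test_that("laminar distributions normalize to 100 and localize correctly", {
  cells <- data.frame(id = 1:7, scope = rep("SO", 7), M = TRUE)
  ld <- laminar_distribution(cells, "M")
  expect_equal(ld$pct[ld$scope == "SO"], 100)
  expect_equal(sum(ld$pct), 100)
  fx <- coloc_fix()
  cells2 <- detect_cells_image(fx$sim$image, coloc_config_fig1(), fx$map)
  ld2 <- laminar_distribution(cells2, "APP")
  expect_equal(sum(ld2$pct), 100)
  none <- laminar_distribution(cells2[!cells2$APP & !cells2$GABABR1, ], "APP")
  expect_true(none$undefined[1])
})
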
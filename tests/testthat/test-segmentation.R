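test_that("noiseless sections segment exactly", {
  fx <- small_sim(noiseless = TRUE)
  img <- fx$sim$image
  v <- get_channel(img, "VGLUT1")
  hip <- delineate_hippocampus(v, seg_params(), img$pixel_size)
  expect_identical(sum(hip), sum(fx$map$labels > 0))   # area recovered exactly
  bands <- segment_cell_body_layers(v, hip, seg_params(), img$pixel_size,
                                    wfs1 = get_channel(img, "WFS1"))
  truth_sp <- laminaq:::region_mask(fx$map, "CA1_SP") |
    laminaq:::region_mask(fx$map, "CA23_SP")
  expect_equal(laminaq:::jaccard(bands$sp, truth_sp), 1.0)
  expect_equal(laminaq:::jaccard(bands$sg, laminaq:::region_mask(fx$map, "DG_SG")), 1.0)
})

test_that("noisy sections segment with high per-region fidelity", {
  fx <- small_sim(noiseless = FALSE)
  map <- segment_image(fx$sim$image)
  truth_hipp <- fx$map$labels > 0
  expect_lt(abs(sum(map$labels > 0) - sum(truth_hipp)) / sum(truth_hipp), 0.02)
  for (rg in REGION_CODES) {
    j <- laminaq:::jaccard(laminaq:::region_mask(fx$map, rg),
                           laminaq:::region_mask(map, rg))
    expect_gte(j, 0.85)
  }
  sp <- laminaq:::jaccard(
    laminaq:::region_mask(fx$map, "CA1_SP") | laminaq:::region_mask(fx$map, "CA23_SP"),
    laminaq:::region_mask(map, "CA1_SP") | laminaq:::region_mask(map, "CA23_SP"))
  expect_gte(sp, 0.9)
})

test_that("the CA1/CA2-3 boundary lands within 2 px of truth", {
  fx <- small_sim(noiseless = FALSE)
  map <- segment_image(fx$sim$image)
  truth_cols <- which(colSums(laminaq:::region_mask(fx$map, "CA23_SP")) > 0)
  seg_cols <- which(colSums(laminaq:::region_mask(map, "CA23_SP")) > 0)
  expect_lte(abs(min(truth_cols) - min(seg_cols)), 2)
})

test_that("degenerate inputs are refused with diagnostics", {
  flat <- matrix(50, 64, 64)
  expect_error(delineate_hippocampus(flat, seg_params(), 1), "threshold")
  hip <- matrix(TRUE, 64, 64)
  expect_error(segment_cell_body_layers(flat, hip, seg_params(), 1),
               "no candidate band")
  # bright tissue without any dark band: all dark components below min area
  v <- matrix(200, 128, 128) + matrix(rnorm(128^2), 128, 128)
  v[60:62, 60:62] <- 10
  expect_error(segment_cell_body_layers(v, matrix(TRUE, 128, 128),
                                        seg_params(), 1),
               "no candidate band")
})

test_that("imported regions pass through bit-faithfully", {
  fx <- small_sim(noiseless = TRUE)
  out <- partition_laminae(NULL, NULL, NULL, seg_params(),
                           fx$map$pixel_size, imported = fx$map)
  expect_identical(out, fx$map)
  out2 <- segment_image(fx$sim$image, imported = fx$map)
  expect_identical(out2, fx$map)
})

test_that("a hippocampus of only SP and SG leaves other laminae empty with a warning", {
  fx <- small_sim(noiseless = TRUE)
  sp <- laminaq:::region_mask(fx$map, "CA1_SP") | laminaq:::region_mask(fx$map, "CA23_SP")
  sg <- laminaq:::region_mask(fx$map, "DG_SG")
  expect_warning(
    map <- partition_laminae(sp | sg, sp, sg, seg_params(), fx$map$pixel_size),
    "empty laminae")
  present <- unique(map$labels[map$labels > 0])
  lam <- map$codes$lamina[match(present, map$codes$label)]
  expect_setequal(lam, c("SP", "SG"))
})

test_that("subfield split is exact for a step WFS1 profile and warns when uniform", {
  labels <- matrix(0L, 60, 80)
  labels[10:50, 10:70] <- 1L
  codes <- data.frame(label = 1L, subfield = "CA", lamina = "SR",
                      region = "CA_SR")
  map <- new_lamina_map(labels, codes, 1)
  wfs1 <- matrix(0, 60, 80)
  wfs1[, 10:39] <- 100   # step exactly at column 40
  out <- split_subfields(map, wfs1, seg_params())
  ca1 <- laminaq:::region_mask(out, "CA1_SR")
  expect_identical(which(colSums(ca1) > 0), 10:39)
  expect_identical(unname(out$labels > 0), unname(labels > 0))
  expect_warning(split_subfields(map, matrix(100, 60, 80), seg_params()),
                 "uniformly high")
})

test_that("partitioning is idempotent under relabelling", {
  fx <- small_sim(noiseless = TRUE)
  m1 <- segment_image(fx$sim$image)
  m2 <- segment_image(fx$sim$image)
  expect_identical(m1$labels, m2$labels)
  # disjoint regions: label counts partition the foreground
  expect_identical(sum(tabulate(m1$labels)), sum(m1$labels > 0))
})
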
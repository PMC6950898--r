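test_that("triangle threshold equals the brute-force geometric oracle", {
  set.seed(42)
  for (i in 1:200) {
    h <- random_histogram()
    expect_identical(triangle_threshold(h), triangle_oracle(h))
  }
})

test_that("triangle handles ties, spikes and degenerate histograms as documented", {
  # symmetric histogram: equal tails resolve to the right tail
  sym <- stats::dnorm(1:256, 128, 20) * 1e5
  expect_identical(triangle_threshold(sym), triangle_oracle(sym))
  # two-spike histogram: threshold strictly between the spikes
  spikes <- numeric(256); spikes[21] <- 1000; spikes[201] <- 80
  thr <- triangle_threshold(spikes)
  expect_gt(thr, 20); expect_lt(thr, 200)
  expect_error(triangle_threshold(c(0, 5, 0)), "degenerate")
  expect_error(triangle_threshold(rep(0, 256)), "degenerate")
})

test_that("shifting all intensities shifts the threshold bin equally", {
  set.seed(1)
  base <- round(pmax(rnorm(5000, 60, 12), 0))
  img <- matrix(base, 50, 100)
  t0 <- make_plaque_mask(img, 1)$threshold_bin
  t1 <- make_plaque_mask(img + 30, 1)$threshold_bin
  expect_lte(abs((t1 - t0) - 30), 1)   # up to one bin of rounding
})

test_that("the strict 10 um^2 particle filter keeps exactly the large particles", {
  img <- matrix(10, 120, 120)
  img <- plant_rect(img, 10, 10, 2, 2)      # 4 um^2 at 1 um/px
  img <- plant_rect(img, 30, 30, 3, 3)      # 9
  img <- plant_rect(img, 60, 60, 5, 5)      # 25
  img <- plant_rect(img, 90, 20, 10, 10)    # 100
  pm <- make_plaque_mask(img, pixel_size = 1)
  expect_identical(nrow(pm$particles), 2L)
  expect_setequal(round(pm$particles$area_um2), c(25, 100))
  # a particle of exactly 10.0 um^2 is excluded (strict >)
  img2 <- plant_rect(matrix(10, 60, 60), 20, 20, 2, 5)
  pm2 <- make_plaque_mask(img2, pixel_size = 1)
  expect_identical(nrow(pm2$particles), 0L)
  expect_false(any(pm2$mask))              # empty mask is a valid result
})

test_that("particles are 8-connected and mask pixels partition into particles", {
  img <- matrix(10, 40, 40)
  # two 3x3 blocks touching only at a corner: one 8-connected particle
  img <- plant_rect(img, 10, 10, 3, 3)
  img <- plant_rect(img, 13, 13, 3, 3)
  pm <- make_plaque_mask(img, pixel_size = 2)  # 18 px = 72 um^2 > 10
  expect_identical(nrow(pm$particles), 1L)
  expect_identical(sum(pm$mask) * 4, sum(pm$particles$area_um2))
})

test_that("raising the size cutoff never increases mask area", {
  fx <- small_sim()
  ab <- get_channel(fx$sim$image, "ABETA")
  areas <- vapply(c(0, 5, 10, 20, 50),
                  function(a) sum(make_plaque_mask(ab, 1.3, a)$mask), numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("region measurement equals a per-pixel double-loop oracle", {
  set.seed(99)
  for (rep in 1:5) {
    labels <- matrix(sample(0:4, 64 * 64, replace = TRUE), 64, 64)
    codes <- data.frame(label = 1:4, subfield = c("CA1", "CA1", "DG", "DG"),
                        lamina = c("SO", "SP", "MO", "SG"),
                        region = c("CA1_SO", "CA1_SP", "DG_MO", "DG_SG"))
    map <- new_lamina_map(labels, codes, 2)
    mask <- matrix(stats::runif(64 * 64) < 0.3, 64, 64)
    got <- measure_regions(map, mask)
    for (l in 1:4) {
      np <- 0; nm <- 0
      for (r in 1:64) for (c in 1:64) {
        if (labels[r, c] == l) {
          np <- np + 1
          if (mask[r, c]) nm <- nm + 1
        }
      }
      row <- got[got$region == codes$region[l], ]
      expect_identical(row$area_um2, np * 4)
      expect_identical(row$plaque_area_um2, nm * 4)
      expect_equal(row$area_fraction_pct, 100 * nm / np)
    }
  }
})

test_that("aggregates pool pixels exactly", {
  fx <- small_sim()
  q <- quantify_image(fx$sim$image, fx$map)
  m <- q$measurements
  g <- function(r, col) m[[col]][m$region == r]
  for (col in c("area_um2", "plaque_area_um2")) {
    expect_equal(g("CA1", col), sum(sapply(c("CA1_SO", "CA1_SP", "CA1_SR", "CA1_SLM"), g, col)))
    expect_equal(g("HIPP", col), g("CA1", col) + g("CA23", col) + g("DG", col))
    expect_equal(g("HIPP", col), sum(sapply(REGION_CODES, g, col)))
  }
})

test_that("degenerate masks give 0% and 100% fractions and shape mismatches error", {
  labels <- matrix(1L, 10, 10)
  codes <- data.frame(label = 1L, subfield = "DG", lamina = "H", region = "DG_H")
  map <- new_lamina_map(labels, codes, 1)
  expect_true(all(measure_regions(map, matrix(FALSE, 10, 10))$area_fraction_pct == 0))
  expect_true(all(measure_regions(map, matrix(TRUE, 10, 10))$area_fraction_pct == 100))
  expect_error(measure_regions(map, matrix(TRUE, 5, 5)), "shape")
})

test_that("recovered per-region plaque area tracks the planted footprint", {
  fx <- small_sim()
  q <- quantify_image(fx$sim$image, fx$map)
  m <- merge(q$measurements, fx$sim$truth$planted_area)
  m <- m[m$planted_area_um2 > 500, ]   # regions with enough signal
  expect_true(all(abs(m$plaque_area_um2 / m$planted_area_um2 - 1) <= 0.10))
})
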
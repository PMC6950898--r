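test_that("percent reduction handles the canonical and degenerate cases", {
  x <- c(3, 4, 5)
  expect_equal(percent_reduction(x, x)$reduction_pct, 0)
  expect_equal(percent_reduction(x, c(0, 0))$reduction_pct, 100)
  r <- percent_reduction(c(4, 5, 6), c(1, 1.25, 1.5))
  expect_equal(r$reduction_pct, 75)
  expect_true(percent_reduction(c(0, 0), c(1, 2))$undefined)
})

test_that("delta-method SEM agrees with a bootstrap of the ratio of means", {
  ctl <- c(4, 5, 6); cko <- c(1, 1.25, 1.5)
  r <- percent_reduction(ctl, cko)
  expect_equal(r$reduction_pct, 75)
  set.seed(11)
  n <- 1e5
  # parametric bootstrap from the fitted arm distributions (the sampling
  # model the delta method linearizes; a plug-in resample of 3 points is too
  # coarse to estimate an SD against)
  bm_c <- colMeans(matrix(stats::rnorm(3 * n, mean(ctl), stats::sd(ctl)), 3))
  bm_k <- colMeans(matrix(stats::rnorm(3 * n, mean(cko), stats::sd(cko)), 3))
  boot_sem <- stats::sd(100 * (1 - bm_k / bm_c))
  expect_lt(abs(r$sem - boot_sem) / boot_sem, 0.10)
  # and for a larger, noisier draw with CV ~ 0.3
  set.seed(12)
  ctl2 <- stats::rlnorm(8, log(10), 0.3); cko2 <- stats::rlnorm(8, log(7), 0.3)
  r2 <- percent_reduction(ctl2, cko2)
  bm_c <- colMeans(matrix(sample(ctl2, 8 * n, replace = TRUE), 8))
  bm_k <- colMeans(matrix(sample(cko2, 8 * n, replace = TRUE), 8))
  boot2 <- stats::sd(100 * (1 - bm_k / bm_c))
  expect_lt(abs(r2$sem - boot2) / boot2, 0.10)
})

test_that("the pooled-variance t-test matches hand computation and identities", {
  expect_equal(t_test_arms(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  expect_equal(t_test_arms(c(2, 3, 4), c(2, 3, 4))$statistic, 0)
  tt <- t_test_arms(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(tt$statistic, 3), -3.674)
  # single-region two-way ANOVA F equals the squared t statistic
  tab <- data.frame(arm = rep(c("control", "cko"), each = 3),
                    region = "DG_MO",
                    area_fraction_pct = c(1, 2, 3, 4, 5, 6))
  a <- two_way_anova(tab)
  expect_equal(a$statistic[a$term == "arm"], tt$statistic^2)
})

test_that("two-way ANOVA validates factors and detects a planted arm effect", {
  bad <- data.frame(arm = "control", region = rep(c("A", "B"), 3),
                    area_fraction_pct = rnorm(6))
  expect_error(two_way_anova(bad), "both arms")
  areas <- region_areas(build_geometry(small_geometry()))
  cc <- cohort_config_fig3(small_geometry())
  hits <- vapply(1:60, function(s) {
    tab <- simulate_measurements(areas, cc$cfg, n_per_arm = 8, paired = FALSE,
                                 seed = s)
    a <- two_way_anova(tab)
    a$p_value[a$term == "arm"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("statistics are invariant under rescaling of the measurements", {
  set.seed(3)
  tab <- data.frame(arm = rep(c("control", "cko"), each = 8),
                    region = rep(rep(c("CA1_SO", "DG_MO"), each = 4), 2),
                    area_fraction_pct = rlnorm(16, 1, 0.4))
  tab2 <- tab; tab2$area_fraction_pct <- tab2$area_fraction_pct * 7.3
  expect_equal(reduction_table(tab)$reduction_pct,
               reduction_table(tab2)$reduction_pct)
  a1 <- two_way_anova(tab); a2 <- two_way_anova(tab2)
  expect_equal(a1$statistic, a2$statistic)
  c1 <- tab$area_fraction_pct[tab$arm == "control"]
  k1 <- tab$area_fraction_pct[tab$arm == "cko"]
  expect_equal(t_test_arms(c1, k1)$statistic,
               t_test_arms(7.3 * c1, 7.3 * k1)$statistic)
})

test_that("time-course summaries recover monotone aging and flag single animals", {
  areas <- region_areas(build_geometry(small_geometry()))
  cfg <- effect_config()
  rows <- list()
  for (age in c(2, 3, 4, 6)) {
    tab <- simulate_measurements(areas, cfg, n_per_arm = 5, age_months = age,
                                 seed = 100 + age)
    tab <- tab[tab$arm == "control", ]
    tab$age_months <- age
    tab$animal <- paste0(tab$animal, "_", age)
    rows[[as.character(age)]] <- tab
  }
  tc <- time_course_summary(do.call(rbind, rows))
  big <- c("CA1_SLM", "CA1_SO", "DG_MO", "CA23_SLM")
  for (rg in big) {
    m <- tc$summary$mean[tc$summary$region == rg]
    expect_true(all(diff(m) > 0))
  }
  expect_true(all(tc$anova$p_value < 0.01))
  # single animal per age: SEM undefined and flagged
  solo <- data.frame(animal = letters[1:2], age_months = c(2, 3),
                     region = "DG_H", area_fraction_pct = c(1, 2))
  ts <- time_course_summary(solo)
  expect_true(all(ts$summary$sem_undefined))
  expect_true(all(is.na(ts$summary$sem)))
})

test_that("the raster and measurement-level generator paths agree", {
  # same model: expected area fraction from the fast path matches the
  # rendered, measured fraction on the true label map within Monte Carlo error
  fx <- small_sim()
  areas <- region_areas(fx$map)
  cfg <- effect_config()
  fast <- do.call(rbind, lapply(1:10, function(s) {
    tab <- simulate_measurements(areas, cfg, n_per_arm = 1, paired = FALSE,
                                 seed = s)
    tab$animal <- paste0(tab$animal, "_", s)   # keep replicate animals distinct
    tab
  }))
  fast_hipp <- mean(add_aggregates(fast, areas) |>
                      (\(d) d$area_fraction_pct[d$region == "HIPP" &
                                                  grepl("^c", d$animal)])())
  q <- quantify_image(fx$sim$image, fx$map)
  raster_hipp <- q$measurements$area_fraction_pct[q$measurements$region == "HIPP"]
  expect_lt(abs(fast_hipp - raster_hipp) / raster_hipp, 0.15)
})
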
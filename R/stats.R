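# Group-level statistics: percent reductions with delta-method SEM, two-way
# ANOVA over arm x region, Student's t-test, time-course summaries.

#' Percent reduction between arms with delta-method SEM
#'
#' Reduction = 100 (1 - mean(cko) / mean(control)), i.e. a ratio of arm
#' means (arms are independent animals; no pairing exists in the design).
#' Uncertainty propagates the two arm SEMs through the ratio to first order:
#' SEM = 100 (mb/ma) sqrt((SEa/ma)^2 + (SEb/mb)^2).
#'
#' @param control,cko numeric vectors of per-animal measurements (n >= 2).
#' @return data.frame reduction_pct, sem, n_control, n_cko, undefined.
#' @export
percent_reduction <- function(control, cko) {
  stopifnot(length(control) >= 2, length(cko) >= 2)
  ma <- mean(control); mb <- mean(cko)
  if (!is.finite(ma) || ma <= 0)
    return(data.frame(reduction_pct = NA_real_, sem = NA_real_,
                      n_control = length(control), n_cko = length(cko),
                      undefined = TRUE))
  sa <- stats::sd(control) / sqrt(length(control))
  sb <- stats::sd(cko) / sqrt(length(cko))
  ratio <- mb / ma
  sem <- 100 * ratio * sqrt((sa / ma)^2 + if (mb > 0) (sb / mb)^2 else 0)
  data.frame(reduction_pct = 100 * (1 - ratio), sem = sem,
             n_control = length(control), n_cko = length(cko),
             undefined = FALSE)
}

#' Per-region reduction table from an animal measurement table
#'
#' @param table data.frame with columns animal, arm ("control"/"cko"),
#'   region, area_fraction_pct.
#' @return data.frame region + [percent_reduction()] columns.
#' @export
reduction_table <- function(table) {
  stopifnot(all(c("arm", "region", "area_fraction_pct") %in% names(table)))
  out <- lapply(unique(table$region), function(rg) {
    ctl <- table$area_fraction_pct[table$region == rg & table$arm == "control"]
    cko <- table$area_fraction_pct[table$region == rg & table$arm == "cko"]
    cbind(region = rg, percent_reduction(ctl, cko))
  })
  do.call(rbind, out)
}

#' Two-way ANOVA over arm x region
#'
#' Classical two-factor decomposition with interaction on the per-animal area
#' fractions, p-values from the F distribution. Untransformed by default (the
#' reference analysis reports raw percent area); `log_transform` applies
#' log(x + offset) first.
#'
#' @param table data.frame with arm, region, area_fraction_pct.
#' @param log_transform log-transform the response first.
#' @param offset additive offset inside the log.
#' @return data.frame term, df, sumsq, meansq, statistic (F), p_value.
#' @export
two_way_anova <- function(table, log_transform = FALSE, offset = 0.01) {
  stopifnot(all(c("arm", "region", "area_fraction_pct") %in% names(table)))
  if (length(unique(table$arm)) < 2)
    stop_config("two-way ANOVA needs both arms; got %s",
                paste(unique(table$arm), collapse = ", "))
  if (length(unique(table$region)) < 1)
    stop_config("two-way ANOVA needs at least one region")
  y <- table$area_fraction_pct
  if (log_transform) y <- log(y + offset)
  dat <- data.frame(y = y, arm = factor(table$arm),
                    region = factor(table$region))
  single_region <- nlevels(dat$region) < 2
  fit <- if (single_region) stats::aov(y ~ arm, data = dat) else
    stats::aov(y ~ arm * region, data = dat)
  tab <- summary(fit)[[1]]
  data.frame(term = trimws(rownames(tab)), df = tab$Df, sumsq = tab$`Sum Sq`,
             meansq = tab$`Mean Sq`, statistic = tab$`F value`,
             p_value = tab$`Pr(>F)`, row.names = NULL)
}

#' Unpaired two-sided Student's t-test
#'
#' Classical pooled-variance t. The degenerate zero-variance case is handled
#' explicitly: equal means give t = 0, p = 1.
#'
#' @param control,cko numeric vectors (n >= 2 each).
#' @return data.frame statistic, df, p_value.
#' @export
t_test_arms <- function(control, cko) {
  stopifnot(length(control) >= 2, length(cko) >= 2)
  if (stats::sd(control) == 0 && stats::sd(cko) == 0) {
    eq <- isTRUE(all.equal(mean(control), mean(cko)))
    return(data.frame(statistic = if (eq) 0 else Inf,
                      df = length(control) + length(cko) - 2,
                      p_value = if (eq) 1 else 0))
  }
  tt <- stats::t.test(control, cko, var.equal = TRUE)
  data.frame(statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value)
}

#' Time-course summary across ages
#'
#' Per age and region: mean area fraction and SEM (undefined and flagged with
#' a single animal), plus a one-way ANOVA across ages per region.
#'
#' @param table data.frame with animal, age_months, region,
#'   area_fraction_pct (one arm).
#' @return list(summary, anova): the per-age/per-region table and the
#'   per-region one-way ANOVA table.
#' @export
time_course_summary <- function(table) {
  stopifnot(all(c("age_months", "region", "area_fraction_pct") %in% names(table)))
  ages <- sort(unique(table$age_months))
  if (length(ages) < 2) stop_config("time course needs >= 2 ages")
  smry <- do.call(rbind, lapply(unique(table$region), function(rg) {
    do.call(rbind, lapply(ages, function(a) {
      v <- table$area_fraction_pct[table$region == rg & table$age_months == a]
      data.frame(region = rg, age_months = a, n = length(v),
                 mean = mean(v),
                 sem = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_,
                 sem_undefined = length(v) < 2)
    }))
  }))
  av <- do.call(rbind, lapply(unique(table$region), function(rg) {
    sub <- table[table$region == rg, ]
    fit <- stats::aov(area_fraction_pct ~ factor(age_months), data = sub)
    tab <- summary(fit)[[1]]
    no_resid <- is.null(tab$`F value`) || stats::df.residual(fit) == 0
    data.frame(region = rg, df = tab$Df[1],
               statistic = if (no_resid) NA_real_ else tab$`F value`[1],
               p_value = if (no_resid) NA_real_ else tab$`Pr(>F)`[1])
  }))
  list(summary = smry, anova = av)
}

#' Fast measurement-level cohort simulation
#'
#' Draws per-animal, per-region area fractions from the same generative model
#' as the raster path — Poisson plaque counts at area x density x age x
#' per-animal multiplier, log-normal plaque areas, strict > `min_area_um2`
#' size filter — without rendering or segmenting images. Used for replicate-
#' heavy calibration studies (null distribution of the arm tests, power).
#'
#' @param areas data.frame region / area_um2 (e.g. [region_areas()] of the
#'   cohort geometry), laminar regions only.
#' @param cfg [effect_config()].
#' @param n_per_arm animals per arm.
#' @param age_months cohort age.
#' @param paired use common random numbers (cKO = thinned control field of
#'   the matched animal); FALSE gives fully independent arms.
#' @param seed master seed.
#' @param min_area_um2 particle filter cutoff.
#' @return data.frame animal, arm, region, area_fraction_pct.
#' @export
simulate_measurements <- function(areas, cfg, n_per_arm = 8L, age_months = 3,
                                  paired = TRUE, seed = 1L, min_area_um2 = 10) {
  areas <- areas[areas$region %in% REGION_CODES, ]
  dens <- cfg$baseline_density[areas$region]
  am <- as.character(age_months)
  age_mult <- if (am %in% names(cfg$age_scaling)) cfg$age_scaling[[am]] else 1
  ratio <- cfg$cko_density_ratio[areas$region]
  sdlog_an <- sqrt(log(1 + cfg$animal_cv^2))
  rows <- list()
  for (i in seq_len(n_per_arm)) {
    set.seed(derive_seed(seed, i))
    mult_c <- stats::rlnorm(1, -sdlog_an^2 / 2, sdlog_an)
    mult_k <- if (paired) mult_c else stats::rlnorm(1, -sdlog_an^2 / 2, sdlog_an)
    for (j in seq_len(nrow(areas))) {
      lam <- areas$area_um2[j] / 1e6 * dens[j] * age_mult
      n_c <- stats::rpois(1, lam * mult_c)
      a_c <- stats::rlnorm(n_c, 2 * cfg$radius_meanlog + log(pi),
                           2 * cfg$radius_sdlog)
      if (paired) {
        keep <- stats::runif(n_c) < ratio[j]
        a_k <- a_c[keep]
      } else {
        n_k <- stats::rpois(1, lam * ratio[j] * mult_k)
        a_k <- stats::rlnorm(n_k, 2 * cfg$radius_meanlog + log(pi),
                             2 * cfg$radius_sdlog)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        animal = paste0(c("c", "k"), i),
        arm = c("control", "cko"),
        region = areas$region[j],
        area_fraction_pct = 100 * c(sum(a_c[a_c > min_area_um2]),
                                    sum(a_k[a_k > min_area_um2])) /
          areas$area_um2[j])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Append pixel-pooled aggregate rows to a measurement table
#'
#' @param table animal measurement table over laminar regions.
#' @param areas region areas (same geometry).
#' @return table with CA1 / CA23 / DG / HIPP rows added per animal.
#' @export
add_aggregates <- function(table, areas) {
  a <- stats::setNames(areas$area_um2, areas$region)
  groups <- list(CA1 = grep("^CA1_", REGION_CODES, value = TRUE),
                 CA23 = grep("^CA23_", REGION_CODES, value = TRUE),
                 DG = grep("^DG_", REGION_CODES, value = TRUE),
                 HIPP = REGION_CODES)
  extra <- list()
  for (an in unique(table$animal)) {
    sub <- table[table$animal == an, ]
    for (g in names(groups)) {
      rg <- intersect(groups[[g]], sub$region)
      if (!length(rg)) next
      w <- a[rg]
      af <- sum(sub$area_fraction_pct[match(rg, sub$region)] * w) / sum(w)
      extra[[length(extra) + 1L]] <- data.frame(
        animal = an, arm = sub$arm[1], region = g, area_fraction_pct = af)
    }
  }
  rbind(table[, c("animal", "arm", "region", "area_fraction_pct")],
        do.call(rbind, extra))
}
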
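#!/usr/bin/env Rscript
# Group statistics for the two-arm cohort: per-region percent reductions with
# delta-method SEMs, arm x region two-way ANOVA, and the simulated soluble
# Abeta42 ELISA comparison (12 vs 12, Student's t).

library(laminaq)

meas <- read.csv("results/measurements_fig3.csv")
red <- reduction_table(meas)
write.csv(red, "results/reductions_fig3.csv", row.names = FALSE)

cat("aggregate percent reductions (cKO vs control):\n")
print(red[red$region %in% c("HIPP", "CA1", "CA1_SP", "DG", "DG_MO"),
          c("region", "reduction_pct", "sem")], digits = 3)

av <- two_way_anova(meas[meas$region %in% REGION_CODES, ])
write.csv(av, "results/anova_fig3.csv", row.names = FALSE)
cat("\ntwo-way ANOVA (arm x region):\n")
print(av, digits = 3)

cfg <- effect_config()
elisa <- data.frame(
  arm = rep(c("control", "cko"), each = 12),
  abeta42 = c(sample_elisa(cfg, "control", 12, 901L),
              sample_elisa(cfg, "cko", 12, 902L)))
ctl <- elisa$abeta42[elisa$arm == "control"]
cko <- elisa$abeta42[elisa$arm == "cko"]
er <- percent_reduction(ctl, cko)
tt <- t_test_arms(ctl, cko)
write.csv(cbind(er, t = tt$statistic, p = tt$p_value),
          "results/elisa_fig3.csv", row.names = FALSE)
cat(sprintf("\nELISA: %.1f %% +/- %.1f reduction, t = %.2f, p = %.2g\n",
            er$reduction_pct, er$sem, tt$statistic, tt$p_value))
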
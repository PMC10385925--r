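#!/usr/bin/env Rscript
# Runs the full statistical battery over the simulated cohort: breed
# comparison of adrenal volume with REGWQ letters, between-breed CVs with
# weight correlations, attenuation side tests, and the weight-group RVA
# comparison. Reads results/cohort.csv (run 01_simulate_cohort.R first).

suppressPackageStartupMessages(library(adrenomorph))

out_dir <- "results"
cohort_path <- file.path(out_dir, "cohort.csv")
if (!file.exists(cohort_path))
  stop("run analysis/01_simulate_cohort.R first (missing ", cohort_path, ")")
cohort <- read_cohort_csv(cohort_path)

rep <- cohort_report(cohort, out_dir = file.path(out_dir, "cohort_report"))
print(rep)

cat("\nWeight-group RVA comparison:\n")
for (sd_ in c("left", "right")) {
  wg <- weight_group_difference(cohort, "rva", side = sd_)
  cat(sprintf("  %s gland: light median %.2f vs heavy %.2f, rank-sum p = %.2g\n",
              sd_, wg$median_light, wg$median_heavy, wg$p_value))
}

cat("\nAttenuation side differences per breed:\n")
att <- rep$attenuation_table
for (i in seq_len(nrow(att)))
  cat(sprintf("  %-22s left %.1f HU, right %.1f HU, %s p = %.3g\n",
              att$breed[i], att$left_mean[i], att$right_mean[i],
              att$side_test[i], att$side_p[i]))

cat("\nSex and neuter status (RVA, Kruskal-Wallis):\n")
for (grp in c("sex", "neutered")) {
  left <- cohort[cohort$side == "left", ]
  kw <- kruskal.test(left$rva, factor(left[[grp]]))
  cat(sprintf("  %s: p = %.3f\n", grp, kw$p.value))
}
cat("\nTables written under", file.path(out_dir, "cohort_report"), "\n")
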
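#!/usr/bin/env Rscript
# Step 4 — group-level statistics on the per-cell summaries.
#
# Mirrors the study's reporting: unpaired two-tailed t tests for the
# two-group kinetic metrics, and a one-way ANOVA with Sidak post hocs for
# the amplitude comparison across the four (group x stimulus-type) cells.
# Requires step 3.

suppressPackageStartupMessages(library(catrace))

s <- read.delim("results/cell_summary.tsv")
s <- s[s$eligible == "TRUE" | s$eligible == TRUE, ]
g1 <- s[s$group == "group1", ]
g2 <- s[s$group == "group2", ]

for (metric in c("mean_amplitude", "k_sys", "k_sys_random", "k_caf",
                 "serca_function", "fractional_release")) {
  cmp <- compare_two_groups(g1[[metric]], g2[[metric]],
                            labels = c("control", "serca-enhanced"),
                            metric = metric)
  cat(cmp$summary, "\n")
  write_comparison_tsv(cmp, sprintf("results/compare_%s.tsv", metric))
}

# amplitude across group x stimulus type (paced vs caffeine), one-way with
# Sidak-adjusted pairwise comparisons
amp <- data.frame(
  value = c(g1$mean_amplitude, g2$mean_amplitude,
            g1$amplitude_caffeine, g2$amplitude_caffeine),
  cell = rep(c("control:paced", "enhanced:paced",
               "control:caffeine", "enhanced:caffeine"),
             times = c(nrow(g1), nrow(g2), nrow(g1), nrow(g2))))
aov_cmp <- compare_multi_groups(amp$value, amp$cell, design = "one-way",
                                adjust = "sidak", metric = "amplitude")
cat("\n", aov_cmp$summary, "\n", sep = "")
print(aov_cmp$posthoc, digits = 3, row.names = FALSE)
write_comparison_tsv(aov_cmp, "results/compare_amplitude_anova.tsv")
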
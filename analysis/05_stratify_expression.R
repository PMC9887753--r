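#!/usr/bin/env Rscript
# Step 5 — quartile stratification of an expression vector.
#
# The stratification rule used for grouping donors by transcript abundance:
# bottom and top quartiles form the low and high groups, then values outside
# 1.5 x IQR (quartiles and IQR from the full vector) are excluded as
# outliers. Run on a synthetic TPM-like vector (lognormal, with a few
# extreme values) since the stratification operates on any numeric vector.

suppressPackageStartupMessages(library(catrace))

set.seed(20260930)
n <- 400
tpm <- exp(rnorm(n, log(12), 0.6))
tpm[sample(n, 3)] <- tpm[sample(n, 3)] * 40  # extreme outliers
ids <- sprintf("donor%03d", seq_len(n))

s <- stratify_quartiles(tpm, ids)
cat(sprintf("Q1 = %.3f, Q3 = %.3f, IQR = %.3f (quantile type %d)\n",
            s$q1, s$q3, s$iqr, s$quantile_type))
cat(sprintf("low group: %d donors; high group: %d donors; excluded: %d\n",
            length(s$low_ids), length(s$high_ids),
            length(s$excluded_outlier_ids)))

out <- data.frame(
  id = c(s$low_ids, s$high_ids, s$excluded_outlier_ids),
  stratum = rep(c("low", "high", "excluded"),
                c(length(s$low_ids), length(s$high_ids),
                  length(s$excluded_outlier_ids))))
dir.create("results", showWarnings = FALSE)
utils::write.table(out, "results/expression_strata.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("strata written to results/expression_strata.tsv\n")
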
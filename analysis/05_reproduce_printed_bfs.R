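#!/usr/bin/env Rscript
# Step 5: reproduce the published Bayes factors from the bundled printed
# group summaries (Table-1 means and 95% CIs, correlation coefficients,
# n = 49). This is the deterministic reproduction surface of the package:
# no simulation is involved, only the inference engine applied to the
# printed numbers.

suppressPackageStartupMessages(library(mmnload))

rep <- reproduce_printed_bfs()
dir.create("results", showWarnings = FALSE)
write.table(rep$erp, "results/reproduced_erp_bfs.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(rep$correlations, "results/reproduced_correlation_bfs.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

cat("uniform-prior Bayes factors from printed summaries (n = 49):\n")
for (i in seq_len(nrow(rep$erp))) {
  cat(sprintf("  %-13s BF01 two-tailed %6.2f | directional %6.2f | BF10 %8.2f\n",
              rep$erp$measure[i], rep$erp$bf01_twotailed[i],
              rep$erp$bf01_directional[i], rep$erp$bf10_twotailed[i]))
}
cat("flat-prior correlation Bayes factors:\n")
for (i in seq_len(nrow(rep$correlations))) {
  cat(sprintf("  %-22s r = %+.2f  BF10 = %.2f  BF01 = %.2f\n",
              rep$correlations$measure[i], rep$correlations$r[i],
              rep$correlations$bf10[i], rep$correlations$bf01[i]))
}
cat("wrote results/reproduced_erp_bfs.tsv and",
    "results/reproduced_correlation_bfs.tsv\n")
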
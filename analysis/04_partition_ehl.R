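#!/usr/bin/env Rscript
# Step 4 — partitioning of evaporative heat loss.
#
# Simulates a two-line mask-respirometry session (mask line pulled at
# 500 ml/min carrying the respiratory water signal, chamber line at
# 200 ml/min carrying the cutaneous signal) for 36 birds at 25 and 40
# degC, inverts both lines, and summarizes the respiratory/cutaneous
# split per temperature stratum.

suppressPackageStartupMessages(library(tnz))
dir.create("results", showWarnings = FALSE)

session <- generate_mask_session(partition_truth(), n_birds = 36,
                                 seed = 42)
records <- partition_session(session)
sm <- summarize_partition(records)
write.csv(sm, "results/partition_summary.csv", row.names = FALSE)

for (i in seq_len(nrow(sm))) {
  cat(sprintf(
    "Ta = %d degC: REHL %.4f W, CEHL %.4f W; cutaneous share %.0f%% (per-bird mean) / %.0f%% (pooled); median REHL/CEHL %.2f\n",
    sm$ta_set_c[i], sm$rehl_mean[i], sm$cehl_mean[i],
    100 * sm$cehl_fraction_mean[i], 100 * sm$cehl_fraction_pooled[i],
    sm$ratio_median[i]))
}
cat("The cutaneous avenue dominates at 25 degC; above the TNZ the",
    "respiratory avenue takes over.\n")
cat("Wrote results/partition_summary.csv\n")
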
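#!/usr/bin/env Rscript
# Stage 2: voxelise every subplot cloud (0.4 m voxels) and compute the
# canopy space filling index under the four canopy-space definitions,
# plus their pairwise Pearson correlations across subplots.
#
# Rebuilds the stage-1 stand deterministically from the shared seed, so this
# script only needs results/ for its outputs.
#
# Outputs: results/csfi.csv, results/csfi_correlations.csv.

library(canopyfill)
SEED <- 42
dir.create("results", showWarnings = FALSE)

design <- make_design(seed = SEED)
stand <- simulate_stand(design, params = sim_params(), seed = SEED + 1)
cfg <- run_config(seed = SEED)
csfi_tab <- stand_csfi_table(stand, cfg)

valid <- csfi_tab[csfi_tab$valid, ]
means <- tapply(valid$csfi, valid$definition, mean)
cat("mean CSFI by definition:\n")
print(round(means[CANOPY_DEFINITIONS], 3))
cat(sprintf("invalid definition records: %d of %d\n",
            sum(!csfi_tab$valid), nrow(csfi_tab)))

corr <- csfi_correlations(csfi_tab)
cat("pairwise Pearson correlations:\n")
print(round(corr, 3))

write.csv(csfi_tab, "results/csfi.csv", row.names = FALSE)
write.csv(as.data.frame(corr), "results/csfi_correlations.csv")
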
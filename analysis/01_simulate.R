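#!/usr/bin/env Rscript
# Stage 1: build the experimental design and simulate the stand.
#
# The design mirrors a classic tree-diversity plantation: two monoculture
# plots per species over six species spanning three growth guilds, six
# three-species mixtures (one species per guild) and six six-species
# mixtures, with the monocultures of one high-mortality pioneer removed —
# 22 plots of 45 x 45 m, four subplots each, 88 subplots in total.
#
# Outputs: results/design.csv, results/inventory.csv, and one example
# subplot point cloud (results/example_subplot.xyz).

library(canopyfill)
SEED <- 42
dir.create("results", showWarnings = FALSE)

design <- make_design(seed = SEED)
cat(sprintf("design: %d plots (%d mono, %d mix3, %d mix6), %d subplots\n",
            nrow(design), sum(design$type == "mono"),
            sum(design$type == "mix3"), sum(design$type == "mix6"),
            attr(design, "n_subplots")))
write.csv(design, "results/design.csv", row.names = FALSE)

stand <- simulate_stand(design, params = sim_params(), seed = SEED + 1)
inv <- stand$inventory
cat(sprintf("stand: %d trees, %.1f%% alive at second census\n",
            nrow(inv), 100 * mean(inv$alive_t2)))
write.csv(inv, "results/inventory.csv", row.names = FALSE)

# one example subplot cloud, clipped and split exactly as the analysis does
geom <- plot_geometry()
cloud <- sample_point_cloud(stand, design$plot_id[1], seed = SEED + 1001)
sw <- split_subplots(clip_buffer(cloud, geom), geom)$SW
write_cloud(sw, "results/example_subplot.xyz")
cat(sprintf("example subplot cloud: %d points, max height %.1f m\n",
            nrow(sw), max(sw$z)))
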
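#!/usr/bin/env Rscript
# Simulate the default synthetic benchmark world and write it to plain-text
# files under results/world/. Every later analysis regenerates the same
# world from the same seed, so these files are for inspection and reuse
# outside R.

suppressMessages(library(cypscout))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cfg <- world_config(seed = seed)
world <- gen_world(cfg)
write_world(world, "results/world")

cat("Synthetic world (seed ", seed, "):\n", sep = "")
print(world$library)
cat("  tree: ", length(world$phylo$tree$tip.label), " leaves in ",
    length(unique(world$phylo$labels)), " clades\n", sep = "")
cat("  genomes: ", length(world$genomes$targets), " targets, ",
    nrow(world$genomes$model$genes), " genes\n", sep = "")
cat("  dock table: ", nrow(world$dock$table), " receptor-ligand pairs\n",
    sep = "")
cat("files written to results/world/\n")
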
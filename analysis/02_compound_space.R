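#!/usr/bin/env Rscript
# Compound-space analysis: Tanimoto similarity over the library, Butina
# clustering with a cutoff scan, and the intra-/inter-group similarity
# distributions that show how chemically coherent the planted groups are.

suppressMessages(library(cypscout))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)

lib <- gen_compounds(world_config(seed = seed))
sim <- tanimoto_matrix(lib$fingerprints)

scan <- choose_cutoff(sim, candidates = seq(0.3, 0.8, by = 0.1), floor = 2)
cat("Cutoff scan (chosen:", scan$cutoff, "):\n")
print(scan$scan, row.names = FALSE)
write.table(scan$scan, "results/cutoff_scan.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cl <- butina_cluster(sim, scan$cutoff)
print(cl)
write.table(data.frame(id = names(cl$labels), cluster = cl$labels,
                       planted_group = unname(lib$groups[names(cl$labels)])),
            "results/clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pure <- all(table(lib$groups[names(cl$labels)], cl$labels) %in%
              c(0, table(lib$groups)))
cat("clusters coincide with planted groups:", pure, "\n")

dists <- intra_inter_distributions(sim, lib$groups)
cat(sprintf("intra-group TI: mean %.3f (n = %d); inter-group TI: mean %.3f (n = %d)\n",
            mean(dists$intra), length(dists$intra),
            mean(dists$inter), length(dists$inter)))
write.table(rbind(data.frame(pair_type = "intra", ti = dists$intra),
                  data.frame(pair_type = "inter", ti = dists$inter)),
            "results/ti_distributions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
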
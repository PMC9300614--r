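#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic multiome study.
#
# Builds the default study conditions (4 forebrain regions x 3 maturation
# states x 150 cells, 200 genes with planted enhancer-gene links, planted
# outlier barcodes, region-matched histone peak sets) and writes the
# dataset plus ground truth under results/dataset/ in the package's
# exchange formats. Later stages read from that directory, so the whole
# analysis also exercises the I/O round trip.

library(epilink)

seed <- 1L
design <- simulation_design()
sim <- simulate_multiome(design, seed = seed)
write_dataset(sim, "results/dataset")

cat(sprintf("cells: %d  peaks: %d  genes: %d\n",
            nrow(sim$cells), length(sim$peaks), nrow(sim$annotation)))
cat(sprintf("planted enhancer-gene links: %d\n", nrow(sim$truth$true_links)))
cat(sprintf("planted outlier barcodes: %d\n",
            length(sim$truth$planted_outliers)))
cat(sprintf("early / late trend genes: %d / %d\n",
            length(sim$truth$early_genes), length(sim$truth$late_genes)))
cat("dataset written to results/dataset/\n")
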
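#!/usr/bin/env Rscript
# Generates the default two-cell-line synthetic dataset (seeded) that every
# downstream analysis step consumes. Writes results/scenario/ with a FASTA
# genome, per-TF narrowPeak + bedGraph files, gene model, FPKM table, PFM
# motifs, a ready pipeline config and the planted ground truth.

suppressMessages(library(secistrome))

dir.create("results", showWarnings = FALSE)
unlink("results/scenario", recursive = TRUE)
sc <- generate_scenario(scenario_params(seed = 1), dir = "results/scenario")

cat("Planted super-enhancers by label:\n")
print(table(sc$truth$ses$label))
cat("Planted constituents by label:\n")
print(table(sc$truth$constituents$label))
cat(sprintf("Dataset written to %s (%d files)\n", sc$dir,
            length(list.files(sc$dir, recursive = TRUE))))
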
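#!/usr/bin/env Rscript
# Step 1 — simulate the in vivo study design.
#
# Ten compounds (7 genotoxins, DEN hybridized in duplicate at half weight;
# 3 non-genotoxins), four timepoints, one pooled treatment sample per
# (chemical cell, timepoint), eight individual solvent-control animals per
# solvent and timepoint, 10,000 genes. Five genes are spiked as GTX-specific
# responders at a mean 8-fold induction; everything else is null.
#
# Writes the full dataset (bulky) to scratch/sim/ and a small truth summary
# to results/.

library(gtxscore)

seed <- 1L
design <- study_design()
effects <- default_effects()

ds <- generate_dataset(design, effects, seed = seed)
print(ds)

dir.create("results", showWarnings = FALSE)
write_dataset(ds, "scratch/sim")
cat("dataset written to scratch/sim/ (seed", seed, ")\n")

truth_tab <- as.data.frame(table(ds$truth$label))
names(truth_tab) <- c("label", "n_genes")
write.table(truth_tab, "results/sim_truth_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("spiked responsive genes:",
    paste(effects$responsive_gene_ids, collapse = ", "), "\n")
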
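#!/usr/bin/env Rscript
# Step 3 — average-linkage clustering of the top 50 genes.
#
# Log2-ratio profiles of the 50 highest-scoring genes across the 44
# treatment conditions, 1 - uncentered Pearson correlation distance, UPGMA
# on both genes and conditions. The headline structure is the condition
# tree: its root split should place genotoxin and non-genotoxin conditions
# on opposite branches.

library(gtxscore)

ds <- if (dir.exists("scratch/sim")) read_dataset("scratch/sim") else
  generate_dataset(study_design(), default_effects(), seed = 1L)
out <- rank_genes(ds)

cl <- cluster_top(out$scores, out$calls, n = 50)

dir.create("results", showWarnings = FALSE)
as_newick(cl$gene_tree, "results/gene_tree.nwk")
as_newick(cl$condition_tree, "results/condition_tree.nwk")
prof <- data.frame(gene_id = rownames(cl$profiles), cl$profiles,
                   check.names = FALSE)
write.table(prof, "results/top50_log2ratio_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

bp <- root_bipartition(cl$condition_tree)
cls <- function(ids) table(ds$samples$class[match(ids, ds$samples$sample_id)])
cat("condition-tree root split:\n")
cat("  branch 1:", paste(names(cls(bp[[1]])), cls(bp[[1]]), collapse = ", "), "\n")
cat("  branch 2:", paste(names(cls(bp[[2]])), cls(bp[[2]]), collapse = ", "), "\n")
cat("trees written to results/*.nwk; reordered profiles to",
    "results/top50_log2ratio_profiles.tsv\n")
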
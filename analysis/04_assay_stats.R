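#!/usr/bin/env Rscript
# Step 4 — biomarker-validation assay statistics on packaged synthetic data.
#
# Emulates the bench validation of a DNA-damage-responsive transcript:
# qPCR relative quantification (2^-ddCt) of the candidate gene across an
# alkylating-agent dose series, olive tail moment from comet-assay
# measurements of the same doses, a linear regression of mean damage on
# mean induction, and micronucleus frequencies for an aneugen. All input
# tables are synthetic (inst/extdata/synthetic_*.csv) and deliberately
# small; the statistics are the package's closed-form operations.

library(gtxscore)

extdata <- function(f) system.file("extdata", f, package = "gtxscore")

# --- qPCR: per-dose mean fold change over control -------------------------
ct <- read.csv(extdata("synthetic_qpcr_ct.csv"))
ctl <- ct[ct$group == "control", ]
ctl_target <- mean(ctl$target_ct); ctl_ref <- mean(ctl$ref_ct)
ct$fold <- ddct_fold_change(ct$target_ct, ct$ref_ct, ctl_target, ctl_ref)
fold_by_dose <- aggregate(fold ~ group + dose_mM, ct, mean)
fold_by_dose <- fold_by_dose[order(fold_by_dose$dose_mM), ]
cat("mean 2^-ddCt fold change by dose:\n")
print(fold_by_dose, digits = 3, row.names = FALSE)

# --- comet assay: per-dose mean olive tail moment -------------------------
comet <- read.csv(extdata("synthetic_comet.csv"))
comet$otm <- olive_tail_moment(comet$tail_length_um, comet$pct_dna_in_tail,
                               units = "percent")
otm_by_dose <- aggregate(otm ~ group + dose_mM, comet, mean)
otm_by_dose <- otm_by_dose[order(otm_by_dose$dose_mM), ]
cat("\nmean olive tail moment (um) by dose:\n")
print(otm_by_dose, digits = 3, row.names = FALSE)

# --- expression vs damage regression (per-dose means) ---------------------
stopifnot(identical(fold_by_dose$group, otm_by_dose$group))
fit <- dose_response_regression(fold_by_dose$fold, otm_by_dose$otm)
cat("\nexpression-damage regression: ")
print(fit)

# --- micronucleus frequencies ---------------------------------------------
mn <- read.csv(extdata("synthetic_micronucleus.csv"))
freq <- micronucleus_frequency(mn$mn_cells, mn$total_cells)
mn$per_1000 <- freq$per_1000
cat("\nmicronucleus frequency (per 1000 cells):\n")
print(mn[, c("group", "dose_uM", "per_1000")], row.names = FALSE)

dir.create("results", showWarnings = FALSE)
summary_tab <- merge(fold_by_dose, otm_by_dose)
write.table(summary_tab, "results/assay_dose_response.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(slope = fit$slope, intercept = fit$intercept,
                       r_squared = fit$r_squared, n = fit$n),
            "results/assay_regression.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nsummaries written to results/assay_*.tsv\n")
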
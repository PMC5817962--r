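#!/usr/bin/env Rscript

# Step 4: ROC curves over the BH-threshold grid and the optimal threshold
# per replicate number.
#
# Against the stringent full-data truth list, each subsampled analysis
# yields a ROC curve as the BH threshold sweeps [0, 1]; the Youden-optimal
# threshold is extracted per subsample and summarized as the median per
# replicate number. The fitted slope of log2(threshold) on r tests the
# empirical 2^-r rule.

suppressMessages(library(pilotpower))

counts <- read_count_table("results/pilot_counts.tsv", "matrix_tsv")
design <- read_study_design("results/pilot_design.tsv")
truth <- read_gene_set("results/truth_de_genes.txt")

r_values <- 2:6
tab <- optimal_threshold_by_replicates(counts, design, truth,
                                       r_values = r_values,
                                       n_repetitions = 10, seed = 17)
print(tab)
write.table(tab, "results/optimal_thresholds.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

fit <- fit_threshold_vs_replicates(tab)
message("log2(optimal threshold) ~ r: slope ", round(fit$slope, 3),
        ", intercept ", round(fit$intercept, 3))
message("a slope near -1 with intercept near 0 is the 2^-r rule; ",
        "2^-r predicts ", paste(signif(2^-r_values, 2), collapse = " "),
        " for r = ", paste(r_values, collapse = " "))

# one full ROC curve for the smallest design, for plotting elsewhere
sub <- subsample_replicates(counts, design, 2, seed = 1)
curve <- roc_curve(run_de(sub$counts, sub$design), truth)
write.table(curve, "results/roc_curve_r2.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote per-r optimal thresholds and an r = 2 ROC curve under results/")
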
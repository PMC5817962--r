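#!/usr/bin/env Rscript

# Step 1: simulate the pilot experiment.
#
# A desk-scale stand-in for a two-condition bulk RNA-Seq pilot (ovary vs
# young fruit style design): 4,000 genes, 8 biological replicates per
# condition, 1 M reads per sample, roughly half the genes truly DE. The
# full-scale defaults (20,000 genes, 5 M reads) are what the package tests
# use; this workflow keeps every step fast enough to re-run interactively.

suppressMessages(library(pilotpower))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

spec <- pilot_spec(n_genes = 4000, replicates_per_condition = 8,
                   target_library_size = 1e6, seed = 20180214)
pilot <- generate_pilot(spec)

message("simulated ", nrow(pilot$counts), " genes x ", ncol(pilot$counts),
        " samples; ", sum(pilot$truth$is_de), " truly DE genes")
message("library sizes: ", paste(round(colSums(pilot$counts) / 1e6, 2),
                                 collapse = " "), " M reads")

# generator calibration: naive fold changes should track the truth closely
mae <- empirical_lfc_check(pilot$counts, pilot$design, pilot$truth)
message("mean |observed - true| log2FC on DE genes: ", round(mae, 3))

write_count_table(pilot$counts, file.path(out_dir, "pilot_counts.tsv"))
write.table(pilot$design, file.path(out_dir, "pilot_design.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(pilot$truth, file.path(out_dir, "pilot_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote pilot counts, design and truth tables under results/")
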
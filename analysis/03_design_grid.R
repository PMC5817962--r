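#!/usr/bin/env Rscript

# Step 3: the replicate-by-depth evaluation grid.
#
# For every (replicate number, library size) combination, repeated random
# subsamples of the pilot are analyzed and four indicators are aggregated:
# the median number of DE genes, its stability (genes common to every
# repetition), the median power against the reference list, and the
# stability power -- overall and within the low/high expression strata.
# A desk-scale grid (r in 2..5, depths 0.25/0.5/0.75 M, 10 repetitions)
# stands in for the full 6 x 6 x 45 design.

suppressMessages(library(pilotpower))

counts <- read_count_table("results/pilot_counts.tsv", "matrix_tsv")
design <- read_study_design("results/pilot_design.tsv")
reference <- read_gene_set("results/reference_de_genes.txt")

params <- analysis_params(replicate_grid = 2:5,
                          depth_grid = c(2.5e5, 5e5, 7.5e5),
                          n_repetitions = 10,
                          master_seed = 3)

message("running ", length(params$replicate_grid) * length(params$depth_grid),
        " grid cells x ", params$n_repetitions, " repetitions ...")
cells <- run_grid(counts, design, params)

full <- run_de(counts, design)
strata <- expression_strata(setNames(full$logCPM, full$gene))
summary <- aggregate_indicators(cells, reference, strata)
write_indicator_table(summary, "results/grid_indicators.tsv")
write_run_summary(params, cells, "results/grid_run_summary.json")

message("indicators at the grid corners:")
print(summary[summary$depth %in% range(summary$depth) &
                summary$r %in% range(summary$r),
              c("r", "depth", "median_nde", "stability_nde",
                "median_power", "stability_power")])

# replicate-vs-depth trade-off at a fixed total read budget (~1 M reads)
view <- equal_budget_view(summary, total_reads = 1e6, tolerance = 0.25)
message("equal-budget comparison (~1 M total reads): ",
        attr(view, "dominance"), " dominate(s)")
print(view[, c("r", "depth", "median_power", "stability_power")])

gap <- power_stability_gap(100 * view$median_power[1],
                           100 * view$stability_power[1])
message("power minus stability power at the smallest r: ",
        round(gap, 1), " percentage points")
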
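# Orchestration of the (replicate number x depth) evaluation grid.

#' Run the replicate-by-depth subsampling grid
#'
#' For every combination of replicate number `r` (from
#' `params$replicate_grid`) and target depth `d` (from `params$depth_grid`)
#' and every repetition: subsample `r` replicates per condition without
#' replacement, thin each retained sample to `d` reads, run the DE pipeline
#' (the common/tagwise dispersion-mode rule applies per cell), and record the
#' genes declared DE at `params$alpha_de`. When `r` equals the number of
#' available replicates there is only one possible replicate draw, so that
#' configuration is run once. Per-cell seeds are derived from
#' `params$master_seed` and the cell's indices, so cells are reproducible and
#' computable in any order.
#'
#' @param counts Pilot count matrix.
#' @param design Pilot design.
#' @param params An [analysis_params()] object.
#' @param pair Two condition labels (default: the design's two conditions).
#' @return List of grid cells (class `grid_cells`); each cell is a list with
#'   `r`, `depth`, `repetition`, `seed`, `dispersion_mode`, `de_set`.
#' @export
run_grid <- function(counts, design, params = analysis_params(), pair = NULL) {
  validate_design(design, counts)
  if (is.null(pair)) {
    conds <- unique(design$condition)
    if (length(conds) != 2L) stop("design has ", length(conds),
                                  " conditions; supply 'pair'")
    pair <- conds
  }
  avail <- vapply(pair, function(cond)
    length(.condition_samples(counts, design, cond)), integer(1L))
  if (max(params$replicate_grid) > min(avail)) {
    stop("replicate_grid exceeds available replicates (",
         min(avail), " in condition '", pair[which.min(avail)], "')")
  }
  min_depth_cap <- max(colSums(counts))
  if (any(params$depth_grid > min_depth_cap)) {
    stop("depth_grid exceeds every observed library size")
  }

  cells <- list()
  for (ri in seq_along(params$replicate_grid)) {
    r <- params$replicate_grid[ri]
    # full-data configuration: only one possible replicate draw
    n_rep <- if (all(avail == r)) 1L else params$n_repetitions
    for (di in seq_along(params$depth_grid)) {
      d <- params$depth_grid[di]
      for (rep_i in seq_len(n_rep)) {
        seed_sub <- derive_seed(params$master_seed, 1L, ri, di, rep_i)
        seed_thin <- derive_seed(params$master_seed, 2L, ri, di, rep_i)
        sub <- subsample_replicates(counts, design, r, seed_sub)
        thinned <- thin_counts(sub$counts, d, seed_thin)
        res <- run_de(thinned, sub$design, params, pair)
        prov <- attr(res, "provenance")
        cells[[length(cells) + 1L]] <- list(
          r = r, depth = d, repetition = rep_i, seed = seed_sub,
          dispersion_mode = prov$dispersion_mode,
          de_set = res$gene[res$padj < params$alpha_de])
      }
    }
  }
  structure(cells, class = "grid_cells")
}

#' Aggregate per-cell DE gene sets into indicator summaries
#'
#' Per (r, depth): the median over repetitions of the number of DE genes,
#' the stability (size of the intersection of the block's DE sets), the
#' median power against `reference`, and the stability power (power of the
#' intersection). When `strata` labels are supplied, the same four
#' indicators are also computed restricted to the low- and high-expression
#' strata by first intersecting every DE set and the reference with the
#' stratum's genes.
#'
#' @param cells Output of [run_grid()].
#' @param reference Full-data reference DE gene set (non-empty).
#' @param strata Optional named factor from [expression_strata()].
#' @return Data frame with one row per (r, depth).
#' @export
aggregate_indicators <- function(cells, reference, strata = NULL) {
  if (!length(cells)) stop("no grid cells")
  key <- vapply(cells, function(cell) paste(cell$r, cell$depth), character(1L))
  out <- list()
  for (k in unique(key)) {
    block <- cells[key == k]
    reps <- sort(as.integer(vapply(block, function(cell)
      as.numeric(cell$repetition), numeric(1L))))
    expected <- seq_len(max(reps))
    if (!identical(reps, expected)) {
      stop("missing repetition(s) ", paste(setdiff(expected, reps),
                                           collapse = ", "),
           " for cell (r = ", block[[1L]]$r, ", depth = ",
           block[[1L]]$depth, ")")
    }
    sets <- lapply(block, `[[`, "de_set")
    row <- data.frame(r = block[[1L]]$r, depth = block[[1L]]$depth,
                      .block_indicators(sets, reference))
    if (!is.null(strata)) {
      for (level in c("low", "high")) {
        genes <- names(strata)[strata == level]
        sub_sets <- lapply(sets, intersect, genes)
        sub_ref <- intersect(reference, genes)
        ind <- .block_indicators(sub_sets, sub_ref)
        names(ind) <- paste0(names(ind), "_", level)
        row <- cbind(row, ind)
      }
    }
    out[[k]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$r, res$depth), , drop = FALSE]
}

.block_indicators <- function(sets, reference) {
  common <- stability_set(sets)
  has_ref <- length(reference) > 0
  data.frame(
    median_nde = stats::median(lengths(sets)),
    stability_nde = length(common),
    median_power = if (has_ref)
      stats::median(vapply(sets, de_power, numeric(1L),
                           reference = reference)) else NA_real_,
    stability_power = if (has_ref) de_power(common, reference) else NA_real_)
}

#' Equal-budget comparison of replicate/depth combinations
#'
#' Selects the grid combinations whose total read budget `r * depth` lies
#' within `tolerance` of `total_reads`, orders them by replicate number
#' ascending (depth therefore descending), and attaches their indicator
#' values. The attached `dominance` attribute classifies the trade-off from
#' the association between the indicator and `r` along the list: indicators
#' improving with more replicates (at constant total reads) mean the
#' replicate number dominates the library size, and vice versa.
#'
#' @param summary Output of [aggregate_indicators()].
#' @param total_reads Total read budget (e.g. 4e7).
#' @param tolerance Relative tolerance on the budget (default 0.15).
#' @param indicator Summary column used for the dominance call
#'   (default `"median_power"`).
#' @return The qualifying summary rows sorted by `r`, with attribute
#'   `dominance` in `c("replicates", "depth", "balanced")`.
#' @export
equal_budget_view <- function(summary, total_reads, tolerance = 0.15,
                              indicator = "median_power") {
  budget <- summary$r * summary$depth
  keep <- abs(budget - total_reads) <= tolerance * total_reads
  if (sum(keep) < 2L) {
    stop("fewer than two grid combinations within ", tolerance * 100,
         "% of a ", total_reads, "-read budget")
  }
  view <- summary[keep, , drop = FALSE]
  view <- view[order(view$r), , drop = FALSE]
  rho <- suppressWarnings(stats::cor(view$r, view[[indicator]],
                                     method = "spearman"))
  dominance <- if (is.na(rho) || rho == 0) "balanced"
  else if (rho > 0) "replicates" else "depth"
  attr(view, "dominance") <- dominance
  view
}
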
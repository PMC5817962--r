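# Sampling devices for the design evaluation: replicate subsetting, count
# thinning to a target library size, and multinomial pseudo-replicates.

#' Subsample replicates without replacement
#'
#' Draws exactly `r` samples per condition, uniformly without replacement and
#' independently per condition. Column order of the result follows the
#' original matrix, so drawing all available replicates returns the input in
#' canonical order.
#'
#' @param counts Count matrix (genes x samples).
#' @param design Design data frame (`sample`, `condition`).
#' @param r Number of replicates to keep per condition (>= 2).
#' @param seed Integer RNG seed.
#' @return List with subsetted `counts` and `design`.
#' @export
subsample_replicates <- function(counts, design, r, seed) {
  validate_design(design, counts)
  if (r < 2L) stop("r must be >= 2")
  set.seed(seed)
  chosen <- character(0)
  for (cond in unique(design$condition)) {
    ids <- .condition_samples(counts, design, cond)
    if (length(ids) < r) {
      stop("condition '", cond, "' has ", length(ids),
           " replicates, fewer than r = ", r)
    }
    chosen <- c(chosen, sample(ids, r))
  }
  keep <- colnames(counts)[colnames(counts) %in% chosen]
  list(counts = counts[, keep, drop = FALSE],
       design = design[match(keep, design$sample), , drop = FALSE])
}

#' Thin counts to a target library size
#'
#' Per column, draws exactly `target` reads without replacement from the
#' column's reads (a multivariate hypergeometric draw over genes), so thinned
#' counts never exceed the originals and every thinned column sums exactly to
#' `target`. Columns already at or below `target` pass through unchanged,
#' with a warning for those strictly below. This count-level thinning matches
#' read-level subsampling of the aligned reads in distribution.
#'
#' @param counts Count matrix.
#' @param target Reads per sample after thinning (>= 0).
#' @param seed Integer RNG seed.
#' @return Thinned count matrix of the same shape.
#' @export
thin_counts <- function(counts, target, seed) {
  if (target < 0) stop("target must be >= 0")
  set.seed(seed)
  target <- as.integer(round(target))
  out <- counts
  totals <- colSums(counts)
  low <- totals < target
  if (any(low)) {
    warning("column(s) below target left unchanged: ",
            paste(colnames(counts)[low], collapse = ", "))
  }
  for (j in which(totals > target)) {
    out[, j] <- .thin_column(counts[, j], target)
  }
  out
}

# Sequential conditional hypergeometric draw: gene i receives
# Hypergeometric(y_i, remaining others, reads still to draw).
.thin_column <- function(y, target) {
  out <- integer(length(y))
  rem <- sum(y)
  k <- target
  for (i in seq_along(y)) {
    if (k == 0L) break
    yi <- y[i]
    if (yi == 0L) next
    rem <- rem - yi
    if (rem == 0L) {
      out[i] <- as.integer(k)
      break
    }
    d <- stats::rhyper(1L, yi, rem, k)
    out[i] <- as.integer(d)
    k <- k - d
  }
  out
}

#' Simulate pseudo-replicates of one biological condition
#'
#' For each new replicate: draw independent uniform coefficients (one per
#' source replicate), normalize them to sum to one, form the corresponding
#' convex combination of the source columns' gene proportions, and draw the
#' counts from a multinomial with that probability vector and `target`
#' reads. Pseudo-replicates therefore preserve the condition's mean
#' expression profile (means and between-replicate variation enter through
#' the random mixing weights) and have column sums exactly `target`.
#'
#' @param condition_matrix Count matrix of the source replicates of a single
#'   condition (genes x replicates, >= 1 column, no all-zero column).
#' @param n_new Number of pseudo-replicates to simulate.
#' @param target Library size (reads) of each pseudo-replicate.
#' @param seed Integer RNG seed.
#' @return Integer matrix (genes x `n_new`) with columns `sim_1`, `sim_2`, ...
#' @export
simulate_pseudo_replicates <- function(condition_matrix, n_new, target, seed) {
  if (n_new < 1L) stop("n_new must be >= 1")
  if (target < 1) stop("target must be >= 1")
  totals <- colSums(condition_matrix)
  if (any(totals == 0)) stop("all-zero source column(s): ",
                             paste(colnames(condition_matrix)[totals == 0],
                                   collapse = ", "))
  set.seed(seed)
  props <- sweep(condition_matrix, 2L, totals, "/")
  k <- ncol(props)
  out <- matrix(0L, nrow = nrow(condition_matrix), ncol = n_new,
                dimnames = list(rownames(condition_matrix),
                                paste0("sim_", seq_len(n_new))))
  for (j in seq_len(n_new)) {
    u <- stats::runif(k)
    w <- u / sum(u)
    p <- as.vector(props %*% w)
    out[, j] <- stats::rmultinom(1L, size = round(target), prob = p)
  }
  out
}
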
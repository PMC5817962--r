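# ROC curves over the FDR-threshold grid, optimal-threshold extraction and
# the threshold-vs-replicate-number fit.

#' ROC curve over BH-threshold values against a truth list
#'
#' For each threshold `t`, genes with adjusted p-value strictly below `t` are
#' declared DE and (FPR, TPR) are computed against `truth` via
#' [confusion_rates()]. The default threshold grid is the sorted distinct
#' adjusted p-values of the result augmented with the decade points
#' 0.0025, 0.005, 0.01, 0.025, 0.05, 0.1, 0.25, 0.5, 1, plus 0 and a point
#' just above 1 so the curve reaches (1, 1).
#'
#' @param result A `de_result`.
#' @param truth Truth gene set (non-empty proper subset of the genes).
#' @param thresholds Optional numeric threshold grid.
#' @return Data frame of class `roc_curve` with columns `threshold`, `fpr`,
#'   `tpr`, sorted by threshold.
#' @export
roc_curve <- function(result, truth, thresholds = NULL) {
  universe <- result$gene
  truth <- unique(truth)
  if (!length(truth) || length(truth) >= length(universe)) {
    stop("need 0 < |truth| < number of genes")
  }
  if (length(setdiff(truth, universe))) stop("truth must be a subset of the genes")
  if (is.null(thresholds)) {
    decades <- c(0.0025, 0.005, 0.01, 0.025, 0.05, 0.1, 0.25, 0.5, 1)
    thresholds <- c(0, result$padj, decades, 1 + 1e-9)
  }
  thresholds <- sort(unique(thresholds))
  is_truth <- result$gene %in% truth
  x_t <- sort(result$padj[is_truth])
  x_f <- sort(result$padj[!is_truth])
  # strict declaration: count of padj < t
  tp <- findInterval(thresholds, x_t, left.open = TRUE)
  fp <- findInterval(thresholds, x_f, left.open = TRUE)
  curve <- data.frame(threshold = thresholds,
                      fpr = fp / length(x_f),
                      tpr = tp / length(x_t))
  class(curve) <- c("roc_curve", "data.frame")
  curve
}

#' Optimal FDR threshold of a ROC curve
#'
#' Default criterion is Youden's J = TPR - FPR; `"corner"` minimizes the
#' Euclidean distance to the perfect-classification corner (0, 1). Ties
#' (within 1e-12) are broken by the smallest threshold.
#'
#' @param curve A [roc_curve()].
#' @param criterion `"youden"` or `"corner"`.
#' @return The optimal threshold (scalar).
#' @export
optimal_threshold <- function(curve, criterion = c("youden", "corner")) {
  criterion <- match.arg(criterion)
  score <- if (criterion == "youden") {
    curve$tpr - curve$fpr
  } else {
    -sqrt(curve$fpr^2 + (1 - curve$tpr)^2)
  }
  best <- max(score)
  min(curve$threshold[score >= best - 1e-12])
}

#' Fit the optimal-threshold vs replicate-number relationship
#'
#' Ordinary least squares of `log2(threshold)` on the replicate number `r`.
#' An empirical `2^-r` law corresponds to slope -1 and intercept 0.
#'
#' @param pairs Data frame with columns `r` and `threshold` (>= 2 distinct
#'   `r` values, thresholds > 0).
#' @return List with `slope`, `intercept` and the fitted `lm` object.
#' @export
fit_threshold_vs_replicates <- function(pairs) {
  if (length(unique(pairs$r)) < 2L) stop("need >= 2 distinct replicate numbers")
  if (any(pairs$threshold <= 0)) stop("thresholds must be positive")
  fit <- stats::lm(log2(threshold) ~ r, data = pairs)
  coefs <- stats::coef(fit)
  list(slope = unname(coefs["r"]), intercept = unname(coefs["(Intercept)"]),
       fit = fit)
}

#' Median Youden-optimal thresholds over replicate subsamples
#'
#' Convenience driver for the threshold-vs-replicates analysis: for each
#' replicate number in `r_values`, draws `n_repetitions` random replicate
#' subsamples of the pilot, runs the DE pipeline, computes the ROC against
#' `truth`, extracts the optimal threshold, and reports the median per `r`.
#'
#' @param counts,design Pilot data (two conditions).
#' @param truth Truth gene set (full-data DE at a stringent threshold).
#' @param r_values Replicate numbers to evaluate.
#' @param n_repetitions Subsamples per replicate number (default 30).
#' @param seed Integer seed; repetition `j` at `r_values[i]` uses
#'   `derive_seed(seed, i, j)`.
#' @param params [analysis_params()] passed to [run_de()].
#' @param criterion Passed to [optimal_threshold()].
#' @return Data frame with columns `r` and `threshold` (median optimal
#'   threshold), suitable for [fit_threshold_vs_replicates()].
#' @export
optimal_threshold_by_replicates <- function(counts, design, truth, r_values,
                                            n_repetitions = 30L, seed = 1L,
                                            params = analysis_params(),
                                            criterion = "youden") {
  rows <- lapply(seq_along(r_values), function(i) {
    r <- r_values[i]
    thr <- vapply(seq_len(n_repetitions), function(j) {
      sub <- subsample_replicates(counts, design, r, derive_seed(seed, i, j))
      res <- run_de(sub$counts, sub$design, params)
      optimal_threshold(roc_curve(res, truth), criterion = criterion)
    }, numeric(1L))
    data.frame(r = r, threshold = stats::median(thr))
  })
  do.call(rbind, rows)
}
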
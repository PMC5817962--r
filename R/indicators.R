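# Evaluation statistics: reference/truth lists, power, confusion rates,
# stability, expression strata and mock within-condition FPR.
#
# All threshold comparisons are strict (padj < alpha).

#' Reference and truth DE gene sets
#'
#' `reference_de_set` extracts the power reference list: genes of a
#' *full-data* DE result with adjusted p-value strictly below
#' `alpha_reference` (a very stringent threshold, default 1e-4).
#' `truth_de_set` does the same at `alpha_truth` (default 1e-3) to form the
#' estimated list of truly DE genes used for TPR/FPR calculations.
#'
#' @param full_result A `de_result` from the complete pilot data.
#' @param alpha_reference,alpha_truth Strict adjusted-p thresholds.
#' @return Character vector of gene ids.
#' @export
reference_de_set <- function(full_result, alpha_reference = 1e-4) {
  full_result$gene[full_result$padj < alpha_reference]
}

#' @rdname reference_de_set
#' @export
truth_de_set <- function(full_result, alpha_truth = 1e-3) {
  full_result$gene[full_result$padj < alpha_truth]
}

#' Power of a declared DE gene set against a reference list
#'
#' Fraction of the reference list recovered:
#' `|declared intersect reference| / |reference|`.
#'
#' @param declared Declared DE gene set.
#' @param reference Non-empty reference gene set.
#' @return Fraction in `[0, 1]`.
#' @export
de_power <- function(declared, reference) {
  if (!length(reference)) stop("reference set is empty")
  length(intersect(declared, reference)) / length(unique(reference))
}

#' Confusion rates against a truth list
#'
#' TPR = true positives / `|truth|`; FPR = false positives /
#' `|universe| - |truth|`; TNR = 1 - FPR exactly.
#'
#' @param declared Declared DE gene set (subset of `universe`).
#' @param truth Estimated truly-DE gene set (non-empty, proper subset of
#'   `universe`).
#' @param universe All genes tested.
#' @return List of class `confusion_rates` with `tpr`, `fpr`, `tnr` and the
#'   underlying counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_rates <- function(declared, truth, universe) {
  declared <- unique(declared); truth <- unique(truth)
  universe <- unique(universe)
  if (length(setdiff(truth, universe))) stop("truth must be a subset of universe")
  if (length(setdiff(declared, universe))) stop("declared must be a subset of universe")
  if (!length(truth) || length(truth) >= length(universe)) {
    stop("need 0 < |truth| < |universe|")
  }
  tp <- length(intersect(declared, truth))
  fp <- length(declared) - tp
  fn <- length(truth) - tp
  tn <- length(universe) - tp - fp - fn
  fpr <- fp / (length(universe) - length(truth))
  structure(list(tpr = tp / length(truth), fpr = fpr, tnr = 1 - fpr,
                 tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_rates")
}

#' Stability set: genes common to every repeated analysis
#'
#' @param sets Non-empty list of gene sets (character vectors).
#' @return Their intersection.
#' @export
stability_set <- function(sets) {
  if (!length(sets)) stop("need at least one gene set")
  Reduce(intersect, sets)
}

#' Expression strata from mean logCPM
#'
#' Genes are labelled `low` (mean logCPM strictly below the first quartile),
#' `high` (strictly above the third quartile) or `medium` (in between);
#' quartiles use linear-interpolation quantiles. With all values tied every
#' gene is `medium`.
#'
#' @param mean_logcpm Named per-gene mean logCPM values (>= 4 genes).
#' @return Named factor with levels `low`, `medium`, `high`.
#' @export
expression_strata <- function(mean_logcpm) {
  if (length(mean_logcpm) < 4L) stop("need >= 4 genes")
  q <- stats::quantile(mean_logcpm, c(0.25, 0.75), names = FALSE, type = 7)
  lab <- rep("medium", length(mean_logcpm))
  lab[mean_logcpm < q[1L]] <- "low"
  lab[mean_logcpm > q[2L]] <- "high"
  factor(stats::setNames(lab, names(mean_logcpm)),
         levels = c("low", "medium", "high"))
}

#' Mock within-condition false positive rate
#'
#' Repeatedly splits the replicates of a single biological condition into
#' two disjoint groups of size `group_size`, runs the full DE pipeline on
#' each mock contrast, and reports the fraction of all genes declared DE at
#' `alpha_fpr` -- every declaration is a false positive by construction,
#' since both groups come from the same condition.
#'
#' @param condition_matrix Count matrix of one condition's replicates.
#' @param group_size Replicates per mock group `k` (condition needs >= 2k).
#' @param n_splits Number of random splits (default 30).
#' @param alpha_fpr Strict adjusted-p threshold (default 0.01).
#' @param seed Integer seed; split `i` uses `derive_seed(seed, i)`.
#' @param params [analysis_params()] passed to [run_de()].
#' @return Numeric vector of per-split FPR values.
#' @export
mock_null_fpr <- function(condition_matrix, group_size, n_splits = 30L,
                          alpha_fpr = 0.01, seed = 1L,
                          params = analysis_params()) {
  m <- ncol(condition_matrix)
  if (2L * group_size > m) {
    stop("2 * group_size = ", 2L * group_size, " exceeds the ", m,
         " available replicates")
  }
  vapply(seq_len(n_splits), function(i) {
    set.seed(derive_seed(seed, i))
    chosen <- sample(colnames(condition_matrix), 2L * group_size)
    g1 <- chosen[seq_len(group_size)]
    g2 <- chosen[group_size + seq_len(group_size)]
    sub <- condition_matrix[, c(g1, g2), drop = FALSE]
    design <- data.frame(sample = c(g1, g2),
                         condition = rep(c("mock1", "mock2"),
                                         each = group_size),
                         stringsAsFactors = FALSE)
    res <- run_de(sub, design, params, pair = c("mock1", "mock2"))
    mean(res$padj < alpha_fpr)
  }, numeric(1L))
}

#' Worked-example helpers on reported indicator pairs
#'
#' `replicate_specific_fraction` is the fraction of declared DE genes that
#' are specific to the particular replicates drawn, computed from a median
#' DE-gene count and the corresponding stability count:
#' `(n_de - stability) / n_de`. `power_stability_gap` is the gap between the
#' median power and the stability power (percentage points when inputs are
#' percentages).
#'
#' @param n_de Median number of DE genes at one design setting.
#' @param stability Number of DE genes common to all repetitions.
#' @param power_median,power_stability Median power and stability power.
#' @return A single number.
#' @export
replicate_specific_fraction <- function(n_de, stability) {
  if (n_de <= 0) stop("n_de must be positive")
  if (stability > n_de) stop("stability cannot exceed n_de")
  (n_de - stability) / n_de
}

#' @rdname replicate_specific_fraction
#' @export
power_stability_gap <- function(power_median, power_stability) {
  power_median - power_stability
}
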
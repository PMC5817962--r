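# Meta-analysis stage: descriptors of pairwise contrasts and pseudo-replicate
# DE-count surfaces across replicate numbers and library sizes.

#' Descriptors of one pairwise contrast
#'
#' Summarizes a two-condition comparison by: the rounded (half away from
#' zero) mean number of replicates per condition; the mean library size per
#' replicate; the mean absolute distance between the two condition mean
#' expressions (logCPM scale, averaged over genes); the mean over genes of
#' the average of the two within-condition variances (logCPM scale); and the
#' number of DE genes at `alpha_de` from the exact-test pipeline. When a
#' condition has fewer than two replicates the descriptors are still
#' computed but `n_de` is `NA` (no valid DE contrast).
#'
#' @param counts Count matrix.
#' @param design Design data frame.
#' @param pair Two condition labels.
#' @param alpha_de Strict adjusted-p threshold for the DE count
#'   (default 0.05).
#' @param params [analysis_params()] used for the DE run.
#' @return One-row data frame: `condition_a`, `condition_b`, `r_mean`,
#'   `mean_library_size`, `distance`, `variance`, `n_de`.
#' @export
contrast_descriptors <- function(counts, design, pair, alpha_de = 0.05,
                                 params = analysis_params()) {
  validate_design(design, counts)
  idx_a <- .condition_samples(counts, design, pair[1L])
  idx_b <- .condition_samples(counts, design, pair[2L])
  if (!length(idx_a) || !length(idx_b)) stop("pair condition absent from design")
  keep <- c(idx_a, idx_b)
  sub <- counts[, keep, drop = FALSE]
  factors <- tmm_factors(sub)
  lc <- log_cpm(sub, factors)
  m_a <- rowMeans(lc[, idx_a, drop = FALSE])
  m_b <- rowMeans(lc[, idx_b, drop = FALSE])
  var_of <- function(block, m) {
    n <- ncol(block)
    if (n < 2L) return(rep(NA_real_, nrow(block)))
    rowSums((block - m)^2) / (n - 1)
  }
  v_a <- var_of(lc[, idx_a, drop = FALSE], m_a)
  v_b <- var_of(lc[, idx_b, drop = FALSE], m_b)
  n_de <- NA_integer_
  if (length(idx_a) >= 2L && length(idx_b) >= 2L) {
    res <- run_de(counts, design, params, pair)
    n_de <- sum(res$padj < alpha_de)
  }
  data.frame(condition_a = pair[1L], condition_b = pair[2L],
             r_mean = .round_half_away(mean(c(length(idx_a), length(idx_b)))),
             mean_library_size = mean(colSums(sub)),
             distance = mean(abs(m_a - m_b)),
             variance = mean((v_a + v_b) / 2),
             n_de = n_de,
             stringsAsFactors = FALSE)
}

# round() halves to even; the descriptor uses half away from zero.
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Pseudo-replicate DE-count surface over condition pairs
#'
#' For every unordered pair of conditions, every replicate number in
#' `r_values`, every library size and every repetition: simulate that many
#' pseudo-replicates per condition (multinomial draws from a random convex
#' combination of the condition's real replicates, see
#' [simulate_pseudo_replicates()]), run the DE pipeline on the
#' all-pseudo-replicate contrast, and record the number of DE genes at
#' `params$alpha_de`. The output has exactly
#' `pairs * |r_values| * |library_sizes| * n_sim` rows.
#'
#' @param conditions Named list of count matrices, one per biological
#'   condition (>= 2 replicates each).
#' @param r_values Pseudo-replicate numbers per condition.
#' @param library_sizes Pseudo-replicate library sizes (reads).
#' @param n_sim Repetitions per combination (default 3).
#' @param params [analysis_params()] (supplies `alpha_de`).
#' @param seed Integer master seed.
#' @return Long-format data frame: `condition_a`, `condition_b`, `r`,
#'   `library_size`, `repetition`, `n_de`.
#' @export
meta_grid <- function(conditions, r_values, library_sizes, n_sim = 3L,
                      params = analysis_params(), seed = 1L) {
  if (length(conditions) < 2L) stop("need >= 2 conditions")
  if (is.null(names(conditions)) || anyDuplicated(names(conditions))) {
    stop("conditions must be a uniquely named list")
  }
  for (nm in names(conditions)) {
    if (ncol(conditions[[nm]]) < 2L) {
      stop("condition '", nm, "' needs >= 2 source replicates")
    }
  }
  if (any(r_values < 2L)) stop("r_values must be >= 2")
  if (any(library_sizes < 1)) stop("library_sizes must be positive")

  pairs <- utils::combn(names(conditions), 2L)
  rows <- list()
  for (pi in seq_len(ncol(pairs))) {
    cond_a <- pairs[1L, pi]
    cond_b <- pairs[2L, pi]
    for (ri in seq_along(r_values)) {
      r <- r_values[ri]
      for (si in seq_along(library_sizes)) {
        size <- library_sizes[si]
        for (sim in seq_len(n_sim)) {
          sim_a <- simulate_pseudo_replicates(
            conditions[[cond_a]], r, size,
            derive_seed(seed, 1L, pi, ri, si, sim))
          sim_b <- simulate_pseudo_replicates(
            conditions[[cond_b]], r, size,
            derive_seed(seed, 2L, pi, ri, si, sim))
          colnames(sim_a) <- paste0("a_", seq_len(r))
          colnames(sim_b) <- paste0("b_", seq_len(r))
          counts <- cbind(sim_a, sim_b)
          design <- data.frame(sample = colnames(counts),
                               condition = rep(c(cond_a, cond_b), each = r),
                               stringsAsFactors = FALSE)
          res <- run_de(counts, design, params, pair = c(cond_a, cond_b))
          rows[[length(rows) + 1L]] <- data.frame(
            condition_a = cond_a, condition_b = cond_b, r = r,
            library_size = size, repetition = sim,
            n_de = sum(res$padj < params$alpha_de),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quantile summary of a meta-grid table
#'
#' Minimum, quartiles, median and maximum of the DE-gene count per
#' (replicate number, library size), pooled over condition pairs and
#' repetitions -- the aggregation behind "minimum number of DE genes one is
#' almost sure to obtain" readings.
#'
#' @param table Output of [meta_grid()].
#' @return Data frame with one row per (r, library_size).
#' @export
meta_grid_summary <- function(table) {
  key <- interaction(table$r, table$library_size, drop = TRUE)
  rows <- lapply(split(table, key), function(block) {
    q <- stats::quantile(block$n_de, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(r = block$r[1L], library_size = block$library_size[1L],
               min = q[1L], q1 = q[2L], median = q[3L], q3 = q[4L],
               max = q[5L])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$r, out$library_size), , drop = FALSE]
  rownames(out) <- NULL
  out
}
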
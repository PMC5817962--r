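# Negative-binomial exact-test DE engine.
#
# Pipeline per contrast: TMM normalization -> logCPM -> conditional-likelihood
# dispersion (common, or tagwise with weighted-likelihood shrinkage) ->
# sum-conditioned two-sided exact test on library-equalized pseudo-counts ->
# Benjamini-Hochberg adjustment. The dispersion and exact-test stages work on
# pseudo-counts obtained by deterministically rescaling each column to the
# geometric-mean effective library size and rounding, which removes the
# library-size nuisance from the conditional likelihood.

DISPERSION_LOWER <- 1e-6
DISPERSION_UPPER <- 10

#' TMM normalization factors
#'
#' Trimmed mean of M-values against a reference sample. The reference is the
#' column whose 75th-percentile count proportion is closest to the mean of
#' those percentiles. For each sample, gene-wise log2 fold changes `M` and
#' average log2 abundances `A` are computed against the reference on genes
#' positive in both; the most extreme 30 percent of `M` from each tail and 5
#' percent of `A` from each tail are trimmed, and the factor is two to the
#' power of the weighted mean of the surviving `M`, with weights equal to the
#' inverse asymptotic binomial variance
#' `(N_j - y_gj) / (N_j y_gj) + (N_r - y_gr) / (N_r y_gr)` inverted.
#' Factors are rescaled so their geometric mean is exactly one. If fewer than
#' 10 genes survive trimming for a sample, its factor falls back to 1 with a
#' warning.
#'
#' @param counts Count matrix with >= 2 samples.
#' @param trim_m,trim_a Tail trim fractions for `M` and `A` (defaults 0.30
#'   and 0.05; set to 0 to disable trimming).
#' @param ref_column Optional reference column index or name; default is the
#'   75th-percentile rule above.
#' @return Named numeric vector of per-sample scale factors (geometric mean
#'   1). Effective library size of sample j is `colSums(counts)[j] * f[j]`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                        ref_column = NULL) {
  if (ncol(counts) < 2L) stop("TMM needs >= 2 samples")
  N <- colSums(counts)
  if (any(N == 0)) stop("all-zero sample column(s)")
  if (!any(rowSums(counts > 0) == ncol(counts))) {
    stop("no gene with positive counts in all samples")
  }
  q75 <- apply(counts, 2L, function(y) stats::quantile(y / sum(y), 0.75,
                                                       names = FALSE))
  if (is.null(ref_column)) {
    ref <- which.min(abs(q75 - mean(q75)))
  } else if (is.character(ref_column)) {
    ref <- match(ref_column, colnames(counts))
  } else {
    ref <- as.integer(ref_column)
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair_factor(counts[, j], counts[, ref], N[j], N[ref],
                     trim_m, trim_a, colnames(counts)[j])
  }, numeric(1L))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

.tmm_pair_factor <- function(y, yr, Nj, Nr, trim_m, trim_a, label) {
  keep <- y > 0 & yr > 0
  y <- as.numeric(y[keep]); yr <- as.numeric(yr[keep])
  if (!length(y)) {
    warning("no shared positive genes for sample ", label, "; factor set to 1")
    return(1)
  }
  p <- y / Nj
  pr <- yr / Nr
  M <- log2(p / pr)
  A <- 0.5 * log2(p * pr)
  # inverse asymptotic binomial variance of M
  w <- 1 / ((Nj - y) / (Nj * y) + (Nr - yr) / (Nr * yr))
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rM <- rank(M)
  rA <- rank(A)
  kept <- rM >= lo_m & rM <= hi_m & rA >= lo_a & rA <= hi_a
  if ((trim_m > 0 || trim_a > 0) && sum(kept) < 10L) {
    warning("fewer than 10 genes survive TMM trimming for sample ", label,
            "; factor set to 1")
    return(1)
  }
  2^(sum(w[kept] * M[kept]) / sum(w[kept]))
}

#' log2 counts per million
#'
#' `logCPM_gj = log2((y_gj + prior) / (N_j f_j + 2 prior) * 1e6)` with
#' effective library sizes from the TMM factors. The prior count keeps zero
#' counts finite.
#'
#' @param counts Count matrix.
#' @param factors Normalization factors from [tmm_factors()].
#' @param prior_count Prior count (default 0.5).
#' @return Numeric matrix of logCPM values, same shape as `counts`.
#' @export
log_cpm <- function(counts, factors, prior_count = 0.5) {
  eff <- colSums(counts) * factors
  log2(sweep(counts + prior_count, 2L, eff + 2 * prior_count, "/") * 1e6)
}

# Library-equalized pseudo-counts: rescale each column to the geometric mean
# of the effective library sizes and round. Deterministic.
.pseudo_counts <- function(counts, factors) {
  eff <- colSums(counts) * factors
  n_star <- exp(mean(log(eff)))
  pseudo <- round(sweep(counts, 2L, n_star / eff, "*"))
  list(pseudo = pseudo, common_size = n_star)
}

# Per-gene NB conditional log-likelihood of within-group counts given their
# sum, for one group of equal-mean replicates (phi-dependent terms only).
# Y: genes x replicates pseudo-counts; phi: scalar or per-gene vector.
.group_cond_loglik <- function(Y, phi) {
  n <- ncol(Y)
  r <- 1 / phi
  z <- rowSums(Y)
  rowSums(lgamma(Y + r)) - n * lgamma(r) + lgamma(n * r) - lgamma(z + n * r)
}

# Summed conditional log-likelihood over all genes and all usable groups.
.cond_loglik_total <- function(group_mats, phi) {
  total <- 0
  for (Y in group_mats) total <- total + sum(.group_cond_loglik(Y, phi))
  total
}

# Split pseudo-counts into per-condition matrices with >= 2 replicates.
.usable_groups <- function(pseudo, design) {
  groups <- list()
  for (cond in unique(design$condition)) {
    ids <- .condition_samples(pseudo, design, cond)
    if (length(ids) >= 2L) groups[[cond]] <- pseudo[, ids, drop = FALSE]
  }
  if (!length(groups)) stop("no condition with >= 2 replicates")
  groups
}

#' Common NB dispersion by conditional maximum likelihood
#'
#' Counts are first rescaled to a common effective library size
#' (geometric mean) as pseudo-counts; the common dispersion maximizes the
#' conditional log-likelihood of the within-condition pseudo-counts given
#' their sums, summed over genes and over all conditions with at least two
#' replicates. One-dimensional maximization on the log scale over
#' `[1e-6, 10]` with tolerance 1e-4 in log space.
#'
#' @param counts Count matrix.
#' @param design Design data frame.
#' @param factors TMM factors.
#' @return The common dispersion estimate (scalar).
#' @export
estimate_common_dispersion <- function(counts, design, factors) {
  validate_design(design, counts)
  pseudo <- .pseudo_counts(counts, factors)$pseudo
  groups <- .usable_groups(pseudo, design)
  bounds <- log(c(DISPERSION_LOWER, DISPERSION_UPPER))
  obj <- function(lphi) .cond_loglik_total(groups, exp(lphi))
  opt <- stats::optimize(obj, interval = bounds, maximum = TRUE, tol = 1e-4)
  # optimize() never quite reaches the interval ends; take the best of the
  # interior optimum and the two bounds so boundary solutions are exact.
  cand <- c(opt$maximum, bounds)
  vals <- c(opt$objective, obj(bounds[1L]), obj(bounds[2L]))
  exp(cand[which.max(vals)])
}

#' Tagwise NB dispersions by weighted conditional likelihood
#'
#' Per gene, the dispersion maximizes the gene's own conditional
#' log-likelihood plus `prior_weight` times the average per-gene conditional
#' log-likelihood across all genes (the pooled likelihood whose maximizer is
#' the common dispersion), shrinking each gene-wise estimate toward the
#' common value; `prior_weight` is in pseudo-gene units. Maximization is a
#' dense log-scale grid search over `[1e-6, 10]` followed by one parabolic
#' interpolation step, vectorized across genes.
#'
#' @param counts Count matrix.
#' @param design Design data frame.
#' @param factors TMM factors.
#' @param phi_common Common dispersion (used only for degenerate inputs).
#' @param prior_weight Shrinkage weight (default 10).
#' @param ngrid Number of grid points (default 240).
#' @return Numeric vector of per-gene dispersions.
#' @export
estimate_tagwise_dispersion <- function(counts, design, factors, phi_common,
                                        prior_weight = 10, ngrid = 240L) {
  validate_design(design, counts)
  pseudo <- .pseudo_counts(counts, factors)$pseudo
  groups <- .usable_groups(pseudo, design)
  G <- nrow(counts)
  lgrid <- seq(log(DISPERSION_LOWER), log(DISPERSION_UPPER),
               length.out = ngrid)
  h <- lgrid[2L] - lgrid[1L]
  cll <- matrix(0, nrow = G, ncol = ngrid)
  for (k in seq_len(ngrid)) {
    phi <- exp(lgrid[k])
    for (Y in groups) cll[, k] <- cll[, k] + .group_cond_loglik(Y, phi)
  }
  penalty <- colMeans(cll)
  score <- cll + matrix(prior_weight * penalty, G, ngrid, byrow = TRUE)
  imax <- max.col(score, ties.method = "first")
  lphi <- lgrid[imax]
  interior <- imax > 1L & imax < ngrid
  if (any(interior)) {
    i <- imax[interior]
    idx <- cbind(seq_len(G)[interior], i)
    s0 <- score[idx]
    sm <- score[cbind(idx[, 1L], i - 1L)]
    sp <- score[cbind(idx[, 1L], i + 1L)]
    denom <- sm - 2 * s0 + sp
    offset <- ifelse(abs(denom) > 0, 0.5 * (sm - sp) / denom, 0)
    offset <- pmin(pmax(offset, -1), 1)
    lphi[interior] <- lgrid[i] + offset * h
  }
  phi_g <- exp(pmin(pmax(lphi, log(DISPERSION_LOWER)),
                    log(DISPERSION_UPPER)))
  names(phi_g) <- rownames(counts)
  phi_g
}

#' Sum-conditioned NB exact test for one two-condition contrast
#'
#' Pseudo-counts equalized to a common library size are summed within each
#' condition. Under the null, the two group sums are negative binomial with
#' means proportional to the replicate numbers and the gene's dispersion,
#' which makes the first group's sum, conditional on the total `s`,
#' beta-binomial-distributed over the partitions `(a, s - a)`. The two-sided
#' p-value is the total conditional probability of all partitions whose
#' probability is at most that of the observed one (relative tie tolerance
#' 1e-12), and is capped at 1. Genes with zero total get `p = 1` and
#' `logFC = 0` by contract. The log2 fold change is the ratio of the
#' prior-augmented (0.5 per group) normalized group means,
#' `pair[2]` over `pair[1]`.
#'
#' @param counts Count matrix.
#' @param design Design data frame.
#' @param dispersions List with elements `mode` (`"common"` or `"tagwise"`),
#'   `common` (scalar) and, for tagwise mode, `tagwise` (per-gene vector); a
#'   bare numeric scalar or per-gene vector is also accepted.
#' @param factors TMM factors.
#' @param pair Character vector of the two condition labels to compare.
#' @return Data frame with columns `gene`, `logFC`, `pvalue`.
#' @export
exact_test <- function(counts, design, dispersions, factors, pair) {
  validate_design(design, counts)
  if (length(pair) != 2L) stop("pair must name exactly two conditions")
  idx1 <- .condition_samples(counts, design, pair[1L])
  idx2 <- .condition_samples(counts, design, pair[2L])
  if (!length(idx1) || !length(idx2)) stop("pair condition absent from design")
  n1 <- length(idx1)
  n2 <- length(idx2)
  pseudo <- .pseudo_counts(counts, factors)$pseudo
  a <- rowSums(pseudo[, idx1, drop = FALSE])
  b <- rowSums(pseudo[, idx2, drop = FALSE])
  s <- a + b

  phi <- .dispersion_vector(dispersions, nrow(counts))
  pvalue <- rep(1, nrow(counts))
  nz <- s > 0
  if (any(nz)) {
    pvalue[nz] <- .exact_nb_pvalue(a[nz], s[nz], n1, n2, phi[nz])
  }
  logfc <- log2((b / n2 + 0.5) / (a / n1 + 0.5))
  logfc[s == 0] <- 0
  data.frame(gene = rownames(counts), logFC = logfc, pvalue = pvalue,
             stringsAsFactors = FALSE)
}

.dispersion_vector <- function(dispersions, G) {
  if (is.list(dispersions)) {
    phi <- if (identical(dispersions$mode, "tagwise")) {
      dispersions$tagwise
    } else {
      dispersions$common
    }
  } else {
    phi <- dispersions
  }
  if (length(phi) == 1L) phi <- rep(phi, G)
  if (length(phi) != G) stop("dispersion vector length does not match gene count")
  pmax(phi, 0)
}

# Two-sided conditional p-values by full enumeration over all partitions
# (a, s - a) of each gene's total, delegated to the compiled kernel (see
# src/exact_test.cpp). Conditional on the total s, the first group's sum is
# beta-binomial with parameters (n1 / phi, n2 / phi) -- Binomial(s, n1 /
# (n1 + n2)) in the Poisson limit phi -> 0 -- and the enumeration walks the
# log pmf ratio, so each gene costs O(s) with flat memory.
.exact_nb_pvalue <- function(a, s, n1, n2, phi, tie_tol = 1e-12) {
  G <- length(s)
  if (length(phi) == 1L) phi <- rep(phi, G)
  p <- .exact_nb_pvalue_cpp(as.numeric(a), as.numeric(s),
                            as.numeric(n1), as.numeric(n2),
                            as.numeric(phi), tie_tol)
  # Degenerate underflow (observed partition probability rounds to zero):
  # the p-value is below double precision; report the smallest positive
  # double rather than an exact zero.
  p[p == 0 | is.nan(p)] <- .Machine$double.xmin
  pmin(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]): sort ascending,
#' `q_i = min over k >= i of p_k * m / k`, capped at 1, returned in input
#' order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Run the full DE pipeline for one contrast
#'
#' TMM normalization, dispersion estimation (common mode when the smaller
#' replicate number of the pair is at most 4, tagwise otherwise), the
#' sum-conditioned exact test, and BH adjustment. No gene filtering is
#' applied. All settings are recorded in the result's `provenance`
#' attribute.
#'
#' @param counts Count matrix.
#' @param design Design data frame.
#' @param params An [analysis_params()] object.
#' @param pair Two condition labels; defaults to the design's two conditions
#'   when it has exactly two.
#' @return A data frame of class `de_result` with columns `gene`, `logFC`,
#'   `logCPM`, `pvalue`, `padj`, one row per gene of the input, and a
#'   `provenance` attribute (list: `pair`, `n_per_condition`,
#'   `dispersion_mode`, `phi_common`, `factors`).
#' @export
run_de <- function(counts, design, params = analysis_params(), pair = NULL) {
  validate_design(design, counts)
  if (is.null(pair)) {
    conds <- unique(design$condition)
    if (length(conds) != 2L) stop("design has ", length(conds),
                                  " conditions; supply 'pair'")
    pair <- conds
  }
  idx1 <- .condition_samples(counts, design, pair[1L])
  idx2 <- .condition_samples(counts, design, pair[2L])
  if (length(idx1) < 2L || length(idx2) < 2L) {
    stop("both conditions of the pair need >= 2 replicates")
  }
  keep <- c(idx1, idx2)
  keep <- colnames(counts)[colnames(counts) %in% keep]
  sub <- counts[, keep, drop = FALSE]
  sub_design <- design[match(keep, design$sample), , drop = FALSE]

  factors <- tmm_factors(sub)
  min_rep <- min(length(idx1), length(idx2))
  mode <- if (min_rep <= 4L) "common" else "tagwise"
  phi_common <- estimate_common_dispersion(sub, sub_design, factors)
  dispersions <- list(mode = mode, common = phi_common)
  if (mode == "tagwise") {
    dispersions$tagwise <- estimate_tagwise_dispersion(
      sub, sub_design, factors, phi_common,
      prior_weight = params$dispersion_prior_weight)
  }
  et <- exact_test(sub, sub_design, dispersions, factors, pair)
  logcpm <- rowMeans(log_cpm(sub, factors))
  result <- data.frame(gene = et$gene, logFC = et$logFC, logCPM = logcpm,
                       pvalue = et$pvalue, padj = bh_adjust(et$pvalue),
                       stringsAsFactors = FALSE, row.names = NULL)
  attr(result, "provenance") <- list(
    pair = pair,
    n_per_condition = c(length(idx1), length(idx2)),
    dispersion_mode = mode,
    phi_common = phi_common,
    factors = factors)
  class(result) <- c("de_result", "data.frame")
  result
}
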
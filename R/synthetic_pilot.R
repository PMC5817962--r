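# Synthetic two-condition pilot generator.
#
# Emulates a tomato-ovary style bulk RNA-Seq pilot: two conditions, up to
# 8+ biological replicates each, negative-binomial counts with gene-wise
# gamma dispersions, a large fraction of truly DE genes with heterogeneous
# fold changes, and known ground truth for every downstream evaluation.

#' Specification of a synthetic pilot dataset
#'
#' Defaults mirror a well-powered plant bulk RNA-Seq pilot: 20,000 genes,
#' eight biological replicates per condition, 5 million reads per sample,
#' half the genes truly DE. Relative gene abundances are log-normal;
#' gene-wise NB dispersions are gamma with mean
#' `dispersion_shape * dispersion_scale` (default 0.05, i.e. a biological
#' coefficient of variation around 0.22). True log2 fold changes are
#' symmetric around zero with standard deviation `lfc_sd`, truncated away
#' from `|lfc| < lfc_min` so a "DE" gene is never degenerate.
#'
#' @param n_genes Number of genes (>= 10).
#' @param replicates_per_condition Biological replicates per condition.
#' @param target_library_size Expected reads per sample.
#' @param pi_de Fraction of truly DE genes (Bernoulli per gene).
#' @param lfc_sd Standard deviation of true log2 fold changes.
#' @param lfc_min Minimum absolute true log2 fold change.
#' @param baseline_log_mean,baseline_log_sd Log-normal (natural log)
#'   parameters of relative gene abundance.
#' @param dispersion_shape,dispersion_scale Gamma parameters of the gene-wise
#'   NB dispersion.
#' @param seed Integer RNG seed.
#' @return A list of class `pilot_spec`.
#' @export
pilot_spec <- function(n_genes = 20000L,
                       replicates_per_condition = 8L,
                       target_library_size = 5e6,
                       pi_de = 0.5,
                       lfc_sd = 1,
                       lfc_min = 0.25,
                       baseline_log_mean = 0,
                       baseline_log_sd = 1.5,
                       dispersion_shape = 2,
                       dispersion_scale = 0.025,
                       seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               replicates_per_condition = as.integer(replicates_per_condition),
               target_library_size = as.numeric(target_library_size),
               pi_de = pi_de, lfc_sd = lfc_sd, lfc_min = lfc_min,
               baseline_log_mean = baseline_log_mean,
               baseline_log_sd = baseline_log_sd,
               dispersion_shape = dispersion_shape,
               dispersion_scale = dispersion_scale,
               seed = as.integer(seed))
  if (spec$n_genes < 10L) stop("n_genes must be >= 10")
  if (spec$replicates_per_condition < 2L) stop("need >= 2 replicates per condition")
  if (spec$pi_de < 0 || spec$pi_de > 1) stop("pi_de must lie in [0, 1]")
  for (a in c("target_library_size", "lfc_sd", "baseline_log_sd",
              "dispersion_shape", "dispersion_scale")) {
    if (spec[[a]] <= 0) stop(a, " must be > 0")
  }
  if (spec$lfc_min < 0) stop("lfc_min must be >= 0")
  structure(spec, class = "pilot_spec")
}

#' Generate a synthetic two-condition pilot dataset
#'
#' Counts for gene g in a sample of condition A (resp. B) are drawn from a
#' negative binomial with mean `L * q_g * 2^(-lfc_g / 2) / norm_A` (resp.
#' `+lfc_g / 2`, `norm_B`) and variance `mean * (1 + mean * phi_g)`, where
#' `q_g` are the normalized baseline abundances, `L` the target library size
#' and the per-condition normalizers make the expected column sums equal `L`.
#' Splitting the effect symmetrically between the conditions keeps the grand
#' mean abundance effect-free, so composition bias stays small by design.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec A [pilot_spec()].
#' @return A list with elements `counts` (integer matrix, conditions labelled
#'   `A`/`B`), `design` (data frame `sample`, `condition`) and `truth` (data
#'   frame `gene`, `is_de`, `lfc`).
#' @export
generate_pilot <- function(spec) {
  stopifnot(inherits(spec, "pilot_spec"))
  set.seed(spec$seed)
  G <- spec$n_genes
  r <- spec$replicates_per_condition
  L <- spec$target_library_size

  q <- stats::rlnorm(G, spec$baseline_log_mean, spec$baseline_log_sd)
  q <- q / sum(q)
  phi <- stats::rgamma(G, shape = spec$dispersion_shape,
                       scale = spec$dispersion_scale)

  is_de <- stats::runif(G) < spec$pi_de
  lfc <- numeric(G)
  n_de <- sum(is_de)
  if (n_de > 0L) {
    mag <- .rtrunc_abs_normal(n_de, spec$lfc_sd, spec$lfc_min)
    sgn <- sample(c(-1, 1), n_de, replace = TRUE)
    lfc[is_de] <- sgn * mag
  }

  rel_a <- q * 2^(-lfc / 2)
  rel_b <- q * 2^(lfc / 2)
  mu_a <- L * rel_a / sum(rel_a)
  mu_b <- L * rel_b / sum(rel_b)

  genes <- sprintf("g%05d", seq_len(G))
  samples <- c(paste0("A_", seq_len(r)), paste0("B_", seq_len(r)))
  counts <- matrix(0L, nrow = G, ncol = 2L * r,
                   dimnames = list(genes, samples))
  size <- 1 / phi
  for (j in seq_len(r)) {
    counts[, j] <- stats::rnbinom(G, mu = mu_a, size = size)
    counts[, r + j] <- stats::rnbinom(G, mu = mu_b, size = size)
  }

  design <- data.frame(sample = samples,
                       condition = rep(c("A", "B"), each = r),
                       stringsAsFactors = FALSE)
  truth <- data.frame(gene = genes, is_de = is_de, lfc = lfc,
                      stringsAsFactors = FALSE)
  list(counts = counts, design = design, truth = truth)
}

# |N(0, sd)| conditioned on being >= lower, by rejection.
.rtrunc_abs_normal <- function(n, sd, lower) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- abs(stats::rnorm(2L * (n - length(out)) + 10L, 0, sd))
    out <- c(out, draw[draw >= lower])
  }
  out[seq_len(n)]
}

#' Calibration check: naive fold-change recovery on DE genes
#'
#' Computes, over the truly DE genes, the mean absolute difference between
#' the observed log2 ratio of library-size-normalized condition means (CPM
#' scale, 0.5 prior to avoid zeros) and the true log2 fold change. Small
#' values mean the generator's effect sizes are recoverable at the simulated
#' depth and replication.
#'
#' @param counts,design A pilot count matrix and its design.
#' @param truth Truth table from [generate_pilot()].
#' @return Mean absolute error (log2 units).
#' @export
empirical_lfc_check <- function(counts, design, truth) {
  validate_design(design, counts)
  if (any(truth$is_de & truth$lfc == 0)) {
    stop("inconsistent truth: is_de gene with zero fold change")
  }
  if (!any(truth$is_de)) stop("no DE genes in truth")
  conditions <- unique(design$condition)
  if (length(conditions) != 2L) stop("expected exactly two conditions")
  idx_a <- .condition_samples(counts, design, conditions[1L])
  idx_b <- .condition_samples(counts, design, conditions[2L])
  if (length(idx_a) < 4L || length(idx_b) < 4L) {
    stop("need >= 4 replicates per condition")
  }
  cpm <- sweep(counts, 2L, colSums(counts), "/") * 1e6
  m_a <- rowMeans(cpm[, idx_a, drop = FALSE])
  m_b <- rowMeans(cpm[, idx_b, drop = FALSE])
  obs <- log2((m_b + 0.5) / (m_a + 0.5))
  de <- truth$is_de[match(rownames(counts), truth$gene)]
  lfc <- truth$lfc[match(rownames(counts), truth$gene)]
  mean(abs(obs[de] - lfc[de]))
}
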
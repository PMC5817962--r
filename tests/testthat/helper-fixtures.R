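# Shared fixture builders. Everything is generated in code; no stored data.

# Tiny deterministic two-condition matrix with equal column sums, so that
# with unit normalization factors the pseudo-counts equal the raw counts.
toy_counts <- function() {
  counts <- matrix(
    c(10, 12, 11, 13,
      50, 48, 52, 46,
      5,  6,  4,  9,
      100, 99, 98, 97,
      35, 35, 35, 35),
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("g", 1:5), c("a1", "a2", "b1", "b2")))
  storage.mode(counts) <- "integer"
  counts
}

toy_design <- function(counts = toy_counts()) {
  data.frame(sample = colnames(counts),
             condition = rep(c("A", "B"), each = ncol(counts) / 2),
             stringsAsFactors = FALSE)
}

# Small NB pilot for engine-level tests.
small_pilot <- function(n_genes = 500, reps = 8, lib = 1e5, seed = 401, ...) {
  generate_pilot(pilot_spec(n_genes = n_genes,
                            replicates_per_condition = reps,
                            target_library_size = lib, seed = seed, ...))
}

# Independent brute-force oracle for the sum-conditioned exact test:
# direct pmf products, no recurrences, no blocking.
oracle_exact_pvalue <- function(a, s, n1, n2, phi) {
  av <- 0:s
  if (phi < 1e-8) {
    pr <- dbinom(av, s, n1 / (n1 + n2))
  } else {
    pr <- dnbinom(av, size = n1 / phi, mu = n1 * s / (n1 + n2)) *
      dnbinom(s - av, size = n2 / phi, mu = n2 * s / (n1 + n2))
  }
  obs <- pr[a + 1]
  sum(pr[pr <= obs * (1 + 1e-12)]) / sum(pr)
}

# Independent step-up BH oracle: literal textbook loop.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    q[ord[i]] <- running
  }
  q
}

# Independent conditional log-likelihood for dispersion oracles: ratio of NB
# pmfs (the mean cancels in the conditional law).
oracle_cond_loglik <- function(y, phi) {
  n <- length(y)
  m <- mean(y) + 0.5
  sum(dnbinom(y, size = 1 / phi, mu = m, log = TRUE)) -
    dnbinom(sum(y), size = n / phi, mu = n * m, log = TRUE)
}
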
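# Brute-force two-sided Mann-Whitney p by enumerating all rank assignments.
# Valid for untied data; the null rank-sum distribution is symmetric, so the
# two-sided p is the probability of a rank-sum at least as far from its mean.
exact_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  rk <- rank(pooled)
  obs <- sum(rk[seq_len(m)])
  mu <- m * (length(pooled) + 1) / 2
  combs <- utils::combn(length(pooled), m)
  stats_all <- apply(combs, 2, function(idx) sum(rk[idx]))
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}

# Adjusted Rand index between two partitions (vectors of labels).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maximum - expected)
}

# Small cohort configuration used across tests (kept light for speed).
tiny_config <- function(seed = 1, ...) {
  defaults <- list(n_samples = 80, n_probes = 600, n_genes = 900, n_bins = 300,
                   n_nuclei = 120, seed = seed,
                   module_sizes = c(C0 = 40, C1 = 50, C2 = 50, C3 = 30))
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# Expression container with block-correlated genes: each block shares a
# latent factor; used as ground truth for clustering tests.
block_expression <- function(block_sizes, n_samples = 100, noise_sd = 0.3,
                             seed = 1) {
  set.seed(seed)
  ng <- sum(block_sizes)
  labels <- rep(seq_along(block_sizes), block_sizes)
  factors <- matrix(stats::rnorm(length(block_sizes) * n_samples),
                    length(block_sizes), n_samples)
  mat <- factors[labels, ] + matrix(stats::rnorm(ng * n_samples, sd = noise_sd),
                                    ng, n_samples)
  rownames(mat) <- sprintf("G%04d", seq_len(ng))
  colnames(mat) <- sprintf("S%03d", seq_len(n_samples))
  list(mat = mat, labels = stats::setNames(labels, rownames(mat)))
}
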
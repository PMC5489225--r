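# Shared fixture builders. Everything is generated in code at test time.

# Tiny deterministic cohort for arithmetic oracles.
tiny_cohort <- function(seed = 101, n = 60, m = 8) {
  set.seed(seed)
  truth <- sample_architecture(arch_spec(
    m_snps = m, maf_range = c(0.2, 0.5),
    effect = list(prop = 0, sd = 0), interaction = list(prop = 0, sd = 0),
    error_model = list(family = "normal", sd = 1), seed = seed))
  G <- simulate_genotypes(truth, n, seed = seed + 1)
  y <- rnorm(n)
  list(truth = truth, G = G, y = y)
}

# Block-LD genotype fixture for pruning tests.
ld_fixture <- function(seed = 77, n = 800, m = 60, block = 6, rho = 0.9) {
  truth <- sample_architecture(arch_spec(
    m_snps = m, maf_range = c(0.2, 0.5),
    effect = list(prop = 0, sd = 0), interaction = list(prop = 0, sd = 0),
    seed = seed))
  G <- simulate_genotypes(truth, n, seed = seed + 1,
                          ld = list(block_size = block, rho = rho))
  list(truth = truth, G = G)
}

# Independent Mann-Whitney oracle: exhaustive enumeration over all
# assignments of the pooled values to the two groups (no ties assumed).
mw_enumerate_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  r_obs <- sum(rank(pool)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(n1 + n2, n1)
  Us <- apply(combos, 2, function(idx)
    sum(rank(pool)[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  # two-sided: double the smaller tail, capped at 1
  p_lo <- mean(Us <= r_obs)
  p_hi <- mean(Us >= r_obs)
  min(1, 2 * min(p_lo, p_hi))
}
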
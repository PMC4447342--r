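# Shared fixtures and independent oracles for the test suite.

# Brute-force Benjamini-Hochberg step-up, written directly from the
# definition q_i = min_{j : p_(j) >= p_(i)} p_(j) * m / j, capped at 1.
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(seq_len(m), function(j) {
      if (p[o[j]] >= p[i]) p[o[j]] * m / j else Inf
    }, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

# Ordinary pooled-variance two-sample t-test, textbook form.
pooled_t_reference <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  s2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(s2 * (1 / n1 + 1 / n2))
}

# Fisher-z independence test closure over a fixed data matrix, for driving
# the pure-R skeleton engine as a cross-check of the compiled search.
fisher_test_closure <- function(data, alpha) {
  corr <- cor(t(data))
  n <- ncol(data)
  function(i, j, S) {
    if (n - length(S) - 3 <= 0) return(NA)
    r <- partial_correlation(corr, i, j, S)
    fisher_z_decision(r, n, length(S), alpha) == "independent"
  }
}

# Tiny target-set collection builder for MGSA tests.
toy_collection <- function(sets, universe) {
  structure(list(sets = sets, universe = universe), class = "target_sets")
}

# Random MGSA instance over a small universe.
random_mgsa_instance <- function(m, n_universe = 30, seed = 1) {
  set.seed(seed)
  uni <- sprintf("t%02d", seq_len(n_universe))
  sets <- lapply(seq_len(m), function(j)
    sort(sample(uni, sample(3:10, 1))))
  names(sets) <- sprintf("R%02d", seq_len(m))
  obs <- sort(unique(unlist(sets[sample.int(m, min(2, m))])))
  list(coll = toy_collection(sets, uni), observed = obs)
}
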
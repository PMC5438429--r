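# Shared fixtures and independent oracles for the test suite.

# Random binary fingerprint tibble with bit ids 0..(n_bits-1).
random_fingerprints <- function(n, n_bits, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    mat <- matrix(rbinom(n * n_bits, 1L, p), nrow = n)
    aicmax:::fingerprint_tibble(mat, sprintf("c%04d", seq_len(n)),
                                seq_len(n_bits) - 1L)
  })
}

random_labels <- function(n, p = 0.5, seed = 1) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1L, p)
    # guarantee both classes so entropy is positive
    if (all(y == y[1])) y[1] <- 1L - y[1]
    y
  })
}

# MCC oracle: the phi coefficient is the Pearson correlation of the expanded
# 0/1 truth and prediction vectors.
mcc_phi_oracle <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
  pred  <- c(rep(1, tp), rep(1, fp), rep(0, fn), rep(0, tn))
  stats::cor(truth, pred)
}

# Wilcoxon oracle: literal enumeration of all 2^n sign assignments.
# Returns P(W >= observed) for the one-sided greater alternative.
wilcoxon_enumeration_oracle <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- apply(signs, 1L, function(s) sum(r[unlist(s)]))
  mean(w_all >= w_obs - 1e-9)
}

# Entropy-based AIC oracle for a single bit, computed from explicit 2x2
# relative frequencies (independent of the package's pattern machinery).
singleton_aic_oracle <- function(bit_values, labels) {
  n <- length(labels)
  mi <- 0
  for (xv in 0:1) for (yv in 0:1) {
    pxy <- mean(bit_values == xv & labels == yv)
    if (pxy == 0) next
    mi <- mi + pxy * log2(pxy / (mean(bit_values == xv) * mean(labels == yv)))
  }
  py <- mean(labels == 1)
  mi / (-py * log2(py) - (1 - py) * log2(1 - py))
}
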
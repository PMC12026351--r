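# Shared fixture builders for the test suite.  Everything is generated in
# code under fixed seeds; no data files.

# Random InfoMat with nonnegative entries.
random_infomat <- function(m, seed, log_base = "e") {
  set.seed(seed)
  infomat(matrix(runif(m * m), m, m), log_base = log_base,
          estimator_tag = "exact")
}

# Build the four prefix views directly from replicate window matrices
# (rows = replicates, columns = steps, scalar per step).  Independent of
# split_blocks/prefix_views, for feeding entry estimators in isolation.
views_from_windows <- function(xw, yw, i, j) {
  v <- list(
    hh = cbind(xw[, seq_len(i - 1L), drop = FALSE],
               yw[, seq_len(j - 1L), drop = FALSE]),
    xh = cbind(xw[, seq_len(i), drop = FALSE],
               yw[, seq_len(j - 1L), drop = FALSE]),
    hy = cbind(xw[, seq_len(i - 1L), drop = FALSE],
               yw[, seq_len(j), drop = FALSE]),
    xy = cbind(xw[, seq_len(i), drop = FALSE],
               yw[, seq_len(j), drop = FALSE])
  )
  structure(v, i = i, j = j, d_x = 1L, d_y = 1L,
            class = c("prefix_views", "list"))
}

# Random dense PMF over binary (n_x, n_y)-prefixes whose probabilities are
# integer multiples of 1/total, so exact-count samples exist.
random_binary_pmf <- function(n_x, n_y, seed, total = 512L) {
  set.seed(seed)
  tuples <- as.matrix(expand.grid(rep(list(0:1), n_x + n_y)))
  dimnames(tuples) <- NULL
  counts <- as.vector(stats::rmultinom(1L, total, runif(nrow(tuples)) + 0.05))
  keep <- counts > 0L
  empirical_pmf(tuples[keep, , drop = FALSE], counts[keep] / total, n_x)
}

# Mutual information I(A; B) between two discrete columnsets by direct
# enumeration over a PMF support: treats each side as a single variable.
mi_by_enumeration <- function(support, probs, cols_a, cols_b) {
  key <- function(cols) {
    apply(support[, cols, drop = FALSE], 1L, paste, collapse = ",")
  }
  a <- key(cols_a); b <- key(cols_b); ab <- paste(a, b)
  pa <- tapply(probs, a, sum)
  pb <- tapply(probs, b, sum)
  pab <- tapply(probs, ab, sum)
  names_ab <- do.call(rbind, strsplit(names(pab), " "))
  sum(pab * log(pab / (pa[names_ab[, 1L]] * pb[names_ab[, 2L]])))
}

# Symmetric-coupling AR spec with a k-step joint Markov band; coupling
# strengths keep the companion spectral radius well below 1.
band_ar_spec <- function(kbar) {
  c0 <- if (kbar <= 2L) 0.15 else 0.08
  cf <- rep(c0, kbar + 1L)
  ar_spec(kbar_x = kbar, kbar_y = kbar,
          alpha_x = c(0, cf[-1L]), alpha_y = c(0, cf[-1L]),
          beta_x = cf, beta_y = c(0, cf[-1L]))
}
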
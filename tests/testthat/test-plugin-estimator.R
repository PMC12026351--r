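test_that("plug-in entropy matches closed forms", {
  expect_equal(plugin_entropy(rep(0:1, each = 500)), log(2))
  expect_equal(plugin_entropy(rep(0:1, each = 500), log_base = "2"), 1)
  expect_equal(plugin_entropy(rep(1:4, each = 25)), log(4))
  expect_equal(plugin_entropy(c(1, 2, 2, 2)),
               -(0.25 * log(0.25) + 0.75 * log(0.75)))
  expect_equal(plugin_entropy(rep(7, 100)), 0)      # constant samples
  # empty prefix has entropy 0
  expect_equal(plugin_entropy(matrix(0, 10, 0)), 0)
  expect_error(plugin_entropy(integer(0)), "empty")
})

test_that("plug-in entropy is maximal for uniform counts", {
  set.seed(5)
  h_unif <- plugin_entropy(rep(1:8, each = 16))
  for (s in 1:5) {
    skewed <- sample(1:8, 128, replace = TRUE, prob = runif(8) + 0.1)
    expect_lte(plugin_entropy(skewed), h_unif + 1e-12)
  }
})

test_that("XOR example reproduces the classic CMI values", {
  # x-prefix = (Z, X), y-prefix = (Y) with Y = X xor Z, all fair bits
  sup <- as.matrix(expand.grid(z = 0:1, x = 0:1))
  sup <- cbind(sup, y = bitwXor(sup[, 1], sup[, 2]))
  pmf <- empirical_pmf(sup, rep(0.25, 4), n_x = 2)
  # I(X_2; Y_1 | X_1) = I(X; Y | Z) = ln 2
  expect_equal(exact_cmi_bruteforce(pmf, 2, 1), log(2))
  # I(X_1; Y_1) = I(Z; Y) = 0
  expect_equal(exact_cmi_bruteforce(pmf, 1, 1), 0)
  expect_equal(exact_cmi_bruteforce(pmf, 2, 1, log_base = "2"), 1)
})

test_that("product PMFs have zero CMI everywhere", {
  set.seed(6)
  px <- runif(4); px <- px / sum(px)
  py <- runif(4); py <- py / sum(py)
  supx <- as.matrix(expand.grid(0:1, 0:1))
  sup <- as.matrix(expand.grid(1:4, 1:4))
  prob <- px[sup[, 1]] * py[sup[, 2]]
  tuples <- cbind(supx[sup[, 1], ], supx[sup[, 2], ])
  pmf <- empirical_pmf(tuples, prob, n_x = 2)
  for (i in 1:2) for (j in 1:2) {
    expect_lt(abs(exact_cmi_bruteforce(pmf, i, j)), 1e-12)
  }
})

test_that("the four exact entries sum to the full mutual information", {
  # chain rule checked by enumeration on random dense binary PMFs
  for (seed in 1:5) {
    pmf <- random_binary_pmf(2, 2, seed = 300 + seed)
    entries <- sum(sapply(1:2, function(i) {
      sapply(1:2, function(j) exact_cmi_bruteforce(pmf, i, j))
    }))
    full <- mi_by_enumeration(pmf$support, pmf$probabilities, 1:2, 3:4)
    expect_equal(entries, full, tolerance = 1e-12)
  }
})

test_that("plug-in CMI equals the enumeration oracle on exact-count samples", {
  for (seed in 1:8) {
    pmf <- random_binary_pmf(2, 2, seed = 400 + seed)
    s <- sample_pmf(pmf, 512, exact_counts = TRUE)
    for (i in 1:2) for (j in 1:2) {
      v <- views_from_windows(s$x, s$y, i, j)
      expect_lt(abs(plugin_cmi_entry(v) - exact_cmi_bruteforce(pmf, i, j)),
                1e-12)
    }
  }
})

test_that("plug-in entries converge to oracle values with sample size", {
  pmf <- random_binary_pmf(2, 2, seed = 77)
  set.seed(78)
  s <- sample_pmf(pmf, 2e5)
  for (i in 1:2) for (j in 1:2) {
    v <- views_from_windows(s$x, s$y, i, j)
    expect_lt(abs(plugin_cmi_entry(v) - exact_cmi_bruteforce(pmf, i, j)),
              0.01)
  }
})

test_that("identity channel gives a log(2) diagonal InfoMat", {
  set.seed(80)
  x <- sample(0:1, 4e4, replace = TRUE)
  ps <- paired_sequences(x, x, alphabet = "discrete")
  M <- as.matrix(estimate_infomat_plugin(ps, m = 4))
  expect_equal(diag(M), rep(log(2), 4), tolerance = 0.01)
  expect_lt(max(abs(M - diag(diag(M)))), 0.01)
})

test_that("estimator guards discrete input and prefix length", {
  ps <- simulate_correlated_iid(0.5, 1000, seed = 1)
  expect_error(estimate_infomat_plugin(ps, 3), "discrete")
  ch <- simulate_ising(2000, seed = 1)
  expect_error(estimate_infomat_plugin(ch, m = 8), "prefix_cap")
  # the cap is configurable (short input, so undersampling is flagged)
  M8 <- suppressWarnings(estimate_infomat_plugin(ch, m = 8, prefix_cap = 16))
  expect_s3_class(M8, "infomat")
  # severe undersampling triggers a warning
  expect_warning(
    estimate_infomat_plugin(
      paired_sequences(sample(1:8, 300, replace = TRUE),
                       sample(1:8, 300, replace = TRUE),
                       alphabet = "discrete"),
      m = 3, prefix_cap = 12),
    "undersampled")
})
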
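test_that("closed-form bivariate Gaussian MI behaves as expected", {
  expect_equal(gaussian_mi_closed_form(0), 0)
  expect_equal(gaussian_mi_closed_form(0.9), -0.5 * log(1 - 0.81))
  expect_equal(gaussian_mi_closed_form(0.9), gaussian_mi_closed_form(-0.9))
  expect_equal(gaussian_mi_closed_form(0.5, log_base = "2"),
               -0.5 * log2(0.75))
  expect_error(gaussian_mi_closed_form(1), "rho")
})

test_that("entry estimator recovers MI of independent and correlated pairs", {
  set.seed(10)
  N <- 1e5
  xw <- matrix(rnorm(N), ncol = 1)
  yw <- matrix(rnorm(N), ncol = 1)
  v <- views_from_windows(xw, yw, 1, 1)
  expect_lt(abs(gaussian_cmi_entry(v)), 0.01)  # independence

  yw2 <- 0.9 * xw + sqrt(1 - 0.81) * yw
  v2 <- views_from_windows(xw, yw2, 1, 1)
  expect_equal(gaussian_cmi_entry(v2), gaussian_mi_closed_form(0.9),
               tolerance = 0.01)
  # bits scale by 1/log(2)
  expect_equal(gaussian_cmi_entry(v2, log_base = "2") * log(2),
               gaussian_cmi_entry(v2), tolerance = 1e-10)
})

test_that("log-determinant formula matches the analytic covariance of an AR pair", {
  # two-step system: x2 = a x1 + e, y_t = r x_t + w_t; population covariance
  # of (x1, x2, y1, y2) assembled by hand
  a <- 0.6; r <- 0.8; se2 <- 1 - a^2; sw2 <- 1 - r^2
  # x1, x2 ~ N(0,1), cov(x1,x2) = a
  K <- matrix(0, 4, 4)
  K[1, 1] <- K[2, 2] <- 1
  K[1, 2] <- K[2, 1] <- a
  K[3, 3] <- K[4, 4] <- r^2 + sw2
  K[3, 4] <- K[4, 3] <- r^2 * a
  K[1, 3] <- K[3, 1] <- r; K[2, 4] <- K[4, 2] <- r
  K[1, 4] <- K[4, 1] <- r * a; K[2, 3] <- K[3, 2] <- r * a

  # oracle: Lemma-style four-entropy combination with Gaussian differential
  # entropies 0.5 log((2 pi e)^d |K|)
  hG <- function(idx) {
    if (length(idx) == 0) return(0)
    0.5 * (length(idx) * log(2 * pi * exp(1)) +
             determinant(K[idx, idx, drop = FALSE])$modulus[1])
  }
  xi <- function(i) seq_len(i); yj <- function(j) 2 + seq_len(j)
  for (i in 1:2) for (j in 1:2) {
    oracle <- hG(c(xi(i), yj(j - 1))) + hG(c(xi(i - 1), yj(j))) -
      hG(c(xi(i - 1), yj(j - 1))) - hG(c(xi(i), yj(j)))
    expect_equal(gaussian_cmi_from_cov(K, i, j, m = 2), oracle,
                 tolerance = 1e-12)
  }

  # sample covariance converges to the analytic value
  set.seed(11)
  n <- 2e5
  x <- numeric(n); x[1] <- rnorm(1)
  for (t in 2:n) x[t] <- a * x[t - 1] + rnorm(1, sd = sqrt(se2))
  y <- r * x + rnorm(n, sd = sqrt(sw2))
  # disjoint pairs of steps as replicates of (x1, x2, y1, y2)
  odd <- seq(1, n, by = 2)
  xw <- cbind(x[odd], x[odd + 1]); yw <- cbind(y[odd], y[odd + 1])
  v <- views_from_windows(xw, yw, 2, 2)
  expect_equal(gaussian_cmi_entry(v), gaussian_cmi_from_cov(K, 2, 2, m = 2),
               tolerance = 0.02)
})

test_that("Lemma-form equivalence holds on random covariances", {
  # the (2 pi e)^d factors cancel between the four entropies, so the
  # half-log-determinant ratio equals the entropy combination for any
  # positive-definite covariance
  for (seed in 1:5) {
    set.seed(seed)
    m <- 3
    A <- matrix(rnorm(36), 6)
    K <- crossprod(A) / 6 + diag(0.5, 6)
    hG <- function(idx) {
      if (length(idx) == 0) return(0)
      0.5 * (length(idx) * log(2 * pi * exp(1)) +
               determinant(K[idx, idx, drop = FALSE])$modulus[1])
    }
    for (i in 1:m) for (j in 1:m) {
      xi <- seq_len(i); xi1 <- seq_len(i - 1)
      yj <- m + seq_len(j); yj1 <- m + seq_len(j - 1)
      oracle <- hG(c(xi, yj1)) + hG(c(xi1, yj)) - hG(c(xi1, yj1)) -
        hG(c(xi, yj))
      expect_equal(gaussian_cmi_from_cov(K, i, j, m = m), oracle,
                   tolerance = 1e-10)
    }
  }
})

test_that("i.i.d. correlated pair yields a diagonal InfoMat", {
  ps <- simulate_correlated_iid(0.9, 1e5, seed = 21)
  M <- as.matrix(estimate_infomat_gaussian(ps, m = 5))
  expect_equal(diag(M), rep(gaussian_mi_closed_form(0.9), 5),
               tolerance = 0.02)
  expect_lt(max(abs(M - diag(diag(M)))), 0.01)

  ps0 <- simulate_correlated_iid(0, 5e4, seed = 22)
  expect_lt(max(abs(as.matrix(estimate_infomat_gaussian(ps0, m = 4)))), 0.01)
})

test_that("estimates are invariant under separate linear maps of x and y", {
  ps <- simulate_correlated_iid(0.7, 2e4, seed = 23)
  M1 <- as.matrix(estimate_infomat_gaussian(ps, m = 3))
  ps2 <- paired_sequences(-3.2 * ps$x, 0.4 * ps$y + 7)
  M2 <- as.matrix(estimate_infomat_gaussian(ps2, m = 3))
  expect_equal(M1, M2, tolerance = 1e-7)
})

test_that("degenerate and undersized inputs are reported", {
  set.seed(30)
  xw <- matrix(rnorm(6), ncol = 2)
  expect_error(gaussian_cmi_entry(views_from_windows(xw, xw, 2, 2)),
               "insufficient replicates")
  # zero-variance coordinates: singular covariance without the ridge
  z <- rep(1, 50)
  expect_error(
    gaussian_cmi_entry(views_from_windows(cbind(z, z), cbind(z, z), 2, 2),
                       ridge = 0),
    "singular|degenerate")
})
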
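test_that("ar_spec enforces lag-0 conventions and stationarity", {
  expect_error(ar_spec(kbar_x = 1, alpha_x = c(0.5, 0.2)), "lag-0")
  expect_error(ar_spec(kbar_x = 1, alpha_y = c(0.3, 0)), "lag-0")
  expect_error(ar_spec(kbar_y = 1, beta_y = c(0.4, 0.1)), "lag-0")
  expect_error(ar_spec(kbar_x = 1, alpha_x = c(0, 1.2)), "non-stationary")
  sp <- band_ar_spec(2)
  expect_lt(sp$spectral_radius, 1)
})

test_that("simulators are bit-reproducible given a seed", {
  expect_identical(simulate_gaussian_ar(band_ar_spec(2), 500, seed = 9),
                   simulate_gaussian_ar(band_ar_spec(2), 500, seed = 9))
  expect_identical(simulate_correlated_iid(0.9, 500, seed = 9),
                   simulate_correlated_iid(0.9, 500, seed = 9))
  expect_identical(simulate_ising(500, seed = 9),
                   simulate_ising(500, seed = 9))
  t1 <- simulate_trapdoor(500, seed = 9)
  t2 <- simulate_trapdoor(500, seed = 9)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
})

test_that("correlated iid pair has the requested correlation and law", {
  ps <- simulate_correlated_iid(0.9, 1e5, seed = 13)
  expect_lt(abs(cor(ps$x, ps$y) - 0.9), 0.01)
  expect_lt(abs(sd(ps$y) - 1), 0.02)
  expect_error(simulate_correlated_iid(1.0, 100, 1), "rho")
})

test_that("uncoupled AR processes produce a near-zero InfoMat", {
  sp <- ar_spec(kbar_x = 1, kbar_y = 1, alpha_x = c(0, 0.5),
                beta_y = c(0, 0.5))
  ps <- simulate_gaussian_ar(sp, 4e4, seed = 14)
  expect_lt(max(abs(as.matrix(estimate_infomat_gaussian(ps, m = 4)))), 0.01)
})

test_that("instantaneous-only coupling concentrates on the diagonal", {
  ps <- simulate_gaussian_ar(ar_spec(beta_x = 0.5), 4e4, seed = 15)
  M <- as.matrix(estimate_infomat_gaussian(ps, m = 4))
  # expected per-step MI: y = 0.5 x + e => rho^2 = 0.25/1.25
  expect_lt(max(abs(diag(M) - 0.5 * log(1 + 0.25))), 0.02)
  expect_lt(max(abs(M - diag(diag(M)))), 0.01)
})

test_that("one-sided lagged coupling fills a single triangle", {
  # y driven only by past x: information flows x -> y
  sp <- ar_spec(kbar_x = 1, kbar_y = 1, alpha_x = c(0, 0.3),
                beta_x = c(0, 0.6), beta_y = c(0, 0.3))
  ps <- simulate_gaussian_ar(sp, 6e4, seed = 16)
  M <- estimate_infomat_gaussian(ps, m = 6)
  expect_gt(directed_information(M, "x_to_y", 1), 10 *
              max(directed_information(M, "y_to_x", 1), 1e-4))
})

test_that("cyclic shift relocates the information band", {
  ps <- simulate_correlated_iid(0.9, 6e4, seed = 17)
  # identity shift returns the input unchanged
  same <- apply_invertible_distortion(ps, m = 6, shift = 0)
  expect_equal(same$x, ps$x)
  expect_equal(same$y, ps$y)

  shifted <- apply_invertible_distortion(ps, m = 6, shift = 4)
  M <- as.matrix(estimate_infomat_gaussian(shifted, m = 6))
  band <- M[cbind(1:2, 5:6)]            # entries (i, i + 4)
  wrap <- M[cbind(3:6, 1:4)]            # cyclic remainder at offset -(m - T)
  rest <- M[col(M) != row(M) + 4 & col(M) != row(M) - 2]
  expect_gt(min(band), 0.6)
  expect_gt(min(wrap), 0.6)
  expect_lt(max(abs(rest)), 0.15)
})

test_that("distortion maps are validated", {
  ps <- simulate_correlated_iid(0.5, 600, seed = 18)
  expect_error(apply_invertible_distortion(ps, 6, 0, map_x = "log"),
               "nonpositive")
  expect_error(apply_invertible_distortion(ps, 6, 6), "shift")
  expect_error(apply_invertible_distortion(ps, 6, 0, map_x = "sine"),
               "unknown")
  # cube keeps discretized dependence (invertibility sanity check)
  cubed <- apply_invertible_distortion(ps, 6, 0, map_y = "cube")
  expect_equal(cor(rank(ps$y), rank(cubed$y)), 1)
})

test_that("Ising channel outputs copy the current or previous input", {
  ch <- simulate_ising(2e5, seed = 19)
  x <- ch$x[, 1]; y <- ch$y[, 1]
  t <- 2:ch$n
  expect_true(all(y[t] == x[t] | y[t] == x[t - 1]))
  # the coin is fair: P(y = x | x changed) ~ 0.5
  changed <- which(x[t] != x[t - 1]) + 1
  expect_equal(mean(y[changed] == x[changed]), 0.5, tolerance = 0.01)
})

test_that("Trapdoor channel respects its state recursion and Z-channel law", {
  ch <- simulate_trapdoor(2e5, seed = 20)
  x <- ch$x[, 1]; y <- ch$y[, 1]; s <- attr(ch, "state")
  sprev <- c(0L, s[-length(s)])
  expect_identical(s, bitwXor(bitwXor(sprev, x), y))
  # Z-channel passes 0 faithfully when the state is 0
  pass0 <- sprev == 0L & x == 0L
  expect_true(all(y[pass0] == 0L))
  # S-channel passes 1 faithfully when the state is 1
  pass1 <- sprev == 1L & x == 1L
  expect_true(all(y[pass1] == 1L))
  # randomized branches are fair coins
  rand <- sprev != x
  expect_equal(mean(y[rand]), 0.5, tolerance = 0.01)
})
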
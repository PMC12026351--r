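test_that("total information sums all entries", {
  expect_equal(total_information(infomat(diag(0.5, 3))), 1.5)
  M <- infomat(matrix(c(0.1, 0.3, 0.2, 0.4), 2))
  expect_equal(total_information(M), 1.0)

  # brute-force double-loop oracle on a random nonnegative matrix
  M <- random_infomat(5, seed = 11)
  acc <- 0
  for (i in 1:5) for (j in 1:5) acc <- acc + M$entries[i, j]
  expect_equal(total_information(M), acc)
})

test_that("directed information is the shifted triangular sum", {
  M <- infomat(diag(0.7, 4))
  expect_equal(directed_information(M, "x_to_y"), 0.7 * 4) # diagonal included
  expect_equal(directed_information(M, "x_to_y", delay = 1), 0)

  # entries: [,1] = (0.1, 0.3); [,2] = (0.2, 0.4)
  M2 <- infomat(matrix(c(0.1, 0.3, 0.2, 0.4), 2))
  expect_equal(directed_information(M2, "x_to_y"), 0.7)
  expect_equal(directed_information(M2, "y_to_x", delay = 1), 0.3)

  expect_error(directed_information(M2, "x_to_y", delay = 2), "delay")
  expect_error(directed_information(M2, "x_to_y", delay = -1), "delay")
})

test_that("transfer entropy columns avoid the diagonal", {
  M <- random_infomat(4, seed = 3)
  E <- M$entries
  expect_equal(transfer_entropy_column(M, 2, "x_to_y"), E[1, 3] + E[2, 3])
  expect_equal(transfer_entropy_column(M, 3, "y_to_x"),
               E[4, 1] + E[4, 2] + E[4, 3])
  D <- infomat(diag(1, 4))
  for (i in 1:3) {
    expect_equal(transfer_entropy_column(D, i, "x_to_y"), 0)
    expect_equal(transfer_entropy_column(D, i, "y_to_x"), 0)
  }
  expect_error(transfer_entropy_column(M, 4, "x_to_y"), "i")
})

test_that("instantaneous information is the trace", {
  expect_equal(instantaneous_information(infomat(diag(0.2, 6))), 1.2)
  off <- matrix(1, 3, 3) - diag(1, 3)
  expect_equal(instantaneous_information(infomat(off)), 0)
})

test_that("conservation identities hold exactly for arbitrary matrices", {
  for (seed in 1:20) {
    m <- 2L + (seed %% 6L)
    M <- random_infomat(m, seed = 100 + seed)
    tot <- total_information(M)
    # Massey: total splits into forward DI and 1-delayed backward DI
    expect_equal(directed_information(M, "x_to_y") +
                   directed_information(M, "y_to_x", 1), tot)
    # past/present decomposition
    expect_equal(directed_information(M, "x_to_y", 1) +
                   directed_information(M, "y_to_x", 1) +
                   instantaneous_information(M), tot)
    # 1-delayed DI equals the sum of transfer entropy columns
    for (d in c("x_to_y", "y_to_x")) {
      te_sum <- sum(vapply(seq_len(m - 1L), transfer_entropy_column,
                           0, M = M, direction = d))
      expect_equal(directed_information(M, d, 1), te_sum)
    }
  }
})

test_that("decomposition report residuals vanish and reduce correctly", {
  # diagonal matrix: TE sums are zero and all residuals vanish
  repd <- decomposition_report(infomat(diag(0.4, 5)))
  expect_equal(unname(repd$residuals), rep(0, 5))
  expect_equal(sum(repd$te_columns), 0)

  M <- random_infomat(6, seed = 42)
  repr <- decomposition_report(M)
  expect_true(all(abs(repr$residuals) < 1e-12))
  expect_true(verify_identities(M))

  # 2x2: the delay-0 / delay-1 difference is exactly the diagonal
  M2 <- random_infomat(2, seed = 7)
  expect_equal(directed_information(M2, "x_to_y", 0),
               directed_information(M2, "x_to_y", 1) +
                 sum(diag(M2$entries)))
})

test_that("all measures are linear in the matrix", {
  A <- random_infomat(5, seed = 1)
  B <- random_infomat(5, seed = 2)
  comb <- infomat(2.5 * A$entries - 1.25 * B$entries)
  funs <- list(
    total_information,
    function(M) directed_information(M, "y_to_x", 2),
    instantaneous_information,
    function(M) transfer_entropy_column(M, 3, "x_to_y")
  )
  for (f in funs) {
    expect_equal(f(comb), 2.5 * f(A) - 1.25 * f(B))
  }
})

test_that("infomat constructor validates its input", {
  expect_error(infomat(matrix(1, 2, 3)), "square")
  expect_error(infomat(matrix(c(1, NA, 1, 1), 2)), "NA")
  expect_error(infomat(diag(2), log_base = "10"), "log_base")
  expect_identical(infomat(diag(2), log_base = "nats")$log_base, "e")
  expect_identical(infomat(diag(2), log_base = "bits")$log_base, "2")
})
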
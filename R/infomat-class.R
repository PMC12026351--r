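#' Construct an information matrix
#'
#' An information matrix (InfoMat) for a pair of jointly observed sequences
#' \eqn{(X^m, Y^m)} is the \eqn{m \times m} matrix whose \eqn{(i,j)} entry is
#' the conditional mutual information
#' \deqn{I_{i,j} = I(X_i; Y_j \mid X^{i-1}, Y^{j-1}),}
#' i.e. the dependence between step \eqn{i} of the X-process and step \eqn{j}
#' of the Y-process given the joint past of both.  By the chain rule the
#' entries sum to the full mutual information \eqn{I(X^m; Y^m)}, and classic
#' sequential measures (directed information, transfer entropy, instantaneous
#' information) are subset sums of its entries.
#'
#' Each population entry is nonnegative, but estimated entries may be
#' (slightly) negative; raw estimates are stored unmodified so that the exact
#' conservation identities between measures are preserved.  Clipping at zero
#' is a display-time option of [render_heatmap()].
#'
#' @param entries numeric square matrix of (estimated) conditional mutual
#'   information values.
#' @param log_base `"e"` for nats (default) or `"2"` for bits; the base in
#'   which `entries` are expressed.  All derived measures inherit it.
#' @param estimator_tag free-text provenance of the entries, e.g. `"gaussian"`,
#'   `"plugin"`, `"neural"`, or `"exact"`.
#'
#' @return An object of class `"infomat"`: a list with elements `m`,
#'   `entries`, `log_base`, `estimator_tag`.
#' @seealso [total_information()], [directed_information()],
#'   [transfer_entropy_column()], [instantaneous_information()],
#'   [decomposition_report()]
#' @export
#' @examples
#' M <- infomat(diag(0.5, 3))
#' total_information(M)
infomat <- function(entries, log_base = c("e", "2"),
                    estimator_tag = "unspecified") {
  log_base <- normalize_log_base(log_base)
  entries <- as.matrix(entries)
  if (!is.numeric(entries) || nrow(entries) != ncol(entries) ||
      nrow(entries) < 1L) {
    stop("'entries' must be a square numeric matrix", call. = FALSE)
  }
  if (anyNA(entries)) {
    stop("'entries' must not contain NA", call. = FALSE)
  }
  dimnames(entries) <- NULL
  structure(
    list(m = nrow(entries), entries = entries, log_base = log_base,
         estimator_tag = as.character(estimator_tag)[1L]),
    class = "infomat"
  )
}

# Accepts "e"/"2" and the friendly aliases "nats"/"bits".
normalize_log_base <- function(log_base) {
  lb <- as.character(log_base)[1L]
  lb <- switch(lb, nats = "e", bits = "2", lb)
  if (!lb %in% c("e", "2")) {
    stop("'log_base' must be one of \"e\" (nats) or \"2\" (bits)",
         call. = FALSE)
  }
  lb
}

#' @export
print.infomat <- function(x, ...) {
  unit <- if (x$log_base == "e") "nats" else "bits"
  cat(sprintf("InfoMat: %d x %d [%s] (estimator: %s)\n",
              x$m, x$m, unit, x$estimator_tag))
  cat(sprintf("  total information  I(X^m;Y^m) = %.6g %s\n",
              total_information(x), unit))
  cat(sprintf("  directed  X->Y = %.6g   Y->X (1-delayed) = %.6g\n",
              directed_information(x, "x_to_y"),
              directed_information(x, "y_to_x", delay = 1L)))
  cat(sprintf("  instantaneous (trace)       = %.6g\n",
              instantaneous_information(x)))
  invisible(x)
}

#' @export
as.matrix.infomat <- function(x, ...) x$entries

check_infomat <- function(M) {
  if (!inherits(M, "infomat")) stop("expected an 'infomat' object",
                                    call. = FALSE)
  invisible(M)
}

#' Total mutual information of an InfoMat
#'
#' The sum of all \eqn{m^2} entries: by the chain rule this equals
#' \eqn{I(X^m; Y^m)}.
#'
#' @param M an [infomat()] object.
#' @return scalar, in `M`'s log base.
#' @export
total_information <- function(M) {
  check_infomat(M)
  sum(M$entries)
}

match_direction <- function(direction) {
  match.arg(direction, c("x_to_y", "y_to_x"))
}

#' Directed information as a triangular subset sum
#'
#' Directed information \eqn{I(X^m \to Y^m) = \sum_i I(X^i; Y_i | Y^{i-1})}
#' is the sum of the upper triangle of the InfoMat *including* the diagonal.
#' The reverse direction is the lower triangle.  The k-delayed variant
#' \eqn{I(D^k \circ X^m \to Y^m)} delays the source by `k` steps and
#' corresponds to shifting the triangle off the diagonal: right by `k` for
#' `x_to_y`, down by `k` for `y_to_x`.
#'
#' @param M an [infomat()] object.
#' @param direction `"x_to_y"` or `"y_to_x"`.
#' @param delay nonnegative integer delay \eqn{k < m} applied to the source
#'   process; `0` includes the diagonal.
#' @return scalar, in `M`'s log base.
#' @export
#' @examples
#' M <- infomat(matrix(c(0.1, 0.3, 0.2, 0.4), 2)) # column-major
#' directed_information(M, "x_to_y")              # 0.1 + 0.2 + 0.4
#' directed_information(M, "y_to_x", delay = 1)   # 0.3
directed_information <- function(M, direction = c("x_to_y", "y_to_x"),
                                 delay = 0L) {
  check_infomat(M)
  direction <- match_direction(direction)
  delay <- as.integer(delay)
  if (delay < 0L || delay >= M$m) {
    stop(sprintf("'delay' must satisfy 0 <= delay < m = %d", M$m),
         call. = FALSE)
  }
  E <- M$entries
  keep <- if (direction == "x_to_y") col(E) >= row(E) + delay
          else                       row(E) >= col(E) + delay
  sum(E[keep])
}

#' Instantaneous information (trace of the InfoMat)
#'
#' Same-time-step dependence given the shared history:
#' \eqn{I_{inst}(X^m, Y^m) = \sum_i I(X_i; Y_i | X^{i-1}, Y^{i-1})}, the
#' trace of the InfoMat.
#'
#' @inheritParams total_information
#' @return scalar, in `M`'s log base.
#' @export
instantaneous_information <- function(M) {
  check_infomat(M)
  sum(diag(M$entries))
}

#' Transfer entropy term as a partial column sum
#'
#' The transfer entropy term \eqn{T^{X\to Y}_{i+1}(i,i) = I(X^i; Y_{i+1} |
#' Y^i)} measures the strictly-past influence of X on the next Y step.  In
#' the InfoMat it is the column of length `i` sitting in column `i + 1` above
#' the diagonal (rows 1..i); it never touches the diagonal.  The `y_to_x`
#' direction is the transpose-symmetric partial row.
#'
#' @param M an [infomat()] object.
#' @param i source history length, `1 <= i <= m - 1` (1-based, as in the
#'   usual transfer-entropy notation).
#' @param direction `"x_to_y"` or `"y_to_x"`.
#' @return scalar, in `M`'s log base.
#' @export
transfer_entropy_column <- function(M, i, direction = c("x_to_y", "y_to_x")) {
  check_infomat(M)
  direction <- match_direction(direction)
  i <- as.integer(i)
  if (i < 1L || i > M$m - 1L) {
    stop(sprintf("'i' must satisfy 1 <= i <= m - 1 = %d", M$m - 1L),
         call. = FALSE)
  }
  if (direction == "x_to_y") sum(M$entries[seq_len(i), i + 1L])
  else                       sum(M$entries[i + 1L, seq_len(i)])
}

# Sum of the k-th shifted diagonal in the given direction: entries
# M[a, a+k] (x_to_y) or M[a+k, a] (y_to_x).  The difference between the
# k- and (k+1)-delayed triangles.
shifted_diagonal_sum <- function(M, k, direction) {
  E <- M$entries
  a <- seq_len(M$m - k)
  if (direction == "x_to_y") sum(E[cbind(a, a + k)])
  else                       sum(E[cbind(a + k, a)])
}

#' All derived measures and conservation-identity residuals
#'
#' Evaluates, as exact subset sums over the matrix entries: the total mutual
#' information, directed information in both directions (plain and delayed),
#' every transfer entropy term, the instantaneous information, and the
#' residual of each conservation identity relating them:
#' \describe{
#'   \item{massey}{\eqn{I(X^m;Y^m) = I(X^m \to Y^m) + I(D \circ Y^m \to X^m)}}
#'   \item{instantaneous_decomposition}{\eqn{I(X^m;Y^m) = I(D\circ X^m \to
#'     Y^m) + I(D\circ Y^m \to X^m) + I_{inst}}}
#'   \item{prop1}{the k-delayed directed information equals the sum of its
#'     shifted-triangle partial columns (transfer entropy terms at k = 1),
#'     for every `1 <= k < m` and both directions}
#'   \item{prop2}{total = both transfer entropy sums + trace}
#'   \item{prop3}{\eqn{I(D^k\circ X^m \to Y^m) = I(D^{k+1}\circ X^m \to Y^m)
#'     + } the k-th shifted diagonal sum, for every `0 <= k < m - 1` and both
#'     directions}
#' }
#' Because every identity is a rearrangement of the same addends, each
#' residual is zero up to floating-point rounding of re-ordered sums,
#' whatever the entries are.  Residuals are reported for the worst `k`.
#'
#' @inheritParams total_information
#' @param max_delay largest delay for which delayed directed information is
#'   tabulated in the report (identities are always checked over all delays).
#' @return A `"measure_report"` list: `total_mi`, `di_forward`, `di_backward`,
#'   `delayed_di` (matrix, delays x directions), `te_columns` (matrix,
#'   index x directions), `instantaneous`, `residuals` (named numeric),
#'   `log_base`.
#' @export
decomposition_report <- function(M, max_delay = M$m - 1L) {
  check_infomat(M)
  m <- M$m
  max_delay <- min(as.integer(max_delay), m - 1L)
  dirs <- c("x_to_y", "y_to_x")

  total <- total_information(M)
  trace <- instantaneous_information(M)
  di0 <- vapply(dirs, function(d) directed_information(M, d, 0L), 0)

  delays <- seq_len(max_delay)
  delayed <- matrix(0, nrow = max_delay, ncol = 2L,
                    dimnames = list(delays, dirs))
  for (d in dirs) for (k in delays) {
    delayed[k, d] <- directed_information(M, d, k)
  }

  te <- matrix(0, nrow = max(m - 1L, 0L), ncol = 2L,
               dimnames = list(seq_len(m - 1L), dirs))
  for (d in dirs) for (i in seq_len(m - 1L)) {
    te[i, d] <- transfer_entropy_column(M, i, d)
  }

  # Partial-column sums of the k-shifted triangle: for x_to_y, column b has
  # rows 1..(b - k); the k = 1 case is exactly the transfer entropy terms.
  shifted_partial_cols <- function(k, d) {
    b <- seq.int(k + 1L, m)
    if (d == "x_to_y") sum(vapply(b, function(bb) sum(M$entries[seq_len(bb - k), bb]), 0))
    else               sum(vapply(b, function(bb) sum(M$entries[bb, seq_len(bb - k)]), 0))
  }

  prop1 <- 0
  for (d in dirs) for (k in seq_len(m - 1L)) {
    prop1 <- max(prop1, abs(directed_information(M, d, k) -
                              shifted_partial_cols(k, d)))
  }
  prop3 <- 0
  if (m >= 2L) {
    for (d in dirs) for (k in 0:(m - 2L)) {
      prop3 <- max(prop3, abs(directed_information(M, d, k) -
                                directed_information(M, d, k + 1L) -
                                shifted_diagonal_sum(M, k, d)))
    }
  }
  di1 <- vapply(dirs, function(d) {
    if (m >= 2L) directed_information(M, d, 1L) else 0
  }, 0)

  residuals <- c(
    massey = total - (di0[["x_to_y"]] + di1[["y_to_x"]]),
    instantaneous_decomposition =
      total - (di1[["x_to_y"]] + di1[["y_to_x"]] + trace),
    prop1 = prop1,
    prop2 = total - (sum(te) + trace),
    prop3 = prop3
  )

  structure(
    list(total_mi = total,
         di_forward = di0[["x_to_y"]],
         di_backward = di0[["y_to_x"]],
         delayed_di = delayed,
         te_columns = te,
         instantaneous = trace,
         residuals = residuals,
         log_base = M$log_base),
    class = "measure_report"
  )
}

#' @export
print.measure_report <- function(x, ...) {
  unit <- if (x$log_base == "e") "nats" else "bits"
  cat(sprintf("Sequential information measures [%s]\n", unit))
  cat(sprintf("  I(X^m;Y^m)            = %.6g\n", x$total_mi))
  cat(sprintf("  I(X^m -> Y^m)         = %.6g\n", x$di_forward))
  cat(sprintf("  I(Y^m -> X^m)         = %.6g\n", x$di_backward))
  cat(sprintf("  I_inst (trace)        = %.6g\n", x$instantaneous))
  if (nrow(x$delayed_di) >= 1L) {
    cat(sprintf("  I(D o X^m -> Y^m)     = %.6g\n", x$delayed_di[1L, "x_to_y"]))
    cat(sprintf("  I(D o Y^m -> X^m)     = %.6g\n", x$delayed_di[1L, "y_to_x"]))
  }
  cat("  identity residuals (should vanish):\n")
  for (nm in names(x$residuals)) {
    cat(sprintf("    %-28s %.3e\n", nm, x$residuals[[nm]]))
  }
  invisible(x)
}

#' Check the conservation identities of an InfoMat
#'
#' Convenience wrapper around [decomposition_report()]: returns `TRUE` when
#' every identity residual is below `tol` relative to the total information
#' (floor 1), which holds for any matrix since the identities are exact
#' rearrangements.
#'
#' @inheritParams total_information
#' @param tol relative tolerance (default `1e-9`).
#' @return logical scalar with attribute `"residuals"`.
#' @export
verify_identities <- function(M, tol = 1e-9) {
  rep <- decomposition_report(M)
  scale <- max(1, abs(rep$total_mi))
  ok <- all(abs(rep$residuals) <= tol * scale)
  structure(ok, residuals = rep$residuals)
}
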
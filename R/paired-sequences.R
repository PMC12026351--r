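#' Construct a paired, time-aligned sequence object
#'
#' Holds two jointly observed streams of equal length `n`, each possibly
#' vector-valued per time step.  This is the common input of all InfoMat
#' estimators.
#'
#' @param x,y numeric vectors (dimension 1 per step) or `n x d` matrices
#'   (one row per time step).
#' @param alphabet `"auto"` (default), `"real"`, or `"discrete"`.  Under
#'   `"auto"`, integer-valued storage is classified as discrete, double as
#'   real; estimators that require one kind check this field.
#' @return An object of class `"paired_sequences"` with fields `x`, `y`
#'   (always matrices), `n`, `d_x`, `d_y`, `alphabet`.
#' @export
#' @examples
#' ps <- paired_sequences(rnorm(100), rnorm(100))
#' ps$n
paired_sequences <- function(x, y, alphabet = c("auto", "real", "discrete")) {
  alphabet <- match.arg(alphabet)
  x <- as_step_matrix(x, "x")
  y <- as_step_matrix(y, "y")
  if (nrow(x) != nrow(y)) {
    stop("'x' and 'y' must have the same number of time steps", call. = FALSE)
  }
  if (nrow(x) < 1L) stop("empty sequences", call. = FALSE)
  if (alphabet == "auto") {
    alphabet <- if (is_discrete_storage(x) && is_discrete_storage(y))
      "discrete" else "real"
  }
  structure(
    list(x = x, y = y, n = nrow(x), d_x = ncol(x), d_y = ncol(y),
         alphabet = alphabet),
    class = "paired_sequences"
  )
}

as_step_matrix <- function(v, name) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 1L)
  v <- as.matrix(v)
  if (!is.numeric(v)) stop(sprintf("'%s' must be numeric", name),
                           call. = FALSE)
  if (anyNA(v)) stop(sprintf("'%s' contains NA", name), call. = FALSE)
  dimnames(v) <- NULL
  v
}

is_discrete_storage <- function(v) {
  is.integer(v) || all(v == round(v))
}

#' @export
print.paired_sequences <- function(x, ...) {
  cat(sprintf("paired_sequences: n = %d, d_x = %d, d_y = %d, alphabet = %s\n",
              x$n, x$d_x, x$d_y, x$alphabet))
  invisible(x)
}

#' Split a long paired recording into replicated m-length windows
#'
#' Every entry of an m-by-m InfoMat is estimated from N replicates of an
#' aligned `(x, y)` window of length `m`.  Two splitting modes are offered:
#' \describe{
#'   \item{disjoint}{`N = floor(n / m)` non-overlapping windows.  Under an
#'     i.i.d.-block assumption the replicates are independent, which the
#'     estimator guarantees rely on.  This is the default.}
#'   \item{sliding}{`N = n - m` windows, window `l` starting at offset `l`
#'     (a "correlated dataset").  Replicates overlap and are dependent, so
#'     variance guarantees no longer hold; useful when the recording is
#'     short.  A warning reminds of this.}
#' }
#'
#' @param pair a [paired_sequences()] object.
#' @param m window length (the InfoMat dimension).  At least one full
#'   window must fit (`n > m`); with fewer than two (`n < 2m`) a warning
#'   flags that single-window estimates are unreliable.
#' @param mode `"disjoint"` (default) or `"sliding"`.
#' @return An object of class `"block_dataset"`: fields `m`, `mode`, `N`,
#'   `d_x`, `d_y`, `alphabet`, and `x`, `y` — `N x (m * d)` matrices whose
#'   columns are time-major (step t occupies columns `(t-1)*d + 1 .. t*d`).
#' @export
split_blocks <- function(pair, m, mode = c("disjoint", "sliding")) {
  stopifnot(inherits(pair, "paired_sequences"))
  mode <- match.arg(mode)
  m <- as.integer(m)
  if (m < 1L) stop("'m' must be a positive integer", call. = FALSE)
  n <- pair$n
  if (n <= m) {
    stop(sprintf("insufficient data: need n > m (n = %d, m = %d)", n, m),
         call. = FALSE)
  }
  if (n < 2L * m) {
    warning(sprintf(
      "insufficient data for replicated windows (n = %d < 2m = %d); ",
      n, 2L * m), "estimates from a single window are unreliable",
      call. = FALSE)
  }
  starts <- if (mode == "disjoint") {
    N <- n %/% m
    seq.int(1L, by = m, length.out = N)
  } else {
    warning("sliding windows are correlated replicates; ",
            "variance guarantees of the disjoint split no longer hold",
            call. = FALSE)
    seq_len(n - m)
  }
  structure(
    list(m = m, mode = mode, N = length(starts),
         d_x = pair$d_x, d_y = pair$d_y, alphabet = pair$alphabet,
         x = window_matrix(pair$x, starts, m),
         y = window_matrix(pair$y, starts, m)),
    class = "block_dataset"
  )
}

# Rows = replicates, columns = time-major flattening of an m-step window.
window_matrix <- function(series, starts, m) {
  d <- ncol(series)
  out <- matrix(0, nrow = length(starts), ncol = m * d)
  for (t in seq_len(m)) {
    out[, (t - 1L) * d + seq_len(d)] <- series[starts + t - 1L, , drop = FALSE]
  }
  out
}

#' @export
print.block_dataset <- function(x, ...) {
  cat(sprintf("block_dataset: N = %d windows of length m = %d (%s split)\n",
              x$N, x$m, x$mode))
  invisible(x)
}

# Column indices of the first i steps of a time-major window matrix.
prefix_cols <- function(i, d) seq_len(i * d)

#' Extract the four prefix views an InfoMat entry estimator consumes
#'
#' For entry \eqn{(i, j)}, every estimator needs, per replicate, the four
#' nested flattened prefix vectors
#' \eqn{(x^{i-1}, y^{j-1})}, \eqn{(x^{i}, y^{j-1})}, \eqn{(x^{i-1}, y^{j})},
#' \eqn{(x^{i}, y^{j})} — the joint histories with and without the current
#' X and Y step.  A prefix of length 0 contributes no columns.
#'
#' @param blocks a [split_blocks()] result.
#' @param i,j 1-based step indices, `1 <= i, j <= m`.
#' @return An object of class `"prefix_views"`: a list of four `N x k`
#'   matrices named `hh`, `xh`, `hy`, `xy` (h = history only), with
#'   attributes `i`, `j`, `d_x`, `d_y` for slicing out the current steps.
#' @export
prefix_views <- function(blocks, i, j) {
  stopifnot(inherits(blocks, "block_dataset"))
  i <- as.integer(i); j <- as.integer(j)
  if (i < 1L || i > blocks$m || j < 1L || j > blocks$m) {
    stop(sprintf("(i, j) must lie in 1..m = %d", blocks$m), call. = FALSE)
  }
  xc <- function(k) blocks$x[, prefix_cols(k, blocks$d_x), drop = FALSE]
  yc <- function(k) blocks$y[, prefix_cols(k, blocks$d_y), drop = FALSE]
  views <- list(
    hh = cbind(xc(i - 1L), yc(j - 1L)),
    xh = cbind(xc(i),      yc(j - 1L)),
    hy = cbind(xc(i - 1L), yc(j)),
    xy = cbind(xc(i),      yc(j))
  )
  structure(views, i = i, j = j, d_x = blocks$d_x, d_y = blocks$d_y,
            class = c("prefix_views", "list"))
}
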
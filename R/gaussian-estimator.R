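#' Closed-form bivariate Gaussian mutual information
#'
#' For a jointly Gaussian pair with correlation `rho`,
#' \eqn{I(X;Y) = -\tfrac12 \log(1 - \rho^2)}.  Used as the analytic
#' reference for estimator validation.
#'
#' @param rho correlation coefficient, `|rho| < 1`.
#' @param log_base `"e"` (nats) or `"2"` (bits).
#' @return scalar mutual information.
#' @export
#' @examples
#' gaussian_mi_closed_form(0.9) # 0.8304 nats
gaussian_mi_closed_form <- function(rho, log_base = c("e", "2")) {
  log_base <- normalize_log_base(log_base)
  if (!is.numeric(rho) || abs(rho) >= 1) {
    stop("'rho' must satisfy |rho| < 1", call. = FALSE)
  }
  v <- -0.5 * log1p(-rho^2)
  if (log_base == "2") v / log(2) else v
}

# log |K| via Cholesky; the 0x0 matrix has determinant 1 by convention.
logdet_chol <- function(K) {
  if (length(K) == 0L) return(0)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) {
    stop("covariance matrix is singular after ridging; ",
         "degenerate input (collinear coordinates or too few replicates)",
         call. = FALSE)
  }
  2 * sum(log(diag(ch)))
}

add_ridge <- function(K, ridge) {
  if (length(K) == 0L || ridge <= 0) return(K)
  K + diag(ridge * mean(diag(K)), nrow(K))
}

#' Gaussian conditional mutual information from a known covariance
#'
#' Evaluates the log-determinant ratio
#' \deqn{I(X_i; Y_j | X^{i-1}, Y^{j-1}) = \tfrac12 \log
#'   \frac{|K_{X^i,Y^{j-1}}| \, |K_{X^{i-1},Y^j}|}
#'        {|K_{X^{i-1},Y^{j-1}}| \, |K_{X^i,Y^j}|}}
#' on an explicit covariance matrix of the stacked window
#' \eqn{(X^m, Y^m)} (x steps first, time-major within each block).  The
#' determinant of the empty matrix is 1, so at `i = j = 1` this is the
#' unconditional Gaussian mutual information.
#'
#' Useful directly when the population covariance is known analytically;
#' [estimate_infomat_gaussian()] calls it on the sample covariance.
#'
#' @param K covariance matrix of dimension `m * (d_x + d_y)`.
#' @param i,j 1-based step indices.
#' @param m number of steps covered by `K`.
#' @param d_x,d_y per-step dimensions.
#' @param log_base `"e"` or `"2"`.
#' @param ridge relative ridge added to the diagonal (0 for exact input).
#' @return scalar conditional mutual information.
#' @export
gaussian_cmi_from_cov <- function(K, i, j, m, d_x = 1L, d_y = 1L,
                                  log_base = c("e", "2"), ridge = 0) {
  log_base <- normalize_log_base(log_base)
  K <- as.matrix(K)
  if (nrow(K) != m * (d_x + d_y)) {
    stop("'K' must have dimension m * (d_x + d_y)", call. = FALSE)
  }
  K <- add_ridge(K, ridge)
  idx <- function(ii, jj) {
    c(seq_len(ii * d_x), m * d_x + seq_len(jj * d_y))
  }
  ld <- function(ii, jj) {
    s <- idx(ii, jj)
    logdet_chol(K[s, s, drop = FALSE])
  }
  v <- 0.5 * (ld(i, j - 1L) + ld(i - 1L, j) - ld(i - 1L, j - 1L) - ld(i, j))
  if (log_base == "2") v / log(2) else v
}

#' Gaussian estimate of one InfoMat entry from replicate prefix views
#'
#' Centers each view's columns, forms sample covariances, applies the ridge,
#' and returns the half-log-determinant ratio of the four covariances (see
#' [gaussian_cmi_from_cov()]).  Estimates may be slightly negative; they are
#' returned unmodified.
#'
#' @param views a [prefix_views()] object (or plain list of the four
#'   replicate matrices `hh`, `xh`, `hy`, `xy`).
#' @param log_base `"e"` or `"2"`.
#' @param ridge relative ridge (fraction of the mean diagonal) added before
#'   factorization; default `1e-10`.
#' @param center subtract the column means of each view first (default TRUE;
#'   set FALSE when the recording was centered globally upstream).
#' @return scalar estimate.
#' @export
gaussian_cmi_entry <- function(views, log_base = c("e", "2"),
                               ridge = 1e-10, center = TRUE) {
  log_base <- normalize_log_base(log_base)
  stopifnot(is.list(views), length(views) == 4L)
  ld <- vapply(views, function(V) {
    V <- as.matrix(V)
    if (ncol(V) == 0L) return(0)
    if (nrow(V) < ncol(V) + 1L) {
      stop(sprintf(
        "insufficient replicates: %d for a %d-dimensional view", nrow(V),
        ncol(V)), call. = FALSE)
    }
    if (center) V <- sweep(V, 2L, colMeans(V))
    K <- add_ridge(crossprod(V) / nrow(V), ridge)
    logdet_chol(K)
  }, 0)
  v <- 0.5 * (ld[["xh"]] + ld[["hy"]] - ld[["hh"]] - ld[["xy"]])
  if (log_base == "2") v / log(2) else v
}

#' Estimate an InfoMat under a joint-Gaussian model
#'
#' Splits the recording into replicated m-length windows
#' ([split_blocks()]), centers every coordinate with its global mean over
#' the whole recording, estimates the single covariance matrix of the
#' stacked window \eqn{(X^m, Y^m)}, and fills each entry with the
#' log-determinant ratio of its four nested principal submatrices.  Because
#' the covariance of any prefix is a principal submatrix of the full window
#' covariance, all \eqn{m^2} entries share one covariance estimate, which
#' keeps them mutually consistent and makes the whole matrix cost a handful
#' of Cholesky factorizations.
#'
#' @param pair a real-valued [paired_sequences()] object.
#' @param m InfoMat dimension; requires `n >= 2m`.
#' @param mode window split, `"disjoint"` (default) or `"sliding"`; see
#'   [split_blocks()].
#' @param log_base `"e"` (nats, default) or `"2"` (bits).
#' @param ridge relative ridge added to the covariance diagonal.
#' @return An [infomat()] with `estimator_tag = "gaussian"`.
#' @export
#' @examples
#' ps <- simulate_correlated_iid(rho = 0.9, n = 2000, seed = 1)
#' M <- estimate_infomat_gaussian(ps, m = 3)
#' round(as.matrix(M), 2)
estimate_infomat_gaussian <- function(pair, m,
                                      mode = c("disjoint", "sliding"),
                                      log_base = c("e", "2"),
                                      ridge = 1e-10) {
  stopifnot(inherits(pair, "paired_sequences"))
  log_base <- normalize_log_base(log_base)
  if (pair$alphabet != "real") {
    warning("Gaussian estimator applied to discrete-coded data; ",
            "consider estimate_infomat_plugin()")
  }
  pair$x <- sweep(pair$x, 2L, colMeans(pair$x))
  pair$y <- sweep(pair$y, 2L, colMeans(pair$y))
  blocks <- split_blocks(pair, m, mode)
  d_x <- blocks$d_x; d_y <- blocks$d_y
  V <- cbind(blocks$x, blocks$y)
  if (nrow(V) < ncol(V) + 1L) {
    warning(sprintf(
      "N = %d replicates for a %d-dimensional window; covariance is rank ",
      nrow(V), ncol(V)),
      "deficient and entries rely entirely on the ridge")
  }
  K <- add_ridge(crossprod(V) / nrow(V), ridge)

  # Cache log-determinants of the (i, j) prefix grid, i, j in 0..m.
  L <- matrix(0, m + 1L, m + 1L)
  for (i in 0:m) for (j in 0:m) {
    s <- c(seq_len(i * d_x), m * d_x + seq_len(j * d_y))
    L[i + 1L, j + 1L] <- tryCatch(
      logdet_chol(K[s, s, drop = FALSE]),
      error = function(e) {
        stop(sprintf("entry prefix (i = %d, j = %d): %s", i, j,
                     conditionMessage(e)), call. = FALSE)
      })
  }
  E <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    E[i, j] <- 0.5 * (L[i + 1L, j] + L[i, j + 1L] - L[i, j] -
                        L[i + 1L, j + 1L])
  }
  if (log_base == "2") E <- E / log(2)
  infomat(E, log_base = log_base, estimator_tag = "gaussian")
}
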
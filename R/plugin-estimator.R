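#' Empirical probability mass function over paired symbol prefixes
#'
#' A finite joint PMF over tuples \eqn{(x_1..x_{m_x}, y_1..y_{m_y})}, used
#' as the exact reference distribution for the brute-force conditional
#' mutual information oracle ([exact_cmi_bruteforce()]).
#'
#' @param support matrix with one row per distinct tuple; the first `n_x`
#'   columns are the X-prefix symbols, the rest the Y-prefix.
#' @param probabilities nonnegative weights, one per row, summing to 1
#'   (within 1e-12).
#' @param n_x number of X columns in `support`.
#' @return An object of class `"empirical_pmf"`.
#' @export
empirical_pmf <- function(support, probabilities, n_x) {
  support <- as.matrix(support)
  n_x <- as.integer(n_x)
  if (n_x < 0L || n_x > ncol(support)) {
    stop("'n_x' must lie in 0..ncol(support)", call. = FALSE)
  }
  if (nrow(support) != length(probabilities)) {
    stop("one probability per support row required", call. = FALSE)
  }
  if (any(probabilities < 0) || abs(sum(probabilities) - 1) > 1e-12) {
    stop("'probabilities' must be nonnegative and sum to 1 (within 1e-12)",
         call. = FALSE)
  }
  keys <- apply(support, 1L, paste, collapse = "\r")
  if (anyDuplicated(keys)) {
    stop("support rows must be unique", call. = FALSE)
  }
  structure(list(support = support, probabilities = as.numeric(probabilities),
                 n_x = n_x, n_y = ncol(support) - n_x),
            class = "empirical_pmf")
}

# Collapse the rows of a discrete matrix to integer keys 1..K.
row_keys <- function(V) {
  if (ncol(V) == 0L) return(rep.int(1L, nrow(V)))
  if (ncol(V) == 1L) return(match(V[, 1L], unique(V[, 1L])))
  keys <- do.call(paste, c(asplit(V, 2L), sep = "\r"))
  match(keys, unique(keys))
}

entropy_from_counts <- function(counts, log_base) {
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  h <- -sum(p * log(p))
  if (log_base == "2") h / log(2) else h
}

#' Plug-in entropy of a discrete replicate group
#'
#' Substitutes empirical frequencies into the entropy formula:
#' \eqn{\hat H = -\sum_s \hat p(s) \log \hat p(s)} over the distinct rows of
#' the sample matrix.  No bias correction is applied.  The entropy of the
#' zero-length prefix (a matrix with no columns) is 0.
#'
#' @param samples matrix of discrete symbols, one replicate per row (a
#'   vector is treated as one column).
#' @param log_base `"e"` (nats) or `"2"` (bits).
#' @return scalar entropy estimate.
#' @export
#' @examples
#' plugin_entropy(rep(0:1, each = 500), log_base = "2") # 1 bit
plugin_entropy <- function(samples, log_base = c("e", "2")) {
  log_base <- normalize_log_base(log_base)
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L)
  if (nrow(samples) == 0L) stop("empty sample set", call. = FALSE)
  if (ncol(samples) == 0L) return(0)
  entropy_from_counts(tabulate(row_keys(samples)), log_base)
}

#' Plug-in estimate of one InfoMat entry
#'
#' Uses the four-entropy decomposition
#' \deqn{I(X_i;Y_j|X^{i-1},Y^{j-1}) = H(X^i,Y^{j-1}) + H(X^{i-1},Y^j)
#'   - H(X^{i-1},Y^{j-1}) - H(X^i,Y^j)}
#' with each term a plug-in entropy of the corresponding replicate view.
#' At `i = j = 1` this is the plug-in mutual information.
#'
#' @inheritParams gaussian_cmi_entry
#' @param log_base `"e"` or `"2"`.
#' @return scalar estimate (may be slightly negative).
#' @export
plugin_cmi_entry <- function(views, log_base = c("e", "2")) {
  log_base <- normalize_log_base(log_base)
  stopifnot(is.list(views), length(views) == 4L)
  h <- vapply(views, plugin_entropy, 0, log_base = log_base)
  h[["xh"]] + h[["hy"]] - h[["hh"]] - h[["xy"]]
}

#' Exact conditional mutual information by enumeration
#'
#' Computes \eqn{I(X_i; Y_j | X^{i-1}, Y^{j-1})} exactly on a finite PMF by
#' explicit marginalization and conditioning: for every joint history
#' \eqn{h = (x^{i-1}, y^{j-1})} it forms the conditional joint of
#' \eqn{(X_i, Y_j)}, its conditional marginals, and sums
#' \eqn{p(h)\sum_{a,b} p(a,b|h) \log \frac{p(a,b|h)}{p(a|h)p(b|h)}}.
#' Serves as the independent reference for the plug-in estimator.
#'
#' @param pmf an [empirical_pmf()] object.
#' @param i,j 1-based step indices with `i <= n_x`, `j <= n_y`.
#' @param log_base `"e"` or `"2"`.
#' @return scalar conditional mutual information.
#' @export
exact_cmi_bruteforce <- function(pmf, i, j, log_base = c("e", "2")) {
  log_base <- normalize_log_base(log_base)
  stopifnot(inherits(pmf, "empirical_pmf"))
  i <- as.integer(i); j <- as.integer(j)
  if (i < 1L || i > pmf$n_x || j < 1L || j > pmf$n_y) {
    stop("(i, j) outside the prefixes covered by the PMF", call. = FALSE)
  }
  S <- pmf$support
  p <- pmf$probabilities
  xcol <- seq_len(pmf$n_x)
  ycol <- pmf$n_x + seq_len(pmf$n_y)
  hk <- row_keys(S[, c(xcol[seq_len(i - 1L)], ycol[seq_len(j - 1L)]),
                   drop = FALSE])
  ak <- row_keys(S[, xcol[i], drop = FALSE])
  bk <- row_keys(S[, ycol[j], drop = FALSE])

  total <- 0
  for (h in unique(hk)) {
    sel <- hk == h
    ph <- sum(p[sel])
    if (ph <= 0) next
    a <- ak[sel]; b <- bk[sel]; w <- p[sel] / ph
    # conditional joint and marginals of (X_i, Y_j) given this history
    jk <- paste(a, b)
    pj <- vapply(split(w, jk), sum, 0)
    pa <- vapply(split(w, a), sum, 0)
    pb <- vapply(split(w, b), sum, 0)
    ja <- sub(" .*", "", names(pj))
    jb <- sub(".* ", "", names(pj))
    keep <- pj > 0
    contrib <- sum(pj[keep] * log(pj[keep] /
                                    (pa[ja[keep]] * pb[jb[keep]])))
    total <- total + ph * contrib
  }
  if (log_base == "2") total / log(2) else total
}

#' Draw i.i.d. tuples from an empirical PMF
#'
#' Sampling helper for convergence tests of the plug-in estimator: returns
#' `n` rows of the PMF's support drawn with its probabilities (or, with
#' `exact_counts = TRUE`, a deterministic sample whose empirical frequencies
#' equal the PMF exactly — requires `n * probabilities` to be integers).
#'
#' @param pmf an [empirical_pmf()] object.
#' @param n number of tuples.
#' @param exact_counts replicate each support row `n * p` times instead of
#'   sampling.
#' @return A [paired_sequences()]-compatible list: matrices `x` (`n x n_x`)
#'   and `y` (`n x n_y`).
#' @export
sample_pmf <- function(pmf, n, exact_counts = FALSE) {
  stopifnot(inherits(pmf, "empirical_pmf"))
  if (exact_counts) {
    counts <- pmf$probabilities * n
    if (max(abs(counts - round(counts))) > 1e-9) {
      stop("'n' times the probabilities must be integers for exact counts",
           call. = FALSE)
    }
    rows <- rep.int(seq_len(nrow(pmf$support)), round(counts))
  } else {
    rows <- sample.int(nrow(pmf$support), n, replace = TRUE,
                       prob = pmf$probabilities)
  }
  list(x = pmf$support[rows, seq_len(pmf$n_x), drop = FALSE],
       y = pmf$support[rows, pmf$n_x + seq_len(pmf$n_y), drop = FALSE])
}

#' Estimate an InfoMat for finite-alphabet data by plug-in entropies
#'
#' Canonically encodes the observed symbols as integer codes, splits the
#' recording into replicated windows, and evaluates every entry through the
#' four-entropy decomposition.  The entropies of all \eqn{(i, j)} prefix
#' pairs are computed once on a grid and shared between entries, so the
#' whole matrix costs \eqn{(m+1)^2} tabulations.
#'
#' The support of the joint prefix grows exponentially with `i + j`; when
#' the number of symbols conditioned on is large relative to the number of
#' replicates the plug-in estimate degrades badly.  The estimator therefore
#' refuses when `2 m` exceeds `prefix_cap` (raise the cap explicitly when
#' the sample size supports it) and warns when the observed support of the
#' longest prefix approaches the replicate count.
#'
#' @param pair a discrete [paired_sequences()] object.
#' @param m InfoMat dimension; requires `n >= 2m`.
#' @param mode window split; see [split_blocks()].
#' @param log_base `"e"` or `"2"` (channel rates are conventionally bits).
#' @param prefix_cap maximum allowed joint prefix length `i + j` (default
#'   12 symbols).
#' @return An [infomat()] with `estimator_tag = "plugin"`.
#' @export
#' @examples
#' ps <- simulate_ising(n = 4000, seed = 7)
#' M <- estimate_infomat_plugin(ps, m = 3, log_base = "2")
#' round(as.matrix(M), 2)
estimate_infomat_plugin <- function(pair, m,
                                    mode = c("disjoint", "sliding"),
                                    log_base = c("e", "2"),
                                    prefix_cap = 12L) {
  stopifnot(inherits(pair, "paired_sequences"))
  log_base <- normalize_log_base(log_base)
  if (pair$alphabet != "discrete") {
    stop("plug-in estimator requires a discrete alphabet; ",
         "use estimate_infomat_gaussian() for real-valued data",
         call. = FALSE)
  }
  m <- as.integer(m)
  if (2L * m > prefix_cap) {
    stop(sprintf(
      paste0("joint prefix length 2m = %d exceeds prefix_cap = %d; the ",
             "plug-in support grows exponentially with the conditioned ",
             "history. Increase 'prefix_cap' only if n is large enough ",
             "(support can reach |alphabet|^(i+j))."),
      2L * m, prefix_cap), call. = FALSE)
  }
  blocks <- split_blocks(pair, m, mode)
  N <- blocks$N

  # Per-step integer codes (coordinates of one step collapsed first).
  step_codes <- function(W, d) {
    sapply(seq_len(ncol(W) / d), function(t) {
      row_keys(W[, (t - 1L) * d + seq_len(d), drop = FALSE])
    })
  }
  cx <- step_codes(blocks$x, blocks$d_x)
  cy <- step_codes(blocks$y, blocks$d_y)
  Kx <- max(cx); Ky <- max(cy)
  if (Kx^m * Ky^m > 2^52) {
    stop("alphabet too large for exact integer prefix encoding at this m",
         call. = FALSE)
  }
  # Cumulative mixed-radix prefix codes, column t+1 = code of the length-t
  # prefix (column 1 = empty prefix).
  cum_codes <- function(cc, K) {
    out <- matrix(0, N, m + 1L)
    for (t in seq_len(m)) out[, t + 1L] <- out[, t] * K + (cc[, t] - 1)
    out
  }
  px <- cum_codes(cx, Kx)
  py <- cum_codes(cy, Ky)

  H <- matrix(0, m + 1L, m + 1L)
  support_max <- 0L
  for (i in 0:m) for (j in 0:m) {
    if (i == 0L && j == 0L) next
    key <- px[, i + 1L] * Ky^j + py[, j + 1L]
    counts <- tabulate(match(key, unique(key)))
    support_max <- max(support_max, length(counts))
    H[i + 1L, j + 1L] <- entropy_from_counts(counts, log_base)
  }
  if (support_max > N / 5) {
    warning(sprintf(
      paste0("observed joint support (%d patterns) approaches the number ",
             "of replicates (%d); plug-in entries are undersampled"),
      support_max, N))
  }
  E <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    E[i, j] <- H[i + 1L, j] + H[i, j + 1L] - H[i, j] - H[i + 1L, j + 1L]
  }
  infomat(E, log_base = log_base, estimator_tag = "plugin")
}
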
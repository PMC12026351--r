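#' Configuration of the gaussianizing-flow estimator
#'
#' The neural estimator maps each variable through a strictly monotone
#' mixture-of-Gaussian-CDF transform
#' \deqn{\tau(x; h) = \sum_{j=1}^{k} w_j(h)\, \Phi(x; \mu_j(h),
#'   \sigma_j^2(h)),}
#' whose parameters are produced by a small conditioner network from the
#' conditioning history \eqn{h}, followed by the inverse standard-normal
#' CDF.  Since \eqn{\partial\tau/\partial x} is a Gaussian mixture density,
#' maximizing the flow's change-of-variables log-likelihood (uniform base)
#' is exactly conditional mixture-density maximum likelihood, which is how
#' the model is trained (minibatch Adam).
#'
#' @param k_components mixture size `k`.
#' @param width,depth hidden width and number of hidden layers of the
#'   conditioner network (ignored when there is no conditioning).
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed integer seed controlling initialization and shuffling.
#' @param clamp the uniform output is clamped to `[clamp, 1 - clamp]`
#'   before the inverse normal CDF, bounding the transformed samples.
#' @param cmi_formula how the Gaussian formula is applied to the
#'   transformed samples: `"conditional"` (default) keeps the original
#'   conditioning block in the covariance, `"unconditional"` assumes the
#'   conditioner absorbed it and uses the plain Gaussian MI of the
#'   transformed pair.
#' @return list of class `"maf_config"`.
#' @export
maf_config <- function(k_components = 10L, width = 64L, depth = 2L,
                       epochs = 200L, batch_size = 256L,
                       learning_rate = 1e-3, seed = 1L, clamp = 1e-6,
                       cmi_formula = c("conditional", "unconditional")) {
  cmi_formula <- match.arg(cmi_formula)
  stopifnot(k_components >= 1L, width >= 1L, depth >= 1L, epochs >= 1L,
            batch_size >= 1L, learning_rate > 0, clamp > 0, clamp < 0.5)
  structure(list(k_components = as.integer(k_components),
                 width = as.integer(width), depth = as.integer(depth),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 clamp = clamp, cmi_formula = cmi_formula),
            class = "maf_config")
}

# ---- mixture-density conditioner network (hand-rolled, CPU) --------------

mdn_init <- function(q, k, width, depth, target_std) {
  params <- list()
  if (q > 0L) {
    dims <- c(q, rep(width, depth), 3L * k)
    for (l in seq_len(length(dims) - 1L)) {
      params[[paste0("W", l)]] <-
        matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = 1 / sqrt(dims[l])),
               dims[l], dims[l + 1L])
      params[[paste0("b", l)]] <- numeric(dims[l + 1L])
    }
    last <- length(dims) - 1L
  } else {
    params$b1 <- numeric(3L * k)
    last <- 1L
  }
  # seed the mixture means at marginal quantiles and moderate widths so the
  # initial model already approximates the marginal law
  b <- params[[paste0("b", last)]]
  b[k + seq_len(k)] <- stats::quantile(target_std, probs = seq_len(k) / (k + 1))
  b[2L * k + seq_len(k)] <- log(0.5)
  params[[paste0("b", last)]] <- b
  attr(params, "q") <- q
  attr(params, "k") <- k
  attr(params, "depth") <- if (q > 0L) depth else 0L
  params
}

mdn_forward <- function(params, H) {
  q <- attr(params, "q"); depth <- attr(params, "depth")
  acts <- list()
  if (q > 0L) {
    a <- H
    for (l in seq_len(depth)) {
      a <- tanh(sweep(a %*% params[[paste0("W", l)]], 2L,
                      params[[paste0("b", l)]], "+"))
      acts[[l]] <- a
    }
    out <- sweep(a %*% params[[paste0("W", depth + 1L)]], 2L,
                 params[[paste0("b", depth + 1L)]], "+")
  } else {
    out <- matrix(params$b1, nrow(H), length(params$b1), byrow = TRUE)
  }
  list(out = out, acts = acts)
}

# Split the raw output into mixture parameters.
mdn_params <- function(out, k) {
  a <- out[, seq_len(k), drop = FALSE]
  mu <- out[, k + seq_len(k), drop = FALSE]
  s <- pmin(pmax(out[, 2L * k + seq_len(k), drop = FALSE], -7), 7)
  amax <- apply(a, 1L, max)
  w <- exp(a - amax)
  w <- w / rowSums(w)
  list(w = w, mu = mu, sd = exp(s))
}

# Mean negative log-likelihood and its gradient w.r.t. the raw outputs.
mdn_nll_grad <- function(out, x, k) {
  mp <- mdn_params(out, k)
  z <- (x - mp$mu) / mp$sd
  comp <- log(mp$w) - 0.5 * z^2 - log(mp$sd) - 0.5 * log(2 * pi)
  cmax <- apply(comp, 1L, max)
  ll <- cmax + log(rowSums(exp(comp - cmax)))
  r <- exp(comp - ll)                       # component posteriors
  B <- length(x)
  dout <- cbind(r - mp$w,                   # d(-ll)/da (before the -1/B)
                r * z / mp$sd,
                r * (z^2 - 1))
  list(nll = -mean(ll), dout = -dout / B)
}

mdn_backward <- function(params, H, acts, dout) {
  q <- attr(params, "q"); depth <- attr(params, "depth")
  grads <- list()
  if (q == 0L) {
    grads$b1 <- colSums(dout)
    return(grads)
  }
  d <- dout
  for (l in seq.int(depth + 1L, 1L)) {
    inp <- if (l == 1L) H else acts[[l - 1L]]
    grads[[paste0("W", l)]] <- crossprod(inp, d)
    grads[[paste0("b", l)]] <- colSums(d)
    if (l > 1L) {
      d <- (d %*% t(params[[paste0("W", l)]])) * (1 - acts[[l - 1L]]^2)
    }
  }
  grads
}

mdn_fit <- function(x, H, config, reseed = TRUE) {
  if (reseed) set.seed(config$seed)
  k <- config$k_components
  N <- length(x)
  params <- mdn_init(ncol(H), k, config$width, config$depth, x)
  pn <- names(params)
  mstate <- vstate <- lapply(params, function(p) p * 0)
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  nb <- max(1L, ceiling(N / config$batch_size))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(N)
    for (b in seq_len(nb)) {
      idx <- ord[seq.int((b - 1L) * config$batch_size + 1L,
                         min(b * config$batch_size, N))]
      fw <- mdn_forward(params, H[idx, , drop = FALSE])
      ng <- mdn_nll_grad(fw$out, x[idx], k)
      if (!is.finite(ng$nll)) {
        stop("gaussianizer training diverged (non-finite loss); ",
             "reduce 'learning_rate'", call. = FALSE)
      }
      grads <- mdn_backward(params, H[idx, , drop = FALSE], fw$acts, ng$dout)
      step <- step + 1L
      corr <- sqrt(1 - beta2^step) / (1 - beta1^step)
      for (nm in pn) {
        g <- grads[[nm]]
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g^2
        params[[nm]] <- params[[nm]] -
          lr * corr * mstate[[nm]] / (sqrt(vstate[[nm]]) + eps)
      }
    }
  }
  params
}

# ---- gaussianizer ---------------------------------------------------------

#' Fit a conditional gaussianizing transform
#'
#' Learns, for each coordinate of `target`, a strictly monotone
#' mixture-of-Gaussian-CDF map conditioned on `conditioning` and on the
#' earlier target coordinates (autoregressive order), by maximizing the
#' exact change-of-variables log-likelihood.  Applying the fitted CDF
#' mixture and then the inverse standard-normal CDF yields approximately
#' standard-normal outputs whatever the (continuous) input law.
#'
#' @param target `N x d` real matrix (or vector) to gaussianize.
#' @param conditioning `N x q` matrix of conditioning variables; may have
#'   zero columns or be `NULL` for the unconditional case.
#' @param config a [maf_config()].
#' @param reseed seed the RNG from `config$seed` before fitting (set
#'   `FALSE` when an outer loop manages the seed).
#' @return An object of class `"gaussianizer"`; use [transform_samples()]
#'   to map data through it.
#' @export
#' @examples
#' x <- exp(rnorm(2000))   # log-normal
#' g <- fit_conditional_gaussianizer(x, NULL,
#'   maf_config(epochs = 30, seed = 2))
#' z <- transform_samples(g, x, NULL)
fit_conditional_gaussianizer <- function(target, conditioning = NULL,
                                         config = maf_config(),
                                         reseed = TRUE) {
  stopifnot(inherits(config, "maf_config"))
  if (is.null(dim(target))) target <- matrix(target, ncol = 1L)
  target <- as.matrix(target)
  if (nrow(target) < 2L || ncol(target) < 1L) {
    stop("empty target", call. = FALSE)
  }
  if (!all(is.finite(target))) {
    stop("target contains non-finite values; the likelihood would diverge",
         call. = FALSE)
  }
  if (is.null(conditioning)) conditioning <- matrix(0, nrow(target), 0L)
  conditioning <- as.matrix(conditioning)
  if (nrow(conditioning) != nrow(target)) {
    stop("conditioning and target must have the same number of rows",
         call. = FALSE)
  }
  if (reseed) set.seed(config$seed)
  std <- function(V) {
    mu <- colMeans(V)
    sd <- apply(V, 2L, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    list(mu = mu, sd = sd, V = sweep(sweep(V, 2L, mu), 2L, sd, "/"))
  }
  ts <- std(target)
  cs <- std(conditioning)
  models <- vector("list", ncol(target))
  for (cc in seq_len(ncol(target))) {
    H <- cbind(cs$V, ts$V[, seq_len(cc - 1L), drop = FALSE])
    models[[cc]] <- mdn_fit(ts$V[, cc], H, config, reseed = FALSE)
  }
  structure(list(models = models, target_std = ts[c("mu", "sd")],
                 cond_std = cs[c("mu", "sd")], d = ncol(target),
                 q = ncol(conditioning), config = config),
            class = "gaussianizer")
}

#' Map samples through a fitted gaussianizer
#'
#' Evaluates the fitted CDF-mixture per coordinate, clamps the uniform
#' output away from \{0, 1\}, and applies the inverse standard-normal CDF.
#'
#' @param g a fitted [fit_conditional_gaussianizer()] object.
#' @param target,conditioning samples laid out as at fitting time.
#' @return `N x d` matrix of approximately standard-normal values.
#' @export
transform_samples <- function(g, target, conditioning = NULL) {
  stopifnot(inherits(g, "gaussianizer"))
  if (is.null(dim(target))) target <- matrix(target, ncol = 1L)
  target <- as.matrix(target)
  if (is.null(conditioning)) conditioning <- matrix(0, nrow(target), 0L)
  conditioning <- as.matrix(conditioning)
  stopifnot(ncol(target) == g$d, ncol(conditioning) == g$q)
  tstd <- sweep(sweep(target, 2L, g$target_std$mu), 2L, g$target_std$sd, "/")
  cstd <- if (g$q > 0L) {
    sweep(sweep(conditioning, 2L, g$cond_std$mu), 2L, g$cond_std$sd, "/")
  } else conditioning
  clamp <- g$config$clamp
  k <- g$config$k_components
  out <- matrix(0, nrow(target), g$d)
  for (cc in seq_len(g$d)) {
    H <- cbind(cstd, tstd[, seq_len(cc - 1L), drop = FALSE])
    mp <- mdn_params(mdn_forward(g$models[[cc]], H)$out, k)
    u <- rowSums(mp$w * stats::pnorm((tstd[, cc] - mp$mu) / mp$sd))
    out[, cc] <- stats::qnorm(pmin(pmax(u, clamp), 1 - clamp))
  }
  out
}

# Evaluate the CDF-mixture (uniform output) at arbitrary target values for
# fixed conditioning rows; used to verify strict monotonicity.
gaussianizer_cdf <- function(g, x, conditioning = NULL, coordinate = 1L) {
  stopifnot(inherits(g, "gaussianizer"), coordinate == 1L)
  if (is.null(conditioning)) conditioning <- matrix(0, length(x), 0L)
  conditioning <- as.matrix(conditioning)
  tstd <- (x - g$target_std$mu[1L]) / g$target_std$sd[1L]
  cstd <- if (g$q > 0L) {
    sweep(sweep(conditioning, 2L, g$cond_std$mu), 2L, g$cond_std$sd, "/")
  } else conditioning
  mp <- mdn_params(mdn_forward(g$models[[1L]], cstd)$out,
                   g$config$k_components)
  rowSums(mp$w * stats::pnorm((tstd - mp$mu) / mp$sd))
}

# Gaussian CMI I(X;Y|Z) from sample covariance of the stacked columns.
gaussian_cmi_xyz <- function(X, Y, Z, log_base = "e", ridge = 1e-10) {
  ld <- function(V) {
    if (ncol(V) == 0L) return(0)
    V <- sweep(V, 2L, colMeans(V))
    logdet_chol(add_ridge(crossprod(V) / nrow(V), ridge))
  }
  v <- 0.5 * (ld(cbind(X, Z)) + ld(cbind(Y, Z)) - ld(Z) - ld(cbind(X, Y, Z)))
  if (log_base == "2") v / log(2) else v
}

#' Neural estimate of one InfoMat entry
#'
#' Fits two conditional gaussianizers — the current X step given the joint
#' history \eqn{(X^{i-1}, Y^{j-1})} and the current Y step given the same
#' history — maps the samples through them, and evaluates the Gaussian
#' conditional mutual information formula on the transformed samples.
#' Because each transform is a conditional diffeomorphism, the population
#' conditional mutual information is invariant under it; the estimate is in
#' general a lower bound of the true value, since marginally Gaussian
#' outputs need not be jointly Gaussian.
#'
#' @param views a [prefix_views()] object (its `i`, `j`, `d_x`, `d_y`
#'   attributes locate the current steps inside the views).
#' @param config a [maf_config()].
#' @param log_base `"e"` or `"2"`.
#' @return scalar estimate.
#' @export
neural_cmi_entry <- function(views, config = maf_config(),
                             log_base = c("e", "2")) {
  log_base <- normalize_log_base(log_base)
  stopifnot(inherits(views, "prefix_views"))
  i <- attr(views, "i"); j <- attr(views, "j")
  d_x <- attr(views, "d_x"); d_y <- attr(views, "d_y")
  Z <- views$hh
  Xi <- views$xh[, (i - 1L) * d_x + seq_len(d_x), drop = FALSE]
  Yj <- views$xy[, i * d_x + (j - 1L) * d_y + seq_len(d_y), drop = FALSE]
  set.seed(config$seed)
  gx <- fit_conditional_gaussianizer(Xi, Z, config, reseed = FALSE)
  gy <- fit_conditional_gaussianizer(Yj, Z, config, reseed = FALSE)
  Xp <- transform_samples(gx, Xi, Z)
  Yp <- transform_samples(gy, Yj, Z)
  if (config$cmi_formula == "conditional") {
    gaussian_cmi_xyz(Xp, Yp, Z, log_base)
  } else {
    gaussian_cmi_xyz(Xp, Yp, Z[, 0L, drop = FALSE], log_base)
  }
}

#' Estimate an InfoMat with the gaussianizing-flow estimator
#'
#' Applies [neural_cmi_entry()] to every `(i, j)` prefix pair of the split
#' recording.  One model pair is trained per entry, so the cost scales with
#' \eqn{m^2} times the cost of a single fit; prefer the Gaussian estimator
#' for large `m` or near-linear data.  An entry whose training diverges is
#' flagged (recorded in the `"failed_entries"` attribute with its error
#' message) and set to `NA_real_`-free 0 rather than aborting the matrix.
#'
#' @param pair a real-valued [paired_sequences()].
#' @param m InfoMat dimension.
#' @param config a [maf_config()]; entry-level seeds are derived from
#'   `config$seed` deterministically.
#' @param mode window split; see [split_blocks()].
#' @param log_base `"e"` or `"2"`.
#' @return An [infomat()] with `estimator_tag = "neural"`.
#' @export
estimate_infomat_neural <- function(pair, m, config = maf_config(),
                                    mode = c("disjoint", "sliding"),
                                    log_base = c("e", "2")) {
  stopifnot(inherits(pair, "paired_sequences"),
            inherits(config, "maf_config"))
  log_base <- normalize_log_base(log_base)
  blocks <- split_blocks(pair, m, mode)
  E <- matrix(0, m, m)
  failed <- list()
  for (i in seq_len(m)) for (j in seq_len(m)) {
    cfg <- config
    cfg$seed <- (config$seed + 7919L * i + 104729L * j) %% .Machine$integer.max
    E[i, j] <- tryCatch(
      neural_cmi_entry(prefix_views(blocks, i, j), cfg, log_base),
      error = function(e) {
        failed[[sprintf("(%d,%d)", i, j)]] <<- conditionMessage(e)
        0
      })
  }
  if (length(failed) > 0L) {
    warning(sprintf("%d entr%s failed and were zeroed: %s",
                    length(failed), if (length(failed) == 1L) "y" else "ies",
                    paste(names(failed), collapse = ", ")))
  }
  M <- infomat(E, log_base = log_base, estimator_tag = "neural")
  attr(M, "failed_entries") <- failed
  M
}
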
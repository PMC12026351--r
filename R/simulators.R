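#' Specify a joint Gaussian autoregressive pair
#'
#' Defines the two coupled scalar recursions
#' \deqn{X_t = \sum_{k} \alpha^X_k X_{t-k} + \alpha^Y_k Y_{t-k} + N^X_t,
#'   \qquad
#'   Y_t = \sum_{k} \beta^X_k X_{t-k} + \beta^Y_k Y_{t-k} + N^Y_t,}
#' with independent centered Gaussian innovations.  Coefficient vectors are
#' indexed from lag 0: `alpha_x[k + 1]` multiplies \eqn{X_{t-k}} in the X
#' equation, etc.
#'
#' Lag-0 terms need care: a process cannot depend on its own current value,
#' and simultaneous lag-0 dependence in both directions would make the
#' per-step system cyclic.  The convention here is that \eqn{X_t} is drawn
#' first and \eqn{Y_t} given \eqn{X_t}: the lag-0 self-coefficients
#' (`alpha_x[1]`, `beta_y[1]`) and the lag-0 Y-to-X coefficient
#' (`alpha_y[1]`) must be zero, while `beta_x[1]` realizes instantaneous
#' X-to-Y coupling.
#'
#' Stationarity (spectral radius of the companion form of the reduced joint
#' system strictly below 1) is checked at construction.
#'
#' @param kbar_x,kbar_y memory lengths of the X and Y equations.
#' @param alpha_x,alpha_y length `kbar_x + 1` weights of the X equation on
#'   lagged X resp. lagged Y.
#' @param beta_x,beta_y length `kbar_y + 1` weights of the Y equation on
#'   lagged X resp. lagged Y.
#' @param noise_var_x,noise_var_y innovation variances (> 0).
#' @param decay optional function of the time index returning a
#'   multiplicative modulation of all coupling coefficients at that step
#'   (time-varying dependence hook); `NULL` for a constant system.
#' @return An object of class `"ar_spec"`.
#' @export
#' @examples
#' # instantaneous-only coupling: y_t = 0.5 x_t + noise
#' sp <- ar_spec(kbar_x = 0, kbar_y = 0, beta_x = 0.5)
ar_spec <- function(kbar_x = 0L, kbar_y = 0L,
                    alpha_x = numeric(kbar_x + 1L),
                    alpha_y = numeric(kbar_x + 1L),
                    beta_x = numeric(kbar_y + 1L),
                    beta_y = numeric(kbar_y + 1L),
                    noise_var_x = 1, noise_var_y = 1,
                    decay = NULL) {
  kbar_x <- as.integer(kbar_x); kbar_y <- as.integer(kbar_y)
  stopifnot(kbar_x >= 0L, kbar_y >= 0L,
            noise_var_x > 0, noise_var_y > 0)
  pad <- function(v, len, nm) {
    v <- as.numeric(v)
    if (length(v) == 1L && len > 1L) v <- c(v, numeric(len - 1L))
    if (length(v) != len) {
      stop(sprintf("'%s' must have length %d (lags 0..%d)", nm, len,
                   len - 1L), call. = FALSE)
    }
    v
  }
  alpha_x <- pad(alpha_x, kbar_x + 1L, "alpha_x")
  alpha_y <- pad(alpha_y, kbar_x + 1L, "alpha_y")
  beta_x <- pad(beta_x, kbar_y + 1L, "beta_x")
  beta_y <- pad(beta_y, kbar_y + 1L, "beta_y")
  if (alpha_x[1L] != 0 || beta_y[1L] != 0) {
    stop("lag-0 self-coefficients (alpha_x[1], beta_y[1]) must be zero",
         call. = FALSE)
  }
  if (alpha_y[1L] != 0) {
    stop("lag-0 Y-to-X coupling (alpha_y[1]) must be zero: X_t is drawn ",
         "before Y_t; use beta_x[1] for instantaneous coupling",
         call. = FALSE)
  }
  if (!is.null(decay) && !is.function(decay)) {
    stop("'decay' must be NULL or a function of the time index",
         call. = FALSE)
  }
  spec <- structure(
    list(kbar_x = kbar_x, kbar_y = kbar_y,
         alpha_x = alpha_x, alpha_y = alpha_y,
         beta_x = beta_x, beta_y = beta_y,
         noise_var_x = noise_var_x, noise_var_y = noise_var_y,
         decay = decay),
    class = "ar_spec"
  )
  sr <- ar_spectral_radius(spec)
  if (sr >= 1) {
    stop(sprintf(
      "non-stationary specification: companion spectral radius %.3f >= 1",
      sr), call. = FALSE)
  }
  spec$spectral_radius <- sr
  spec
}

# Spectral radius of the companion matrix of the reduced joint system.
# The structural form A0 Z_t = sum_k A_k Z_{t-k} + N_t with
# A0 = [[1, 0], [-beta_x0, 1]] is reduced by C_k = A0^{-1} A_k.
ar_spectral_radius <- function(spec) {
  p <- max(spec$kbar_x, spec$kbar_y)
  if (p == 0L) return(0)
  lag <- function(v, k) if (k + 1L <= length(v)) v[k + 1L] else 0
  A0inv <- solve(matrix(c(1, -spec$beta_x[1L], 0, 1), 2L))
  comp <- matrix(0, 2L * p, 2L * p)
  for (k in seq_len(p)) {
    Ak <- matrix(c(lag(spec$alpha_x, k), lag(spec$beta_x, k),
                   lag(spec$alpha_y, k), lag(spec$beta_y, k)), 2L)
    comp[1:2, (2L * k - 1L):(2L * k)] <- A0inv %*% Ak
  }
  if (p > 1L) {
    comp[3:(2L * p), 1:(2L * (p - 1L))] <- diag(2L * (p - 1L))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate a joint Gaussian autoregressive pair
#'
#' Runs the coupled recursion of an [ar_spec()] from zero initial
#' conditions, discards a burn-in of `50 * max(kbar_x, kbar_y) + 100` steps
#' so the retained stretch is effectively stationary, and returns `n`
#' post-burn-in samples.
#'
#' @param spec an [ar_spec()].
#' @param n number of retained samples.
#' @param seed RNG seed (all simulators are bit-reproducible given it).
#' @return A real-valued [paired_sequences()].
#' @export
simulate_gaussian_ar <- function(spec, n, seed) {
  stopifnot(inherits(spec, "ar_spec"), n >= 1L)
  set.seed(as.integer(seed))
  burn <- 50L * max(spec$kbar_x, spec$kbar_y) + 100L
  total <- n + burn
  ex <- stats::rnorm(total, sd = sqrt(spec$noise_var_x))
  ey <- stats::rnorm(total, sd = sqrt(spec$noise_var_y))
  x <- numeric(total); y <- numeric(total)
  kx <- spec$kbar_x; ky <- spec$kbar_y
  for (t in seq_len(total)) {
    g <- if (is.null(spec$decay)) 1 else spec$decay(max(t - burn, 1L))
    sx <- 0
    for (k in seq_len(kx)) {
      if (t - k >= 1L) {
        sx <- sx + spec$alpha_x[k + 1L] * x[t - k] +
          spec$alpha_y[k + 1L] * y[t - k]
      }
    }
    x[t] <- g * sx + ex[t]
    sy <- spec$beta_x[1L] * x[t]
    for (k in seq_len(ky)) {
      if (t - k >= 1L) {
        sy <- sy + spec$beta_x[k + 1L] * x[t - k] +
          spec$beta_y[k + 1L] * y[t - k]
      }
    }
    y[t] <- g * sy + ey[t]
  }
  keep <- burn + seq_len(n)
  paired_sequences(x[keep], y[keep], alphabet = "real")
}

#' Simulate an i.i.d. correlated Gaussian pair
#'
#' \eqn{Y_t = \rho X_t + \sqrt{1 - \rho^2} Z_t} with \eqn{X, Z} i.i.d.
#' standard normal, so each step carries mutual information
#' \eqn{-\tfrac12 \log(1 - \rho^2)} and steps are independent.
#'
#' @param rho correlation, `|rho| < 1`.
#' @param n number of samples.
#' @param seed RNG seed.
#' @return A real-valued [paired_sequences()].
#' @export
simulate_correlated_iid <- function(rho, n, seed) {
  if (abs(rho) >= 1) stop("'rho' must satisfy |rho| < 1", call. = FALSE)
  set.seed(as.integer(seed))
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  paired_sequences(x, y, alphabet = "real")
}

distortion_maps <- list(
  identity = identity,
  cube = function(v) v^3,
  exp = exp,
  arcsinh = asinh,
  log = function(v) {
    if (any(v <= 0)) {
      stop("'log' map is undefined on nonpositive samples; use a ",
           "full-support invertible map such as 'cube' or 'arcsinh'",
           call. = FALSE)
    }
    log(v)
  }
)

resolve_map <- function(f, name) {
  if (is.function(f)) return(f)
  f <- as.character(f)[1L]
  if (!f %in% names(distortion_maps)) {
    stop(sprintf("unknown %s '%s'; built-ins: %s", name, f,
                 paste(names(distortion_maps), collapse = ", ")),
         call. = FALSE)
  }
  distortion_maps[[f]]
}

#' Cyclically shift and invertibly distort a paired sequence
#'
#' Within every disjoint window of length `m`, the Y samples are cyclically
#' shifted forward by `shift` steps (so `Y` at window position `t + shift`
#' is the original `Y` at position `t`), then strictly monotone per-sample
#' maps are applied to each margin.  Because both operations are invertible,
#' every conditional mutual information value is preserved: the dependence
#' that sat on the diagonal moves to the `shift`-th off-diagonal band with
#' unchanged per-entry values.  This is the standard stress test for
#' estimators that assume linearity.
#'
#' @param pair a [paired_sequences()] (scalar per step).
#' @param m window length within which the cyclic shift is applied;
#'   requires `shift < m`.  `n` is truncated to a multiple of `m`.
#' @param shift nonnegative cyclic shift of Y within each window.
#' @param map_x,map_y strictly monotone maps applied per sample: a function
#'   or one of `"identity"`, `"cube"`, `"exp"`, `"arcsinh"`, `"log"`
#'   (`"log"` requires positive support and errors otherwise).
#' @return A new [paired_sequences()].
#' @export
apply_invertible_distortion <- function(pair, m, shift = 0L,
                                        map_x = "identity",
                                        map_y = "identity") {
  stopifnot(inherits(pair, "paired_sequences"))
  m <- as.integer(m); shift <- as.integer(shift)
  if (shift < 0L || shift >= m) {
    stop("'shift' must satisfy 0 <= shift < m", call. = FALSE)
  }
  if (pair$d_x != 1L || pair$d_y != 1L) {
    stop("distortion supports scalar-per-step sequences", call. = FALSE)
  }
  fx <- resolve_map(map_x, "map_x")
  fy <- resolve_map(map_y, "map_y")
  nw <- pair$n %/% m
  if (nw < 1L) stop("need n >= m", call. = FALSE)
  n <- nw * m
  if (n < pair$n) {
    warning(sprintf("truncating to %d samples (%d full windows of %d)",
                    n, nw, m))
  }
  x <- pair$x[seq_len(n), 1L]
  y <- pair$y[seq_len(n), 1L]
  if (shift > 0L) {
    pos <- rep(seq_len(m), nw)                      # position within window
    src <- seq_len(n) - shift + m * (pos <= shift)  # cyclic source index
    y <- y[src]
  }
  paired_sequences(fx(x), fy(y), alphabet = "real")
}

#' Simulate the Ising channel with oblivious i.i.d. input
#'
#' A binary channel with one-step memory: each output copies the current or
#' the previous input with probability 1/2 each,
#' \eqn{Y_t = X_t} w.p. 0.5, else \eqn{X_{t-1}}.  The input is channel-
#' oblivious \eqn{X_t \sim} i.i.d. Bernoulli(1/2) (no feedback); the
#' pre-transmission input \eqn{X_0} is an independent Bernoulli(1/2) draw.
#'
#' @param n number of channel uses.
#' @param seed RNG seed.
#' @return A discrete [paired_sequences()] of 0/1 symbols.
#' @export
simulate_ising <- function(n, seed) {
  stopifnot(n >= 1L)
  set.seed(as.integer(seed))
  x <- sample(0:1, n + 1L, replace = TRUE)  # x[1] is X_0
  coin <- sample(c(TRUE, FALSE), n, replace = TRUE)
  xt <- x[-1L]
  xprev <- x[-(n + 1L)]
  y <- ifelse(coin, xt, xprev)
  paired_sequences(as.integer(xt), as.integer(y), alphabet = "discrete")
}

#' Simulate the Trapdoor channel with oblivious i.i.d. input
#'
#' A binary finite-state channel: given state \eqn{S_{t-1} = 0} the output
#' passes through a Z-channel with crossover 1/2 (input 0 transmitted
#' faithfully, input 1 randomized), given \eqn{S_{t-1} = 1} through the
#' mirror-image S-channel (input 1 faithful, input 0 randomized); the state
#' updates as \eqn{S_t = S_{t-1} \oplus X_t \oplus Y_t}.  Inputs are
#' channel-oblivious i.i.d. Bernoulli(1/2) and the initial state is
#' \eqn{S_0 = 0}.
#'
#' @inheritParams simulate_ising
#' @return A discrete [paired_sequences()] of 0/1 symbols with attribute
#'   `"state"` carrying the state trace.
#' @export
simulate_trapdoor <- function(n, seed) {
  stopifnot(n >= 1L)
  set.seed(as.integer(seed))
  x <- sample(0:1, n, replace = TRUE)
  coin <- sample(0:1, n, replace = TRUE)
  y <- integer(n); s <- integer(n)
  state <- 0L
  for (t in seq_len(n)) {
    # faithful when the input matches the transparent symbol of the active
    # channel (0 for Z when state 0, 1 for S when state 1), i.e. x == state
    y[t] <- if (x[t] == state) x[t] else coin[t]
    state <- bitwXor(bitwXor(state, x[t]), y[t])
    s[t] <- state
  }
  out <- paired_sequences(x, y, alphabet = "discrete")
  attr(out, "state") <- s
  out
}
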
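# Shared numerical helpers: harmonic curves over the 24-h day, seeded
# evaluation, WAIC-from-draws, and small weighted-statistics utilities.

#' Harmonic curve over the 24-hour day
#'
#' A periodic curve \eqn{b_0 + \sum_{k=1}^K a_k \sin(2\pi k t/24) + c_k
#' \cos(2\pi k t/24)} used throughout the package: as a login-intensity
#' shape, as a diurnal accuracy or session-length modulation in the
#' generator, and as the fitted mean curve of harmonic regression.
#'
#' @param b0 intercept (mesor).
#' @param a numeric vector of sine coefficients, one per harmonic
#'   \eqn{k = 1, \dots, K}; may be empty for a constant curve.
#' @param c numeric vector of cosine coefficients, same length as `a`.
#' @return An object of class `harmonic_curve`.
#' @examples
#' h <- harmonic_curve(0.8, a = 0.1, c = 0)
#' predict(h, t = c(0, 6, 12, 18))
#' @export
harmonic_curve <- function(b0 = 0, a = numeric(), c = numeric()) {
  a <- as.numeric(a); c <- as.numeric(c)
  if (length(a) != length(c)) {
    stop("harmonic_curve: `a` and `c` must have the same length (one pair per harmonic)")
  }
  structure(list(b0 = as.numeric(b0), a = a, c = c, K = length(a)),
            class = "harmonic_curve")
}

#' @rdname harmonic_curve
#' @param object,x a `harmonic_curve`.
#' @param t times of day in hours (any real; evaluated modulo 24).
#' @param ... unused.
#' @export
predict.harmonic_curve <- function(object, t, ...) {
  y <- rep_len(object$b0, length(t))
  if (object$K > 0) {
    for (k in seq_len(object$K)) {
      ang <- 2 * pi * k * t / 24
      y <- y + object$a[k] * sin(ang) + object$c[k] * cos(ang)
    }
  }
  y
}

#' @rdname harmonic_curve
#' @export
print.harmonic_curve <- function(x, ...) {
  cat(sprintf("harmonic curve (period 24 h), K = %d, b0 = %.4g\n", x$K, x$b0))
  if (x$K > 0) {
    for (k in seq_len(x$K)) {
      cat(sprintf("  k = %d: a (sin) = %.4g, c (cos) = %.4g, amplitude = %.4g\n",
                  k, x$a[k], x$c[k], sqrt(x$a[k]^2 + x$c[k]^2)))
    }
  }
  invisible(x)
}

#' Amplitude and peak time of a fitted first harmonic
#'
#' For a sine/cosine pair \eqn{a \sin\theta + c \cos\theta} with
#' \eqn{\theta = 2\pi k t/24}, the amplitude is \eqn{\sqrt{a^2+c^2}} and the
#' (first) peak time solves \eqn{\theta = \mathrm{atan2}(a, c)}.
#'
#' @param a sine coefficient.
#' @param c cosine coefficient.
#' @param k harmonic order (default 1).
#' @return `harmonic_amplitude`: the amplitude. `harmonic_peak_time`: the peak
#'   time in hours in `[0, 24/k)`.
#' @export
harmonic_amplitude <- function(a, c, k = 1) sqrt(a^2 + c^2)

#' @rdname harmonic_amplitude
#' @export
harmonic_peak_time <- function(a, c, k = 1) {
  (24 / (2 * pi * k)) * (atan2(a, c) %% (2 * pi))
}

#' WAIC from a matrix of pointwise posterior log-densities
#'
#' Computes the widely-applicable information criterion from an `S x n` matrix
#' of log predictive densities, `ll[s, i] = log p(y_i | theta_s)`:
#' \deqn{\mathrm{lppd} = \sum_i \log \frac{1}{S}\sum_s e^{ll_{si}}, \quad
#'   p_\mathrm{waic} = \sum_i \mathrm{Var}_s(ll_{si}), \quad
#'   \mathrm{WAIC} = -2(\mathrm{lppd} - p_\mathrm{waic}).}
#'
#' @param ll numeric matrix of log-densities, draws in rows, observations in
#'   columns.
#' @return A list with elements `lppd`, `p_waic`, `waic` and `n_obs`.
#' @examples
#' waic_from_loglik(matrix(-1.2, nrow = 50, ncol = 3)) # p_waic = 0
#' @export
waic_from_loglik <- function(ll) {
  ll <- as.matrix(ll)
  if (!is.numeric(ll) || any(!is.finite(ll))) {
    stop("waic_from_loglik: `ll` must be a finite numeric matrix")
  }
  S <- nrow(ll)
  # column-wise log-mean-exp, stabilised
  mx <- apply(ll, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2, mx, "-"))))
  p_i <- apply(ll, 2, stats::var)
  if (S == 1) p_i <- rep(0, ncol(ll))
  lppd <- sum(lppd_i)
  p_waic <- sum(p_i)
  list(lppd = lppd, p_waic = p_waic, waic = -2 * (lppd - p_waic),
       n_obs = ncol(ll))
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's
# random-number state afterwards. Keeps package functions from clobbering
# user simulations.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Weighted mean / RMSE over paired values and predictions.
weighted_rmse <- function(y, pred, w = rep(1, length(y))) {
  ok <- is.finite(y) & is.finite(pred) & is.finite(w) & w > 0
  sqrt(sum(w[ok] * (y[ok] - pred[ok])^2) / sum(w[ok]))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# design matrix of sin/cos pairs up to harmonic K at times t (hours)
harmonic_design <- function(t, K) {
  X <- matrix(1, nrow = length(t), ncol = 1 + 2 * K)
  colnames(X) <- c("(Intercept)",
                   if (K > 0) paste0(rep(c("sin", "cos"), K),
                                     rep(seq_len(K), each = 2)))
  if (K > 0) {
    for (k in seq_len(K)) {
      ang <- 2 * pi * k * t / 24
      X[, 2 * k] <- sin(ang)
      X[, 2 * k + 1] <- cos(ang)
    }
  }
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a
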
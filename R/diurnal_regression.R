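# Time-of-day analyses: half-hour binning of session metrics, harmonic
# (cosinor) and polynomial baseline regression with weighted least squares
# or a Bayesian weighted normal model (for WAIC), frozen-model out-of-sample
# RMSE, and the two-cohort replication protocol.

#' Bin a session metric over the 24-hour day
#'
#' Assigns each session to one of 48 half-hour bins by its local start time
#' (half-open bins `[k/2, (k+1)/2)`) and summarises the chosen metric per
#' bin: mean session accuracy, fraction of all logins, or mean session
#' length in trials. Bin weight is the number of contributing sessions;
#' the value is `NA` where the weight is 0.
#'
#' @param sessions a data frame from [session_summaries()].
#' @param metric `"session_accuracy"`, `"login_fraction"` or
#'   `"session_length"`.
#' @return A `day_series` data frame with 48 rows: `bin_start_hour`,
#'   `t_mid`, `value`, `weight`.
#' @export
bin_day <- function(sessions, metric = c("session_accuracy", "login_fraction",
                                         "session_length")) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(sessions))
  if (nrow(sessions) == 0) stop("bin_day: empty input")
  if (is.null(sessions$start_local_time)) {
    stop("bin_day: sessions lack start_local_time; localise the log first")
  }
  s <- sessions
  if (metric == "session_accuracy") {
    s <- s[!is.na(s$mean_accuracy), , drop = FALSE]
    if (nrow(s) == 0) stop("bin_day: no sessions with test trials")
  }
  bin <- pmin(floor(s$start_local_time / 0.5), 47)
  w <- tabulate(bin + 1L, nbins = 48L)
  value <- switch(metric,
    login_fraction = w / sum(w),
    session_accuracy = {
      v <- rep(NA_real_, 48)
      agg <- rowsum(s$mean_accuracy, bin)
      v[as.integer(rownames(agg)) + 1L] <- agg[, 1]
      v / ifelse(w > 0, w, NA)
    },
    session_length = {
      v <- rep(NA_real_, 48)
      agg <- rowsum(as.numeric(s$n_trials), bin)
      v[as.integer(rownames(agg)) + 1L] <- agg[, 1]
      v / ifelse(w > 0, w, NA)
    })
  value[w == 0] <- NA_real_
  out <- data.frame(bin_start_hour = (0:47) * 0.5,
                    t_mid = (0:47) * 0.5 + 0.25,
                    value = value, weight = w)
  attr(out, "metric") <- metric
  attr(out, "timezone_mode") <- attr(sessions, "timezone_mode")
  attr(out, "n_sessions") <- nrow(s)
  class(out) <- c("day_series", "data.frame")
  out
}

#' @export
print.day_series <- function(x, ...) {
  cat(sprintf("day series: %s over 48 half-hour bins (%d sessions%s)\n",
              attr(x, "metric"), attr(x, "n_sessions") %||% NA,
              if (!is.null(attr(x, "timezone_mode")))
                paste0(", timezone mode ", attr(x, "timezone_mode")) else ""))
  nz <- sum(x$weight > 0)
  cat(sprintf("  %d non-empty bins; value range [%.4g, %.4g]\n",
              nz, min(x$value, na.rm = TRUE), max(x$value, na.rm = TRUE)))
  invisible(x)
}

# --- model descriptors ------------------------------------------------------

#' Candidate daily-model descriptors
#'
#' Shorthand for the usual candidate set: `"intercept"` (constant),
#' `"h1"` ... `"h5"` (harmonic order 1-5), `"linear"` and `"quadratic"`
#' (polynomials in clock time).
#'
#' @param max_harmonic highest harmonic order to include.
#' @param polynomials include the linear/quadratic-in-time baselines.
#' @return Character vector of descriptors accepted by [fit_day_model()].
#' @export
day_model_candidates <- function(max_harmonic = 5, polynomials = TRUE) {
  c("intercept", paste0("h", seq_len(max_harmonic)),
    if (polynomials) c("linear", "quadratic"))
}

day_model_design <- function(model, t) {
  if (grepl("^h[0-9]+$", model)) {
    K <- as.integer(sub("^h", "", model))
    harmonic_design(t, K)
  } else if (model == "intercept") {
    harmonic_design(t, 0)
  } else if (model == "linear") {
    cbind("(Intercept)" = 1, t = t)
  } else if (model == "quadratic") {
    cbind("(Intercept)" = 1, t = t, t2 = t^2)
  } else {
    stop("unknown day-model descriptor: ", model)
  }
}

#' Fit a daily curve to a binned series
#'
#' Regression of the binned values on a harmonic or polynomial basis of time
#' of day, weighting each bin by its session count (the bin mean is treated
#' as a mean of `weight` replicates with variance `sigma^2 / weight`).
#' Empty bins are omitted. Two inference engines share this likelihood:
#'
#' * `"weighted_least_squares"`: classical WLS point estimates.
#' * `"bayesian"`: weighted normal regression with weakly-informative priors
#'   (coefficients `N(0, (10 sd(y))^2)`, residual sd half-normal with scale
#'   `2.5 sd(y)`). The sigma posterior is computed exactly on a dense grid
#'   (the coefficient block is conjugate and integrated analytically),
#'   `draws` joint posterior draws are taken, and lppd / p_waic / WAIC are
#'   computed from the pointwise log-densities. Deterministic given `seed`.
#'
#' @param series a `day_series` from [bin_day()], or any data frame with
#'   columns `t_mid`, `value`, `weight`.
#' @param model a descriptor from [day_model_candidates()], or a
#'   [harmonic_curve()]'s order via `"h<K>"`.
#' @param inference `"bayesian"` or `"weighted_least_squares"`.
#' @param draws posterior draws for the Bayesian engine.
#' @param seed RNG seed for the posterior draws.
#' @return A `harmonic_fit`: coefficients (named as the design columns), the
#'   fitted [harmonic_curve()] when the model is harmonic, a `report` with
#'   `lppd`, `p_waic`, `waic`, `point_loglik`, `rmse` (in-sample, weighted)
#'   and `n_obs`, and the posterior draws (Bayesian engine).
#' @export
fit_day_model <- function(series, model = "h1",
                          inference = c("bayesian", "weighted_least_squares"),
                          draws = 2000, seed = 1L) {
  inference <- match.arg(inference)
  stopifnot(is.data.frame(series))
  ok <- is.finite(series$value) & series$weight > 0
  t <- series$t_mid[ok]; y <- series$value[ok]; w <- as.numeric(series$weight[ok])
  X <- day_model_design(model, t)
  p <- ncol(X)
  if (length(y) < p + 2) {
    stop("fit_day_model: need at least p + 2 non-missing bins (p = ", p, ")")
  }
  qx <- qr(X * sqrt(w))
  if (qx$rank < p) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("fit_day_model: rank-deficient design; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  wls <- stats::lm.wfit(X, y, w)
  beta_wls <- wls$coefficients
  resid <- y - drop(X %*% beta_wls)
  s0 <- if (length(y) > p) sqrt(sum(w * resid^2) / (length(y) - p)) else 0

  fit <- list(model = model, inference = inference,
              harmonic = grepl("^(h[0-9]+|intercept)$", model),
              K = if (grepl("^h[0-9]+$", model)) as.integer(sub("^h", "", model))
                  else if (model == "intercept") 0L else NA_integer_,
              n_obs = length(y), train = list(t = t, y = y, w = w))

  if (inference == "weighted_least_squares") {
    fit$coefficients <- beta_wls
    fit$sigma <- s0
    fit$report <- list(lppd = NA_real_, p_waic = NA_real_, waic = NA_real_,
                       point_loglik = weighted_normal_loglik(y, drop(X %*% beta_wls),
                                                             max(s0, 1e-12), w),
                       rmse = weighted_rmse(y, drop(X %*% beta_wls), w),
                       n_obs = length(y))
  } else {
    s_y <- max(stats::sd(y), 1e-8)
    prior_sd_beta <- 10 * s_y
    prior_scale_sigma <- 2.5 * s_y
    post <- with_seed(seed, bayes_weighted_lm(X, y, w, prior_sd_beta,
                                              prior_scale_sigma, draws,
                                              s0 = s0))
    fit$coefficients <- post$beta_mean
    names(fit$coefficients) <- colnames(X)
    fit$sigma <- post$sigma_mean
    fit$draws <- list(beta = post$beta, sigma = post$sigma)
    wc <- waic_from_loglik(post$ll)
    fit$report <- list(lppd = wc$lppd, p_waic = wc$p_waic, waic = wc$waic,
                       point_loglik = weighted_normal_loglik(
                         y, drop(X %*% post$beta_mean), post$sigma_mean, w),
                       rmse = weighted_rmse(y, drop(X %*% post$beta_mean), w),
                       n_obs = length(y))
  }
  if (fit$harmonic) {
    K <- fit$K
    b <- fit$coefficients
    fit$curve <- harmonic_curve(b[1],
                                a = if (K > 0) b[2 * seq_len(K)] else numeric(),
                                c = if (K > 0) b[2 * seq_len(K) + 1] else numeric())
  }
  attr(fit$train, "metric") <- attr(series, "metric")
  structure(fit, class = "harmonic_fit")
}

# log-likelihood of bin means under the replication-count weight convention
weighted_normal_loglik <- function(y, mu, sigma, w) {
  sum(stats::dnorm(y, mu, sigma / sqrt(w), log = TRUE))
}

# Bayesian weighted normal regression via exact conjugate beta | sigma and a
# dense grid over sigma (marginal likelihood with beta integrated out).
bayes_weighted_lm <- function(X, y, w, prior_sd_beta, prior_scale_sigma,
                              draws, s0 = NULL, grid_size = 320) {
  n <- length(y); p <- ncol(X)
  tau2 <- prior_sd_beta^2
  lo <- max(if (!is.null(s0) && s0 > 0) s0 / 50 else 1e-9, 1e-12)
  hi <- max(if (!is.null(s0) && s0 > 0) s0 * 50 else 0, 4 * prior_scale_sigma,
            1e-6)
  sig_grid <- exp(seq(log(lo), log(hi), length.out = grid_size))
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  XtWy <- drop(XtW %*% y)
  yWy <- sum(w * y^2)
  sum_log_w <- sum(log(w))

  log_post <- vapply(sig_grid, function(sig) {
    s2 <- sig^2
    A <- XtWX / s2 + diag(1 / tau2, p)
    R <- chol(A)
    b <- XtWy / s2
    m_quad <- sum(backsolve(R, b, transpose = TRUE)^2)  # b' A^-1 b
    logml <- -n / 2 * log(2 * pi) + 0.5 * (sum_log_w - n * log(s2)) -
      0.5 * p * log(tau2) - sum(log(diag(R))) - 0.5 * (yWy / s2 - m_quad)
    # half-normal prior on sigma
    logml + stats::dnorm(sig, 0, prior_scale_sigma, log = TRUE)
  }, 0)
  log_post <- log_post - max(log_post)
  pr <- exp(log_post); pr <- pr / sum(pr)
  idx <- sample.int(grid_size, draws, replace = TRUE, prob = pr)
  sigma <- sig_grid[idx]

  beta <- matrix(0, nrow = draws, ncol = p)
  for (u in unique(idx)) {
    sig <- sig_grid[u]
    A <- XtWX / sig^2 + diag(1 / tau2, p)
    R <- chol(A)
    m <- backsolve(R, backsolve(R, XtWy / sig^2, transpose = TRUE))
    rows <- which(idx == u)
    z <- matrix(stats::rnorm(length(rows) * p), nrow = p)
    beta[rows, ] <- t(m + backsolve(R, z))
  }
  mu <- beta %*% t(X)                      # draws x n
  sd_mat <- outer(sigma, 1 / sqrt(w))      # draws x n
  ll <- stats::dnorm(matrix(y, nrow = draws, ncol = n, byrow = TRUE),
                     mu, sd_mat, log = TRUE)
  list(beta = beta, sigma = sigma, ll = ll,
       beta_mean = colMeans(beta), sigma_mean = mean(sigma))
}

#' @export
coef.harmonic_fit <- function(object, ...) object$coefficients

#' Predict a fitted daily curve
#'
#' @param object a `harmonic_fit`.
#' @param t times of day in hours.
#' @param ... unused.
#' @export
predict.harmonic_fit <- function(object, t, ...) {
  drop(day_model_design(object$model, t) %*% object$coefficients)
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf("daily model '%s' (%s), %d bins\n", x$model, x$inference, x$n_obs))
  print(signif(x$coefficients, 5))
  r <- x$report
  if (is.finite(r$waic %||% NA)) {
    cat(sprintf("  lppd %.3f, p_waic %.3f, WAIC %.3f; in-sample weighted RMSE %.4g\n",
                r$lppd, r$p_waic, r$waic, r$rmse))
  } else {
    cat(sprintf("  in-sample weighted RMSE %.4g\n", r$rmse))
  }
  invisible(x)
}

#' Out-of-sample RMSE of a frozen daily model
#'
#' Evaluates a previously fitted model on a new binned series without any
#' refitting: the square root of the weighted mean squared difference
#' between bin values and the frozen predictions, weights being the new
#' series' bin weights.
#'
#' @param frozen a `harmonic_fit`.
#' @param new_series a `day_series`.
#' @return The weighted RMSE.
#' @export
oos_rmse <- function(frozen, new_series) {
  stopifnot(inherits(frozen, "harmonic_fit"), is.data.frame(new_series))
  ok <- is.finite(new_series$value) & new_series$weight > 0
  weighted_rmse(new_series$value[ok],
                predict(frozen, new_series$t_mid[ok]),
                as.numeric(new_series$weight[ok]))
}

# WAIC table over a candidate set (internal)
fit_candidates <- function(series, candidates, inference = "bayesian",
                           draws = 2000, seed = 1L) {
  fits <- list()
  for (j in seq_along(candidates)) {
    fits[[candidates[j]]] <- fit_day_model(series, candidates[j],
                                           inference = inference,
                                           draws = draws, seed = seed + j)
  }
  fits
}

waic_table <- function(fits, margin = 2) {
  waic <- vapply(fits, function(f) f$report$waic, 0)
  tab <- data.frame(model = names(fits), waic = waic,
                    delta_waic = waic - min(waic),
                    lppd = vapply(fits, function(f) f$report$lppd, 0),
                    p_waic = vapply(fits, function(f) f$report$p_waic, 0),
                    row.names = NULL)
  tab <- tab[order(tab$waic), ]
  rownames(tab) <- NULL
  gap <- if (nrow(tab) > 1) tab$waic[2] - tab$waic[1] else Inf
  winner <- tab$model[1]
  tied <- tab$model[tab$delta_waic < margin]
  list(table = tab, winner = winner, tied_set = tied,
       margin_to_runner_up = gap)
}

#' Two-cohort replication protocol for a daily metric
#'
#' Runs the pre-registered-style three-stage pipeline on two independent
#' logs: (i) fit all candidate daily models to sample 1 (timezone mode
#' `"none"`) and compare by WAIC; (ii) evaluate the frozen sample-1 models on
#' sample 2 binned without timezone correction (out-of-sample RMSE, a direct
#' replication); (iii) refit all candidates to sample 2 with per-user
#' timezone adjustment and compare by WAIC.
#'
#' @param log1,log2 `trial_log`s for the two cohorts.
#' @param metric a [bin_day()] metric.
#' @param candidates model descriptors (default [day_model_candidates()]).
#' @param inference,draws,seed passed to [fit_day_model()].
#' @param margin WAIC margin under which models are reported as tied.
#' @return A `replication_report` with `stage1` (fits + WAIC table),
#'   `stage2` (RMSE table on the direct-replication series) and `stage3`
#'   (refit WAIC table, timezone-adjusted).
#' @export
replication_protocol <- function(log1, log2, metric = "session_accuracy",
                                 candidates = day_model_candidates(),
                                 inference = "bayesian", draws = 2000,
                                 seed = 1L, margin = 2) {
  if (inference != "bayesian") {
    stop("replication_protocol: the WAIC stages require inference = \"bayesian\"")
  }
  s1 <- bin_day(session_summaries(localize_times(log1, "none")), metric)
  s2_direct <- bin_day(session_summaries(localize_times(log2, "none")), metric)
  s2_adj <- bin_day(session_summaries(localize_times(log2, "per_user_offset")),
                    metric)

  fits1 <- fit_candidates(s1, candidates, inference, draws, seed)
  tab1 <- waic_table(fits1, margin)
  rmse <- vapply(fits1, function(f) oos_rmse(f, s2_direct), 0)
  tab2 <- data.frame(model = names(rmse), rmse = rmse, row.names = NULL)
  tab2 <- tab2[order(tab2$rmse), ]
  rownames(tab2) <- NULL
  fits3 <- fit_candidates(s2_adj, candidates, inference, draws, seed + 1000L)
  tab3 <- waic_table(fits3, margin)

  structure(list(metric = metric, candidates = candidates,
                 series = list(sample1 = s1, sample2_direct = s2_direct,
                               sample2_adjusted = s2_adj),
                 stage1 = c(tab1, list(fits = fits1)),
                 stage2 = list(table = tab2, winner = tab2$model[1]),
                 stage3 = c(tab3, list(fits = fits3))),
            class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("replication protocol: %s\n", x$metric))
  cat(sprintf("stage 1 (sample 1, WAIC): winner %s (tied set: %s)\n",
              x$stage1$winner, paste(x$stage1$tied_set, collapse = ", ")))
  print(transform(x$stage1$table, waic = round(waic, 2),
                  delta_waic = round(delta_waic, 2),
                  lppd = round(lppd, 2), p_waic = round(p_waic, 2)))
  cat(sprintf("stage 2 (sample 2 direct, frozen-model RMSE): best %s\n",
              x$stage2$winner))
  print(transform(x$stage2$table, rmse = signif(rmse, 4)))
  cat(sprintf("stage 3 (sample 2 refit, timezone-adjusted, WAIC): winner %s (tied set: %s)\n",
              x$stage3$winner, paste(x$stage3$tied_set, collapse = ", ")))
  print(transform(x$stage3$table, waic = round(waic, 2),
                  delta_waic = round(delta_waic, 2),
                  lppd = round(lppd, 2), p_waic = round(p_waic, 2)))
  invisible(x)
}
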
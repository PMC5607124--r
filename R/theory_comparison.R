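# Theoretical daily-behaviour models -- "limited self-control" (peak after
# waking, monotone decline until sleep), "unlimited self-control" (flat
# waking plateau, night trough) and "evening preference" (flat day, monotone
# rise after an evening onset) -- realised as smoothed piecewise-linear
# mean +/- SD curves over the 24-h day, and negative log-likelihood scoring
# of observed data under each.

theory_names <- c("limited_sc", "unlimited_sc", "evening_preference")

#' Parameters for the theoretical daily curves
#'
#' Anchor times and levels of the three curve families. All levels are on an
#' abstract standardised activity scale; observed data are min-max
#' standardised to `[0, 1]` before scoring (see [score_data()]). The SD
#' ribbon is a constant fraction of the plateau level.
#'
#' @param wake wake time, hours.
#' @param sleep_onset sleep onset, hours; values over 24 mean past midnight.
#' @param evening_onset start of the evening rise (evening-preference model).
#' @param evening_peak_time time at which the evening rise levels off.
#' @param trough_level night-time activity level.
#' @param plateau_level waking plateau level.
#' @param day_level daytime level of the evening-preference model.
#' @param decline_level level reached at sleep onset by the limited
#'   self-control decline.
#' @param sd_frac SD ribbon as a fraction of `plateau_level`.
#' @param smooth_hours width (hours) of the moving-average smoother applied
#'   to the piecewise-linear skeleton.
#' @return A `theory_params` list.
#' @export
theory_params <- function(wake = 7, sleep_onset = 25, evening_onset = 18,
                          evening_peak_time = 22, trough_level = 0.1,
                          plateau_level = 1, day_level = 0.6,
                          decline_level = 0.4, sd_frac = 0.15,
                          smooth_hours = 1) {
  if (sleep_onset <= wake) stop("theory_params: sleep onset must be after wake")
  if (sd_frac <= 0) stop("theory_params: SD ribbon must be positive")
  if (!(wake < evening_onset && evening_onset < evening_peak_time &&
        evening_peak_time <= sleep_onset)) {
    stop("theory_params: need wake < evening_onset < evening_peak_time <= sleep_onset")
  }
  structure(as.list(environment()), class = "theory_params")
}

# piecewise-linear skeleton on [0, 24) given (time, level) anchors; times may
# exceed 24 (wrapped); curve is periodic and continuous
theory_skeleton <- function(name, p) {
  w <- p$wake; s <- p$sleep_onset
  rise <- 0.75  # transition width, hours
  anchors <- switch(name,
    limited_sc = rbind(
      c(w - rise, p$trough_level), c(w, p$plateau_level),
      c(s, p$decline_level), c(s + rise, p$trough_level)),
    unlimited_sc = rbind(
      c(w - rise, p$trough_level), c(w, p$plateau_level),
      c(s, p$plateau_level), c(s + rise, p$trough_level)),
    evening_preference = rbind(
      c(w - rise, p$trough_level), c(w, p$day_level),
      c(p$evening_onset, p$day_level),
      c(p$evening_peak_time, p$plateau_level),
      c(s, p$plateau_level), c(s + rise, p$trough_level)),
    stop("unknown theory name: ", name))
  anchors
}

#' Build a theoretical daily-behaviour model
#'
#' Constructs the named theory as a smoothed piecewise-linear mean curve
#' \eqn{\mu(t)} with a strictly positive SD ribbon \eqn{\sigma(t)} (constant,
#' `sd_frac * plateau_level`), both 24-h periodic. `limited_sc` peaks at wake
#' and declines monotonically until sleep onset; `unlimited_sc` is flat over
#' waking hours with a smooth night trough; `evening_preference` holds a flat
#' day level then rises monotonically after the evening onset.
#'
#' @param name one of `"limited_sc"`, `"unlimited_sc"`,
#'   `"evening_preference"`.
#' @param metric label for the metric the model applies to (bookkeeping
#'   only; scoring checks it).
#' @param params a [theory_params()].
#' @return A `theory_model` with vectorised `mu(t)` and `sigma(t)`.
#' @export
build_theory <- function(name = theory_names, metric = "login_fraction",
                         params = theory_params()) {
  name <- match.arg(name)
  stopifnot(inherits(params, "theory_params"))
  anchors <- theory_skeleton(name, params)
  # dense periodic grid, then moving-average smoothing
  step <- 0.02
  grid <- seq(0, 24 - step, by = step)
  at <- anchors[, 1] %% 24
  lv <- anchors[, 2]
  o <- order(at)
  at <- at[o]; lv <- lv[o]
  # wrap for periodic interpolation
  at_ext <- c(at - 24, at, at + 24)
  lv_ext <- rep(lv, 3)
  mu_raw <- stats::approx(at_ext, lv_ext, xout = grid)$y
  half <- max(1L, round(params$smooth_hours / 2 / step))
  kern <- rep(1 / (2 * half + 1), 2 * half + 1)
  mu_sm <- stats::filter(c(utils::tail(mu_raw, half), mu_raw,
                           utils::head(mu_raw, half)),
                         kern, sides = 2)
  mu_sm <- as.numeric(mu_sm)[(half + 1):(half + length(grid))]
  sigma0 <- params$sd_frac * params$plateau_level
  mu_fun <- stats::approxfun(c(grid, 24), c(mu_sm, mu_sm[1]))
  structure(list(name = name, metric = metric, params = params,
                 grid = grid, mu_grid = mu_sm, sigma0 = sigma0,
                 mu = function(t) mu_fun(t %% 24),
                 sigma = function(t) rep_len(sigma0, length(t))),
            class = "theory_model")
}

#' @export
print.theory_model <- function(x, ...) {
  cat(sprintf("theory model '%s' for %s: mu in [%.3f, %.3f], sigma = %.3f\n",
              x$name, x$metric, min(x$mu_grid), max(x$mu_grid), x$sigma0))
  invisible(x)
}

#' @export
predict.theory_model <- function(object, t, ...) {
  data.frame(t = t, mu = object$mu(t), sigma = object$sigma(t))
}

#' Min-max standardise observed values
#'
#' Maps values affinely so that their observed range is `[0, 1]`, putting
#' accuracy, login fraction and session length on the common scale of the
#' theory curves. Reversible via the returned attributes `offset`/`scale`.
#'
#' @param y numeric values.
#' @return Standardised values with attributes `offset` and `scale`.
#' @export
minmax_standardize <- function(y) {
  lo <- min(y, na.rm = TRUE); hi <- max(y, na.rm = TRUE)
  if (hi <= lo) stop("minmax_standardize: values have no spread")
  structure((y - lo) / (hi - lo), offset = lo, scale = hi - lo)
}

#' Score observations under a theoretical model
#'
#' Gaussian negative log-likelihood of observed values given the theory's
#' mean and SD curves:
#' \deqn{\mathrm{NLL} = \sum_i w_i\left[\ln\sigma(t_i) + \tfrac12\ln(2\pi) +
#'   \frac{(y_i-\mu(t_i))^2}{2\sigma(t_i)^2}\right].}
#' A `day_series` is scored per bin with its weights; a data frame with
#' columns `t` and `y` is scored one observation at a time (`w_i = 1`).
#'
#' @param observations a `day_series` or a data frame with columns `t`, `y`.
#' @param model a `theory_model`.
#' @param standardize min-max standardise the values first (the convention
#'   that puts different metrics on the curves' scale); set `FALSE` when the
#'   data are already on that scale.
#' @param weighted use bin weights (ignored for per-observation input).
#' @return The negative log-likelihood (scalar).
#' @export
score_data <- function(observations, model, standardize = TRUE,
                       weighted = TRUE) {
  stopifnot(inherits(model, "theory_model"))
  if (inherits(observations, "day_series")) {
    obs_metric <- attr(observations, "metric")
    if (!is.null(obs_metric) && !identical(obs_metric, model$metric)) {
      stop("score_data: series metric ", obs_metric,
           " does not match model metric ", model$metric)
    }
    ok <- is.finite(observations$value) & observations$weight > 0
    t <- observations$t_mid[ok]
    y <- observations$value[ok]
    w <- if (weighted) as.numeric(observations$weight[ok]) else rep(1, sum(ok))
  } else {
    stopifnot(all(c("t", "y") %in% names(observations)))
    t <- observations$t; y <- observations$y; w <- rep(1, length(y))
  }
  if (standardize) y <- as.numeric(minmax_standardize(y))
  mu <- model$mu(t); sig <- model$sigma(t)
  sum(w * (log(sig) + 0.5 * log(2 * pi) + (y - mu)^2 / (2 * sig^2)))
}

#' Deviance table of datasets against theories
#'
#' Scores each labelled dataset under each theoretical model and reports the
#' full cross-table of negative log-likelihoods (rows = models, columns =
#' datasets; smaller is better) plus a winner per dataset.
#'
#' @param datasets a named list of observation sets ([score_data()] inputs)
#'   sharing metric and scale.
#' @param models a list of `theory_model`s (default: all three with default
#'   parameters, built for the metric of the first dataset).
#' @param ... passed to [score_data()].
#' @return A `deviance_table`.
#' @export
theory_table <- function(datasets, models = NULL, ...) {
  stopifnot(is.list(datasets), length(datasets) >= 1)
  if (is.null(names(datasets))) names(datasets) <- paste0("dataset", seq_along(datasets))
  if (is.null(models)) {
    metric <- attr(datasets[[1]], "metric") %||% "login_fraction"
    models <- lapply(theory_names, build_theory, metric = metric)
    names(models) <- theory_names
  }
  if (is.null(names(models))) {
    names(models) <- vapply(models, function(m) m$name, "")
  }
  nll <- matrix(NA_real_, nrow = length(models), ncol = length(datasets),
                dimnames = list(names(models), names(datasets)))
  for (i in seq_along(models)) {
    for (j in seq_along(datasets)) {
      nll[i, j] <- score_data(datasets[[j]], models[[i]], ...)
    }
  }
  winners <- rownames(nll)[apply(nll, 2, which.min)]
  names(winners) <- colnames(nll)
  structure(list(nll = nll, winners = winners), class = "deviance_table")
}

#' @export
print.deviance_table <- function(x, ...) {
  cat("deviance (negative log-likelihood; smaller = better)\n")
  print(signif(x$nll, 5))
  cat("winners:\n")
  for (j in names(x$winners)) cat(sprintf("  %s: %s\n", j, x$winners[j]))
  invisible(x)
}
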
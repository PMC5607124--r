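# Within-session fatigue analysis: learn-trial removal and 5-trial accuracy
# smoothing, multilevel null/linear/quadratic fits on trial order or elapsed
# time, AIC comparison, and peak/drop summaries of the quadratic curve.

#' Smooth test-trial accuracy over a session
#'
#' Drops learn events (keeping the original trial order, so gaps remain),
#' groups the remaining test trials of each session into consecutive bins of
#' `bin_size`, and averages correctness per bin. Trailing partial bins are
#' dropped by default so bin variance stays homogeneous. The bin's axis value
#' is the mean original trial index (`axis = "trial_order"`) or the mean
#' elapsed minutes (`axis = "elapsed_time"`) of its trials.
#'
#' @param log a screened, localised `trial_log`.
#' @param axis `"trial_order"` or `"elapsed_time"`.
#' @param bin_size test trials per bin (default 5).
#' @param drop_partial drop trailing bins with fewer than `bin_size` trials.
#' @return A `smoothed_series` data frame with columns `user_id`,
#'   `session_id`, `start_local_time` (if present), `bin_index`, `axis`,
#'   `axis_value`, `accuracy`, `n_in_bin`. Sessions without test trials are
#'   skipped; their count is in `attr(, "skipped_sessions")`.
#' @export
smooth_sessions <- function(log, axis = c("trial_order", "elapsed_time"),
                            bin_size = 5, drop_partial = TRUE) {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(log), bin_size >= 1)
  skey <- paste(log$user_id, log$session_id, sep = "\r")
  n_sessions_all <- length(unique(skey))

  tst <- log[log$event_type == "test", , drop = FALSE]
  if (nrow(tst) == 0) {
    out <- data.frame(user_id = character(), session_id = character(),
                      bin_index = integer(), axis = character(),
                      axis_value = numeric(), accuracy = numeric(),
                      n_in_bin = integer(), stringsAsFactors = FALSE)
    attr(out, "skipped_sessions") <- n_sessions_all
    class(out) <- c("smoothed_series", "data.frame")
    return(out)
  }
  tst <- tst[order(tst$user_id, tst$session_id, tst$trial_index), , drop = FALSE]
  skey <- paste(tst$user_id, tst$session_id, sep = "\r")
  sid <- match(skey, unique(skey))
  # test-trial ordinal within session
  n_per <- tabulate(sid)
  k <- sequence(n_per)
  bin <- (k - 1L) %/% bin_size + 1L
  bkey <- as.numeric(sid) * 1e6 + bin  # doubles are exact here
  bid <- match(bkey, unique(bkey))
  n_in_bin <- tabulate(bid)
  axis_raw <- if (axis == "trial_order") as.numeric(tst$trial_index)
              else tst$elapsed_seconds / 60
  first <- !duplicated(bid)
  out <- data.frame(
    user_id = tst$user_id[first],
    session_id = tst$session_id[first],
    bin_index = bin[first],
    axis = axis,
    axis_value = rowsum(axis_raw, bid)[, 1] / n_in_bin,
    accuracy = rowsum(as.numeric(tst$correct), bid)[, 1] / n_in_bin,
    n_in_bin = n_in_bin,
    stringsAsFactors = FALSE
  )
  if (!is.null(tst$start_local_time)) {
    out$start_local_time <- tst$start_local_time[first]
  }
  if (drop_partial) out <- out[out$n_in_bin == bin_size, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_sessions") <-
    n_sessions_all - length(unique(paste(out$user_id, out$session_id, sep = "\r")))
  attr(out, "bin_size") <- bin_size
  class(out) <- c("smoothed_series", "data.frame")
  out
}

#' Fit a multilevel fatigue curve
#'
#' Maximum-likelihood fit (lme4, `REML = FALSE`) of smoothed accuracy on a
#' polynomial of the axis value, with a random intercept (null form) or a
#' random intercept plus linear slope (linear/quadratic forms) per group. The
#' quadratic term is fixed-only under the default structure, mirroring the
#' convergence constraints typical of these data; `random_quadratic = TRUE`
#' adds diagonal (uncorrelated) random linear and quadratic terms, as needed
#' for per-session coefficient extraction. The axis is internally rescaled
#' (divided by 100) for optimizer stability; reported coefficients are on the
#' original scale.
#'
#' @param series a `smoothed_series` from [smooth_sessions()].
#' @param form `"null"`, `"linear"` or `"quadratic"`.
#' @param grouping `"user"` or `"user_and_session"` (nested).
#' @param random_quadratic see above; only meaningful for the quadratic form.
#' @return A `fatigue_fit` with fixed effects and standard errors on the
#'   accuracy scale, log-likelihood, AIC, an honest `converged` flag (plus
#'   `singular` and any optimizer messages), and the underlying `lmerMod`.
#' @export
fit_fatigue <- function(series, form = c("quadratic", "linear", "null"),
                        grouping = c("user", "user_and_session"),
                        random_quadratic = FALSE) {
  form <- match.arg(form)
  grouping <- match.arg(grouping)
  stopifnot(is.data.frame(series), nrow(series) > 0)
  if (length(unique(series$user_id)) < 2) {
    stop("fit_fatigue: need at least 2 users")
  }
  d <- data.frame(y = series$accuracy,
                  xs = series$axis_value / 100,
                  user = factor(series$user_id),
                  stringsAsFactors = FALSE)
  d$xs2 <- d$xs^2
  if (grouping == "user_and_session") {
    d$usersession <- factor(paste(series$user_id, series$session_id, sep = ":"))
  }
  fixed <- switch(form, null = "y ~ 1", linear = "y ~ xs",
                  quadratic = "y ~ xs + xs2")
  re_terms <- function(g) {
    if (form == "null") sprintf("(1 | %s)", g)
    else if (random_quadratic && form == "quadratic") {
      sprintf("(1 + xs + xs2 || %s)", g)
    } else sprintf("(1 + xs | %s)", g)
  }
  fml <- paste(fixed, re_terms("user"), sep = " + ")
  if (grouping == "user_and_session") {
    fml <- paste(fml, re_terms("usersession"), sep = " + ")
  }
  messages <- character()
  fit <- withCallingHandlers(
    lme4::lmer(stats::as.formula(fml), data = d, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      messages <<- c(messages, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  singular <- lme4::isSingular(fit)
  conv_msgs <- unlist(c(fit@optinfo$conv$lme4$messages, fit@optinfo$warnings))
  # a boundary (singular) fit is a legitimate optimum with a zero variance
  # component, reported via `singular`, not a convergence failure
  conv_msgs <- conv_msgs[!grepl("singular", conv_msgs, ignore.case = TRUE)]
  messages <- messages[!grepl("singular", messages, ignore.case = TRUE)]
  converged <- length(conv_msgs) == 0 &&
    !any(grepl("failed to converge|unable to evaluate|not converge",
               messages, ignore.case = TRUE))
  # back-transform from the xs = x/100 scale
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  scale_of <- c("(Intercept)" = 1, xs = 100, xs2 = 1e4)
  beta <- b / scale_of[names(b)]
  se <- se / scale_of[names(se)]
  names(beta) <- names(se) <-
    c("beta0", "beta1", "beta2")[seq_along(beta)]
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  structure(list(form = form, axis = series$axis[1], grouping = grouping,
                 random_quadratic = random_quadratic,
                 coefficients = beta, se = se,
                 loglik = ll, df = k, aic = 2 * k - 2 * ll,
                 converged = converged, singular = singular,
                 messages = unique(c(messages, unlist(conv_msgs))),
                 n_obs = nrow(d), n_users = nlevels(d$user),
                 model = fit),
            class = "fatigue_fit")
}

#' @export
coef.fatigue_fit <- function(object, ...) object$coefficients

#' @export
logLik.fatigue_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, class = "logLik")
}

#' Predicted fixed-effect fatigue curve
#'
#' @param object a `fatigue_fit`.
#' @param axis_value trial numbers or elapsed minutes at which to evaluate.
#' @param ... unused.
#' @export
predict.fatigue_fit <- function(object, axis_value, ...) {
  b <- object$coefficients
  out <- rep(b[["beta0"]], length(axis_value))
  if (length(b) > 1) out <- out + b[["beta1"]] * axis_value
  if (length(b) > 2) out <- out + b[["beta2"]] * axis_value^2
  out
}

#' @export
print.fatigue_fit <- function(x, ...) {
  cat(sprintf("fatigue fit: %s form on %s, grouped by %s\n",
              x$form, x$axis, x$grouping))
  tab <- cbind(estimate = x$coefficients, se = x$se)
  print(signif(tab, 5))
  cat(sprintf("  logLik %.2f, df %d, AIC %.2f, %d bins, %d users\n",
              x$loglik, x$df, x$aic, x$n_obs, x$n_users))
  if (!x$converged) cat("  WARNING: fit did not converge:",
                        paste(x$messages, collapse = "; "), "\n")
  else if (x$singular) cat("  note: singular fit (a variance component is zero)\n")
  invisible(x)
}

#' @export
summary.fatigue_fit <- function(object, ...) {
  print(object)
  cat("\nunderlying mixed model:\n")
  print(summary(object$model), correlation = FALSE)
  invisible(object)
}

#' Compare fatigue fits by AIC
#'
#' Builds a Delta-AIC table relative to the best (lowest-AIC) converged fit
#' and names a winner only when its margin over the runner-up is at least
#' `margin` (the conventional rule that information-criterion differences of
#' 2 or more are meaningful); otherwise the verdict is `"indistinguishable"`.
#'
#' @param fits a list of `fatigue_fit`s sharing axis and data.
#' @param margin required AIC margin (default 2).
#' @return A `fatigue_comparison`: the table, the winner (or
#'   `"indistinguishable"`) and the margin to the runner-up.
#' @export
compare_fits <- function(fits, margin = 2) {
  stopifnot(is.list(fits), length(fits) >= 2)
  ok <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (sum(ok) < 2) stop("compare_fits: need at least 2 converged fits")
  fits <- fits[ok]
  axes <- unique(vapply(fits, function(f) f$axis, ""))
  ns <- unique(vapply(fits, function(f) f$n_obs, 0))
  if (length(axes) != 1 || length(ns) != 1) {
    stop("compare_fits: fits must share axis and data")
  }
  aic <- vapply(fits, function(f) f$aic, 0)
  names(aic) <- vapply(fits, function(f) f$form, "")
  tab <- data.frame(form = names(aic), aic = aic,
                    delta_aic = aic - min(aic), row.names = NULL)
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  gap <- if (nrow(tab) > 1) tab$aic[2] - tab$aic[1] else Inf
  winner <- if (gap >= margin) tab$form[1] else "indistinguishable"
  structure(list(table = tab, winner = winner, margin_to_runner_up = gap,
                 margin_rule = margin),
            class = "fatigue_comparison")
}

#' @export
print.fatigue_comparison <- function(x, ...) {
  cat("AIC comparison\n")
  print(transform(x$table, aic = round(aic, 2), delta_aic = round(delta_aic, 2)))
  if (x$winner == "indistinguishable") {
    cat(sprintf("  indistinguishable (margin %.2f < %.2f)\n",
                x$margin_to_runner_up, x$margin_rule))
  } else {
    cat(sprintf("  winner: %s (margin %.2f to runner-up)\n",
                x$winner, x$margin_to_runner_up))
  }
  invisible(x)
}

#' Peak and drop of a fitted quadratic fatigue curve
#'
#' For a quadratic fit with a negative curvature, returns the vertex
#' \eqn{-\beta_1 / (2\beta_2)} (the trial number or minute at which accuracy
#' peaks) and the drop in fitted accuracy from that peak to `horizon`.
#'
#' @param fit a quadratic `fatigue_fit`, or a numeric `(beta0, beta1, beta2)`.
#' @param horizon axis value (trial number or minutes) at which to measure
#'   the drop.
#' @return A list with `vertex`, `peak_accuracy`, `drop` (peak minus fitted
#'   value at the horizon) and `horizon`.
#' @export
quadratic_summary <- function(fit, horizon) {
  b <- if (is.numeric(fit)) fit else {
    if (fit$form != "quadratic") stop("quadratic_summary: fit is not quadratic")
    fit$coefficients
  }
  stopifnot(length(b) == 3)
  b <- as.numeric(b)
  if (b[3] >= 0) stop("quadratic_summary: no interior maximum (beta2 >= 0)")
  vertex <- -b[2] / (2 * b[3])
  q <- function(x) b[1] + b[2] * x + b[3] * x^2
  list(vertex = vertex, peak_accuracy = q(vertex),
       drop = q(vertex) - q(horizon), horizon = horizon)
}
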
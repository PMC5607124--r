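# Exploratory moderation analysis: per-session realizations of the
# within-session fatigue curve (empirical-Bayes predictions from the
# user-and-session grouped quadratic model), regressed on first-harmonic
# time-of-day terms with a 0.008 critical p-value (Bonferroni-style control
# of the 6-test family: 3 components x sine/cosine).

#' Extract per-session fatigue coefficients
#'
#' Fits the quadratic fatigue model grouped within users and sessions
#' (diagonal random intercept, linear and quadratic terms at both levels)
#' and returns, for every session, the model-based (empirical-Bayes)
#' coefficient realizations: fixed effect + user deviation + session
#' deviation for the intercept, linear and quadratic terms. Coefficients are
#' on the trial-index scale.
#'
#' @param log a screened, localised `trial_log` (local start times are
#'   carried into the output for the moderation regression), or an already
#'   smoothed series from [smooth_sessions()] carrying `start_local_time`.
#' @param bin_size passed to [smooth_sessions()].
#' @return A `session_coefficients` data frame: `user_id`, `session_id`,
#'   `start_local_time`, `intercept`, `linear`, `quadratic`, with the
#'   underlying `fatigue_fit` in `attr(, "fit")`.
#' @export
extract_session_coefs <- function(log, bin_size = 5) {
  series <- if (inherits(log, "smoothed_series")) log
            else smooth_sessions(log, axis = "trial_order", bin_size = bin_size)
  if (is.null(series$start_local_time)) {
    stop("extract_session_coefs: no start_local_time; run localize_times() first")
  }
  fit <- fit_fatigue(series, form = "quadratic", grouping = "user_and_session",
                     random_quadratic = TRUE)
  if (!fit$converged) {
    stop("extract_session_coefs: the user-and-session quadratic model did not ",
         "converge (", paste(fit$messages, collapse = "; "), "); ",
         "fall back to grouping = \"user\" via fit_fatigue() and report the ",
         "fallback")
  }
  m <- fit$model
  re <- lme4::ranef(m)
  fx <- lme4::fixef(m)
  skey <- paste(series$user_id, series$session_id, sep = "\r")
  first <- !duplicated(skey)
  users <- series$user_id[first]
  uskey <- paste(series$user_id, series$session_id, sep = ":")[first]

  take <- function(re_grp, keys, col) {
    if (is.null(re_grp) || !col %in% colnames(re_grp)) return(rep(0, length(keys)))
    v <- re_grp[match(keys, rownames(re_grp)), col]
    ifelse(is.na(v), 0, v)
  }
  ru <- re$user; rs <- re$usersession
  # fitted on the xs = x/100 scale; back-transform each term
  int <- fx["(Intercept)"] + take(ru, users, "(Intercept)") +
    take(rs, uskey, "(Intercept)")
  lin <- (fx["xs"] + take(ru, users, "xs") + take(rs, uskey, "xs")) / 100
  qua <- (fx["xs2"] + take(ru, users, "xs2") + take(rs, uskey, "xs2")) / 1e4
  out <- data.frame(user_id = users,
                    session_id = series$session_id[first],
                    start_local_time = series$start_local_time[first],
                    intercept = int, linear = lin, quadratic = qua,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  class(out) <- c("session_coefficients", "data.frame")
  out
}

#' Regress session coefficients on time of day
#'
#' Ordinary regression of each chosen fatigue component on
#' \eqn{\sin(2\pi t/24)} and \eqn{\cos(2\pi t/24)} of the session's local
#' start time. Reports per-term estimates and two-sided p-values, a joint
#' sine+cosine F-test per component, and significance verdicts at
#' `alpha` = .008 -- the Bonferroni-style critical value for the 6-test
#' family (3 components x 2 terms). Optionally uses cluster-robust
#' (by user) standard errors for the t-tests.
#'
#' @param coefs a `session_coefficients` data frame (or any data frame with
#'   `start_local_time` and the component columns).
#' @param components which of `"intercept"`, `"linear"`, `"quadratic"` to
#'   test.
#' @param alpha critical p-value.
#' @param cluster_robust use sandwich cluster-robust (by `user_id`) standard
#'   errors.
#' @param min_sessions minimum number of sessions required.
#' @return A `moderation_report`: data frame with one row per component and
#'   term (`sin`, `cos`, `joint_F`), columns `estimate`, `se`, `statistic`,
#'   `p_value`, `significant`.
#' @export
moderate_by_time <- function(coefs,
                             components = c("intercept", "linear", "quadratic"),
                             alpha = 0.008, cluster_robust = FALSE,
                             min_sessions = 50) {
  components <- match.arg(components, several.ok = TRUE)
  stopifnot(is.data.frame(coefs))
  components <- components[components %in% names(coefs)]
  if (nrow(coefs) < min_sessions) {
    stop("moderate_by_time: need at least ", min_sessions, " sessions")
  }
  t <- coefs$start_local_time
  if (stats::sd(t) < 0.5 || length(unique(round(t, 2))) < 5) {
    stop("moderate_by_time: degenerate spread of session start times")
  }
  s <- sin(2 * pi * t / 24); cc <- cos(2 * pi * t / 24)
  X <- cbind("(Intercept)" = 1, sin = s, cos = cc)
  n <- nrow(X); p <- ncol(X)
  qx <- qr(X)
  Y <- as.matrix(coefs[components])
  B <- qr.coef(qx, Y)
  R <- Y - X %*% B
  df_res <- n - p
  rows <- list()
  for (comp in components) {
    if (cluster_robust) {
      fit <- stats::lm(coefs[[comp]] ~ s + cc)
      V <- sandwich::vcovCL(fit, cluster = coefs$user_id)
      se <- sqrt(diag(V))[c("s", "cc")]
    } else {
      sigma2 <- sum(R[, comp]^2) / df_res
      XtXinv <- chol2inv(qr.R(qx))
      se <- sqrt(sigma2 * diag(XtXinv))[2:3]
    }
    est <- B[2:3, comp]
    tval <- est / se
    pval <- 2 * stats::pt(-abs(tval), df_res)
    # joint F for the sine+cosine pair
    rss1 <- sum(R[, comp]^2)
    rss0 <- sum((coefs[[comp]] - mean(coefs[[comp]]))^2)
    Fstat <- ((rss0 - rss1) / 2) / (rss1 / df_res)
    pF <- stats::pf(Fstat, 2, df_res, lower.tail = FALSE)
    rows[[comp]] <- data.frame(
      component = comp,
      term = c("sin", "cos", "joint_F"),
      estimate = c(est, NA),
      se = c(se, NA),
      statistic = c(tval, Fstat),
      p_value = c(pval, pF),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  rownames(out) <- NULL
  out$amplitude <- NA_real_
  for (comp in components) {
    sel <- out$component == comp
    est <- out$estimate[sel][1:2]
    out$amplitude[sel] <- sqrt(sum(est^2))
  }
  attr(out, "alpha") <- alpha
  attr(out, "n_sessions") <- n
  attr(out, "cluster_robust") <- cluster_robust
  class(out) <- c("moderation_report", "data.frame")
  out
}

#' @export
print.moderation_report <- function(x, ...) {
  cat(sprintf("moderation of fatigue components by time of day (n = %d sessions, alpha = %.3g%s)\n",
              attr(x, "n_sessions"), attr(x, "alpha"),
              if (isTRUE(attr(x, "cluster_robust"))) ", cluster-robust" else ""))
  df <- as.data.frame(x)
  df$estimate <- signif(df$estimate, 4)
  df$se <- signif(df$se, 4)
  df$statistic <- signif(df$statistic, 4)
  df$p_value <- signif(df$p_value, 4)
  df$amplitude <- signif(df$amplitude, 4)
  print(df)
  invisible(x)
}
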
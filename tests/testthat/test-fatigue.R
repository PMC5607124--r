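# Within-session fatigue: smoothing arithmetic, learn-trial invariance,
# multilevel fits, AIC comparison rules and quadratic peak/drop summaries.

mk_session_log <- function(correct, events = rep("test", length(correct)),
                           user = "u1", session = "s1") {
  n <- length(events)
  df <- data.frame(
    user_id = user, session_id = session, trial_index = seq_len(n),
    event_type = events,
    timestamp_utc = as.POSIXct("2016-01-11 12:00:00", tz = "UTC") + 10 * seq_len(n),
    utc_offset_hours = 0L, correct = correct,
    elapsed_seconds = 10 * seq_len(n), stringsAsFactors = FALSE)
  class(df) <- c("trial_log", "data.frame")
  df
}

test_that("5-trial smoothing averages correctness and drops trailing partial bins", {
  cor12 <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE,
             FALSE, TRUE)
  log <- mk_session_log(cor12)
  sm <- smooth_sessions(log)
  expect_equal(nrow(sm), 2L)
  expect_equal(sm$accuracy, c(0.6, 0.8))
  expect_equal(sm$n_in_bin, c(5L, 5L))
  # partial bins retained on request
  sm_all <- smooth_sessions(log, drop_partial = FALSE)
  expect_equal(nrow(sm_all), 3L)
  expect_equal(sm_all$accuracy[3], 0.5)
})

test_that("learn trials never change bin membership, accuracy, or trial order", {
  cor10 <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)
  plain <- mk_session_log(cor10)
  sm0 <- smooth_sessions(plain)
  # interleave learn trials between test trials 3 and 4
  correct <- append(cor10, c(NA, NA), after = 3)
  events <- append(rep("test", 10), c("learn", "learn"), after = 3)
  mixed <- mk_session_log(correct, events)
  sm1 <- smooth_sessions(mixed)
  expect_equal(sm1$accuracy, sm0$accuracy)
  expect_equal(sm1$n_in_bin, sm0$n_in_bin)
  # gaps preserved: the first bin's mean trial index now reflects indices 1:3,6,7
  expect_equal(sm1$axis_value[1], mean(c(1, 2, 3, 6, 7)))
})

test_that("learn-only sessions are skipped and counted", {
  log <- mk_session_log(rep(NA, 6), rep("learn", 6))
  sm <- smooth_sessions(log)
  expect_equal(nrow(sm), 0L)
  expect_equal(attr(sm, "skipped_sessions"), 1L)
})

test_that("fits recover noise-free coefficients and report honest AIC", {
  # constant truth under the linear form
  series <- mk_poly_series(c(0.7, 0, 0), x = seq(3, 98, by = 5), n_users = 6)
  f <- fit_fatigue(series, "linear")
  expect_lt(abs(coef(f)[["beta0"]] - 0.7), 1e-8)
  expect_lt(abs(coef(f)[["beta1"]]), 1e-6)
  # AIC identity on a real fit
  expect_equal(f$aic, 2 * f$df - 2 * f$loglik)
  expect_error(fit_fatigue(series[series$user_id == "u001", ], "linear"),
               "2 users")
})

test_that("elapsed-time and trial-order fits agree in curvature sign when pacing is constant", {
  cfg <- generator_config(n_users = 120, sessions_per_user_mean = 3,
                          sessions_per_user_sd = 1, session_length_base = 140,
                          session_length_sd = 30, learn_fraction = 0.3,
                          fatigue_curve = c(0.8, 1.3333e-3, -8.889e-6),
                          user_intercept_sd = 0.04,
                          seconds_per_trial_mean = 17, seconds_per_trial_sd = 0,
                          seed = 55)
  g <- generate_log(cfg)
  loc <- localize_times(g$log, "none")
  f_tr <- fit_fatigue(smooth_sessions(loc, axis = "trial_order"), "quadratic")
  f_ti <- fit_fatigue(smooth_sessions(loc, axis = "elapsed_time"), "quadratic")
  expect_lt(coef(f_tr)[["beta2"]], 0)
  expect_equal(sign(coef(f_tr)[["beta2"]]), sign(coef(f_ti)[["beta2"]]))
  # constant pacing maps the vertex from trials to minutes
  v_tr <- quadratic_summary(f_tr, 150)$vertex
  v_ti <- quadratic_summary(f_ti, 50)$vertex
  expect_lt(abs(v_ti - v_tr * 17 / 60), 8)
})

test_that("AIC comparison applies the margin-2 winner rule", {
  fake <- function(form, aic) {
    structure(list(form = form, axis = "trial_order", aic = aic,
                   converged = TRUE, n_obs = 100L), class = "fatigue_fit")
  }
  cmp <- compare_fits(list(fake("null", 310), fake("linear", 306),
                           fake("quadratic", 300)))
  expect_equal(cmp$winner, "quadratic")
  expect_equal(cmp$margin_to_runner_up, 6)
  expect_equal(cmp$table$delta_aic, c(0, 6, 10))
  cmp2 <- compare_fits(list(fake("linear", 300), fake("quadratic", 299)))
  expect_equal(cmp2$winner, "indistinguishable")
  expect_error(compare_fits(list(fake("null", 1))), "2")
  unconverged <- fake("linear", 200); unconverged$converged <- FALSE
  expect_error(compare_fits(list(fake("null", 1), unconverged)), "converged")
})

test_that("quadratic summary computes the vertex and drop, rejecting convex fits", {
  expect_equal(quadratic_summary(c(0.8, 0.002, -1e-5), 150)$vertex, 100)
  # oracle: direct evaluation of the polynomial at its vertex and horizon
  b <- c(0.8, 0.002, -1.333e-5)
  q <- function(x) b[1] + b[2] * x + b[3] * x^2
  v <- -b[2] / (2 * b[3])
  s <- quadratic_summary(b, 150)
  expect_equal(s$vertex, v)
  expect_equal(s$drop, q(v) - q(150))
  expect_lt(abs(s$drop - 0.075), 2e-4)
  expect_error(quadratic_summary(c(0.8, 0.002, 1e-6), 150), "interior maximum")
})
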
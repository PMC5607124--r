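# Moderation analysis: per-session coefficient extraction and the
# time-of-day regressions with the 0.008 critical value.

sim_coefs <- function(n, seed, intercept_fun = function(t) rep(0.8, length(t))) {
  set.seed(seed)
  t <- runif(n, 0, 24)
  df <- data.frame(user_id = sprintf("u%03d", sample(50, n, TRUE)),
                   session_id = sprintf("s%05d", seq_len(n)),
                   start_local_time = t,
                   intercept = intercept_fun(t) + rnorm(n, 0, 0.05),
                   linear = rnorm(n, 1e-3, 2e-4),
                   quadratic = rnorm(n, -9e-6, 2e-6))
  class(df) <- c("session_coefficients", "data.frame")
  df
}

test_that("with zero user/session variance all sessions share the fixed effects", {
  cfg <- generator_config(n_users = 60, sessions_per_user_mean = 4,
                          sessions_per_user_sd = 1, session_length_base = 110,
                          session_length_sd = 20, learn_fraction = 0.25,
                          fatigue_curve = c(0.8, 1.3333e-3, -8.889e-6),
                          user_intercept_sd = 0, user_slope_sd = 0,
                          session_intercept_sd = 0, seed = 91)
  g <- generate_log(cfg)
  lg <- localize_times(screen_sessions(g$log)$log, "none")
  coefs <- extract_session_coefs(lg)
  fit <- attr(coefs, "fit")
  expect_true(fit$converged)
  # with no true user/session variance the variance components sit at or
  # near the boundary, so every session's realization collapses onto the
  # fixed effect up to residual shrinkage noise
  expect_lt(sd(coefs$intercept), 0.01)
  expect_lt(sd(coefs$linear), 2e-5)
  expect_lt(sd(coefs$quadratic), 2e-7)
  expect_equal(mean(coefs$intercept), coef(fit)[["beta0"]], tolerance = 5e-3)
  expect_equal(mean(coefs$quadratic), coef(fit)[["beta2"]], tolerance = 2e-6)
})

test_that("session-level intercept spread is recovered (with shrinkage) at 2000 sessions", {
  cfg <- generator_config(n_users = 200, sessions_per_user_mean = 10,
                          sessions_per_user_sd = 2, session_length_base = 150,
                          session_length_sd = 25, learn_fraction = 0.25,
                          fatigue_curve = c(0.8, 1.3333e-3, -8.889e-6),
                          user_intercept_sd = 0.03, user_slope_sd = 0,
                          session_intercept_sd = 0.05, seed = 92)
  g <- generate_log(cfg)
  lg <- localize_times(screen_sessions(g$log)$log, "none")
  coefs <- extract_session_coefs(lg)
  expect_gt(nrow(coefs), 1800)
  per_user_mean <- ave(coefs$intercept, coefs$user_id)
  session_dev_sd <- sd(coefs$intercept - per_user_mean)
  expect_gt(session_dev_sd, 0.03)
  expect_lt(session_dev_sd, 0.07)
})

test_that("determinism: identical logs give identical coefficient tables", {
  cfg <- generator_config(n_users = 40, sessions_per_user_mean = 3,
                          sessions_per_user_sd = 1, session_length_base = 80,
                          session_length_sd = 15, learn_fraction = 0.25,
                          fatigue_curve = c(0.8, 1.3333e-3, -8.889e-6),
                          user_intercept_sd = 0.04, session_intercept_sd = 0.03,
                          seed = 93)
  lg <- localize_times(screen_sessions(generate_log(cfg)$log)$log, "none")
  c1 <- extract_session_coefs(lg)
  c2 <- extract_session_coefs(lg)
  strip <- function(x) {
    attr(x, "fit") <- NULL
    as.data.frame(x)
  }
  expect_identical(strip(c1), strip(c2))
})

test_that("time-of-day regressions report per-term t, joint F and strict-threshold verdicts", {
  coefs <- sim_coefs(800, seed = 1,
                     intercept_fun = function(t) 0.8 + 0.03 * sin(2 * pi * t / 24))
  rep <- moderate_by_time(coefs)
  expect_s3_class(rep, "moderation_report")
  expect_equal(nrow(rep), 9L)  # 3 components x (sin, cos, joint F)
  # strong planted sine modulation of the intercept is detected
  expect_true(rep$significant[rep$component == "intercept" & rep$term == "sin"])
  expect_true(rep$significant[rep$component == "intercept" & rep$term == "joint_F"])
  # the verdict is exactly the strict comparison against alpha
  expect_equal(rep$significant, !is.na(rep$p_value) & rep$p_value < 0.008)
  # amplitude = sqrt(a^2 + c^2) close to planted 0.03
  amp <- rep$amplitude[rep$component == "intercept"][1]
  expect_lt(abs(amp - 0.03), 0.01)
  # cluster-robust variant runs and keeps estimates
  repc <- moderate_by_time(coefs, cluster_robust = TRUE)
  expect_equal(repc$estimate, rep$estimate)
  expect_false(identical(repc$se, rep$se))
})

test_that("degenerate inputs are rejected", {
  coefs <- sim_coefs(30, seed = 2)
  expect_error(moderate_by_time(coefs), "at least 50")
  coefs2 <- sim_coefs(100, seed = 3)
  coefs2$start_local_time <- 12
  expect_error(moderate_by_time(coefs2), "degenerate")
})
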
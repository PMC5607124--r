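# Diurnal analyses: half-hour binning, harmonic regression (exact and
# Bayesian), WAIC behaviour, out-of-sample RMSE and the replication
# protocol.

mk_sessions <- function(start, accuracy = 0.8, n_trials = 50L, user = NULL) {
  n <- length(start)
  s <- data.frame(
    user_id = user %||% sprintf("u%04d", seq_len(n)),
    session_id = sprintf("s%04d", seq_len(n)),
    start_local_time = start, n_trials = n_trials,
    n_test_trials = pmax(1L, n_trials %/% 2L),
    duration_minutes = n_trials * 17 / 60,
    mean_accuracy = accuracy, stringsAsFactors = FALSE)
  s
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("sessions land in half-open half-hour bins with correct weights", {
  s <- mk_sessions(c(0.25, 0.75))
  bd <- bin_day(s, "login_fraction")
  expect_equal(nrow(bd), 48L)
  expect_equal(bd$weight[1:2], c(1L, 1L))
  expect_equal(sum(bd$weight), 2L)

  s10 <- mk_sessions(rep(13.1, 10))
  bd10 <- bin_day(s10, "login_fraction")
  expect_equal(bd10$value[bd10$bin_start_hour == 13], 1.0)
  expect_equal(sum(bd10$value, na.rm = TRUE), 1.0)
  expect_true(all(is.na(bd10$value[bd10$weight == 0])))

  sacc <- mk_sessions(c(6.1, 6.2), accuracy = c(0.4, 0.6))
  bda <- bin_day(sacc, "session_accuracy")
  expect_equal(bda$value[bda$bin_start_hour == 6], 0.5)
  expect_equal(bda$weight[bda$bin_start_hour == 6], 2L)
  expect_error(bin_day(mk_sessions(12)[0, ], "login_fraction"), "empty")
})

test_that("noise-free harmonic series are interpolated exactly", {
  t <- (0:47) * 0.5 + 0.25
  y <- 0.8 + 0.1 * sin(2 * pi * t / 24)
  f <- fit_day_model(mk_day_series(y), "h1", inference = "weighted_least_squares")
  expect_lt(max(abs(coef(f) - c(0.8, 0.1, 0))), 1e-8)
  # constant series, intercept model -> weighted mean
  w <- rep(c(1L, 9L), 24)
  yc <- rep(c(0.2, 0.6), 24)
  fc <- fit_day_model(mk_day_series(yc, weight = w), "intercept",
                      inference = "weighted_least_squares")
  expect_equal(unname(coef(fc)[1]), stats::weighted.mean(yc, w))
  expect_error(fit_day_model(mk_day_series(y, weight = c(rep(1L, 4), rep(0L, 44))),
                             "h1"), "non-missing bins")
})

test_that("predictions are 24h-periodic and phase shifts pass through", {
  t <- (0:47) * 0.5 + 0.25
  y <- 0.5 + 0.2 * sin(2 * pi * (t - 3) / 24)
  f <- fit_day_model(mk_day_series(y), "h1", inference = "weighted_least_squares")
  expect_equal(predict(f, c(1, 5, 20)), predict(f, c(25, 29, 44)))
  peak0 <- harmonic_peak_time(coef(f)[["sin1"]], coef(f)[["cos1"]])
  y2 <- 0.5 + 0.2 * sin(2 * pi * (t - 5) / 24)
  f2 <- fit_day_model(mk_day_series(y2), "h1", inference = "weighted_least_squares")
  peak2 <- harmonic_peak_time(coef(f2)[["sin1"]], coef(f2)[["cos1"]])
  expect_equal((peak2 - peak0) %% 24, 2, tolerance = 1e-6)
})

test_that("the Bayesian engine satisfies WAIC identities and monotone lppd", {
  # degenerate case: identical posterior log-density c at every point
  w0 <- waic_from_loglik(matrix(-1.7, nrow = 200, ncol = 4))
  expect_equal(w0$lppd, 4 * -1.7)
  expect_equal(w0$p_waic, 0)
  expect_equal(w0$waic, -2 * (4 * -1.7))

  t <- (0:47) * 0.5 + 0.25
  set.seed(42)
  y <- 0.6 + 0.08 * sin(2 * pi * t / 24) + rnorm(48, 0, 0.03)
  lppd <- p_waic <- numeric(4)
  for (K in 0:3) {
    f <- fit_day_model(mk_day_series(y), if (K == 0) "intercept" else paste0("h", K),
                       inference = "bayesian", seed = 100 + K)
    lppd[K + 1] <- f$report$lppd
    p_waic[K + 1] <- f$report$p_waic
    expect_equal(f$report$waic, -2 * (f$report$lppd - f$report$p_waic))
    expect_gte(f$report$p_waic, 0)
  }
  # nested richer models never fit worse in-sample (small sampling slack)
  expect_true(all(diff(lppd) > -0.5))
})

test_that("out-of-sample RMSE matches its closed forms and in-sample consistency", {
  s2 <- mk_day_series(c(0.4, 0.6, rep(NA, 46)), weight = c(1L, 1L, rep(0L, 46)))
  const <- fit_day_model(mk_day_series(rep(0.5, 48)), "intercept",
                         inference = "weighted_least_squares")
  expect_equal(oos_rmse(const, s2), 0.1)
  set.seed(7)
  tr <- mk_day_series(0.5 + 0.1 * sin(2 * pi * ((0:47) * 0.5 + 0.25) / 24) +
                        rnorm(48, 0, 0.02), weight = sample(5:30, 48, TRUE))
  f <- fit_day_model(tr, "h1", inference = "weighted_least_squares")
  expect_equal(oos_rmse(f, tr), f$report$rmse)
})

test_that("the replication protocol reproduces phase under timezone adjustment", {
  peak <- 20
  dens <- harmonic_curve(1, a = 0.7 * sin(2 * pi * peak / 24),
                         c = 0.7 * cos(2 * pi * peak / 24))
  mk <- function(seed, offsets, weights) {
    generator_config(n_users = 250, sessions_per_user_mean = 12,
                     sessions_per_user_sd = 4, session_length_base = 20,
                     session_length_sd = 5, learn_fraction = 0.2,
                     login_density = dens, user_intercept_sd = 0.03,
                     utc_offset_choices = offsets, utc_offset_weights = weights,
                     seed = seed)
  }
  g1 <- generate_log(mk(61, 0L, 1))                      # cohort on UTC
  g2 <- generate_log(mk(62, c(-5L, -9L), c(0.5, 0.5)))   # spread offsets
  rp <- replication_protocol(g1$log, g2$log, metric = "login_fraction",
                             candidates = c("intercept", "h1"),
                             draws = 800, seed = 3)
  f3 <- rp$stage3$fits[["h1"]]
  peak3 <- harmonic_peak_time(coef(f3)[["sin1"]], coef(f3)[["cos1"]])
  expect_lt(abs(peak3 - peak), 0.5)
  # the uncorrected direct-replication series is phase-smeared westwards
  f_direct <- fit_day_model(rp$series$sample2_direct, "h1",
                            inference = "weighted_least_squares")
  peak_direct <- harmonic_peak_time(coef(f_direct)[["sin1"]],
                                    coef(f_direct)[["cos1"]])
  expect_gt(abs(peak_direct - peak), abs(peak3 - peak))

  # identical samples: frozen-model RMSE equals the winner's in-sample RMSE
  rp_same <- replication_protocol(g1$log, g1$log, metric = "login_fraction",
                                  candidates = c("intercept", "h1"),
                                  draws = 800, seed = 3)
  win <- rp_same$stage1$winner
  expect_equal(rp_same$stage2$table$rmse[rp_same$stage2$table$model == win],
               rp_same$stage1$fits[[win]]$report$rmse)
})
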
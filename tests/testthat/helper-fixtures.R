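# Shared fixtures: tiny hand-built logs and binned series, plus small
# generator configs used across test files.

# a minimal valid log; rows are (user, session, trial, type, hour_utc,
# offset, correct, elapsed)
tiny_log <- function() {
  df <- data.frame(
    user_id = c("u1", "u1", "u1", "u2", "u2", "u2", "u2"),
    session_id = c("s1", "s1", "s1", "s2", "s2", "s2", "s2"),
    trial_index = c(1L, 2L, 3L, 1L, 2L, 3L, 4L),
    event_type = c("learn", "test", "test", "test", "learn", "test", "test"),
    timestamp_utc = as.POSIXct("2016-01-11 03:30:00", tz = "UTC") +
      c(0, 20, 40, 3600, 3620, 3640, 3660),
    utc_offset_hours = c(-5L, -5L, -5L, -9L, -9L, -9L, -9L),
    correct = c(NA, TRUE, FALSE, TRUE, NA, TRUE, FALSE),
    elapsed_seconds = c(0, 20, 40, 0, 20, 40, 60),
    stringsAsFactors = FALSE
  )
  class(df) <- c("trial_log", "data.frame")
  df
}

write_log_lines <- function(lines) {
  p <- tempfile(fileext = ".csv")
  writeLines(lines, p)
  p
}

log_header <- paste("user_id,session_id,trial_index,event_type,timestamp_utc,",
                    "utc_offset_hours,correct,elapsed_seconds", sep = "")

# a 48-bin day series from a value vector
mk_day_series <- function(value, weight = rep(10L, 48), metric = "session_accuracy") {
  s <- data.frame(bin_start_hour = (0:47) * 0.5, t_mid = (0:47) * 0.5 + 0.25,
                  value = value, weight = weight)
  attr(s, "metric") <- metric
  class(s) <- c("day_series", "data.frame")
  s
}

# a smoothed series with exact polynomial accuracy, n users sharing the curve
mk_poly_series <- function(beta, x = seq(3, 148, by = 5), n_users = 10,
                           user_offsets = rep(0, n_users)) {
  out <- do.call(rbind, lapply(seq_len(n_users), function(u) {
    data.frame(user_id = sprintf("u%03d", u), session_id = "s1",
               bin_index = seq_along(x), axis = "trial_order", axis_value = x,
               accuracy = beta[1] + beta[2] * x + beta[3] * x^2 + user_offsets[u],
               n_in_bin = 5L, stringsAsFactors = FALSE)
  }))
  class(out) <- c("smoothed_series", "data.frame")
  out
}

# small flat generator config (no diurnal structure, no fatigue)
flat_config <- function(n_users = 50, seed = 1, ...) {
  generator_config(n_users = n_users, sessions_per_user_mean = 4,
                   sessions_per_user_sd = 2, session_length_base = 40,
                   session_length_sd = 15, learn_fraction = 0.3,
                   fatigue_curve = c(0.8, 0, 0), user_intercept_sd = 0.05,
                   seed = seed, ...)
}
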
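# Event-log data model: parsing, validation diagnostics, round-tripping,
# timezone localisation and screening.

test_that("valid logs parse with correctness only on test events", {
  p <- write_log_lines(c(
    log_header,
    "u1,s1,1,learn,2016-01-11T03:30:00Z,-5,,10.5",
    "u1,s1,2,test,2016-01-11T03:30:20Z,-5,true,21"
  ))
  log <- read_session_log(p)
  expect_s3_class(log, "trial_log")
  expect_equal(nrow(log), 2L)
  expect_true(is.na(log$correct[log$event_type == "learn"]))
  expect_true(log$correct[log$event_type == "test"])
  expect_equal(log$elapsed_seconds, c(10.5, 21))
})

test_that("malformed rows raise typed errors naming the offending lines", {
  dup <- write_log_lines(c(
    log_header,
    "u1,s1,1,test,2016-01-11T03:30:00Z,-5,true,10",
    "u1,s1,1,test,2016-01-11T03:30:20Z,-5,false,20"
  ))
  err <- expect_error(read_session_log(dup), class = "session_log_parse_error")
  expect_match(conditionMessage(err), "duplicate")
  expect_match(conditionMessage(err), "2")
  expect_match(conditionMessage(err), "3")

  badts <- write_log_lines(c(
    log_header,
    "u1,s1,1,test,201x-01-11T03:30:00Z,-5,true,10",
    "u1,s1,2,test,2016-01-11T03:30:20Z,-5,false,20"
  ))
  expect_error(read_session_log(badts), "timestamp",
               class = "session_log_parse_error")

  neg <- write_log_lines(c(
    log_header,
    "u1,s1,1,test,2016-01-11T03:30:00Z,-5,true,-4"
  ))
  expect_error(read_session_log(neg), "elapsed",
               class = "session_log_parse_error")

  gap <- write_log_lines(c(
    log_header,
    "u1,s1,1,test,2016-01-11T03:30:00Z,-5,true,4",
    "u1,s1,3,test,2016-01-11T03:31:00Z,-5,true,8"
  ))
  expect_error(read_session_log(gap), "contiguous",
               class = "session_log_parse_error")
})

test_that("write/read round trip is bit-identical for generated logs", {
  for (seed in c(2, 9)) {
    g <- generate_log(flat_config(n_users = 15, seed = seed,
                                  utc_offset_choices = c(-8L, -5L)))
    f1 <- tempfile(); f2 <- tempfile()
    write_session_log(g$log, f1)
    back <- read_session_log(f1)
    write_session_log(back, f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_equal(as.data.frame(back), as.data.frame(g$log))
    unlink(c(f1, f2))
  }
})

test_that("localisation applies modular offset arithmetic and preserves order", {
  log <- tiny_log()
  loc <- localize_times(log, "none")
  # u1 starts 03:30 UTC -> 3.5 h clock time
  expect_equal(loc$start_local_time[loc$user_id == "u1"][1], 3.5)
  loc2 <- localize_times(log, "per_user_offset")
  # 03:30 UTC at offset -5 -> 22.5 h local
  expect_equal(loc2$start_local_time[loc2$user_id == "u1"][1], 22.5)
  # 04:30 UTC at offset -9 -> 19.5 h local
  expect_equal(loc2$start_local_time[loc2$user_id == "u2"][1], 19.5)
  # bijection: same rows, same order, one extra column
  expect_identical(loc2[names(log)], log[names(log)])
  # missing offsets are reported by user
  log$utc_offset_hours[log$user_id == "u2"] <- NA
  expect_error(localize_times(log, "per_user_offset"), "u2")
})

test_that("offset -9 applied to 06:00 UTC gives 21.0 local", {
  log <- tiny_log()
  log$timestamp_utc <- as.POSIXct("2016-01-11 06:00:00", tz = "UTC") +
    log$elapsed_seconds
  log$utc_offset_hours <- -9L
  loc <- localize_times(log, "per_user_offset")
  expect_equal(unique(loc$start_local_time), 21.0)
})

test_that("session summaries satisfy their invariants on generated data", {
  g <- generate_log(flat_config(n_users = 25, seed = 4))
  ss <- session_summaries(localize_times(g$log, "none"))
  expect_true(all(ss$n_test_trials <= ss$n_trials))
  expect_true(all(ss$start_local_time >= 0 & ss$start_local_time < 24))
  # mean_accuracy equals the mean of correct over test trials
  one <- ss[which.max(ss$n_test_trials), ]
  rows <- g$log$user_id == one$user_id & g$log$session_id == one$session_id &
    g$log$event_type == "test"
  expect_equal(one$mean_accuracy, mean(g$log$correct[rows]))
})

test_that("screening removes planted violations, reports counts, and is idempotent", {
  g <- generate_log(flat_config(n_users = 30, seed = 5))
  log <- g$log
  # permissive rules change nothing
  perm <- screen_sessions(log, screening_config(min_test_trials = 0,
                                                max_duration_hours = 1e6,
                                                min_sessions_per_user = 0))
  expect_equal(as.data.frame(perm$log), as.data.frame(log))
  expect_true(all(perm$report$removed == 0))
  expect_equal(perm$report$before, perm$report$after)

  # plant: one user with a single session, one over-long session
  skey <- paste(log$user_id, log$session_id)
  one_sess <- log[skey == skey[1], ]
  one_sess$user_id <- "u_lonely"
  long_sess <- one_sess
  long_sess$user_id <- log$user_id[1]
  long_sess$session_id <- "s_marathon"
  long_sess$elapsed_seconds <- seq_len(nrow(long_sess)) * 3600 * 7 / nrow(long_sess)
  planted <- rbind(as.data.frame(log), as.data.frame(one_sess),
                   as.data.frame(long_sess))
  class(planted) <- c("trial_log", "data.frame")
  base_rules <- screening_config(min_test_trials = 1, max_duration_hours = 6,
                                 min_sessions_per_user = 2)
  base <- screen_sessions(log, base_rules)
  out <- screen_sessions(planted, base_rules)
  expect_equal(out$report$removed[["sessions_too_long"]],
               base$report$removed[["sessions_too_long"]] + 1)
  expect_gte(out$report$removed[["users_too_few_sessions"]],
             base$report$removed[["users_too_few_sessions"]] + 1)
  # report accounts for every removal
  expect_equal(out$report$after[["trials"]], nrow(out$log))

  # idempotence
  again <- screen_sessions(out$log, base_rules)
  expect_true(all(again$report$removed == 0))
  expect_equal(as.data.frame(again$log), as.data.frame(out$log))
})

test_that("a user with a single session is dropped by the min-sessions rule", {
  log <- tiny_log()  # u1 and u2 have one session each
  out <- screen_sessions(log, screening_config(min_test_trials = 1,
                                               max_duration_hours = 6,
                                               min_sessions_per_user = 2))
  expect_equal(nrow(out$log), 0L)
  expect_equal(out$report$removed[["users_too_few_sessions"]], 2)
})
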
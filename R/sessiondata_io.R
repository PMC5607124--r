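# Session-log data model: CSV reading/writing, timezone localisation and
# screening filters for timestamped learning-session event logs.
#
# A trial log is a data frame (class "trial_log") with one row per event:
#   user_id          opaque string
#   session_id       opaque string
#   trial_index      1-based order within the session (unique, contiguous)
#   event_type       "learn" or "test"
#   timestamp_utc    POSIXct, UTC
#   utc_offset_hours integer in [-12, 14], or NA when unknown
#   correct          logical; NA on learn events, non-NA on test events
#   elapsed_seconds  non-negative, non-decreasing within a session

log_columns <- c("user_id", "session_id", "trial_index", "event_type",
                 "timestamp_utc", "utc_offset_hours", "correct",
                 "elapsed_seconds")

parse_error <- function(msg, lines = integer()) {
  stop(structure(class = c("session_log_parse_error", "error", "condition"),
                 list(message = msg, call = NULL, lines = lines)))
}

as_trial_log <- function(df) {
  class(df) <- c("trial_log", "data.frame")
  df
}

# order rows by (user, session, trial); sessions keep first-appearance order
# inside a user so ordering is stable across write/read round trips
order_log <- function(df) {
  df <- df[order(df$user_id, df$session_id, df$trial_index), , drop = FALSE]
  rownames(df) <- NULL
  df
}

validate_trial_log <- function(df, line_of = NULL) {
  where <- function(idx) {
    if (is.null(line_of)) paste0("rows ", paste(idx, collapse = ", "))
    else paste0("lines ", paste(line_of[idx], collapse = ", "))
  }
  bad <- which(!df$event_type %in% c("learn", "test"))
  if (length(bad)) {
    parse_error(paste0("unknown event_type at ", where(bad)), bad)
  }
  bad <- which(is.na(df$timestamp_utc))
  if (length(bad)) {
    parse_error(paste0("malformed timestamp at ", where(bad)), bad)
  }
  bad <- which(!is.finite(df$elapsed_seconds) | df$elapsed_seconds < 0)
  if (length(bad)) {
    parse_error(paste0("negative or missing elapsed_seconds at ", where(bad)), bad)
  }
  bad <- which(df$event_type == "test" & is.na(df$correct))
  if (length(bad)) {
    parse_error(paste0("test event without correctness at ", where(bad)), bad)
  }
  bad <- which(df$event_type == "learn" & !is.na(df$correct))
  if (length(bad)) {
    parse_error(paste0("learn event carrying correctness at ", where(bad)), bad)
  }
  bad <- which(!is.na(df$utc_offset_hours) &
                 (df$utc_offset_hours < -12 | df$utc_offset_hours > 14))
  if (length(bad)) {
    parse_error(paste0("utc_offset_hours outside [-12, 14] at ", where(bad)), bad)
  }
  key <- paste(df$user_id, df$session_id, df$trial_index, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    parse_error(paste0("duplicate (session_id, trial_index) at ", where(which(dup))),
                which(dup))
  }
  # per-session contiguity and monotone elapsed time
  skey <- paste(df$user_id, df$session_id, sep = "\r")
  ord <- order(skey, df$trial_index)
  sk <- skey[ord]; ti <- df$trial_index[ord]; el <- df$elapsed_seconds[ord]
  first <- !duplicated(sk)
  bad <- ord[which((first & ti != 1L) | (!first & ti != c(0L, ti[-length(ti)]) + 1L))]
  if (length(bad)) {
    parse_error(paste0("trial_index not contiguous from 1 at ", where(bad)), bad)
  }
  bad <- ord[which(!first & el < c(-Inf, el[-length(el)]))]
  if (length(bad)) {
    parse_error(paste0("elapsed_seconds decreases within a session at ", where(bad)),
                bad)
  }
  invisible(df)
}

#' Read a session event log from CSV
#'
#' Reads the package's CSV dialect (UTF-8, comma-separated, header row with
#' the canonical column names, ISO 8601 UTC timestamps with a trailing `Z`,
#' empty `correct` field on learn events) into a validated trial log.
#' Malformed rows raise a `session_log_parse_error` naming the offending
#' line numbers.
#'
#' @param path path to a CSV file.
#' @return A `trial_log` data frame ordered by (user, session, trial index).
#' @seealso [write_session_log()], [generate_log()]
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) stop("read_session_log: no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), log_columns)) {
    parse_error(paste0("header mismatch: expected ",
                       paste(log_columns, collapse = ","), " but found ",
                       paste(names(raw), collapse = ",")))
  }
  n <- nrow(raw)
  line_of <- seq_len(n) + 1L  # header is line 1
  ts <- as.POSIXct(raw$timestamp_utc, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  ts[!grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}Z$", raw$timestamp_utc)] <- NA
  corr <- rep(NA, n)
  corr[raw$correct == "true"] <- TRUE
  corr[raw$correct == "false"] <- FALSE
  bad_corr <- which(!raw$correct %in% c("", "true", "false"))
  if (length(bad_corr)) {
    parse_error(paste0("unparseable correct field at lines ",
                       paste(line_of[bad_corr], collapse = ", ")),
                bad_corr)
  }
  df <- data.frame(
    user_id = raw$user_id,
    session_id = raw$session_id,
    trial_index = suppressWarnings(as.integer(raw$trial_index)),
    event_type = raw$event_type,
    timestamp_utc = ts,
    utc_offset_hours = suppressWarnings(
      as.integer(ifelse(raw$utc_offset_hours == "", NA, raw$utc_offset_hours))),
    correct = as.logical(corr),
    elapsed_seconds = suppressWarnings(as.numeric(raw$elapsed_seconds)),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(df$trial_index) | df$trial_index < 1L)
  if (length(bad)) {
    parse_error(paste0("bad trial_index at lines ",
                       paste(line_of[bad], collapse = ", ")), bad)
  }
  validate_trial_log(df, line_of = line_of)
  as_trial_log(order_log(df))
}

#' Write a session event log to CSV
#'
#' Writes the canonical CSV dialect. `write_session_log(read_session_log(p))`
#' reproduces the file byte for byte for any valid log.
#'
#' @param log a `trial_log`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "trial_log") || is.data.frame(log))
  log <- order_log(as.data.frame(log)[log_columns])
  out <- data.frame(
    user_id = log$user_id,
    session_id = log$session_id,
    trial_index = as.character(log$trial_index),
    event_type = log$event_type,
    timestamp_utc = format(log$timestamp_utc, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    utc_offset_hours = ifelse(is.na(log$utc_offset_hours), "",
                              as.character(log$utc_offset_hours)),
    correct = ifelse(is.na(log$correct), "",
                     ifelse(log$correct, "true", "false")),
    elapsed_seconds = as.character(log$elapsed_seconds),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(log_columns, collapse = ","), con)
  writeLines(do.call(paste, c(unname(out), sep = ",")), con)
  invisible(path)
}

#' @export
print.trial_log <- function(x, ...) {
  cat(sprintf("trial log: %d events, %d sessions, %d users\n",
              nrow(x), length(unique(paste(x$user_id, x$session_id))),
              length(unique(x$user_id))))
  if (!is.null(x$start_local_time)) {
    cat(sprintf("  localised (%s)\n", attr(x, "timezone_mode") %||% "unknown mode"))
  }
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Attach local session start times
#'
#' Populates a `start_local_time` column (hours in `[0, 24)`, identical for
#' all events of a session, taken from the session's first event) either as
#' the raw UTC clock time (`mode = "none"`, mirroring an analysis that cannot
#' correct for timezones) or shifted by each user's UTC offset
#' (`mode = "per_user_offset"`).
#'
#' @param log a `trial_log`.
#' @param mode `"none"` or `"per_user_offset"`.
#' @return The log with a `start_local_time` column; row order is unchanged.
#' @export
localize_times <- function(log, mode = c("none", "per_user_offset")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(log))
  if (mode == "per_user_offset") {
    missing_users <- unique(log$user_id[is.na(log$utc_offset_hours)])
    if (length(missing_users)) {
      stop("localize_times: utc_offset_hours missing for users: ",
           paste(missing_users, collapse = ", "))
    }
  }
  skey <- paste(log$user_id, log$session_id, sep = "\r")
  first <- !duplicated(skey)
  lt <- as.POSIXlt(log$timestamp_utc[first], tz = "UTC")
  hour_utc <- lt$hour + lt$min / 60 + lt$sec / 3600
  off <- if (mode == "per_user_offset") log$utc_offset_hours[first] else 0
  start_local <- (hour_utc + off) %% 24
  log$start_local_time <- start_local[match(skey, skey[first])]
  attr(log, "timezone_mode") <- mode
  as_trial_log(log)
}

#' Summarise sessions
#'
#' One row per session: local start time, trial counts, duration and mean
#' test accuracy (`NA` when the session has no test trials).
#'
#' @param log a localised `trial_log` (see [localize_times()]).
#' @return A data frame of session summaries.
#' @export
session_summaries <- function(log) {
  stopifnot(is.data.frame(log))
  if (is.null(log$start_local_time)) {
    stop("session_summaries: log has no start_local_time; run localize_times() first")
  }
  skey <- paste(log$user_id, log$session_id, sep = "\r")
  sid <- match(skey, unique(skey))
  is_test <- log$event_type == "test"
  n_trials <- tabulate(sid)
  n_test <- tabulate(sid[is_test], nbins = length(n_trials))
  corr_sum <- rowsum(as.numeric(log$correct[is_test]), sid[is_test])
  mean_acc <- rep(NA_real_, length(n_trials))
  mean_acc[as.integer(rownames(corr_sum))] <- corr_sum[, 1]
  mean_acc <- mean_acc / ifelse(n_test > 0, n_test, NA)
  # sid is assigned in first-appearance order, so tapply's sorted unique
  # values line up with the `first` rows
  dur <- as.numeric(tapply(log$elapsed_seconds, sid, max)) / 60
  first <- !duplicated(sid)
  out <- data.frame(
    user_id = log$user_id[first],
    session_id = log$session_id[first],
    start_local_time = log$start_local_time[first],
    n_trials = n_trials,
    n_test_trials = n_test,
    duration_minutes = dur,
    mean_accuracy = mean_acc,
    stringsAsFactors = FALSE
  )
  attr(out, "timezone_mode") <- attr(log, "timezone_mode")
  rownames(out) <- NULL
  out
}

#' Screening configuration
#'
#' Thresholds for the pre-analysis screening filters. The defaults are
#' conservative, configurable stand-ins (drop sessions with fewer than 5 test
#' trials or longer than 6 hours, drop users with fewer than 2 sessions) and
#' are not canonical: real deployments should set each threshold explicitly.
#'
#' @param min_test_trials minimum test trials a session must contain.
#' @param max_duration_hours maximum plausible session duration.
#' @param min_sessions_per_user minimum sessions a user must contribute.
#' @param drop_untyped_test_trials drop test trials whose correctness is
#'   missing (a data-hygiene trial-level rule; such rows cannot occur in logs
#'   that pass [read_session_log()] validation).
#' @return A `screening_config` list.
#' @export
screening_config <- function(min_test_trials = 5,
                             max_duration_hours = 6,
                             min_sessions_per_user = 2,
                             drop_untyped_test_trials = TRUE) {
  stopifnot(min_test_trials >= 0, max_duration_hours > 0,
            min_sessions_per_user >= 0)
  structure(list(min_test_trials = min_test_trials,
                 max_duration_hours = max_duration_hours,
                 min_sessions_per_user = min_sessions_per_user,
                 drop_untyped_test_trials = drop_untyped_test_trials),
            class = "screening_config")
}

#' Screen a session log
#'
#' Applies the screening filters in a fixed order -- trial level, then session
#' level, then user level -- and returns the retained log together with a
#' report accounting for every removal. Screening is idempotent: applying the
#' same rules to already-screened data removes nothing.
#'
#' @param log a `trial_log`.
#' @param rules a [screening_config()].
#' @return A list with elements `log` (screened `trial_log`) and `report`
#'   (a `screening_report`).
#' @export
screen_sessions <- function(log, rules = screening_config()) {
  stopifnot(is.data.frame(log), inherits(rules, "screening_config"))
  before <- log_totals(log)
  removed <- c()

  # trial level
  if (isTRUE(rules$drop_untyped_test_trials)) {
    bad <- log$event_type == "test" & is.na(log$correct)
    removed["trials_untyped_test"] <- sum(bad)
    log <- log[!bad, , drop = FALSE]
  }

  # session level
  skey <- paste(log$user_id, log$session_id, sep = "\r")
  sid <- match(skey, unique(skey))
  n_test <- tabulate(sid[log$event_type == "test"], nbins = max(sid, 0))
  dur_h <- as.numeric(tapply(log$elapsed_seconds, sid, max)) / 3600
  few_tests <- n_test < rules$min_test_trials
  too_long <- dur_h > rules$max_duration_hours
  removed["sessions_too_few_test_trials"] <- sum(few_tests)
  removed["sessions_too_long"] <- sum(too_long & !few_tests)
  keep_session <- !(few_tests | too_long)
  log <- log[keep_session[sid], , drop = FALSE]

  # user level
  skey <- paste(log$user_id, log$session_id, sep = "\r")
  first <- !duplicated(skey)
  sess_per_user <- table(log$user_id[first])
  bad_users <- names(sess_per_user)[sess_per_user < rules$min_sessions_per_user]
  removed["users_too_few_sessions"] <- length(bad_users)
  log <- log[!log$user_id %in% bad_users, , drop = FALSE]

  rownames(log) <- NULL
  after <- log_totals(log)
  report <- structure(list(rules = rules, removed = removed,
                           before = before, after = after),
                      class = "screening_report")
  list(log = as_trial_log(log), report = report)
}

log_totals <- function(log) {
  c(users = length(unique(log$user_id)),
    sessions = length(unique(paste(log$user_id, log$session_id, sep = "\r"))),
    trials = nrow(log))
}

#' @export
print.screening_report <- function(x, ...) {
  cat("screening report\n")
  cat(sprintf("  before: %d users, %d sessions, %d trials\n",
              x$before["users"], x$before["sessions"], x$before["trials"]))
  for (nm in names(x$removed)) {
    cat(sprintf("  rule %-32s removed %d\n", nm, x$removed[nm]))
  }
  cat(sprintf("  after:  %d users, %d sessions, %d trials\n",
              x$after["users"], x$after["sessions"], x$after["trials"]))
  invisible(x)
}
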
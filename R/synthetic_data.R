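# Synthetic session-log generator. Emulates the statistical structure the
# downstream analyses assume -- over-dispersed per-user session counts,
# diurnal login density with an evening peak, mixed learn/test trials with
# early-session difficulty, a quadratic fatigue curve on the accuracy scale,
# user- and session-level random effects, and user timezone offsets -- with
# every latent quantity exposed in a truth record so each inferential stage
# can be tested by parameter recovery.

#' Generator configuration
#'
#' All parameters of the synthetic cohort. Accuracy is modelled on the
#' probability scale as an additive sum -- quadratic fatigue curve in trial
#' index, early-session difficulty handicap, diurnal modulation, user and
#' session random effects -- clamped to `[0.01, 0.99]` before Bernoulli
#' sampling, matching the linear-model analyses downstream.
#'
#' @param n_users number of users.
#' @param study_days length of the observation window in days.
#' @param login_density [harmonic_curve()] giving the unnormalised intensity
#'   of session starts over local time of day (floored at 0, then normalised
#'   over the 48 half-hour bins).
#' @param sessions_per_user_mean,sessions_per_user_sd moments of the
#'   per-user session count (negative binomial when over-dispersed, Poisson
#'   otherwise; truncated to at least 1).
#' @param session_length_base expected trials per session before diurnal
#'   modulation.
#' @param session_length_sd standard deviation of session length in trials.
#' @param session_length_diurnal [harmonic_curve()], multiplicative
#'   modulation of expected session length by local start time (floored at
#'   0.2).
#' @param learn_fraction probability that a trial is a learn event.
#' @param fatigue_curve numeric `(beta0, beta1, beta2)`: accuracy as a
#'   quadratic in trial index.
#' @param difficulty_gradient size of the additive accuracy handicap on the
#'   earliest test trials of a session (harder items are scheduled first).
#' @param difficulty_tau e-folding constant, in test trials, of that
#'   handicap; the default 3 makes it negligible past the first ten test
#'   trials.
#' @param accuracy_diurnal [harmonic_curve()], additive modulation of
#'   accuracy by local session start time.
#' @param user_intercept_sd,user_slope_sd standard deviations of the
#'   user-level random intercept and random linear slope (per trial).
#' @param session_intercept_sd standard deviation of the session-level
#'   random intercept.
#' @param seconds_per_trial_mean,seconds_per_trial_sd per-trial duration
#'   moments (normal, floored at 0.5 s).
#' @param utc_offset_choices integer UTC offsets users may have.
#' @param utc_offset_weights sampling weights for the offsets.
#' @param seed integer seed; [generate_log()] is bit-reproducible given the
#'   config.
#' @return A validated `generator_config` list.
#' @seealso [reference_cohort_config()], [generate_log()]
#' @export
generator_config <- function(n_users,
                             study_days = 119,
                             login_density = harmonic_curve(1),
                             sessions_per_user_mean = 10,
                             sessions_per_user_sd = 8,
                             session_length_base = 60,
                             session_length_sd = 45,
                             session_length_diurnal = harmonic_curve(1),
                             learn_fraction = 0.3,
                             fatigue_curve = c(0.8, 0, 0),
                             difficulty_gradient = 0,
                             difficulty_tau = 3,
                             accuracy_diurnal = harmonic_curve(0),
                             user_intercept_sd = 0.05,
                             user_slope_sd = 0,
                             session_intercept_sd = 0,
                             seconds_per_trial_mean = 17,
                             seconds_per_trial_sd = 6,
                             utc_offset_choices = 0L,
                             utc_offset_weights = rep(1, length(utc_offset_choices)),
                             seed = 1L) {
  cfg <- list(n_users = as.integer(n_users), study_days = as.integer(study_days),
              login_density = login_density,
              sessions_per_user_mean = sessions_per_user_mean,
              sessions_per_user_sd = sessions_per_user_sd,
              session_length_base = session_length_base,
              session_length_sd = session_length_sd,
              session_length_diurnal = session_length_diurnal,
              learn_fraction = learn_fraction,
              fatigue_curve = as.numeric(fatigue_curve),
              difficulty_gradient = difficulty_gradient,
              difficulty_tau = difficulty_tau,
              accuracy_diurnal = accuracy_diurnal,
              user_intercept_sd = user_intercept_sd,
              user_slope_sd = user_slope_sd,
              session_intercept_sd = session_intercept_sd,
              seconds_per_trial_mean = seconds_per_trial_mean,
              seconds_per_trial_sd = seconds_per_trial_sd,
              utc_offset_choices = as.integer(utc_offset_choices),
              utc_offset_weights = as.numeric(utc_offset_weights),
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  bad <- function(msg) stop("generator_config: ", msg, call. = FALSE)
  if (cfg$n_users < 1) bad("n_users must be positive")
  if (cfg$study_days < 1) bad("study_days must be positive")
  if (cfg$sessions_per_user_mean <= 0) bad("sessions_per_user_mean must be positive")
  if (cfg$sessions_per_user_sd < 0) bad("sessions_per_user_sd must be non-negative")
  if (cfg$session_length_base <= 0) bad("session_length_base must be positive")
  if (cfg$session_length_sd < 0) bad("session_length_sd must be non-negative")
  if (cfg$learn_fraction < 0 || cfg$learn_fraction > 1) bad("learn_fraction must be in [0, 1]")
  if (length(cfg$fatigue_curve) != 3) bad("fatigue_curve must be (beta0, beta1, beta2)")
  if (cfg$user_intercept_sd < 0 || cfg$user_slope_sd < 0 || cfg$session_intercept_sd < 0) {
    bad("random-effect sds must be non-negative")
  }
  if (cfg$seconds_per_trial_mean <= 0) bad("seconds_per_trial_mean must be positive")
  if (length(cfg$utc_offset_choices) != length(cfg$utc_offset_weights) ||
      any(cfg$utc_offset_weights < 0) || sum(cfg$utc_offset_weights) <= 0) {
    bad("utc_offset_weights must be non-negative with a positive sum, one per choice")
  }
  if (any(cfg$utc_offset_choices < -12 | cfg$utc_offset_choices > 14)) {
    bad("utc_offset_choices must lie in [-12, 14]")
  }
  p <- login_bin_probs(cfg$login_density)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12) bad("login_density yields invalid bin probabilities")
  invisible(cfg)
}

# normalised probability of a session starting in each half-hour bin
login_bin_probs <- function(density) {
  mids <- (0:47) * 0.5 + 0.25
  w <- pmax(predict(density, mids), 0)
  if (sum(w) <= 0) stop("login_density is non-positive everywhere")
  w / sum(w)
}

# mean (possibly a vector), sd -> negative binomial (or Poisson) draws; the
# dispersion is anchored at `ref_mean` so a diurnally modulated mean shares
# one size parameter
rcount_meansd <- function(n, mean, sd, ref_mean = mean[1]) {
  if (sd^2 > ref_mean) {
    size <- ref_mean^2 / (sd^2 - ref_mean)
    stats::rnbinom(n, size = size, mu = mean)
  } else {
    stats::rpois(n, mean)
  }
}

#' Reference cohort configuration
#'
#' A documented preset whose marginal moments match a large undergraduate
#' spaced-repetition cohort: ~16.8 sessions per user (SD ~15.7), sessions of
#' ~58.6 trials / ~16.8 minutes, a login density with a late-evening peak and
#' a deep night trough, a quadratic fatigue curve peaking at trial 75 with a
#' 5% accuracy drop (latent scale) by trial 150, a ~1% peak-to-trough diurnal
#' accuracy modulation peaking near 14:00, and user UTC offsets spanning
#' -9..-5. `session_length_base` is set so the expected session length under
#' the login-density start distribution equals `mean_session_trials` by
#' construction.
#'
#' @param n_users number of users (scale knob; the structure, not the size,
#'   is the preset).
#' @param seed integer seed.
#' @param utc_offset_choices,utc_offset_weights timezone mix; defaults span
#'   UTC-9..-5 with Eastern/Central/Pacific dominating.
#' @param mean_session_trials target expected session length in trials.
#' @return A `generator_config`.
#' @export
reference_cohort_config <- function(n_users = 1000, seed = 1L,
                                    utc_offset_choices = c(-5L, -6L, -7L, -8L, -9L),
                                    utc_offset_weights = c(0.35, 0.25, 0.15, 0.24, 0.01),
                                    mean_session_trials = 58.63) {
  # evening-preference login shape: broad daytime plateau, late-evening
  # spike near 21:30, trough near 04:00
  amp_phase <- function(A, peak, k) {
    c(a = A * sin(2 * pi * k * peak / 24), c = A * cos(2 * pi * k * peak / 24))
  }
  h1 <- amp_phase(0.85, 18.5, 1)
  h2 <- amp_phase(0.35, 21.5, 2)
  login <- harmonic_curve(1, a = c(h1["a"], h2["a"]), c = c(h1["c"], h2["c"]))
  len_h1 <- amp_phase(0.12, 20, 1)
  len_mod <- harmonic_curve(1, a = len_h1["a"], c = len_h1["c"])
  acc_h1 <- amp_phase(0.005, 14, 1)
  acc_mod <- harmonic_curve(0, a = acc_h1["a"], c = acc_h1["c"])
  # vertex at trial 75, 5% latent drop between trial 75 and trial 150
  beta2 <- -0.05 / (150 - 75)^2
  beta1 <- -2 * beta2 * 75
  beta0 <- 0.80
  # calibrate base length so E[trials] matches the target under the start
  # distribution implied by the login density
  p <- login_bin_probs(login)
  mean_mod <- sum(p * pmax(predict(len_mod, (0:47) * 0.5 + 0.25), 0.2))
  generator_config(
    n_users = n_users,
    study_days = 119,
    login_density = login,
    sessions_per_user_mean = 16.81,
    sessions_per_user_sd = 15.71,
    session_length_base = mean_session_trials / mean_mod,
    session_length_sd = 45.32,
    session_length_diurnal = len_mod,
    learn_fraction = 0.3,
    fatigue_curve = c(beta0, beta1, beta2),
    difficulty_gradient = 0.05,
    difficulty_tau = 3,
    accuracy_diurnal = acc_mod,
    user_intercept_sd = 0.06,
    user_slope_sd = 1e-4,
    session_intercept_sd = 0.04,
    seconds_per_trial_mean = 16.78 * 60 / 58.63,
    seconds_per_trial_sd = 6,
    utc_offset_choices = utc_offset_choices,
    utc_offset_weights = utc_offset_weights,
    seed = seed
  )
}

#' Fatigue-recovery study configuration
#'
#' A leaner cohort tailored to recovering the within-session quadratic:
#' the same fatigue truth as [reference_cohort_config()] (vertex at trial 75,
#' 5% drop by trial 150) but longer sessions (~150 trials, so the observed
#' range brackets both the vertex and the 150-trial horizon), no
#' early-session difficulty handicap, and a flat timezone.
#'
#' @param n_users number of users.
#' @param seed integer seed.
#' @return A `generator_config`.
#' @export
fatigue_recovery_config <- function(n_users = 500, seed = 1L) {
  beta2 <- -0.05 / (150 - 75)^2
  beta1 <- -2 * beta2 * 75
  acc_h1 <- c(a = 0.005 * sin(2 * pi * 14 / 24), c = 0.005 * cos(2 * pi * 14 / 24))
  generator_config(
    n_users = n_users,
    study_days = 119,
    login_density = harmonic_curve(1, a = 0.5 * sin(2 * pi * 19 / 24),
                                   c = 0.5 * cos(2 * pi * 19 / 24)),
    sessions_per_user_mean = 3,
    sessions_per_user_sd = 1.5,
    session_length_base = 150,
    session_length_sd = 40,
    session_length_diurnal = harmonic_curve(1),
    learn_fraction = 0.3,
    fatigue_curve = c(0.80, beta1, beta2),
    difficulty_gradient = 0,
    accuracy_diurnal = harmonic_curve(0, a = acc_h1["a"], c = acc_h1["c"]),
    user_intercept_sd = 0.05,
    user_slope_sd = 5e-5,
    session_intercept_sd = 0.04,
    seconds_per_trial_mean = 17,
    seconds_per_trial_sd = 6,
    utc_offset_choices = 0L,
    seed = seed
  )
}

#' Generate a synthetic session log
#'
#' Draws a full cohort from a [generator_config()]. All sampling comes from a
#' single pseudo-random stream keyed by `config$seed`, drawn in a fixed
#' order (users, session counts, session days, start bins, start offsets
#' within bin, lengths, session intercepts, event types, correctness,
#' trial durations), so output is bit-reproducible. The caller's RNG state
#' is left untouched.
#'
#' @param config a `generator_config`.
#' @return A list with elements `log` (a `trial_log`) and `truth` (the
#'   config plus every sampled latent: per-user offsets and random effects,
#'   per-session days, local start times, lengths and intercepts).
#' @export
generate_log <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  with_seed(config$seed, generate_log_impl(config))
}

generate_log_impl <- function(cfg) {
  n_users <- cfg$n_users
  users <- data.frame(
    user_id = sprintf("U%05d", seq_len(n_users)),
    utc_offset_hours = cfg$utc_offset_choices[
      sample.int(length(cfg$utc_offset_choices), n_users, replace = TRUE,
                 prob = cfg$utc_offset_weights)],
    user_intercept = stats::rnorm(n_users, 0, cfg$user_intercept_sd),
    user_slope = stats::rnorm(n_users, 0, cfg$user_slope_sd),
    stringsAsFactors = FALSE
  )
  n_sessions <- pmax(rcount_meansd(n_users, cfg$sessions_per_user_mean,
                                   cfg$sessions_per_user_sd), 1L)
  ns <- sum(n_sessions)
  u_of_s <- rep(seq_len(n_users), n_sessions)

  day <- sample.int(cfg$study_days, ns, replace = TRUE) - 1L
  probs <- login_bin_probs(cfg$login_density)
  bin <- sample.int(48L, ns, replace = TRUE, prob = probs)
  start_local <- (bin - 1L) * 0.5 + stats::runif(ns) * 0.5

  len_mod <- pmax(predict(cfg$session_length_diurnal, start_local), 0.2)
  n_trials <- pmax(rcount_meansd(ns, cfg$session_length_base * len_mod,
                                 cfg$session_length_sd,
                                 ref_mean = cfg$session_length_base), 2L)
  s_int <- stats::rnorm(ns, 0, cfg$session_intercept_sd)

  sessions <- data.frame(
    user_id = users$user_id[u_of_s],
    session_id = sprintf("S%07d", seq_len(ns)),
    day = day,
    start_local_time = start_local,
    n_trials = as.integer(n_trials),
    session_intercept = s_int,
    stringsAsFactors = FALSE
  )

  N <- sum(n_trials)
  s_of_t <- rep(seq_len(ns), n_trials)          # session index per trial
  i <- sequence(n_trials)                        # trial_index
  is_learn <- stats::runif(N) < cfg$learn_fraction
  # test-trial ordinal within session (0 for learn trials)
  cs <- cumsum(!is_learn)
  sess_end <- cumsum(n_trials)
  sess_base <- c(0, cs[sess_end[-ns]])
  k <- cs - sess_base[s_of_t]

  b <- cfg$fatigue_curve
  p <- b[1] + b[2] * i + b[3] * i^2 +
    users$user_intercept[u_of_s[s_of_t]] +
    users$user_slope[u_of_s[s_of_t]] * i +
    s_int[s_of_t] +
    predict(cfg$accuracy_diurnal, start_local)[s_of_t]
  p <- p - cfg$difficulty_gradient * exp(-(pmax(k, 1) - 1) / cfg$difficulty_tau)
  p <- clamp(p, 0.01, 0.99)
  correct <- stats::runif(N) < p
  correct[is_learn] <- NA

  dur <- pmax(stats::rnorm(N, cfg$seconds_per_trial_mean, cfg$seconds_per_trial_sd), 0.5)
  cd <- cumsum(dur)
  elapsed <- round(cd - c(0, cd[sess_end[-ns]])[s_of_t], 3)

  base <- as.POSIXct("2016-01-11 00:00:00", tz = "UTC")
  start_utc <- as.numeric(base) + day * 86400 +
    (start_local - users$utc_offset_hours[u_of_s]) * 3600
  # a trial's timestamp is the instant it was presented
  pre_elapsed <- elapsed - round(dur, 3)
  ts <- floor(start_utc[s_of_t] + pmax(pre_elapsed, 0))

  log <- data.frame(
    user_id = sessions$user_id[s_of_t],
    session_id = sessions$session_id[s_of_t],
    trial_index = as.integer(i),
    event_type = ifelse(is_learn, "learn", "test"),
    timestamp_utc = as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
    utc_offset_hours = users$utc_offset_hours[u_of_s[s_of_t]],
    correct = correct,
    elapsed_seconds = elapsed,
    stringsAsFactors = FALSE
  )
  log <- as_trial_log(order_log(log))
  truth <- structure(list(config = cfg, users = users, sessions = sessions),
                     class = "truth_record")
  list(log = log, truth = truth)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("generator config: %d users x ~%.1f sessions (sd %.1f), ",
                     "~%.1f trials/session, learn fraction %.2f, seed %d\n"),
              x$n_users, x$sessions_per_user_mean, x$sessions_per_user_sd,
              x$session_length_base, x$learn_fraction, x$seed))
  b <- x$fatigue_curve
  if (b[3] < 0) {
    cat(sprintf("  fatigue curve: beta = (%.3g, %.3g, %.3g), vertex at trial %.1f\n",
                b[1], b[2], b[3], -b[2] / (2 * b[3])))
  } else {
    cat(sprintf("  fatigue curve: beta = (%.3g, %.3g, %.3g)\n", b[1], b[2], b[3]))
  }
  invisible(x)
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("truth record: %d users, %d sessions, all latents stored\n",
              nrow(x$users), nrow(x$sessions)))
  invisible(x)
}

#' Write a truth record as plain text
#'
#' Sidecar serialisation of a generator truth record: a key-value header for
#' the scalar config parameters plus two CSV blocks for user- and
#' session-level latents.
#'
#' @param truth a `truth_record` from [generate_log()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_record <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  cfg <- truth$config
  scalars <- cfg[vapply(cfg, function(v) is.numeric(v) && length(v) <= 3, TRUE)]
  writeLines("# generator truth record", con)
  for (nm in names(scalars)) {
    writeLines(sprintf("%s: %s", nm, paste(format(scalars[[nm]], digits = 15),
                                           collapse = ", ")), con)
  }
  writeLines("# users", con)
  utils::write.csv(truth$users, con, row.names = FALSE)
  writeLines("# sessions", con)
  utils::write.csv(truth$sessions, con, row.names = FALSE)
  invisible(path)
}
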
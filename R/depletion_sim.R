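# Population-level simulator of daily self-control depletion. Each agent
# carries a reservoir in [0, 1]; awake agents face randomly arriving tasks
# that deplete it by a sampled demand, idle awake steps may recover a
# little, and sleep recovers toward full. The population curve aggregates
# awake agents into 48 half-hour bins, showing how even lenient task
# environments produce a mean decline starting shortly after wake.

#' Depletion simulator configuration
#'
#' @param n_agents number of simulated agents.
#' @param wake_mean,wake_sd wake time distribution (hours; normal, clipped
#'   to `[3, 12]`).
#' @param sleep_onset hour at which agents fall asleep (single value, must
#'   exceed every wake time; at most 24 in this single-day version).
#' @param task_rate task arrivals per awake hour.
#' @param demand_mean,demand_sd task demand (reservoir units; normal
#'   truncated at 0).
#' @param recovery_rate reservoir recovered per rested hour (sleep, or a
#'   successful idle rest).
#' @param rest_prob probability an idle awake step is restful.
#' @param step_minutes time step; must divide 60.
#' @param seed integer seed; the simulation is deterministic given it.
#' @return A `depletion_config`.
#' @export
depletion_config <- function(n_agents = 10000, wake_mean = 7.5, wake_sd = 1,
                             sleep_onset = 23, task_rate = 1,
                             demand_mean = 0.05, demand_sd = 0.02,
                             recovery_rate = 0.05, rest_prob = 0.3,
                             step_minutes = 5, seed = 1L) {
  bad <- function(msg) stop("depletion_config: ", msg, call. = FALSE)
  if (n_agents < 1) bad("n_agents must be positive")
  if (60 %% step_minutes != 0) bad("step_minutes must divide 60")
  if (task_rate < 0) bad("task_rate must be non-negative")
  if (recovery_rate < 0) bad("recovery_rate must be non-negative")
  if (rest_prob < 0 || rest_prob > 1) bad("rest_prob must be in [0, 1]")
  if (demand_mean < 0 || demand_sd < 0) bad("demand moments must be non-negative")
  if (sleep_onset <= wake_mean) bad("sleep_onset must be after mean wake time")
  if (sleep_onset > 24) bad("sleep_onset must be within the simulated day (<= 24)")
  structure(list(n_agents = as.integer(n_agents), wake_mean = wake_mean,
                 wake_sd = wake_sd, sleep_onset = sleep_onset,
                 task_rate = task_rate, demand_mean = demand_mean,
                 demand_sd = demand_sd, recovery_rate = recovery_rate,
                 rest_prob = rest_prob, step_minutes = step_minutes,
                 seed = as.integer(seed)),
            class = "depletion_config")
}

#' Lenient-environment preset
#'
#' A deliberately generous environment -- few tasks, small demands, frequent
#' opportunities to rest -- under which a population decline in mean
#' self-control nevertheless emerges within an hour of the mean wake time.
#'
#' @param n_agents number of agents.
#' @param seed integer seed.
#' @return A `depletion_config`.
#' @export
lenient_depletion_config <- function(n_agents = 10000, seed = 1L) {
  depletion_config(n_agents = n_agents, wake_mean = 7.5, wake_sd = 1,
                   sleep_onset = 23, task_rate = 0.5, demand_mean = 0.05,
                   demand_sd = 0.02, recovery_rate = 0.02, rest_prob = 0.3,
                   seed = seed)
}

#' Simulate one day of population self-control
#'
#' Discrete-time simulation from midnight to midnight. Per agent per step:
#' asleep agents recover `recovery_rate * dt` toward 1; awake agents receive
#' a task with probability `task_rate * dt`, losing the sampled demand
#' (reservoir floored at 0), and otherwise recover `recovery_rate * dt` with
#' probability `rest_prob`. Reservoirs start full at midnight and stay in
#' `[0, 1]` throughout.
#'
#' @param config a [depletion_config()].
#' @return A `population_curve`: 48 half-hour bins with `mean_reservoir` and
#'   `sd_reservoir` among awake agents (NA where no one is awake) and
#'   `fraction_awake`, averaged over the steps in the bin.
#' @export
simulate_day <- function(config) {
  stopifnot(inherits(config, "depletion_config"))
  with_seed(config$seed, simulate_day_impl(config))
}

simulate_day_impl <- function(cfg) {
  n <- cfg$n_agents
  dt <- cfg$step_minutes / 60
  steps <- round(24 / dt)
  wake <- clamp(stats::rnorm(n, cfg$wake_mean, cfg$wake_sd), 3, 12)
  r <- rep(1, n)
  p_task <- min(cfg$task_rate * dt, 1)
  sum_mean <- sum_sq <- sum_awake <- numeric(48)
  n_steps_bin <- n_awake_steps <- integer(48)
  for (s in seq_len(steps)) {
    t0 <- (s - 1) * dt
    awake <- t0 >= wake & t0 < cfg$sleep_onset
    if (any(awake)) {
      u <- stats::runif(n)
      tasked <- awake & u < p_task
      if (any(tasked)) {
        demand <- pmax(stats::rnorm(sum(tasked), cfg$demand_mean, cfg$demand_sd), 0)
        r[tasked] <- pmax(r[tasked] - demand, 0)
      }
      resting <- awake & !tasked & stats::runif(n) < cfg$rest_prob
      r[resting] <- pmin(r[resting] + cfg$recovery_rate * dt, 1)
    }
    asleep <- !awake
    if (any(asleep)) r[asleep] <- pmin(r[asleep] + cfg$recovery_rate * dt, 1)
    bin <- floor(t0 / 0.5) + 1L
    if (any(awake)) {
      ra <- r[awake]
      sum_mean[bin] <- sum_mean[bin] + mean(ra)
      sum_sq[bin] <- sum_sq[bin] + if (length(ra) > 1) stats::sd(ra) else 0
      n_awake_steps[bin] <- n_awake_steps[bin] + 1L
    }
    sum_awake[bin] <- sum_awake[bin] + mean(awake)
    n_steps_bin[bin] <- n_steps_bin[bin] + 1L
  }
  out <- data.frame(
    bin_start_hour = (0:47) * 0.5,
    t_mid = (0:47) * 0.5 + 0.25,
    mean_reservoir = ifelse(n_awake_steps > 0, sum_mean / pmax(n_awake_steps, 1L),
                            NA_real_),
    sd_reservoir = ifelse(n_awake_steps > 0, sum_sq / pmax(n_awake_steps, 1L),
                          NA_real_),
    fraction_awake = sum_awake / n_steps_bin
  )
  attr(out, "config") <- cfg
  class(out) <- c("population_curve", "data.frame")
  out
}

#' @export
print.population_curve <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("population depletion curve (%d agents, task rate %.2g/h)\n",
              cfg$n_agents, cfg$task_rate))
  awake <- which(x$fraction_awake > 0.5)
  if (length(awake)) {
    cat(sprintf("  awake-population mean reservoir: %.3f at first awake bin, min %.3f at %.1f h\n",
                x$mean_reservoir[awake[1]],
                min(x$mean_reservoir[awake]),
                x$t_mid[awake[which.min(x$mean_reservoir[awake])]]))
  }
  invisible(x)
}

#' Sweep depletion configurations
#'
#' Simulates each configuration and summarises its decline: the onset (first
#' bin, counted from the first bin where most of the population is awake,
#' at which the awake-population mean drops below 99% of its wake level) and
#' the total decline from wake level to the daily minimum.
#'
#' @param configs a list of [depletion_config()]s.
#' @return A data frame with one row per config (`task_rate`,
#'   `recovery_rate`, `rest_prob`, `wake_level`, `decline_onset_hour` --
#'   `NA` meaning "never" -- `min_reservoir`, `total_decline`) and the
#'   curves in `attr(, "curves")`.
#' @export
sweep_depletion <- function(configs) {
  stopifnot(is.list(configs), length(configs) >= 1)
  curves <- lapply(configs, simulate_day)
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]; cur <- curves[[i]]
    awake <- which(cur$fraction_awake > 0.5)
    wl <- cur$mean_reservoir[awake[1]]
    below <- awake[which(cur$mean_reservoir[awake] < 0.99 * wl)]
    data.frame(task_rate = cfg$task_rate, recovery_rate = cfg$recovery_rate,
               rest_prob = cfg$rest_prob, wake_level = wl,
               decline_onset_hour = if (length(below)) cur$t_mid[below[1]]
                                    else NA_real_,
               min_reservoir = min(cur$mean_reservoir[awake]),
               total_decline = wl - min(cur$mean_reservoir[awake]),
               end_of_day_mean = cur$mean_reservoir[awake[length(awake)]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  out
}
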
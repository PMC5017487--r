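#' Configuration of the closed-loop activity simulation
#'
#' Exercise arrives as a Poisson process: the number of sessions on each day
#' is Poisson with rate `sessions_per_week / 7`, each session lasts an
#' exponential time with mean `mean_duration` minutes at a fixed intensity of
#' `mean_met` METs, so daily MT is compound-Poisson with mean
#' `sessions_per_week / 7 * mean_duration * mean_met` (about 64.3 MET·min at
#' the defaults 5 MET / 30 min / 3 per week — an insufficiently active
#' simulated user). With prompting on, the decision engine is evaluated each
#' morning on the state through the previous evening and, when a prompt is
#' delivered and the compliance draw succeeds, the prompting value replaces
#' the day's generated activity.
#'
#' @param mean_met Session intensity in METs (default 5).
#' @param mean_duration Mean session duration in minutes (default 30).
#' @param sessions_per_week Mean number of sessions per week (default 3).
#' @param days Number of simulated days (default 60).
#' @param prompting Run the prompting loop (default FALSE).
#' @param compliance Probability that a delivered prompt is followed
#'   (default 1).
#' @param seed Integer seed.
#' @param goal Fitness goal in AAEI points (default 600).
#' @param aaei [aaei_params()].
#' @param prompt [prompt_config()]; its goal defaults to `goal`.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(mean_met = 5, mean_duration = 30,
                              sessions_per_week = 3, days = 60,
                              prompting = FALSE, compliance = 1,
                              seed = 1, goal = 600,
                              aaei = aaei_params(),
                              prompt = prompt_config(goal = goal)) {
  if (mean_met < 0 || mean_duration < 0 || sessions_per_week < 0)
    stop("rates and durations must be non-negative")
  if (days < 0) stop("'days' must be non-negative")
  if (compliance < 0 || compliance > 1) stop("'compliance' must be in [0, 1]")
  structure(list(mean_met = mean_met, mean_duration = mean_duration,
                 sessions_per_week = sessions_per_week, days = days,
                 prompting = isTRUE(prompting), compliance = compliance,
                 seed = seed, goal = goal, aaei = aaei, prompt = prompt),
            class = "simulation_config")
}

# schedule + compliance uniforms under one seed, so a standalone schedule and
# the one inside run_simulation() are identical draws
sim_draws <- function(config) {
  withr::with_seed(config$seed, {
    counts <- stats::rpois(config$days, config$sessions_per_week / 7)
    mt <- vapply(counts, function(kk) {
      if (kk == 0) return(0)
      config$mean_met * sum(stats::rexp(kk, rate = 1 / config$mean_duration))
    }, numeric(1))
    list(mt = mt, u = stats::runif(config$days))
  })
}

#' Generate a Poisson daily activity schedule
#'
#' @param config [simulation_config()].
#' @return Numeric vector of daily MT values (MET·minutes), deterministic
#'   under the config seed.
#' @export
generate_schedule <- function(config) {
  sim_draws(config)$mt
}

#' Run the closed-loop simulation
#'
#' Day loop: (morning, prompting on) evaluate [decide()] on the state through
#' yesterday; if a prompt is delivered and the compliance draw succeeds, the
#' prompting value replaces today's generated activity; then advance the AAEI
#' with the effective MT. Fully reproducible under config + seed.
#'
#' @param config [simulation_config()].
#' @return Object of class `aaei_simulation`: `daily` data frame (day,
#'   MT_generated, MT_effective, I, E, alpha, avg7, avg30, prompt_delivered,
#'   PV, followed), the final `state` and the `config`.
#' @export
run_simulation <- function(config) {
  draws <- sim_draws(config)
  state <- aaei_state(config$aaei)
  n <- config$days
  rec <- data.frame(day = seq_len(n),
                    MT_generated = draws$mt,
                    MT_effective = draws$mt,
                    I = rep(NA_real_, n), E = rep(NA_real_, n),
                    alpha = rep(NA_real_, n),
                    avg7 = rep(NA_real_, n), avg30 = rep(NA_real_, n),
                    prompt_delivered = rep(FALSE, n),
                    PV = rep(NA_real_, n), followed = rep(FALSE, n))
  for (d in seq_len(n)) {
    if (config$prompting) {
      dec <- decide(state, config$prompt)
      if (dec$deliver) {
        rec$prompt_delivered[d] <- TRUE
        rec$PV[d] <- dec$PV
        if (draws$u[d] <= config$compliance) {
          rec$followed[d] <- TRUE
          rec$MT_effective[d] <- dec$PV
        }
      }
    }
    state <- update_index(state, rec$MT_effective[d])
    rec$I[d] <- state$I[d]; rec$E[d] <- state$E[d]
    rec$alpha[d] <- state$alpha[d]
    rec$avg7[d]  <- mean(state$I[max(1, d - 6):d])
    rec$avg30[d] <- mean(state$I[max(1, d - 29):d])
  }
  structure(list(daily = rec, state = state, config = config),
            class = "aaei_simulation")
}

#' Summarise a simulation run
#'
#' @param result An `aaei_simulation`.
#' @return One-row data frame: prompt count, followed count, final 7- and
#'   30-day average AAEI, and days on which the index was at or above goal.
#' @export
summarize_simulation <- function(result) {
  d <- result$daily
  n <- nrow(d)
  data.frame(
    prompts = sum(d$prompt_delivered),
    followed = sum(d$followed),
    final_avg7 = if (n) d$avg7[n] else 0,
    final_avg30 = if (n) d$avg30[n] else 0,
    days_above_goal = sum(d$I >= result$config$goal)
  )
}

#' @export
print.aaei_simulation <- function(x, ...) {
  s <- summarize_simulation(x)
  cat(sprintf(paste0("Closed-loop AAEI simulation: %d days, prompting %s\n",
                     "  prompts %d (followed %d); final avg7 %.1f, ",
                     "avg30 %.1f; %d day(s) at/above goal %g\n"),
              nrow(x$daily), if (x$config$prompting) "on" else "off",
              s$prompts, s$followed, s$final_avg7, s$final_avg30,
              s$days_above_goal, x$config$goal))
  invisible(x)
}

#' Plot a simulation trajectory
#'
#' Daily effective activity as bars with the index, its 7- and 30-day
#' trailing averages and the goal line.
#'
#' @param x An `aaei_simulation`.
#' @param ... Passed to [graphics::plot()].
#' @return The input, invisibly.
#' @export
plot.aaei_simulation <- function(x, ...) {
  d <- x$daily
  old <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(d$MT_effective, names.arg = d$day,
                    ylab = "MT (MET.min)", border = NA, col = "grey60",
                    main = "Daily physical activity")
  graphics::plot(d$day, d$I, type = "l", lwd = 2, xlab = "day",
                 ylab = "AAEI", main = "Index and trailing averages", ...)
  graphics::lines(d$day, d$avg7, lty = 2, col = "blue")
  graphics::lines(d$day, d$avg30, lty = 3, col = "darkgreen")
  graphics::abline(h = x$config$goal, col = "red")
  graphics::legend("topleft", bty = "n", lty = c(1, 2, 3, 1),
                   col = c("black", "blue", "darkgreen", "red"),
                   legend = c("AAEI", "7-day avg", "30-day avg", "goal"))
  invisible(x)
}
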
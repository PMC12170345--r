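#' Simulate a microtubule tip trajectory under a condition preset
#'
#' The state sequence follows a continuous-time Markov chain over the
#' preset's states with exponential dwell times (hazards given by
#' `preset$transition_rates`, per minute). The chain is sampled on a uniform
#' grid with spacing `dt`; within a state, the displacement over one step is
#' `(velocity_mean + N(0, velocity_sd)) * dt / 60` µm. A grid interval
#' containing a state switch uses the time-weighted mean velocity.
#'
#' Position is floored at the stabilized seed (0 µm): a shrinkage excursion
#' that reaches 0 either enters a terminal pause (a block) with probability
#' `preset$block_at_seed_prob`, or switches to `preset$regrow_state`. If
#' `preset$terminal_block` is set, any entry into pause is permanent.
#'
#' @param preset An [condition_preset()] object.
#' @param duration Total simulated time, s.
#' @param dt Sampling interval, s (default 3).
#' @param seed Integer seed; identical seed and parameters give identical
#'   output.
#' @param start_position Initial tip position, µm (default 0).
#' @return An object of class `"mt_trajectory"`: list with `times` (s),
#'   `positions` (µm, >= 0), `true_states` (per-sample labels),
#'   `end_polarity`, `dt`, `rng_seed`, and an `events` data frame of the
#'   underlying continuous-time state path (`t_start`, `t_end`, `state`).
#' @export
simulate_trajectory <- function(preset, duration = 600, dt = 3, seed = NULL,
                                start_position = 0) {
  if (!inherits(preset, "mt_preset")) stop_mtdyn("preset must be an mt_preset")
  if (duration <= 0) stop_mtdyn("duration must be > 0")
  if (dt <= 0) stop_mtdyn("dt must be > 0")
  check_reachability(preset)

  with_seed(seed, {
    n_steps <- floor(duration / dt)
    times <- seq(0, by = dt, length.out = n_steps + 1)
    positions <- numeric(n_steps + 1)
    states_out <- character(n_steps + 1)
    positions[1] <- start_position

    Q <- preset$transition_rates / 60  # hazards per second
    state <- preset$initial_state
    blocked <- FALSE
    ev_start <- 0
    ev_states <- character(0)
    ev_t0 <- numeric(0)
    ev_t1 <- numeric(0)

    draw_dwell <- function(state) {
      if (blocked && state == "pause") return(Inf)
      if (preset$terminal_block && state == "pause") return(Inf)
      h <- sum(Q[state, ])
      if (h <= 0) Inf else stats::rexp(1, h)
    }
    next_state <- function(state) {
      w <- Q[state, ]
      sample(preset$states, 1, prob = w)
    }

    t_event <- draw_dwell(state)
    states_out[1] <- state

    for (i in seq_len(n_steps)) {
      t0 <- times[i]; t1 <- times[i + 1]
      # accumulate time-weighted velocity across any switches in [t0, t1]
      v_acc <- 0
      seg_t <- t0
      while (t_event <= t1) {
        v_acc <- v_acc + preset$velocity_mean[[state]] * (t_event - seg_t)
        seg_t <- t_event
        ev_states <- c(ev_states, state)
        ev_t0 <- c(ev_t0, ev_start); ev_t1 <- c(ev_t1, t_event)
        ev_start <- t_event
        state <- next_state(state)
        t_event <- t_event + draw_dwell(state)
      }
      v_acc <- v_acc + preset$velocity_mean[[state]] * (t1 - seg_t)
      v_mean <- v_acc / dt                                   # µm/min
      noise <- stats::rnorm(1, 0, preset$velocity_sd[[state]])
      disp <- (v_mean + noise) * dt / 60
      pos <- positions[i] + disp
      if (pos <= 0) {
        pos <- 0
        if (state == "shrinkage") {
          # close current event at the floor crossing
          ev_states <- c(ev_states, state)
          ev_t0 <- c(ev_t0, ev_start); ev_t1 <- c(ev_t1, t1)
          ev_start <- t1
          if ("pause" %in% preset$states &&
              stats::runif(1) < preset$block_at_seed_prob) {
            state <- "pause"
            blocked <- TRUE
          } else {
            state <- preset$regrow_state
          }
          t_event <- t1 + draw_dwell(state)
        }
      }
      positions[i + 1] <- pos
      states_out[i + 1] <- state
    }
    ev_states <- c(ev_states, state)
    ev_t0 <- c(ev_t0, ev_start); ev_t1 <- c(ev_t1, times[n_steps + 1])

    structure(
      list(times = times, positions = positions, true_states = states_out,
           end_polarity = "plus", dt = dt, rng_seed = seed,
           preset_name = preset$name,
           events = data.frame(t_start = ev_t0, t_end = ev_t1,
                               state = ev_states,
                               stringsAsFactors = FALSE)),
      class = "mt_trajectory")
  })
}

check_reachability <- function(preset) {
  k <- length(preset$states)
  if (k == 1L) return(invisible(TRUE))
  adj <- preset$transition_rates > 0
  reach <- stats::setNames(rep(FALSE, k), preset$states)
  reach[preset$initial_state] <- TRUE
  repeat {
    new <- reach
    for (s in preset$states[reach]) new <- new | adj[s, ]
    if (all(new == reach)) break
    reach <- new
  }
  # states reachable through the seed-regrowth / blocking mechanics
  if (preset$block_at_seed_prob > 0 && "pause" %in% preset$states)
    reach["pause"] <- TRUE
  if (any(!reach))
    warning("states unreachable from initial_state: ",
            paste(preset$states[!reach], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.mt_trajectory <- function(x, ...) {
  cat("<mt_trajectory> ", length(x$times), " samples, dt = ", x$dt,
      " s, duration = ", max(x$times), " s\n", sep = "")
  cat("  final position:", round(x$positions[length(x$positions)], 3),
      "um;  states visited:",
      paste(unique(x$true_states), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.mt_trajectory <- function(x, ...) {
  graphics::plot(x$times, x$positions, type = "l",
                 xlab = "time (s)", ylab = "tip position (um)", ...)
  invisible(x)
}

#' Time-weighted state occupancy of a simulated trajectory
#'
#' Fraction of simulated time spent in each state, computed from the exact
#' continuous-time event path recorded by [simulate_trajectory()].
#'
#' @param traj An `mt_trajectory`.
#' @return Named numeric vector of fractions summing to 1.
#' @export
state_occupancy <- function(traj) {
  ev <- traj$events
  tot <- tapply(ev$t_end - ev$t_start, ev$state, sum)
  out <- stats::setNames(rep(0, length(MT_STATES)), MT_STATES)
  out[names(tot)] <- tot
  out <- out[out > 0 | names(out) %in% unique(ev$state)]
  out / sum(out)
}

#' Stationary distribution of a preset's state chain
#'
#' Solves pi Q = 0, sum(pi) = 1 for the continuous-time generator built from
#' the preset's hazard matrix. Used as the analytic reference for long-run
#' state occupancy of simulated trajectories (seed-floor mechanics aside).
#'
#' @param preset An `mt_preset`.
#' @return Named numeric vector over `preset$states`.
#' @export
stationary_distribution <- function(preset) {
  R <- preset$transition_rates
  Q <- R
  diag(Q) <- -rowSums(R)
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi_hat <- stats::setNames(as.vector(qr.solve(A, b)), preset$states)
  pi_hat[pi_hat < 0] <- 0
  pi_hat / sum(pi_hat)
}

#' Write / read a trajectory as CSV
#'
#' Columns: `time_s`, `position_um`, `true_state` (empty when unknown).
#' @param traj An `mt_trajectory`.
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time_s = traj$times, position_um = traj$positions,
                   true_state = traj$true_states %||% "",
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param path File path.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "position_um") %in% names(df)))
    stop_mtdyn("trajectory CSV needs columns time_s, position_um")
  dt <- stats::median(diff(df$time_s))
  structure(
    list(times = df$time_s, positions = df$position_um,
         true_states = if ("true_state" %in% names(df)) df$true_state else NULL,
         end_polarity = "plus", dt = dt, rng_seed = NULL, events = NULL),
    class = "mt_trajectory")
}
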
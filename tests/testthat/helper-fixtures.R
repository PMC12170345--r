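# Shared fixtures and independent oracles, built in code at test time.

# Single-state preset with optional per-step velocity noise.
single_state_preset <- function(state = "slow_growth", v = 1, sd = 0) {
  vm <- stats::setNames(v, state)
  vs <- stats::setNames(sd, state)
  condition_preset("single", states = state, velocity_mean = vm,
                   velocity_sd = vs,
                   transition_rates = matrix(0, 1, 1),
                   initial_state = state)
}

two_state_preset <- function(h12 = 6, h21 = 2,
                             v = c(slow_growth = 0.5, pause = 0),
                             sd = c(slow_growth = 0.02, pause = 0.02)) {
  st <- c("slow_growth", "pause")
  condition_preset("two", states = st, velocity_mean = v, velocity_sd = sd,
                   transition_rates = matrix(c(0, h21, h12, 0), 2, 2,
                                             dimnames = list(st, st)),
                   initial_state = "slow_growth")
}

# Wrap a bare position series as an mt_trajectory.
as_traj <- function(positions, dt = 3) {
  structure(list(times = (seq_along(positions) - 1) * dt,
                 positions = positions, true_states = NULL,
                 end_polarity = "plus", dt = dt, rng_seed = NULL,
                 events = NULL),
            class = "mt_trajectory")
}

# Hand-built phase table row(s).
make_phases <- function(t_start, t_end, rate, state,
                        is_block = FALSE) {
  df <- data.frame(t_start = t_start, t_end = t_end,
                   duration = t_end - t_start, rate = rate, state = state,
                   is_block = is_block, end_polarity = "plus",
                   stringsAsFactors = FALSE)
  class(df) <- c("mt_phases", "data.frame")
  df
}

# Independent brute-force segmentation oracle: exhaustive search over all
# changepoint placements with up to max_cp changepoints and segments of at
# least min_len points; per-segment cost is the residual sum of squares of
# an lm() line fit. Returns the best cost and changepoint set.
brute_force_segmentation <- function(t, y, penalty, min_len = 3,
                                     max_cp = 2) {
  n <- length(t)
  seg_rss <- function(a, b) {
    if (b - a + 1 < 2) return(0)
    sum(stats::resid(stats::lm(y[a:b] ~ t[a:b]))^2)
  }
  best <- list(cost = seg_rss(1, n), cps = integer(0))
  if (max_cp >= 1) {
    for (c1 in seq(min_len, n - min_len)) {
      cost1 <- seg_rss(1, c1) + seg_rss(c1 + 1, n) + penalty
      if (cost1 < best$cost) best <- list(cost = cost1, cps = c1)
      if (max_cp >= 2 && n - c1 >= 2 * min_len) {
        for (c2 in seq(c1 + min_len, n - min_len)) {
          cost2 <- seg_rss(1, c1) + seg_rss(c1 + 1, c2) +
            seg_rss(c2 + 1, n) + 2 * penalty
          if (cost2 < best$cost) best <- list(cost = cost2, cps = c(c1, c2))
        }
      }
    }
  }
  best
}

# Noise-free piecewise-linear positions from slopes (per minute) and
# per-piece sample counts.
piecewise_positions <- function(slopes_um_min, n_samples, dt = 3) {
  y <- 0
  out <- numeric(0)
  for (i in seq_along(slopes_um_min)) {
    step <- slopes_um_min[i] * dt / 60
    seg <- y + cumsum(rep(step, n_samples[i]))
    out <- c(out, seg)
    y <- seg[length(seg)]
  }
  c(0, out)
}
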
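test_that("single-state kinematics are exact without noise", {
  p <- single_state_preset(v = 1, sd = 0)
  tr <- simulate_trajectory(p, duration = 60, dt = 3, seed = 1)
  expect_equal(tr$positions[length(tr$positions)], 1.0)
  expect_equal(length(tr$times), length(tr$positions))
  expect_true(all(diff(tr$times) == 3))
  expect_true(all(tr$positions >= 0))
})

test_that("identical seed and parameters give bit-identical trajectories", {
  p <- builtin_presets()$control_shrink
  a <- simulate_trajectory(p, 600, 3, seed = 11)
  b <- simulate_trajectory(p, 600, 3, seed = 11)
  expect_identical(a, b)
  c <- simulate_trajectory(p, 600, 3, seed = 12)
  expect_false(identical(a$positions, c$positions))
})

test_that("state dwell times are exponential with the configured hazard", {
  p <- two_state_preset(h12 = 6, h21 = 2)
  tr <- simulate_trajectory(p, 4.6e5, dt = 5, seed = 99)
  ev <- tr$events
  dw <- (ev$t_end - ev$t_start)[ev$state == "slow_growth"]
  dw <- dw[-length(dw)] / 60       # completed dwells, minutes
  expect_gt(length(dw), 1e4)
  ks <- suppressWarnings(stats::ks.test(dw, "pexp", 6))
  expect_gt(ks$p.value, 0.01)
})

test_that("long-run state occupancy matches the analytic stationary law", {
  p <- two_state_preset(h12 = 6, h21 = 2)
  pi_ref <- stationary_distribution(p)   # brute-force linear solve
  expect_equal(sum(pi_ref), 1)
  expect_equal(unname(pi_ref), c(0.25, 0.75))
  tr <- simulate_trajectory(p, 6e5, dt = 5, seed = 4)   # 10^4 minutes
  occ <- state_occupancy(tr)
  tv <- 0.5 * sum(abs(occ[names(pi_ref)] - pi_ref))
  expect_lt(tv, 0.05)
})

test_that("per-state empirical velocity is within 3 standard errors", {
  p <- two_state_preset(h12 = 1, h21 = 1,
                        v = c(slow_growth = 0.4, pause = 0),
                        sd = c(slow_growth = 0.05, pause = 0.05))
  tr <- simulate_trajectory(p, 30000, dt = 3, seed = 21)
  # steps fully inside a state (same label on both ends, no event between)
  st <- tr$true_states
  inside <- st[-length(st)] == st[-1]
  v_step <- diff(tr$positions) / 3 * 60
  for (s in c("slow_growth", "pause")) {
    sel <- inside & st[-length(st)] == s
    expect_gt(sum(sel), 1000)
    se <- stats::sd(v_step[sel]) / sqrt(sum(sel))
    expect_lt(abs(mean(v_step[sel]) - p$velocity_mean[[s]]), 3 * se)
  }
})

test_that("shrinkage is floored at the seed and can block there", {
  st <- c("fast_growth", "pause", "shrinkage")
  m <- matrix(0, 3, 3, dimnames = list(st, st))
  m["fast_growth", "shrinkage"] <- 6
  p <- condition_preset("blocker", states = st,
                        velocity_mean = c(fast_growth = 2, pause = 0,
                                          shrinkage = -20),
                        velocity_sd = c(fast_growth = 0, pause = 0,
                                        shrinkage = 0),
                        transition_rates = m,
                        initial_state = "fast_growth",
                        block_at_seed_prob = 1, terminal_block = TRUE)
  tr <- simulate_trajectory(p, 600, 3, seed = 8)
  expect_true(all(tr$positions >= 0))
  # once blocked, pause persists to the end of the recording
  i_block <- which(tr$true_states == "pause")[1]
  expect_false(is.na(i_block))
  expect_true(all(tr$true_states[i_block:length(tr$true_states)] == "pause"))
  expect_true(all(tr$positions[i_block:length(tr$positions)] ==
                    tr$positions[i_block]))
})

test_that("unreachable states trigger a warning, not an error", {
  st <- c("slow_growth", "pause")
  m <- matrix(0, 2, 2, dimnames = list(st, st))  # no transitions at all
  p <- condition_preset("stuck", states = st,
                        velocity_mean = c(slow_growth = 1, pause = 0),
                        velocity_sd = c(slow_growth = 0, pause = 0),
                        transition_rates = m, initial_state = "slow_growth")
  expect_warning(simulate_trajectory(p, 60, 3, seed = 1), "unreachable")
})

test_that("invalid durations are rejected", {
  p <- single_state_preset()
  expect_error(simulate_trajectory(p, -5, 3), "duration")
  expect_error(simulate_trajectory(p, 60, 0), "dt")
})

test_that("trajectory CSV round-trips", {
  p <- builtin_presets()$full_ctm
  tr <- simulate_trajectory(p, 300, 3, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- read_trajectory_csv(f)
  expect_equal(back$positions, tr$positions)
  expect_equal(back$times, tr$times)
  expect_equal(back$true_states, tr$true_states)
})
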
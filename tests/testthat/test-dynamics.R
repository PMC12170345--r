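test_that("transition frequencies follow the time-normalized definition", {
  # 2 catastrophes over 10 min of total growth time -> 0.2 per minute
  ph1 <- make_phases(c(0, 300, 330, 530, 560),
                     c(300, 330, 530, 560, 660),
                     c(1, -20, 1, -20, 1),
                     c("fast_growth", "shrinkage", "fast_growth",
                       "shrinkage", "fast_growth"))
  s <- summarize_dynamics(list(ph1), video_length = 660)
  expect_equal(unname(s$n_events[["catastrophe"]]), 2)
  expect_equal(unname(s$transition_frequencies[["catastrophe"]]), 0.2)
  expect_equal(unname(s$transition_frequencies[["rescue"]]), 2 / 1)
})

test_that("an uninterrupted growth trajectory has no defined frequencies", {
  ph <- make_phases(0, 600, 1.1, "fast_growth")
  s <- summarize_dynamics(list(ph))
  expect_equal(unname(s$percent_time[["fast_growth"]]), 100)
  expect_true(is.na(s$transition_frequencies[["rescue"]]))
  expect_true(is.na(s$transition_frequencies[["pause_exit"]]))
  # absent (NA), never coerced to zero
  expect_false(identical(unname(s$transition_frequencies[["rescue"]]), 0))
})

test_that("state times are conserved and percent_time sums to 100", {
  p <- builtin_presets()$cep104_togaram1
  phs <- lapply(1:10, function(i)
    segment_phases(simulate_trajectory(p, 600, 3, seed = i)))
  s <- summarize_dynamics(phs)
  expect_equal(sum(s$percent_time), 100, tolerance = 1e-6)
  total_dur <- sum(vapply(phs, function(ph)
    max(ph$t_end) - min(ph$t_start), numeric(1)))
  expect_equal(s$total_time, total_dur)
  expect_true(all(s$transition_frequencies >= 0, na.rm = TRUE))
  for (cls in names(s$rates))
    if (s$rates[[cls]]$n > 1)
      expect_equal(s$rates[[cls]]$sem,
                   stats::sd(s$rates[[cls]]$rates) /
                     sqrt(s$rates[[cls]]$n))
})

test_that("per-experiment grouping reports mean-of-means", {
  p <- builtin_presets()$full_ctm
  phs <- lapply(1:6, function(i)
    segment_phases(simulate_trajectory(p, 600, 3, seed = 40 + i)))
  s <- summarize_dynamics(phs, experiment = rep(c("e1", "e2", "e3"), 2))
  expect_equal(nrow(s$per_experiment), 3)
  expect_true("slow_growth" %in% names(s$per_experiment))
})

test_that("weighted rate histogram weights by growth duration", {
  # durations 300 s and 100 s -> weights 0.75 and 0.25
  ph <- make_phases(c(0, 300), c(300, 400), c(0.1, 1.0),
                    c("slow_growth", "fast_growth"))
  wh <- weighted_rate_histogram(ph, bin_edges = c(0, 0.5, 1.5))
  expect_equal(wh$histogram$weight, c(0.75, 0.25))
  expect_equal(sum(wh$histogram$weight), 1)
  expect_equal(wh$cumulative$cum_weight, c(0.75, 1))

  one <- make_phases(0, 200, 0.3, "slow_growth")
  wh1 <- weighted_rate_histogram(one)
  expect_equal(sum(wh1$histogram$weight), 1)
  expect_equal(max(wh1$histogram$weight), 1)

  pause_only <- make_phases(0, 600, 0, "pause")
  expect_error(weighted_rate_histogram(pause_only), "no growth events")
})

test_that("weights always sum to one for simulated phase sets", {
  p <- builtin_presets()$togaram1
  for (i in 1:5) {
    ph <- segment_phases(simulate_trajectory(p, 600, 3, seed = 70 + i))
    if (any(ph$state %in% c("fast_growth", "slow_growth"))) {
      wh <- weighted_rate_histogram(ph)
      expect_equal(sum(wh$histogram$weight), 1, tolerance = 1e-9)
      expect_equal(utils::tail(wh$cumulative$cum_weight, 1), 1,
                   tolerance = 1e-9)
    }
  }
})
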
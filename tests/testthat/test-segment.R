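test_that("the four-way classification partitions every finite rate", {
  # published boundaries: faster than 0.02 and up to 0.5 is slow growth,
  # faster than 0.5 fast growth, below -0.02 shrinkage, else pause
  expect_equal(classify_phase(2.27), "fast_growth")
  expect_equal(classify_phase(0.19), "slow_growth")
  expect_equal(classify_phase(0.0), "pause")
  expect_equal(classify_phase(-36.91), "shrinkage")
  # boundary conventions
  expect_equal(classify_phase(0.5), "slow_growth")
  expect_equal(classify_phase(0.5 + 1e-12), "fast_growth")
  expect_equal(classify_phase(0.02), "pause")
  expect_equal(classify_phase(0.02 + 1e-12), "slow_growth")
  expect_equal(classify_phase(-0.02), "pause")
  expect_equal(classify_phase(-0.02 - 1e-12), "shrinkage")
  # exactly one label for a fine grid of rates
  grid <- seq(-40, 5, by = 0.013)
  labs <- classify_phase(grid)
  expect_true(all(labs %in% MT_STATES))
  expect_error(classify_phase(NaN), "finite")
})

test_that("a noise-free two-slope polyline yields exactly two phases", {
  y <- piecewise_positions(c(1, 0), c(40, 40))
  ph <- segment_phases(as_traj(y))
  expect_equal(nrow(ph), 2)
  expect_equal(ph$rate, c(1, 0), tolerance = 1e-9)
  expect_equal(ph$state, c("fast_growth", "pause"))
})

test_that("penalized DP matches the exhaustive changepoint oracle", {
  set.seed(42)
  n_match <- 0
  for (rep in 1:60) {
    n <- sample(12:30, 1)
    n_cp <- sample(0:2, 1)
    dt <- 3
    slopes <- stats::runif(n_cp + 1, -1, 1)
    sizes <- rep(n %/% (n_cp + 1), n_cp + 1)
    sizes[1] <- sizes[1] + n - sum(sizes) - 1
    y <- piecewise_positions(slopes, sizes, dt) +
      stats::rnorm(n, 0, 0.005)
    t <- (seq_len(n) - 1) * dt
    penalty <- stats::runif(1, 0.001, 0.05)
    dp <- mtdyn:::optimal_partition(t, y, penalty, min_len = 3)
    bf <- brute_force_segmentation(t, y, penalty, min_len = 3, max_cp = 2)
    if (length(dp$changepoints) <= 2) {
      expect_equal(dp$cost, bf$cost, tolerance = 1e-8)
      expect_equal(dp$changepoints, bf$cps)
      n_match <- n_match + 1
    }
  }
  expect_gt(n_match, 40)
})

test_that("undersized segments merge into the rate-closer neighbour", {
  # 2-sample blip between two long phases is absorbed
  y <- piecewise_positions(c(1, 1.05, 0), c(30, 2, 30))
  ph <- segment_phases(as_traj(y), min_duration = 9)
  expect_true(all(ph$duration >= 9))
  expect_true(all(ph$state %in% c("fast_growth", "pause")))
})

test_that("degenerate inputs are rejected", {
  expect_error(segment_phases(as_traj(c(1, 2, 3))), "4 samples")
  tr <- as_traj(rep(1, 10))
  tr$times <- rep(0, 10)
  expect_error(segment_phases(tr), "degenerate")
  expect_error(segment_phases(as_traj(cumsum(rep(0.05, 20))),
                              min_duration = 3), "min_duration")
})

test_that("terminal pauses are blocks; transient pauses are not", {
  # pause from 100 s to the end of a 600-s video
  ph <- make_phases(c(0, 100), c(100, 600), c(1.2, 0.0),
                    c("fast_growth", "pause"))
  out <- detect_blocks(ph, video_length = 600)
  expect_true(out$is_block[2])
  expect_equal(out$duration[2], 500)
  # pause followed by growth: transient, not a block
  ph2 <- make_phases(c(0, 100, 400), c(100, 400, 600), c(1.2, 0, 1.1),
                     c("fast_growth", "pause", "fast_growth"))
  out2 <- detect_blocks(ph2, video_length = 600)
  expect_false(any(out2$is_block))
  # block duration is censored at the video length
  ph3 <- make_phases(c(0, 10), c(10, 650), c(1, 0),
                     c("fast_growth", "pause"))
  out3 <- detect_blocks(ph3, video_length = 600)
  expect_true(out3$is_block[2])
  expect_lte(out3$duration[2], 600)
})
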
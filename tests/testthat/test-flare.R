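test_that("generated ends respect the azimuthal spacing rule", {
  e <- simulate_protofilament_end(corked = FALSE, n_pf = 13, seed = 1)
  az <- sort(e$truth$azimuth_deg %% 360)
  gaps <- diff(c(az, az[1] + 360))
  expect_true(all(abs(gaps - 360 / 13) <= 8 + 1e-9))  # 2 x the +/-4 jitter
  expect_equal(length(e$traces), 13)
  # determinism
  e2 <- simulate_protofilament_end(corked = FALSE, n_pf = 13, seed = 1)
  expect_identical(e$traces, e2$traces)
  expect_error(simulate_protofilament_end(n_pf = 2), "n_pf")
})

test_that("wall exit detection finds the first deviating point", {
  # perfectly axial polyline: no flare, exit at the last point
  straight <- cbind(0, 0, seq(0, 40, by = 2))
  expect_equal(find_wall_exit(straight, c(0, 0, 1)), nrow(straight))
  # axial run then a 30 degree bend at point k
  k <- 8
  bend <- rbind(cbind(0, 0, seq(0, by = 2, length.out = k)),
                t(sapply(1:6, function(i)
                  c(i * 2 * sin(pi / 6), 0,
                    2 * (k - 1) + i * 2 * cos(pi / 6)))))
  expect_equal(find_wall_exit(bend, c(0, 0, 1), 10), k)
  # generator truth: detected exit within one point of the generative wall end
  e <- simulate_protofilament_end(FALSE, seed = 7)
  for (i in seq_len(e$n_pf)) {
    kx <- find_wall_exit(e$traces[[i]], e$axis, 10)
    exit_z <- e$traces[[i]][kx, 3]
    expect_lt(abs(exit_z - e$truth$wall_exit_z[i]),
              2 * e$params$step + 1e-9)
  }
})

test_that("flared length matches closed-form fixtures", {
  # blunt trace under the third-point rule: one sampling step
  blunt <- cbind(0, 0, c(-4, -2, 0))
  kb <- find_wall_exit(blunt, c(0, 0, 1))
  expect_equal(kb, 3)
  expect_equal(flared_length(blunt, kb), 2)
  # straight 50 nm extension at 45 degrees plus the closing wall segment
  ext <- rbind(cbind(0, 0, seq(-10, 0, by = 2)),
               t(sapply(seq(2, 50, by = 2), function(s)
                 c(s / sqrt(2), 0, s / sqrt(2)))))
  ke <- find_wall_exit(ext, c(0, 0, 1), 10)
  expect_equal(flared_length(ext, ke), 50 + 2)
  # quarter circle of radius 20 appended to the wall, sampled coarsely so
  # the first arc segment already deviates: chord sum approaches pi R / 2
  th <- seq(0, pi / 2, length.out = 13)   # 7.5 degree steps; first chord
  arc <- cbind(20 * (1 - cos(th)), 0, 20 * sin(th))  # deviates by 3.75 deg
  tr <- rbind(cbind(0, 0, seq(-10, 0, by = 2)), arc[-1, ])
  kq <- find_wall_exit(tr, c(0, 0, 1), 2)
  chord <- 2 * 20 * sin((pi / 2) / 12 / 2) * 12   # exact chord-sum length
  expect_equal(flared_length(tr, kq), chord + 2, tolerance = 1e-9)
  expect_equal(chord, pi * 20 / 2, tolerance = 0.01)
})

test_that("local curvature is zero for lines and 1/R for circles", {
  line <- cbind(seq(0, 20, 2), seq(0, 40, 4), seq(0, 10, 1))
  lc <- local_curvature(line, 1)
  expect_equal(unique(lc$values), 0, tolerance = 1e-10)
  # circle of radius 20 nm: curvature (180/pi)/20 deg/nm, O(h^2) error
  for (np in c(20, 40, 80)) {
    th <- seq(0, pi / 2, length.out = np)
    circ <- cbind(20 * (1 - cos(th)), 0, 20 * sin(th))
    lc <- local_curvature(circ, 1)
    expect_equal(lc$mean, (180 / pi) / 20,
                 tolerance = (pi / 2 / np)^2 + 1e-4)
  }
  expect_true(is.na(local_curvature(line[1:2, ], 1)$mean))
})

test_that("raggedness is the sample s.d. of axial exit positions", {
  pts <- cbind(c(1, -2, 0.5), c(0, 1, -1), c(0, 10, 20))
  expect_equal(raggedness(pts, c(0, 0, 1)), 10)
  coplanar <- cbind(c(1, 2, 3, 4), c(4, 3, 2, 1), rep(5, 4))
  expect_equal(raggedness(coplanar, c(0, 0, 1)), 0)
  expect_true(is.na(raggedness(pts[1:2, ], c(0, 0, 1))))
})

test_that("raggedness parameter is recovered from generated batches", {
  ends <- lapply(1:30, function(i)
    simulate_protofilament_end(FALSE, seed = 500 + i))
  r <- vapply(ends, function(e) summarize_end(e)$raggedness, numeric(1))
  expect_lt(abs(mean(r) - pf_end_params(FALSE)$raggedness_sd) /
              pf_end_params(FALSE)$raggedness_sd, 0.15)
})

test_that("all metrics are invariant under rigid motion", {
  e <- simulate_protofilament_end(FALSE, seed = 3)
  g0 <- summarize_end(e)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  th2 <- 0.4
  Rx <- matrix(c(1, 0, 0, 0, cos(th2), sin(th2),
                 0, -sin(th2), cos(th2)), 3, 3)
  R <- Rx %*% Rz
  moved <- lapply(e$traces, function(m)
    sweep(m %*% t(R), 2, c(5, -3, 11), "+"))
  g1 <- summarize_end(moved, mt_axis = as.vector(R %*% c(0, 0, 1)))
  for (f in c("length_sd", "raggedness", "mean_curvature"))
    expect_equal(g1[[f]], g0[[f]], tolerance = 1e-6)
  expect_equal(g1$per_pf$flared_length, g0$per_pf$flared_length,
               tolerance = 1e-6)
  # the axis can also be re-estimated from the moved roots
  g2 <- summarize_end(moved)
  expect_equal(g2$raggedness, g0$raggedness, tolerance = 1e-6)
})

test_that("flared length never undercuts the straight-line distance", {
  for (i in 1:10) {
    e <- suppressWarnings(
      simulate_protofilament_end(i %% 2 == 0, seed = 900 + i))
    for (tr in e$traces) {
      k <- find_wall_exit(tr, e$axis, 10)
      a <- max(1, k - 1)
      straight <- sqrt(sum((tr[nrow(tr), ] - tr[a, ])^2))
      expect_gte(flared_length(tr, k), straight - 1e-9)
    }
  }
})

test_that("corked ends score lower on every flare metric", {
  fl <- lapply(1:20, function(i) suppressWarnings(
    summarize_end(simulate_protofilament_end(FALSE, seed = i))))
  ck <- lapply(1:20, function(i) suppressWarnings(
    summarize_end(simulate_protofilament_end(TRUE, seed = 100 + i))))
  med_len <- function(g) stats::median(g$per_pf$flared_length)
  expect_lt(stats::median(vapply(ck, med_len, numeric(1))),
            stats::median(vapply(fl, med_len, numeric(1))))
  expect_lt(mean(vapply(ck, `[[`, numeric(1), "length_sd")),
            mean(vapply(fl, `[[`, numeric(1), "length_sd")))
  expect_lt(mean(vapply(ck, `[[`, numeric(1), "raggedness")),
            mean(vapply(fl, `[[`, numeric(1), "raggedness")))
  expect_lt(mean(vapply(ck, `[[`, numeric(1), "mean_curvature")),
            mean(vapply(fl, `[[`, numeric(1), "mean_curvature")))
  expect_true(all(vapply(fl, `[[`, numeric(1), "n_pf") <= 14))
})

test_that("contour files round-trip and reject malformed input", {
  e <- simulate_protofilament_end(FALSE, n_pf = 13, seed = 12)
  f <- withr::local_tempfile(fileext = ".txt")
  write_contours(e, f)
  back <- read_contours(f)
  expect_length(back, 1)
  expect_length(back[[1]]$traces, 13)
  for (i in 1:13)
    expect_equal(unname(back[[1]]$traces[[i]]), unname(e$traces[[i]]),
                 tolerance = 1e-5)
  # truncated / malformed files name the offending line
  writeLines(c("MT 1 13 plus", "PF 1", "0 0 0", "1 bad 2"), f)
  expect_error(read_contours(f), "line 4")
  writeLines(character(0), f)
  expect_error(read_contours(f), "empty")
})
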
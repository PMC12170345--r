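test_that("spot field generator enforces spacing and records truth", {
  f <- simulate_spot_field(100, c("1" = 1), seed = 1)
  expect_equal(nrow(f$truth), 100)
  d <- as.matrix(stats::dist(f$truth[, c("x", "y")]))
  diag(d) <- Inf
  expect_gte(min(d), 4 * f$psf_sigma)
  # identical seed, identical field
  f2 <- simulate_spot_field(100, c("1" = 1), seed = 1)
  expect_identical(f$image, f2$image)
  expect_error(simulate_spot_field(1e5, c("1" = 1), image_size = 64),
               "density")
  expect_error(simulate_spot_field(10, c("1" = 0.4, "2" = 0.4)), "sum to 1")
})

test_that("noiseless monomer intensities equal the monomer mean exactly", {
  f <- simulate_spot_field(50, c("1" = 1), monomer_mean = 800,
                           monomer_sd = 0, noise_sd = 0, seed = 2)
  expect_true(all(f$truth$integrated_intensity == 800))
})

test_that("detection recalls the generator truth at default noise", {
  f <- simulate_spot_field(300, c("1" = 1), image_size = 256, seed = 5)
  det <- detect_spots(f$image)
  # match detections to truth within 2 px
  hit <- vapply(seq_len(nrow(f$truth)), function(i)
    any((det$x - f$truth$x[i])^2 + (det$y - f$truth$y[i])^2 <= 4),
    logical(1))
  expect_gte(mean(hit), 0.95)
  expect_equal(nrow(detect_spots(matrix(0, 64, 64))), 0)
})

test_that("two spots inside the suppression radius give one flagged hit", {
  # two local maxima 2 px apart, inside the 2-sigma suppression radius
  img <- matrix(0, 32, 32)
  img[16, 15] <- 100
  img[16, 17] <- 90
  det <- detect_spots(img, psf_sigma = 1.5)
  expect_equal(nrow(det), 1)
  expect_true(det$crowded[1])
  expect_equal(det$x[1], 15)
})

test_that("2D Gaussian fitting is exact on a noiseless model spot", {
  img <- matrix(5, 21, 21)
  for (xx in 1:21) for (yy in 1:21)
    img[yy, xx] <- 5 + 100 * exp(-((xx - 11.3)^2 + (yy - 10.7)^2) /
                                   (2 * 1.5^2))
  r <- fit_spot(img, 11, 11, 1.5)
  expect_equal(r$amplitude, 100, tolerance = 1e-3)
  expect_equal(r$sigma, 1.5, tolerance = 1e-3)
  expect_equal(r$x, 11.3, tolerance = 1e-3)
  expect_equal(r$y, 10.7, tolerance = 1e-3)
  # closed form: 2 * pi * 100 * 1.5^2
  expect_equal(r$integrated_intensity, 2 * pi * 100 * 2.25,
               tolerance = 1e-3)
  expect_error(fit_spot(img, 2, 2, 1.5), "outside")
})

test_that("intensity histogram finds delta and mixture modes", {
  h <- intensity_histogram(rep(500, 25))
  expect_equal(h$mode, 500)
  expect_error(intensity_histogram(1:5), ">= 10")
  set.seed(9)
  mix <- c(stats::rnorm(400, 1000, 100), stats::rnorm(400, 2000, 140))
  hm <- intensity_histogram(mix)
  expect_gte(length(hm$modes), 2)
  two <- sort(hm$modes[1:2])
  expect_equal(two[1], 1000, tolerance = 0.1)
  expect_equal(two[2], 2000, tolerance = 0.1)
})

test_that("stoichiometry inference is correct and scale-invariant", {
  set.seed(11)
  mono <- stats::rnorm(1000, 1000, 150)
  multim <- lapply(1:4, function(n)
    vapply(1:1000, function(i) sum(stats::rnorm(n, 1000, 150)), numeric(1)))
  for (n in 1:4) {
    st <- infer_stoichiometry(multim[[n]], mono, seed = n)
    expect_equal(st$n, n)
  }
  st1 <- infer_stoichiometry(multim[[2]], mono, seed = 5)
  st2 <- infer_stoichiometry(multim[[2]] * 3.7, mono * 3.7, seed = 5)
  expect_equal(st1$ratio, st2$ratio, tolerance = 1e-12)
  expect_error(infer_stoichiometry(1:5, mono), ">= 10")
})

test_that("fitted dimer and monomer fields give a mode ratio near 2", {
  f1 <- simulate_spot_field(400, c("1" = 1), seed = 21)
  f2 <- simulate_spot_field(400, c("2" = 1), seed = 22)
  r1 <- fit_spots(f1$image)
  r2 <- fit_spots(f2$image)
  expect_gte(nrow(r1), 380)
  st <- infer_stoichiometry(r2, r1, seed = 23)
  expect_equal(st$n, 2)
  expect_equal(st$ratio, 2, tolerance = 0.15)
})

test_that("molecule counting reports end intensity over the monomer mode", {
  set.seed(13)
  mono <- stats::rnorm(500, 1000, 100)
  md <- intensity_histogram(mono)$mode
  mc <- count_molecules_at_end(6 * md, mono, seed = 14)
  expect_equal(mc$count, 6, tolerance = 1e-9)
  expect_true(mc$ci[1] <= mc$count && mc$count <= mc$ci[2])
  expect_error(count_molecules_at_end(-5, mono), "positive")
})
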
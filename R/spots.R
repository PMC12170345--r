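#' Simulate a field of diffraction-limited single-molecule spots
#'
#' Places `n_spots` spots uniformly at random, no two closer than
#' `4 * psf_sigma`, each an n-mer drawn from `stoich_distribution`. The
#' integrated intensity of an n-mer is the sum of n independent monomer
#' draws `N(monomer_mean, monomer_sd)`; the spot is rendered as a symmetric
#' 2D Gaussian of that integrated intensity. Gaussian background noise is
#' added on top of a constant offset.
#'
#' @param n_spots Number of spots.
#' @param stoich_distribution Named numeric vector mapping oligomer size to
#'   probability (must sum to 1), e.g. `c("1" = 0.5, "2" = 0.5)`.
#' @param monomer_mean,monomer_sd Monomer integrated intensity, a.u.
#' @param psf_sigma PSF sigma, px.
#' @param image_size Image side length, px (square image).
#' @param background Constant offset, a.u.
#' @param noise_sd Gaussian noise sd, a.u. (default 10, i.e. a peak
#'   signal-to-noise ratio of about 7 for a monomer at the default
#'   intensity and PSF).
#' @param seed Integer seed.
#' @return List of class `"spot_field"`: `image` (matrix), `truth` (data
#'   frame `x`, `y`, `n`, `integrated_intensity`), and the generative
#'   parameters.
#' @export
simulate_spot_field <- function(n_spots, stoich_distribution = c("1" = 1),
                                monomer_mean = 1000, monomer_sd = 150,
                                psf_sigma = 1.5, image_size = 256,
                                background = 100, noise_sd = 10,
                                seed = NULL) {
  p <- stoich_distribution
  if (abs(sum(p) - 1) > 1e-8) stop_mtdyn("stoichiometry probabilities must sum to 1")
  if (monomer_mean <= 0) stop_mtdyn("monomer_mean must be > 0")
  min_dist <- 4 * psf_sigma
  margin <- ceiling(4 * psf_sigma) + 1
  usable <- (image_size - 2 * margin)^2
  if (n_spots * (min_dist^2) > usable)
    stop_mtdyn("spot density too high: ", n_spots, " spots need more than ",
               round(usable / min_dist^2), " available sites at spacing ",
               min_dist, " px")
  with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    attempts <- 0
    while (length(xs) < n_spots) {
      attempts <- attempts + 1
      if (attempts > 200 * n_spots)
        stop_mtdyn("spot density too high: cannot satisfy ", min_dist,
                   " px spacing for ", n_spots, " spots")
      x <- stats::runif(1, margin, image_size - margin)
      y <- stats::runif(1, margin, image_size - margin)
      if (length(xs) == 0 || min((xs - x)^2 + (ys - y)^2) >= min_dist^2) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    ns <- as.integer(sample(names(p), n_spots, replace = TRUE, prob = p))
    intens <- vapply(ns, function(n)
      sum(stats::rnorm(n, monomer_mean, monomer_sd)), numeric(1))
    intens[intens < 0] <- 0

    img <- matrix(background, image_size, image_size)
    half <- ceiling(4 * psf_sigma)
    for (i in seq_len(n_spots)) {
      amp <- intens[i] / (2 * pi * psf_sigma^2)
      cx <- xs[i]; cy <- ys[i]
      ix <- max(1, floor(cx) - half):min(image_size, ceiling(cx) + half)
      iy <- max(1, floor(cy) - half):min(image_size, ceiling(cy) + half)
      g <- outer(iy, ix, function(r, c)
        amp * exp(-((c - cx)^2 + (r - cy)^2) / (2 * psf_sigma^2)))
      img[iy, ix] <- img[iy, ix] + g
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          nrow(img), ncol(img))
    structure(
      list(image = img,
           truth = data.frame(x = xs, y = ys, n = ns,
                              integrated_intensity = intens),
           psf_sigma = psf_sigma, background = background,
           noise_sd = noise_sd, monomer_mean = monomer_mean,
           monomer_sd = monomer_sd),
      class = "spot_field")
  })
}

#' Detect candidate spots as thresholded local maxima
#'
#' Local maxima above `background mean + threshold_sd * background sd`
#' (both estimated robustly from the image) are candidates; greedy
#' non-maximum suppression with radius `2 * psf_sigma` keeps the brightest
#' of any crowded cluster and flags it.
#'
#' @param image Numeric matrix.
#' @param threshold_sd Detection threshold in background-sd units.
#' @param psf_sigma PSF sigma, px.
#' @return Data frame: `x`, `y` (px, integer maxima), `intensity`,
#'   `crowded` (TRUE when another candidate was suppressed nearby).
#' @export
detect_spots <- function(image, threshold_sd = 3.5, psf_sigma = 1.5) {
  if (length(dim(image)) != 2) stop_mtdyn("image must be a 2D matrix")
  bg <- stats::median(image)
  noise <- stats::mad(image)
  thr <- bg + threshold_sd * max(noise, 1e-9)
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3 || nc < 3) return(data.frame(x = numeric(0), y = numeric(0),
                                          intensity = numeric(0),
                                          crowded = logical(0)))
  core <- image[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (core >= image[2:(nr - 1) + dr, 2:(nc - 1) + dc])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      intensity = numeric(0), crowded = logical(0)))
  cand <- data.frame(x = idx[, 2] + 1, y = idx[, 1] + 1,
                     intensity = core[is_max])
  cand <- cand[order(-cand$intensity), ]
  r2 <- (2 * psf_sigma)^2
  keep <- integer(0); crowded <- logical(0)
  for (i in seq_len(nrow(cand))) {
    if (length(keep) == 0) { keep <- i; crowded <- FALSE; next }
    d2 <- (cand$x[keep] - cand$x[i])^2 + (cand$y[keep] - cand$y[i])^2
    if (all(d2 >= r2)) { keep <- c(keep, i); crowded <- c(crowded, FALSE) }
    else crowded[which.min(d2)] <- TRUE
  }
  out <- cand[keep, ]
  out$crowded <- crowded
  rownames(out) <- NULL
  out
}

#' Fit a symmetric 2D Gaussian to one spot
#'
#' Nonlinear least squares of `b + A * exp(-((x-x0)^2 + (y-y0)^2) /
#' (2 sigma^2))` over a window of half-width
#' `ceiling(window_sigmas * sigma_guess)` around the candidate position
#' (3 sigma by default: wide enough to constrain the offset, narrow enough
#' that neighbouring spots at the generator's 4-sigma minimum spacing stay
#' outside). The integrated intensity is `2 * pi * A * sigma^2`.
#'
#' @param image Numeric matrix.
#' @param x,y Candidate position, px.
#' @param sigma_guess Starting sigma, px.
#' @param window_sigmas Fit window half-width in units of `sigma_guess`.
#' @return One-row data frame (a SpotRecord): `x`, `y`, `amplitude`,
#'   `sigma`, `offset`, `integrated_intensity`, `fit_residual`,
#'   `converged`.
#' @export
fit_spot <- function(image, x, y, sigma_guess = 1.5, window_sigmas = 3) {
  half <- ceiling(window_sigmas * sigma_guess)
  ix <- (round(x) - half):(round(x) + half)
  iy <- (round(y) - half):(round(y) + half)
  if (min(ix) < 1 || min(iy) < 1 || max(ix) > ncol(image) ||
      max(iy) > nrow(image))
    stop_mtdyn("fit window extends outside the image")
  win <- image[iy, ix]
  df <- data.frame(gx = rep(ix, each = length(iy)),
                   gy = rep(iy, times = length(ix)),
                   z = as.vector(win))
  b0 <- min(df$z)
  a0 <- max(df$z) - b0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + A * exp(-((gx - x0)^2 + (gy - y0)^2) / (2 * s^2)),
      data = df,
      start = list(b = b0, A = a0, x0 = x, y0 = y, s = sigma_guess),
      lower = c(b = -Inf, A = 0, x0 = min(ix), y0 = min(iy), s = 0.3),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(data.frame(x = x, y = y, amplitude = NA_real_, sigma = NA_real_,
                      offset = NA_real_, integrated_intensity = NA_real_,
                      fit_residual = NA_real_, converged = FALSE))
  }
  cf <- stats::coef(fit)
  data.frame(x = cf[["x0"]], y = cf[["y0"]], amplitude = cf[["A"]],
             sigma = cf[["s"]], offset = cf[["b"]],
             integrated_intensity = 2 * pi * cf[["A"]] * cf[["s"]]^2,
             fit_residual = sqrt(mean(stats::resid(fit)^2)),
             converged = TRUE)
}

#' Detect and fit every spot in an image
#'
#' @inheritParams detect_spots
#' @return Data frame of SpotRecords. Non-converged fits are dropped (with
#'   a message), as are implausible ones (fitted sigma outside
#'   0.5-2 times the PSF sigma, or non-positive amplitude) — those arise
#'   from noise-driven false detections.
#' @export
fit_spots <- function(image, threshold_sd = 3.5, psf_sigma = 1.5) {
  cand <- detect_spots(image, threshold_sd, psf_sigma)
  half <- ceiling(3 * psf_sigma)
  inside <- cand$x - half >= 1 & cand$x + half <= ncol(image) &
    cand$y - half >= 1 & cand$y + half <= nrow(image)
  cand <- cand[inside, ]
  recs <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
    fit_spot(image, cand$x[i], cand$y[i], psf_sigma)))
  if (is.null(recs)) return(recs)
  bad <- !recs$converged
  if (any(bad)) message(sum(bad), " spot fits did not converge; excluded")
  recs <- recs[!bad, , drop = FALSE]
  # plausibility filter: a genuine diffraction-limited spot must fit with a
  # width near the PSF; noise-driven fits run away to tiny amplitudes and
  # huge sigmas and would corrupt the intensity histogram
  ok <- recs$sigma >= 0.5 * psf_sigma & recs$sigma <= 2 * psf_sigma &
    recs$amplitude > 0
  recs[ok, , drop = FALSE]
}

# Accept a SpotRecord data frame or a bare numeric vector of intensities.
spot_intensities <- function(records) {
  if (is.data.frame(records)) {
    col <- if ("integrated_intensity" %in% names(records))
      "integrated_intensity" else stop_mtdyn("no integrated_intensity column")
    v <- records[[col]]
  } else v <- as.numeric(records)
  v[is.finite(v)]
}

#' Intensity histogram with kernel-smoothed mode estimate
#'
#' Gaussian kernel density (Silverman's rule bandwidth) over the integrated
#' intensities; the primary mode is the highest density peak, and all local
#' maxima exceeding 10% of the peak density are reported (a 50/50
#' monomer-dimer mixture yields two).
#'
#' @param records SpotRecord data frame or numeric intensities.
#' @param bins Number of histogram bins (default 50).
#' @return List of class `"intensity_histogram"`: `histogram` (from
#'   [graphics::hist()], not plotted), `density`, `mode`, `modes`.
#' @export
intensity_histogram <- function(records, bins = 50) {
  v <- spot_intensities(records)
  if (length(v) < 10) stop_mtdyn("need >= 10 records for a histogram")
  h <- graphics::hist(v, breaks = bins, plot = FALSE)
  if (stats::sd(v) == 0) {
    # degenerate delta distribution
    return(structure(list(histogram = h, density = NULL,
                          mode = v[1], modes = v[1]),
                     class = "intensity_histogram"))
  }
  d <- stats::density(v, bw = "nrd0")
  peak_i <- which(diff(sign(diff(d$y))) == -2) + 1
  if (length(peak_i) == 0) peak_i <- which.max(d$y)
  peak_i <- peak_i[d$y[peak_i] > 0.1 * max(d$y)]
  modes <- d$x[peak_i][order(-d$y[peak_i])]
  structure(list(histogram = h, density = d,
                 mode = d$x[which.max(d$y)], modes = modes),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat("<intensity_histogram> mode =", signif(x$mode, 5))
  if (length(x$modes) > 1)
    cat(" (", length(x$modes), " modes: ",
        paste(signif(x$modes, 4), collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Infer oligomer stoichiometry against a monomer reference
#'
#' Ratio of the target intensity mode to the monomer-reference mode, with a
#' bootstrap confidence interval; the rounded ratio is the inferred
#' oligomer number. The estimate is scale-invariant (both sets must come
#' from matched imaging conditions, e.g. adjacent chambers of the same
#' coverslip). A CI spanning two integers is flagged ambiguous.
#'
#' @param target,monomer_reference SpotRecord data frames or intensity
#'   vectors (>= 10 each).
#' @param n_boot Bootstrap replicates (default 200).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return List of class `"stoichiometry"`: `ratio`, `n` (rounded),
#'   `ci` (length 2), `ambiguous`.
#' @export
infer_stoichiometry <- function(target, monomer_reference, n_boot = 200,
                                conf = 0.95, seed = NULL) {
  tv <- spot_intensities(target)
  mv <- spot_intensities(monomer_reference)
  if (length(tv) < 10 || length(mv) < 10)
    stop_mtdyn("need >= 10 records in each set")
  mode_of <- function(v) {
    if (stats::sd(v) == 0) return(v[1])
    d <- stats::density(v, bw = "nrd0")
    d$x[which.max(d$y)]
  }
  ratio <- mode_of(tv) / mode_of(mv)
  ci <- with_seed(seed, {
    bs <- replicate(n_boot, {
      mode_of(sample(tv, replace = TRUE)) / mode_of(sample(mv, replace = TRUE))
    })
    stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  })
  structure(list(ratio = ratio, n = round(ratio), ci = ci,
                 ambiguous = round(ci[1]) != round(ci[2])),
            class = "stoichiometry")
}

#' @export
print.stoichiometry <- function(x, ...) {
  cat(sprintf("<stoichiometry> n = %d (ratio %.3f, CI [%.3f, %.3f]%s)\n",
              x$n, x$ratio, x$ci[1], x$ci[2],
              if (x$ambiguous) ", ambiguous" else ""))
  invisible(x)
}

#' Count molecules at a blocked microtubule end
#'
#' Divides the integrated end intensity by the monomer-reference intensity
#' mode, with a bootstrap CI over the reference set. Dividing the result by
#' the inferred oligomer stoichiometry gives the oligomer count (e.g. ~5-6
#' molecules of a dimeric protein = 2-3 dimers).
#'
#' @param end_intensity Integrated intensity at the end, a.u. (> 0).
#' @param monomer_reference SpotRecord data frame or intensity vector.
#' @param n_boot,conf,seed As in [infer_stoichiometry()].
#' @return List of class `"molecule_count"`: `count`, `ci`.
#' @export
count_molecules_at_end <- function(end_intensity, monomer_reference,
                                   n_boot = 200, conf = 0.95, seed = NULL) {
  if (!is.finite(end_intensity) || end_intensity <= 0)
    stop_mtdyn("end_intensity must be positive")
  mv <- spot_intensities(monomer_reference)
  if (length(mv) < 10) stop_mtdyn("need >= 10 monomer records")
  mode_of <- function(v) {
    if (stats::sd(v) == 0) return(v[1])
    d <- stats::density(v, bw = "nrd0")
    d$x[which.max(d$y)]
  }
  count <- end_intensity / mode_of(mv)
  ci <- with_seed(seed, {
    bs <- replicate(n_boot, end_intensity / mode_of(sample(mv, replace = TRUE)))
    stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  })
  structure(list(count = count, ci = ci), class = "molecule_count")
}

#' @export
print.molecule_count <- function(x, ...) {
  cat(sprintf("<molecule_count> %.2f molecules (CI [%.2f, %.2f])\n",
              x$count, x$ci[1], x$ci[2]))
  invisible(x)
}
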
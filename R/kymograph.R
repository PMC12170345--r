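#' Render a trajectory as a synthetic kymograph
#'
#' Produces the space-time raster a kymograph reslice of a TIRF movie would
#' give: one row per frame (time increasing downward), one column per
#' spatial pixel. Each row carries a lattice signal from the seed (column 1)
#' to the current tip plus a brighter diffraction-limited tip spot, both
#' blurred with a Gaussian PSF. Gaussian noise with standard deviation
#' `tip_amplitude / snr` is added; intensities are clipped at 0.
#'
#' @param traj An `mt_trajectory`.
#' @param pixel_size Spatial pixel size, µm/px (default 0.045).
#' @param psf_sigma PSF sigma, µm (default 0.1).
#' @param snr Peak tip amplitude over background noise sd; `Inf` for a
#'   noise-free image.
#' @param tip_amplitude Peak intensity of the tip spot, a.u.
#' @param lattice_amplitude Intensity of the MT lattice, a.u.
#' @param background Constant background offset, a.u.
#' @param seed Integer seed for the noise.
#' @return Object of class `"mt_kymograph"`: list with `pixel_values`
#'   (frames x pixels matrix), `pixel_size`, `frame_interval`, `channel`,
#'   `background_mean`, `background_sd`.
#' @export
render_kymograph <- function(traj, pixel_size = 0.045, psf_sigma = 0.1,
                             snr = 10, tip_amplitude = 300,
                             lattice_amplitude = 100, background = 20,
                             seed = NULL) {
  if (pixel_size <= 0) stop_mtdyn("pixel_size must be > 0")
  if (psf_sigma < 0) stop_mtdyn("psf_sigma must be >= 0")
  n_frames <- length(traj$times)
  # image wide enough for the whole excursion plus PSF margin; grown, never
  # silently truncated
  width <- ceiling((max(traj$positions) + 4 * psf_sigma) / pixel_size) + 8
  centers <- (seq_len(width) - 1) * pixel_size
  sig <- max(psf_sigma, pixel_size / 4)  # avoid degenerate zero-width PSF
  bg_sd <- if (is.finite(snr)) tip_amplitude / snr else 0

  img <- matrix(background, n_frames, width)
  for (i in seq_len(n_frames)) {
    tip <- traj$positions[i]
    # lattice: convolution of a box [0, tip] with the Gaussian PSF
    lattice <- lattice_amplitude *
      (stats::pnorm((tip - centers) / sig) - stats::pnorm((0 - centers) / sig))
    spot <- tip_amplitude * exp(-(centers - tip)^2 / (2 * sig^2))
    img[i, ] <- img[i, ] + lattice + spot
  }
  if (bg_sd > 0) {
    img <- with_seed(seed, img + matrix(stats::rnorm(length(img), 0, bg_sd),
                                        nrow(img), ncol(img)))
  }
  img[img < 0] <- 0
  structure(
    list(pixel_values = img, pixel_size = pixel_size,
         frame_interval = traj$dt, channel = "tip",
         background_mean = background, background_sd = bg_sd,
         psf_sigma = sig),
    class = "mt_kymograph")
}

#' @export
print.mt_kymograph <- function(x, ...) {
  cat("<mt_kymograph> ", nrow(x$pixel_values), " frames x ",
      ncol(x$pixel_values), " px, ", x$pixel_size, " um/px, ",
      x$frame_interval, " s/frame\n", sep = "")
  invisible(x)
}

#' Trace the microtubule tip through a kymograph
#'
#' For each row (frame), estimates the distal-most tip position at sub-pixel
#' resolution: columns above `background + threshold_sd * sd` define the
#' signal support (runs of at least `min_run` consecutive columns); the
#' local intensity maximum nearest the distal edge of the last run is
#' refined by a three-point parabola on the log intensities, which is exact
#' for a Gaussian line profile. Rows without signal are imputed by linear
#' interpolation and flagged. A running-median despike (odd window) removes
#' isolated outliers.
#'
#' @param kymo An `mt_kymograph` (or plain matrix plus `pixel_size`).
#' @param threshold_sd Detection threshold in background sd units.
#' @param min_run Minimum number of consecutive above-threshold columns for
#'   a valid distal signal run (default 2; suppresses single-pixel noise).
#' @param median_window Odd window length for despiking (default 5).
#' @param pixel_size Used when `kymo` is a bare matrix.
#' @param frame_interval Used when `kymo` is a bare matrix, s.
#' @return An `mt_trajectory` with attribute `"imputed"` marking rows
#'   lacking signal.
#' @export
trace_kymograph <- function(kymo, threshold_sd = 4, min_run = 2,
                            median_window = 5,
                            pixel_size = 0.045, frame_interval = 3) {
  if (inherits(kymo, "mt_kymograph")) {
    img <- kymo$pixel_values
    pixel_size <- kymo$pixel_size
    frame_interval <- kymo$frame_interval
  } else img <- as.matrix(kymo)
  if (nrow(img) < 2) stop_mtdyn("kymograph must have >= 2 rows")
  if (median_window %% 2 != 1) stop_mtdyn("median_window must be odd")

  n <- nrow(img)
  pos <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    row <- img[i, ]
    bg <- stats::median(row)
    noise <- stats::mad(row)
    thr <- bg + threshold_sd * max(noise, 1e-9)
    above <- row > thr
    if (!any(above)) next
    # distal-most run of >= min_run consecutive above-threshold columns;
    # isolated single-pixel noise excursions do not qualify
    r <- rle(above)
    ends_r <- cumsum(r$lengths)
    ok <- which(r$values & r$lengths >= min_run)
    if (length(ok) == 0) next
    tip_col <- ends_r[ok[length(ok)]]
    # walk left from the distal edge to the nearest local maximum, then
    # refine sub-pixel with a 3-point parabola on log intensity (exact for
    # a Gaussian line profile)
    j <- tip_col
    while (j > 1 && row[j - 1] > row[j]) j <- j - 1
    if (j > 1 && j < ncol(img)) {
      l <- log(pmax(row[c(j - 1, j, j + 1)] - bg, 1e-6))
      den <- l[1] - 2 * l[2] + l[3]
      d <- if (den < 0) 0.5 * (l[1] - l[3]) / den else 0
      d <- max(-0.5, min(0.5, d))
      pos[i] <- (j - 1 + d) * pixel_size
    } else {
      pos[i] <- (j - 1) * pixel_size
    }
  }
  if (all(is.na(pos))) stop_mtdyn("no tip signal above background")
  imputed <- is.na(pos)
  if (any(imputed)) {
    idx <- which(!imputed)
    pos <- stats::approx(idx, pos[idx], xout = seq_len(n), rule = 2)$y
  }
  if (n >= median_window) {
    sm <- stats::runmed(pos, median_window)
    spike <- abs(pos - sm) > 3 * pixel_size
    pos[spike] <- sm[spike]
  }
  pos[pos < 0] <- 0
  structure(
    list(times = (seq_len(n) - 1) * frame_interval, positions = pos,
         true_states = NULL, end_polarity = "plus", dt = frame_interval,
         rng_seed = NULL, events = NULL),
    class = "mt_trajectory") -> out
  attr(out, "imputed") <- imputed
  out
}

#' Write / read a kymograph as 16-bit TIFF
#'
#' Intensities are scaled to the 16-bit range on write; the scale factor is
#' not stored, so round-trips preserve relative, not absolute, intensities.
#' @param kymo An `mt_kymograph`.
#' @param path File path.
#' @export
write_kymograph_tiff <- function(kymo, path) {
  img <- kymo$pixel_values
  mx <- max(img)
  if (mx <= 0) mx <- 1
  tiff::writeTIFF(img / mx, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_kymograph_tiff
#' @param pixel_size µm/px to attach on read.
#' @param frame_interval s/frame to attach on read.
#' @export
read_kymograph_tiff <- function(path, pixel_size = 0.045,
                                frame_interval = 3) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  structure(
    list(pixel_values = img, pixel_size = pixel_size,
         frame_interval = frame_interval, channel = "tip",
         background_mean = stats::median(img), background_sd = stats::mad(img),
         psf_sigma = NA_real_),
    class = "mt_kymograph")
}
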
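#' Simulate a FRAP intensity trace with single-exponential recovery
#'
#' Before the bleach the intensity sits at `prebleach`. From the bleach
#' frame onward it follows
#' `postbleach + mobile_fraction * (prebleach - postbleach) * (1 - exp(-k t'))`
#' with `t'` the time since the bleach; Gaussian noise is added to frames
#' after the bleach frame (the bleach frame itself anchors the recovery at
#' its exact post-bleach level).
#'
#' @param prebleach,postbleach Intensity levels, a.u.
#'   (`prebleach > postbleach >= 0`).
#' @param k Recovery rate, 1/s (>= 0; 0 with a positive mobile fraction
#'   means no recovery within any finite observation).
#' @param mobile_fraction Fraction of the bleached signal that recovers,
#'   in \[0, 1\].
#' @param duration Total trace length, s.
#' @param dt Frame interval, s.
#' @param bleach_time Time of the bleach, s (default `duration / 5`).
#' @param noise_sd Gaussian noise sd, a.u.
#' @param seed Integer seed.
#' @return Object of class `"frap_trace"`: `times`, `intensities`,
#'   `bleach_index` (index of the first post-bleach frame), `normalized`
#'   (NULL until [normalize_frap()]).
#' @export
simulate_frap_trace <- function(prebleach, postbleach, k, mobile_fraction,
                                duration = 300, dt = 1,
                                bleach_time = duration / 5,
                                noise_sd = 0, seed = NULL) {
  if (!(prebleach > postbleach && postbleach >= 0))
    stop_mtdyn("need prebleach > postbleach >= 0")
  if (k < 0) stop_mtdyn("k must be >= 0")
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop_mtdyn("mobile_fraction must be in [0, 1]")
  times <- seq(0, duration, by = dt)
  bleach_index <- which(times >= bleach_time)[1]
  if (is.na(bleach_index) || bleach_index < 2)
    stop_mtdyn("bleach_time must leave at least one pre-bleach frame")
  tp <- times - times[bleach_index]
  I <- ifelse(tp < 0, prebleach,
              postbleach + mobile_fraction * (prebleach - postbleach) *
                (1 - exp(-k * tp)))
  if (noise_sd > 0) {
    post <- which(tp > 0)
    I[post] <- with_seed(seed,
                         I[post] + stats::rnorm(length(post), 0, noise_sd))
  }
  structure(list(times = times, intensities = I,
                 bleach_index = bleach_index, normalized = NULL),
            class = "frap_trace")
}

#' Normalize a FRAP trace to its bleach anchors
#'
#' Normalized intensity = `(I_t - I_post) / (I_pre - I_post)` where `I_pre`
#' is the frame acquired immediately before the bleach and `I_post` the
#' frame acquired immediately after it, so the trace is 1 at `I_pre` and 0
#' at `I_post`. The normalization is invariant under any affine rescaling
#' `a * I + b` (a > 0) of the raw intensities. Optionally `pre_frames > 1`
#' averages that many pre-bleach frames for `I_pre`.
#'
#' @param trace A `frap_trace` (or list with `times`, `intensities`,
#'   `bleach_index`).
#' @param pre_frames Number of pre-bleach frames to average for the
#'   pre-bleach anchor (default 1: the single frame immediately before).
#' @return The trace with `normalized` filled in.
#' @export
normalize_frap <- function(trace, pre_frames = 1) {
  bi <- trace$bleach_index
  if (is.null(bi) || bi < 2) stop_mtdyn("bleach_index must be >= 2")
  I <- trace$intensities
  pre_idx <- max(1, bi - pre_frames):(bi - 1)
  I_pre <- mean(I[pre_idx])
  I_post <- I[bi]
  if (I_pre == I_post) stop_mtdyn("no bleach depth: pre and post levels equal")
  trace$normalized <- (I - I_post) / (I_pre - I_post)
  trace
}

#' Fit single-exponential recovery to a normalized FRAP trace
#'
#' Least-squares fit of `plateau * (1 - exp(-k * t'))` to the post-bleach
#' normalized intensities (`t'` = time since bleach). The half-life is
#' `log(2) / k`. A trace with no appreciable recovery (fitted plateau below
#' `no_recovery_plateau`) is classified as no exchange: the plateau is
#' reported near 0 and `k` is unidentifiable, reported as `NA`.
#'
#' @param trace A normalized `frap_trace` ([normalize_frap()] is applied
#'   when needed).
#' @param no_recovery_plateau Plateau below which recovery is declared
#'   absent (default 0.05).
#' @return Object of class `"frap_fit"`: `k` (1/s), `half_life` (s),
#'   `plateau` (mobile fraction), `no_recovery`, `converged`.
#' @export
fit_recovery <- function(trace, no_recovery_plateau = 0.05) {
  if (is.null(trace$normalized)) trace <- normalize_frap(trace)
  bi <- trace$bleach_index
  tp <- trace$times[bi:length(trace$times)] - trace$times[bi]
  y <- trace$normalized[bi:length(trace$times)]
  if (length(tp) < 5) stop_mtdyn("need >= 5 post-bleach frames")

  plateau0 <- max(mean(utils::tail(y, max(3, length(y) %/% 10))), 1e-3)
  if (plateau0 < no_recovery_plateau) {
    return(structure(list(k = NA_real_, half_life = NA_real_,
                          plateau = plateau0, no_recovery = TRUE,
                          converged = TRUE),
                     class = "frap_fit"))
  }
  half_idx <- which(y >= plateau0 / 2)
  k0 <- if (length(half_idx) > 0 && tp[half_idx[1]] > 0)
    log(2) / tp[half_idx[1]] else 1 / max(tp)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-k * tp)),
                      start = list(A = plateau0, k = k0),
                      lower = c(A = 0, k = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(k = NA_real_, half_life = NA_real_,
                          plateau = NA_real_, no_recovery = FALSE,
                          converged = FALSE),
                     class = "frap_fit"))
  }
  cf <- stats::coef(fit)
  if (cf[["A"]] < no_recovery_plateau) {
    return(structure(list(k = NA_real_, half_life = NA_real_,
                          plateau = cf[["A"]], no_recovery = TRUE,
                          converged = TRUE),
                     class = "frap_fit"))
  }
  structure(list(k = cf[["k"]], half_life = log(2) / cf[["k"]],
                 plateau = cf[["A"]], no_recovery = FALSE,
                 converged = TRUE),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  if (x$no_recovery) {
    cat(sprintf("<frap_fit> no exchange (plateau %.3f)\n", x$plateau))
  } else {
    cat(sprintf("<frap_fit> k = %.4g /s, half-life = %.2f s, mobile fraction = %.3f\n",
                x$k, x$half_life, x$plateau))
  }
  invisible(x)
}

#' @export
plot.frap_trace <- function(x, ...) {
  y <- x$normalized %||% x$intensities
  graphics::plot(x$times, y, type = "l", xlab = "time (s)",
                 ylab = if (is.null(x$normalized)) "intensity (a.u.)"
                        else "normalized intensity", ...)
  graphics::abline(v = x$times[x$bleach_index], lty = 2)
  invisible(x)
}

#' Write / read a FRAP trace as CSV
#'
#' Columns `time_s`, `intensity`; the bleach frame is tagged in a comment
#' line `# bleach_index: <i>` at the top of the file.
#' @param trace A `frap_trace`.
#' @param path File path.
#' @export
write_frap_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# bleach_index: ", trace$bleach_index), con)
  utils::write.csv(data.frame(time_s = trace$times,
                              intensity = trace$intensities),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_csv
#' @export
read_frap_csv <- function(path) {
  first <- readLines(path, n = 1)
  bi <- if (grepl("^# bleach_index:", first))
    as.integer(sub("^# bleach_index:\\s*", "", first)) else NA_integer_
  df <- utils::read.csv(path, comment.char = "#")
  if (is.na(bi)) stop_mtdyn("FRAP CSV lacks a '# bleach_index:' header line")
  structure(list(times = df$time_s, intensities = df$intensity,
                 bleach_index = bi, normalized = NULL),
            class = "frap_trace")
}
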
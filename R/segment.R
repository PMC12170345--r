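#' Classify a phase rate into the four-way dynamic-state scheme
#'
#' Events with growth rates faster than 0.02 and up to 0.5 µm/min are slow
#' growth; faster than 0.5 µm/min, fast growth; shrinkage faster than
#' 0.02 µm/min in magnitude, shrinkage; everything else (|rate| <= 0.02,
#' including both boundaries) is a pause. Boundary convention: a rate of
#' exactly 0.5 is slow growth ("faster than 0.5" is fast); exactly 0.02 or
#' -0.02 is a pause.
#'
#' @param rate Numeric vector of signed rates, µm/min.
#' @param slow_min Lower growth threshold (default 0.02 µm/min).
#' @param fast_min Fast-growth threshold (default 0.5 µm/min).
#' @return Character vector of state labels.
#' @export
classify_phase <- function(rate, slow_min = 0.02, fast_min = 0.5) {
  if (any(is.na(rate)) || any(!is.finite(rate)))
    stop_mtdyn("rate must be finite (no NaN/NA)")
  out <- rep("pause", length(rate))
  out[rate > fast_min] <- "fast_growth"
  out[rate > slow_min & rate <= fast_min] <- "slow_growth"
  out[rate < -slow_min] <- "shrinkage"
  out
}

# Cumulative-sum machinery for O(1) per-segment linear-fit RSS.
segment_rss_fun <- function(t, y) {
  n <- length(t)
  Sx <- c(0, cumsum(t)); Sy <- c(0, cumsum(y))
  Sxx <- c(0, cumsum(t * t)); Sxy <- c(0, cumsum(t * y))
  Syy <- c(0, cumsum(y * y))
  # RSS of OLS line on points a..b (1-based, inclusive); vectorized over a
  function(a, b) {
    m <- b - a + 1
    sx <- Sx[b + 1] - Sx[a]; sy <- Sy[b + 1] - Sy[a]
    sxx <- Sxx[b + 1] - Sxx[a]; sxy <- Sxy[b + 1] - Sxy[a]
    syy <- Syy[b + 1] - Syy[a]
    vxx <- sxx - sx * sx / m
    vxy <- sxy - sx * sy / m
    vyy <- syy - sy * sy / m
    rss <- ifelse(vxx > 0, vyy - vxy * vxy / vxx, vyy)
    pmax(rss, 0)
  }
}

# Optimal partition of 1..n into segments of >= min_len points minimizing
# sum(RSS) + penalty * (number of changepoints). Returns changepoint
# indices: last point of each segment except the final one.
optimal_partition <- function(t, y, penalty, min_len) {
  n <- length(t)
  rss <- segment_rss_fun(t, y)
  F <- rep(Inf, n + 1); F[1] <- 0   # F[b+1] = best cost for points 1..b
  prev <- integer(n + 1)
  for (b in min_len:n) {
    a_cand <- seq_len(b - min_len + 1)
    a_cand <- a_cand[a_cand == 1 | a_cand > min_len]  # both parts >= min_len
    costs <- F[a_cand] + rss(a_cand, b) + ifelse(a_cand > 1, penalty, 0)
    best <- which.min(costs)
    # strict-improvement tie-break: earlier (fewer-segment) candidates win
    F[b + 1] <- costs[best]
    prev[b + 1] <- a_cand[best]
  }
  cps <- integer(0)
  b <- n
  while (b > 0) {
    a <- prev[b + 1]
    if (a > 1) cps <- c(a - 1L, cps)
    b <- a - 1
  }
  list(changepoints = as.integer(cps), cost = F[n + 1])
}

#' Segment a tip trajectory into constant-velocity phases
#'
#' Piecewise-linear fit by penalized least-squares changepoint
#' minimization: the trajectory is partitioned into segments minimizing the
#' total residual sum of squares of per-segment line fits plus
#' `penalty` per changepoint (exact dynamic-programming optimum). Each
#' segment's rate is its least-squares slope converted to µm/min and
#' classified with [classify_phase()]; adjacent segments with identical
#' classified states are merged (rates refitted on the merged span) and
#' segments shorter than `min_duration` are merged into the neighbour with
#' the more similar rate.
#'
#' The default penalty is `6 * sigma^2 * log(n)` with `sigma` estimated
#' robustly from second differences of the positions; it is floored at a
#' small positive value so that noise-free polylines are recovered exactly.
#'
#' @param traj An `mt_trajectory`.
#' @param penalty Changepoint penalty (squared-µm units); `NULL` for the
#'   default described above.
#' @param min_duration Minimum phase duration, s (default `2 * dt`, i.e.
#'   three samples — short enough to resolve the 2-3 frame shrinkage
#'   excursions a full depolymerization produces at 3-s sampling).
#' @param slow_min,fast_min Classification thresholds, µm/min.
#' @return An object of class `"mt_phases"`: data frame with columns
#'   `t_start`, `t_end`, `duration` (s), `rate` (µm/min), `state`,
#'   `is_block`, `end_polarity`.
#' @export
segment_phases <- function(traj, penalty = NULL, min_duration = NULL,
                           slow_min = 0.02, fast_min = 0.5) {
  t <- traj$times; y <- traj$positions
  n <- length(t)
  if (n < 4) stop_mtdyn("need >= 4 samples to segment")
  if (diff(range(t)) == 0) stop_mtdyn("degenerate constant-time input")
  dt <- traj$dt %||% stats::median(diff(t))
  if (is.null(min_duration)) min_duration <- 2 * dt
  if (min_duration < 2 * dt) stop_mtdyn("min_duration must be >= 2 * dt")
  # a segment spanning min_duration seconds has min_duration/dt intervals
  min_len <- max(3L, as.integer(round(min_duration / dt)) + 1L)

  if (is.null(penalty)) {
    sig <- stats::mad(diff(y, differences = 2)) / sqrt(6)
    penalty <- max(6 * sig^2 * log(n), 1e-10)
  }

  part <- optimal_partition(t, y, penalty, min_len)
  bounds <- c(0, part$changepoints, n)   # segment i: points (bounds[i]+1):bounds[i+1]

  # Rate of a segment: least-squares slope. Samples at internal phase
  # boundaries mix the velocities of the two adjacent states (the state
  # switch falls inside a frame interval), so for segments with >= 5
  # points the boundary sample on each interior side is excluded from the
  # fit; 3-4 point segments are used whole.
  seg_fit <- function(a, b) {
    a0 <- a; b0 <- b
    if (b - a + 1 >= 5) {
      if (a > 1) a0 <- a + 1
      if (b < n) b0 <- b - 1
    }
    tt <- t[a0:b0]; yy <- y[a0:b0]
    slope <- if (length(tt) < 2 || stats::var(tt) == 0) 0 else
      stats::cov(tt, yy) / stats::var(tt)
    slope * 60   # µm/s -> µm/min
  }
  starts <- bounds[-length(bounds)] + 1
  ends <- bounds[-1]
  rate <- mapply(seg_fit, starts, ends)
  state <- classify_phase(rate, slow_min, fast_min)

  # merge identical-state neighbours, then undersized segments
  repeat {
    merged <- FALSE
    i <- 1
    while (i < length(starts)) {
      if (state[i] == state[i + 1]) {
        ends[i] <- ends[i + 1]
        starts <- starts[-(i + 1)]; ends <- ends[-(i + 1)]
        rate <- rate[-(i + 1)]; state <- state[-(i + 1)]
        rate[i] <- seg_fit(starts[i], ends[i])
        state[i] <- classify_phase(rate[i], slow_min, fast_min)
        merged <- TRUE
      } else i <- i + 1
    }
    # undersized segments: absorb into the rate-closest neighbour
    dur <- (ends - starts) * dt
    short <- which(dur < min_duration - 1e-9)
    if (length(short) > 0 && length(starts) > 1) {
      i <- short[1]
      nb <- if (i == 1) 2
            else if (i == length(starts)) i - 1
            else if (abs(rate[i - 1] - rate[i]) <= abs(rate[i + 1] - rate[i]))
              i - 1 else i + 1
      lo <- min(i, nb); hi <- max(i, nb)
      ends[lo] <- ends[hi]
      starts <- starts[-hi]; ends <- ends[-hi]
      rate <- rate[-hi]; state <- state[-hi]
      rate[lo] <- seg_fit(starts[lo], ends[lo])
      state[lo] <- classify_phase(rate[lo], slow_min, fast_min)
      merged <- TRUE
    }
    if (!merged) break
  }

  # phases tile the observation window: each phase after the first starts
  # at the preceding boundary sample, so durations sum to the trajectory
  # duration
  start_idx <- c(starts[1], pmax(starts[-1] - 1, 1))
  phases <- data.frame(
    t_start = t[start_idx], t_end = t[ends],
    duration = t[ends] - t[start_idx],
    rate = rate, state = state,
    is_block = FALSE,
    end_polarity = traj$end_polarity %||% "plus",
    stringsAsFactors = FALSE)
  class(phases) <- c("mt_phases", "data.frame")
  attr(phases, "cost") <- part$cost
  attr(phases, "penalty") <- penalty
  attr(phases, "video_length") <- max(t)
  phases
}

#' @export
print.mt_phases <- function(x, ...) {
  cat("<mt_phases> ", nrow(x), " phases over ",
      max(x$t_end) - min(x$t_start), " s\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Mark terminal pauses (blocks)
#'
#' A pause phase that persists to the end of the recording with no
#' subsequent growth is a block: growth was arrested and no regrowth
#' occurred for the remainder of the experiment. Transient pauses followed
#' by growth are not blocks. Block durations are censored by the recording
#' length (600 s for a standard 10-min video), which is therefore the
#' maximum reportable pause/block duration.
#'
#' @param phases An `mt_phases` data frame, time-ordered.
#' @param video_length Recording length, s (default 600).
#' @param tol Slack for "extends to the end", s (default one tenth of the
#'   last phase's duration or 1e-6, whichever is larger — effectively the
#'   phase must end at `video_length`).
#' @return `phases` with `is_block` set.
#' @export
detect_blocks <- function(phases, video_length = 600, tol = 1e-6) {
  if (nrow(phases) == 0) return(phases)
  if (is.unsorted(phases$t_start)) stop_mtdyn("phases must be time-ordered")
  phases$is_block <- FALSE
  last <- nrow(phases)
  if (phases$state[last] == "pause" &&
      phases$t_end[last] >= video_length - tol) {
    phases$is_block[last] <- TRUE
    # censor at the recording length
    phases$t_end[last] <- min(phases$t_end[last], video_length)
    phases$duration[last] <- phases$t_end[last] - phases$t_start[last]
  }
  phases
}
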
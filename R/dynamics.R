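GROWTH_STATES <- c("fast_growth", "slow_growth")

#' Summarize plus-end dynamics over a set of segmented trajectories
#'
#' Pools classified phases across trajectories and computes the standard
#' dynamic-instability statistics:
#' \itemize{
#'   \item per-class rate pools with plain and duration-weighted means and
#'     s.e.m.;
#'   \item percent time per state (total state time / total observed time);
#'   \item transition frequencies, each as events per minute of the time in
#'     which the transition could have occurred: catastrophe
#'     (growth to shrinkage, over total growth time), rescue (shrinkage to
#'     growth, over total shrinkage time), pause entry (any state to pause,
#'     over total non-pause time) and pause exit (pause to growth, over
#'     total pause time);
#'   \item pause and block duration pools.
#' }
#' A frequency whose denominator is zero is reported as `NA` (absent), not
#' as 0. With an `experiment` grouping, per-experiment summaries and their
#' mean-of-means are also returned, matching the convention of reporting
#' averaged means from independent experiments.
#'
#' @param phase_sets A single `mt_phases` object or a list of them (one per
#'   trajectory).
#' @param video_length Recording length, s (default 600).
#' @param experiment Optional vector (length = number of trajectories)
#'   assigning each trajectory to an experiment.
#' @param min_rate_duration Phases shorter than this (s) still count toward
#'   state time and transition events but are excluded from the per-class
#'   rate pools (default 10 s: phases fitted on fewer than four samples at
#'   3-s intervals). A phase at the minimal segmentable length has no
#'   interior sampling interval: its slope is dominated by the boundary
#'   intervals, in which the state switch falls mid-interval and the
#'   velocities of adjacent states mix, so its rate estimate is
#'   structurally biased toward the neighbouring states' rates. Set to 0
#'   to pool every phase.
#' @return An object of class `"dynamics_summary"`.
#' @export
summarize_dynamics <- function(phase_sets, video_length = 600,
                               experiment = NULL, min_rate_duration = 10) {
  if (inherits(phase_sets, "mt_phases")) phase_sets <- list(phase_sets)
  if (length(phase_sets) < 1) stop_mtdyn("need >= 1 trajectory")
  phase_sets <- lapply(phase_sets, detect_blocks, video_length = video_length)
  all_ph <- do.call(rbind, lapply(seq_along(phase_sets), function(i) {
    df <- as.data.frame(phase_sets[[i]])
    df$trajectory <- i
    df
  }))

  time_per_state <- vapply(MT_STATES, function(s)
    sum(all_ph$duration[all_ph$state == s]), numeric(1))
  total_time <- sum(all_ph$duration)
  percent_time <- 100 * time_per_state / total_time

  rate_stats <- lapply(stats::setNames(nm = MT_STATES), function(s) {
    ph <- all_ph[all_ph$state == s &
                   all_ph$duration >= min_rate_duration, ]
    if (nrow(ph) == 0)
      return(list(n = 0L, mean = NA_real_, sem = NA_real_,
                  weighted_mean = NA_real_, rates = numeric(0),
                  durations = numeric(0)))
    w <- ph$duration / sum(ph$duration)
    list(n = nrow(ph),
         mean = mean(ph$rate),
         sem = stats::sd(ph$rate) / sqrt(nrow(ph)),
         weighted_mean = sum(w * ph$rate),
         rates = ph$rate, durations = ph$duration)
  })

  count_transitions <- function(ph) {
    s <- ph$state
    if (length(s) < 2)
      return(c(catastrophe = 0, rescue = 0, pause_entry = 0, pause_exit = 0))
    from <- s[-length(s)]; to <- s[-1]
    c(catastrophe = sum(from %in% GROWTH_STATES & to == "shrinkage"),
      rescue = sum(from == "shrinkage" & to %in% GROWTH_STATES),
      pause_entry = sum(from != "pause" & to == "pause"),
      pause_exit = sum(from == "pause" & to %in% GROWTH_STATES))
  }
  trans_counts <- Reduce(`+`, lapply(phase_sets, count_transitions))

  growth_min <- sum(time_per_state[GROWTH_STATES]) / 60
  shrink_min <- time_per_state[["shrinkage"]] / 60
  pause_min <- time_per_state[["pause"]] / 60
  nonpause_min <- (total_time - time_per_state[["pause"]]) / 60
  freq_of <- function(n, denom) if (denom > 0) n / denom else NA_real_
  transition_frequencies <- c(
    catastrophe = freq_of(trans_counts[["catastrophe"]], growth_min),
    rescue = freq_of(trans_counts[["rescue"]], shrink_min),
    pause_entry = freq_of(trans_counts[["pause_entry"]], nonpause_min),
    pause_exit = freq_of(trans_counts[["pause_exit"]], pause_min))

  pause_durations <- all_ph$duration[all_ph$state == "pause" & !all_ph$is_block]
  block_durations <- pmin(all_ph$duration[all_ph$is_block], video_length)

  per_experiment <- NULL
  if (!is.null(experiment)) {
    if (length(experiment) != length(phase_sets))
      stop_mtdyn("experiment must have one entry per trajectory")
    groups <- split(seq_along(phase_sets), experiment)
    per_experiment <- do.call(rbind, lapply(names(groups), function(g) {
      sub <- summarize_dynamics(phase_sets[groups[[g]]], video_length,
                                min_rate_duration = min_rate_duration)
      data.frame(experiment = g,
                 t(sub$percent_time),
                 t(sub$transition_frequencies),
                 mean_growth_rate =
                   mean(c(sub$rates$fast_growth$rates,
                          sub$rates$slow_growth$rates)),
                 stringsAsFactors = FALSE)
    }))
  }

  structure(
    list(percent_time = percent_time,
         time_per_state = time_per_state,
         total_time = total_time,
         rates = rate_stats,
         transition_frequencies = transition_frequencies,
         n_events = trans_counts,
         pause_durations = pause_durations,
         block_durations = block_durations,
         n_trajectories = length(phase_sets),
         video_length = video_length,
         per_experiment = per_experiment),
    class = "dynamics_summary")
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat("<dynamics_summary> ", x$n_trajectories, " trajectories, ",
      round(x$total_time / 60, 1), " min observed\n", sep = "")
  cat("  percent time:",
      paste(sprintf("%s %.1f%%", names(x$percent_time), x$percent_time),
            collapse = ", "), "\n")
  for (s in MT_STATES) {
    r <- x$rates[[s]]
    if (r$n > 0)
      cat(sprintf("  %s: n = %d, rate = %.3f +/- %.3f um/min (weighted %.3f)\n",
                  s, r$n, r$mean, r$sem, r$weighted_mean))
  }
  tf <- x$transition_frequencies
  cat("  transitions (min^-1):",
      paste(sprintf("%s %s", names(tf),
                    ifelse(is.na(tf), "absent", sprintf("%.3f", tf))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Duration-weighted growth-rate histogram
#'
#' Each growth phase contributes its duration divided by the total growth
#' time as weight to the bin containing its rate, so weights sum to 1. The
#' cumulative curve is the running weight sum over rate-sorted phases.
#'
#' @param phases An `mt_phases` data frame (possibly pooled across
#'   trajectories), or a list of them.
#' @param bin_edges Numeric bin edges, µm/min; default covers the observed
#'   range with 0.1 µm/min bins.
#' @return List with `histogram` (data frame: `bin_lo`, `bin_hi`, `weight`)
#'   and `cumulative` (data frame: `rate`, `cum_weight`).
#' @export
weighted_rate_histogram <- function(phases, bin_edges = NULL) {
  if (is.list(phases) && !is.data.frame(phases))
    phases <- do.call(rbind, lapply(phases, as.data.frame))
  g <- phases[phases$state %in% GROWTH_STATES, ]
  if (nrow(g) == 0) stop_mtdyn("no growth events")
  w <- g$duration / sum(g$duration)
  if (is.null(bin_edges)) {
    lo <- floor(min(g$rate) / 0.1) * 0.1
    hi <- ceiling(max(g$rate) / 0.1) * 0.1
    if (hi <= lo) hi <- lo + 0.1
    bin_edges <- seq(lo, hi, by = 0.1)
  }
  idx <- findInterval(g$rate, bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  weight <- vapply(seq_len(length(bin_edges) - 1),
                   function(b) sum(w[idx == b]), numeric(1))
  ord <- order(g$rate)
  list(histogram = data.frame(bin_lo = bin_edges[-length(bin_edges)],
                              bin_hi = bin_edges[-1],
                              weight = weight),
       cumulative = data.frame(rate = g$rate[ord],
                               cum_weight = cumsum(w[ord])))
}
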
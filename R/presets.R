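#' Dynamic-state labels used throughout the package
#'
#' Order is fixed: fast growth, slow growth, pause, shrinkage.
#' @export
MT_STATES <- c("fast_growth", "slow_growth", "pause", "shrinkage")

#' Construct a condition preset for the trajectory generator
#'
#' A preset bundles the generative parameters of one experimental condition:
#' per-state mean velocities and per-step velocity noise, a matrix of
#' per-minute transition hazards between states, and the seed-blocking
#' behaviour (whether a shrinkage excursion that reaches the stabilized seed
#' at position 0 enters a terminal pause, i.e. a block).
#'
#' @param name Label for the condition.
#' @param states Character vector, subset of [MT_STATES].
#' @param velocity_mean Named numeric, µm/min, signed (negative for
#'   shrinkage, 0 for pause). Names must equal `states`.
#' @param velocity_sd Named numeric, µm/min, per-sampling-step Gaussian
#'   velocity noise within a state.
#' @param transition_rates Square numeric matrix of per-minute hazards,
#'   dimnames `states` x `states`, zero diagonal.
#' @param initial_state State the trajectory starts in.
#' @param block_at_seed_prob Probability in \[0, 1\] that shrinkage reaching
#'   position 0 enters a terminal pause rather than regrowing.
#' @param terminal_block If `TRUE`, a pause state, once entered, is never
#'   exited (CEP104-style block).
#' @param regrow_state State entered when shrinkage reaches the seed and the
#'   end is not blocked; defaults to `initial_state`.
#' @param reference Optional list with elements `rate` (the printed rate the
#'   preset encodes, µm/min, signed), `sem` (its printed standard error),
#'   `state` (the generative state carrying it) and `citation` (free-text
#'   source string).
#' @return An object of class `"mt_preset"`.
#' @export
condition_preset <- function(name, states, velocity_mean, velocity_sd,
                             transition_rates, initial_state,
                             block_at_seed_prob = 0,
                             terminal_block = FALSE,
                             regrow_state = initial_state,
                             reference = NULL) {
  states <- match.arg(states, MT_STATES, several.ok = TRUE)
  if (!all(states %in% names(velocity_mean)) ||
      !all(states %in% names(velocity_sd)))
    stop_mtdyn("velocity_mean and velocity_sd must be named for every state")
  velocity_mean <- velocity_mean[states]
  velocity_sd <- velocity_sd[states]
  if (!is.matrix(transition_rates) ||
      nrow(transition_rates) != length(states) ||
      ncol(transition_rates) != length(states))
    stop_mtdyn("transition_rates must be a ", length(states), "x",
               length(states), " matrix")
  dimnames(transition_rates) <- list(states, states)
  if (any(diag(transition_rates) != 0))
    stop_mtdyn("diagonal of transition_rates must be 0")
  if (any(transition_rates < 0)) stop_mtdyn("hazard rates must be >= 0")
  if (any(velocity_sd < 0)) stop_mtdyn("velocity_sd must be >= 0")
  if ("pause" %in% states && velocity_mean[["pause"]] != 0)
    stop_mtdyn("pause velocity_mean must be 0")
  if ("shrinkage" %in% states && velocity_mean[["shrinkage"]] >= 0)
    stop_mtdyn("shrinkage velocity_mean must be negative")
  if (block_at_seed_prob < 0 || block_at_seed_prob > 1)
    stop_mtdyn("block_at_seed_prob must be in [0, 1]")
  initial_state <- match.arg(initial_state, states)
  regrow_state <- match.arg(regrow_state, states)
  structure(
    list(name = name, states = states,
         velocity_mean = velocity_mean, velocity_sd = velocity_sd,
         transition_rates = transition_rates,
         initial_state = initial_state,
         block_at_seed_prob = block_at_seed_prob,
         terminal_block = terminal_block,
         regrow_state = regrow_state,
         reference = reference),
    class = "mt_preset")
}

#' @export
print.mt_preset <- function(x, ...) {
  cat("<mt_preset> ", x$name, "\n", sep = "")
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  cat("  velocity_mean (um/min):",
      paste(sprintf("%s=%g", x$states, x$velocity_mean), collapse = ", "),
      "\n")
  cat("  block_at_seed_prob:", x$block_at_seed_prob,
      " terminal_block:", x$terminal_block, "\n")
  if (!is.null(x$reference))
    cat("  reference rate:", x$reference$rate, "um/min [",
        x$reference$citation, "]\n")
  invisible(x)
}

# helper: hazard matrix from a named list of "from->to" = rate (per minute)
hazards <- function(states, ...) {
  m <- matrix(0, length(states), length(states),
              dimnames = list(states, states))
  rates <- list(...)
  for (key in names(rates)) {
    ft <- strsplit(key, "\\.\\.")[[1]]
    m[ft[1], ft[2]] <- rates[[key]]
  }
  m
}

#' Built-in condition presets
#'
#' A catalogue of generative parameter sets encoding the plus-end dynamics
#' of the reconstituted ciliary-tip-module (CTM) conditions. Mean velocities
#' are the published rates for each condition; transition hazards are
#' package defaults chosen so the simulated time-per-state composition
#' matches each condition qualitatively (the source experiments report
#' state percentages, not hazards). Each preset carries its printed
#' reference rate and a citation string.
#'
#' Conditions:
#' \describe{
#'   \item{eb3_alone}{EB3-only control: fast growth with catastrophes and
#'     full depolymerization back to the seed at 36.91 µm/min.}
#'   \item{control_shrink}{Uninhibited control tuned to produce many
#'     complete shrinkage excursions (same 36.91 µm/min depolymerization).}
#'   \item{cep104_block}{CEP104: growth arrested by a terminal block; no
#'     regrowth for the remainder of the recording.}
#'   \item{togaram1}{TOGARAM1 alone: processive growth at 2.27 µm/min.}
#'   \item{cep104_togaram1}{CEP104 + TOGARAM1: very slow growth at
#'     0.12 µm/min interrupted by transient pauses.}
#'   \item{full_ctm}{All five CTM proteins: slow processive growth at
#'     0.19 µm/min with occasional pausing, no catastrophes.}
#'   \item{minimal_trio}{CEP104 + CSPP1 + TOGARAM1 at reduced pausing-factor
#'     concentration: slow growth episodes at 0.022 µm/min.}
#'   \item{ccdc66_cep104_shrink}{CEP104 + CCDC66: shrinkage slowed to
#'     0.12 µm/min in magnitude.}
#' }
#'
#' @return Named list of [condition_preset()] objects.
#' @export
builtin_presets <- function() {
  eb3 <- condition_preset(
    "eb3_alone",
    states = c("fast_growth", "shrinkage"),
    velocity_mean = c(fast_growth = 2.5, shrinkage = -36.91),
    velocity_sd = c(fast_growth = 0.6, shrinkage = 2.0),
    transition_rates = hazards(c("fast_growth", "shrinkage"),
                               fast_growth..shrinkage = 0.15,
                               shrinkage..fast_growth = 0.1),
    initial_state = "fast_growth",
    reference = list(rate = -36.91, sem = 1.34, state = "shrinkage",
                     citation = "control depolymerization 36.91 +/- 1.34 um/min"))

  control_shrink <- condition_preset(
    "control_shrink",
    states = c("fast_growth", "shrinkage"),
    velocity_mean = c(fast_growth = 2.5, shrinkage = -36.91),
    velocity_sd = c(fast_growth = 0.6, shrinkage = 2.0),
    transition_rates = hazards(c("fast_growth", "shrinkage"),
                               fast_growth..shrinkage = 0.15,
                               shrinkage..fast_growth = 0.05),
    initial_state = "fast_growth",
    reference = list(rate = -36.91, sem = 1.34, state = "shrinkage",
                     citation = "control depolymerization 36.91 +/- 1.34 um/min"))

  cep104_block <- condition_preset(
    "cep104_block",
    states = c("fast_growth", "pause"),
    velocity_mean = c(fast_growth = 2.0, pause = 0),
    velocity_sd = c(fast_growth = 0.6, pause = 0.05),
    transition_rates = hazards(c("fast_growth", "pause"),
                               fast_growth..pause = 0.5),
    initial_state = "fast_growth",
    block_at_seed_prob = 1,
    terminal_block = TRUE,
    reference = list(rate = 0, sem = 0, state = "pause",
                     citation = "CEP104 blocks plus-end growth; no regrowth for the remainder of the experiment"))

  togaram1 <- condition_preset(
    "togaram1",
    states = c("slow_growth", "shrinkage"),
    velocity_mean = c(slow_growth = 2.27, shrinkage = -36.91),
    velocity_sd = c(slow_growth = 0.5, shrinkage = 2.0),
    transition_rates = hazards(c("slow_growth", "shrinkage"),
                               slow_growth..shrinkage = 0.15,
                               shrinkage..slow_growth = 0.3),
    initial_state = "slow_growth",
    reference = list(rate = 2.27, sem = 0.02, state = "slow_growth",
                     citation = "TOGARAM1 alone growth 2.27 +/- 0.02 um/min"))

  cep104_togaram1 <- condition_preset(
    "cep104_togaram1",
    states = c("slow_growth", "pause"),
    velocity_mean = c(slow_growth = 0.12, pause = 0),
    velocity_sd = c(slow_growth = 0.04, pause = 0.03),
    transition_rates = hazards(c("slow_growth", "pause"),
                               slow_growth..pause = 0.4,
                               pause..slow_growth = 1.2),
    initial_state = "slow_growth",
    reference = list(rate = 0.12, sem = 0.01, state = "slow_growth",
                     citation = "CEP104+TOGARAM1 slow polymerization 0.12 +/- 0.01 um/min"))

  full_ctm <- condition_preset(
    "full_ctm",
    states = c("slow_growth", "pause"),
    velocity_mean = c(slow_growth = 0.19, pause = 0),
    velocity_sd = c(slow_growth = 0.04, pause = 0.03),
    transition_rates = hazards(c("slow_growth", "pause"),
                               slow_growth..pause = 0.2,
                               pause..slow_growth = 1.5),
    initial_state = "slow_growth",
    reference = list(rate = 0.19, sem = 0.04, state = "slow_growth",
                     citation = "full CTM slow processive growth 0.19 +/- 0.04 um/min"))

  minimal_trio <- condition_preset(
    "minimal_trio",
    states = c("slow_growth", "pause"),
    velocity_mean = c(slow_growth = 0.022, pause = 0),
    velocity_sd = c(slow_growth = 0.01, pause = 0.01),
    transition_rates = hazards(c("slow_growth", "pause"),
                               slow_growth..pause = 0.3,
                               pause..slow_growth = 1.0),
    initial_state = "slow_growth",
    reference = list(rate = 0.022, sem = 0.01, state = "slow_growth",
                     citation = "CEP104+CSPP1+TOGARAM1 slow growth 0.022 +/- 0.01 um/min"))

  ccdc66_cep104 <- condition_preset(
    "ccdc66_cep104_shrink",
    states = c("fast_growth", "shrinkage"),
    velocity_mean = c(fast_growth = 2.0, shrinkage = -0.12),
    velocity_sd = c(fast_growth = 0.6, shrinkage = 0.04),
    transition_rates = hazards(c("fast_growth", "shrinkage"),
                               fast_growth..shrinkage = 0.4,
                               shrinkage..fast_growth = 0.4),
    initial_state = "fast_growth",
    reference = list(rate = -0.12, sem = 0.02, state = "shrinkage",
                     citation = "CEP104+CCDC66 shrinkage slowed to 0.12 +/- 0.02 um/min"))

  list(eb3_alone = eb3,
       control_shrink = control_shrink,
       cep104_block = cep104_block,
       togaram1 = togaram1,
       cep104_togaram1 = cep104_togaram1,
       full_ctm = full_ctm,
       minimal_trio = minimal_trio,
       ccdc66_cep104_shrink = ccdc66_cep104)
}
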
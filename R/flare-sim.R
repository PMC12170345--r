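#' Default generative parameters for protofilament end models
#'
#' Flared (control, EB3-like) ends have long, strongly curved
#' protofilament flares with ragged wall exits; corked (CTM-like) ends have
#' shorter, less curved flares and a more even wall edge, the directional
#' differences seen between free and corked plus ends. Curvature defaults
#' correspond to ram's-horn arc radii of roughly 20 nm (flared) and 30 nm
#' (corked).
#'
#' @param corked Logical.
#' @return List of generative parameters (all lengths nm, curvature
#'   deg/nm).
#' @export
pf_end_params <- function(corked = FALSE) {
  if (corked)
    list(wall_radius = 11, wall_length = 40,
         flare_length_mean = 8, flare_length_sd = 3,
         curvature_mean = 1.8, curvature_sd = 0.4,
         raggedness_sd = 4, azimuth_jitter = 4, step = 2)
  else
    list(wall_radius = 11, wall_length = 40,
         flare_length_mean = 25, flare_length_sd = 10,
         curvature_mean = 2.86, curvature_sd = 0.5,
         raggedness_sd = 8, azimuth_jitter = 4, step = 2)
}

#' Simulate a traced microtubule end
#'
#' Builds `n_pf` protofilament polylines (root to tip, nm) around a
#' cylindrical wall: protofilaments sit at azimuths `360 / n_pf` degrees
#' apart with a uniform jitter of at most ±`azimuth_jitter` degrees; each
#' runs straight along the microtubule axis from `-wall_length` to a wall
#' exit whose axial position is drawn with sd `raggedness_sd`, then curls
#' outward as a planar circular arc (in the plane containing the axis and
#' the protofilament's radial direction) of drawn length and curvature. A
#' drawn flare length of zero (negative draws are clipped, with a warning)
#' gives a blunt protofilament; blunt traces keep at least three points,
#' the last two one sampling step apart.
#'
#' @param corked Logical; selects [pf_end_params()] defaults.
#' @param n_pf Number of protofilaments (>= 3; typically 13-14).
#' @param params Generative parameter list, see [pf_end_params()].
#' @param mt_id Identifier attached to the model.
#' @param seed Integer seed.
#' @return Object of class `"pf_end"`: `traces` (list of n x 3 matrices),
#'   `axis` (unit vector, here +z), `n_pf`, `corked`, `mt_id`, `params`,
#'   `truth` (data frame: `pf`, `azimuth_deg`, `wall_exit_z`,
#'   `flare_length`, `curvature`).
#' @export
simulate_protofilament_end <- function(corked = FALSE, n_pf = 13,
                                       params = pf_end_params(corked),
                                       mt_id = 1, seed = NULL) {
  if (n_pf < 3) stop_mtdyn("n_pf must be >= 3")
  with_seed(seed, {
    base_az <- (seq_len(n_pf) - 1) * 360 / n_pf
    az <- base_az + stats::runif(n_pf, -params$azimuth_jitter,
                                 params$azimuth_jitter)
    exit_z <- stats::rnorm(n_pf, 0, params$raggedness_sd)
    flare_len <- stats::rnorm(n_pf, params$flare_length_mean,
                              params$flare_length_sd)
    if (any(flare_len < 0)) {
      warning(sum(flare_len < 0),
              " negative flare lengths clipped at 0", call. = FALSE)
      flare_len[flare_len < 0] <- 0
    }
    curv <- pmax(stats::rnorm(n_pf, params$curvature_mean,
                              params$curvature_sd), 0.05)

    traces <- vector("list", n_pf)
    for (i in seq_len(n_pf)) {
      th <- rad(az[i])
      radial <- c(cos(th), sin(th), 0)
      origin <- params$wall_radius * radial
      # straight wall run along +z
      z_wall <- seq(-params$wall_length, exit_z[i], by = params$step)
      if (length(z_wall) < 2 ||
          z_wall[length(z_wall)] < exit_z[i] - 1e-9)
        z_wall <- unique(c(z_wall, exit_z[i]))
      pts <- t(vapply(z_wall, function(z) origin + c(0, 0, z), numeric(3)))
      exit_pt <- origin + c(0, 0, exit_z[i])
      if (flare_len[i] > 0) {
        rho <- 1 / rad(curv[i])            # arc radius, nm
        s <- if (flare_len[i] <= params$step) flare_len[i]
             else unique(c(seq(params$step, flare_len[i],
                               by = params$step), flare_len[i]))
        arc <- t(vapply(s, function(ss) {
          phi <- ss / rho
          exit_pt + rho * sin(phi) * c(0, 0, 1) +
            rho * (1 - cos(phi)) * radial
        }, numeric(3)))
        pts <- rbind(pts, arc)
      }
      # blunt third-point rule: keep >= 3 points ending one step apart
      if (nrow(pts) < 3) {
        extra <- exit_pt - c(0, 0, params$step)
        pts <- rbind(pts[1, , drop = FALSE], extra,
                     pts[nrow(pts), , drop = FALSE])
      }
      colnames(pts) <- c("x", "y", "z")
      traces[[i]] <- pts
    }
    structure(
      list(traces = traces, axis = c(0, 0, 1), n_pf = n_pf,
           corked = corked, mt_id = mt_id, params = params,
           truth = data.frame(pf = seq_len(n_pf), azimuth_deg = az,
                              wall_exit_z = exit_z,
                              flare_length = flare_len,
                              curvature = curv)),
      class = "pf_end")
  })
}

#' @export
print.pf_end <- function(x, ...) {
  cat("<pf_end> MT ", x$mt_id, ": ", x$n_pf, " protofilaments, ",
      if (x$corked) "corked" else "flared", "\n", sep = "")
  invisible(x)
}
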
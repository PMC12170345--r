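#' Write / read protofilament contours in the package plain-text format
#'
#' Format, one microtubule after another:
#' \preformatted{
#' MT <id> <n_pf> <polarity>
#' PF <id>
#' <x_nm> <y_nm> <z_nm>
#' ...
#' }
#' Points are ordered root (inside the wall) to tip.
#'
#' @param ends A `pf_end` object or list of them.
#' @param path File path.
#' @export
write_contours <- function(ends, path) {
  if (inherits(ends, "pf_end")) ends <- list(ends)
  con <- file(path, "w")
  on.exit(close(con))
  for (e in ends) {
    writeLines(sprintf("MT %s %d %s", e$mt_id, length(e$traces),
                       e$polarity %||% "plus"), con)
    for (i in seq_along(e$traces)) {
      writeLines(sprintf("PF %d", i), con)
      m <- e$traces[[i]]
      writeLines(sprintf("%.6g %.6g %.6g", m[, 1], m[, 2], m[, 3]), con)
    }
  }
  invisible(path)
}

#' @rdname write_contours
#' @return `read_contours`: list of `pf_end`-like lists, each with
#'   `mt_id`, `polarity`, `traces` (list of n x 3 matrices).
#' @export
read_contours <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  if (length(lines) == 0 || all(lines == ""))
    stop_mtdyn("empty contour file: ", path)
  ends <- list()
  cur_mt <- NULL; cur_pf <- NULL; cur_pts <- NULL
  flush_pf <- function() {
    if (is.null(cur_pf)) return()
    if (is.null(cur_pts) || nrow(cur_pts) < 2)
      stop_mtdyn("protofilament ", cur_pf, " of MT ", cur_mt$mt_id,
                 " has fewer than 2 points")
    cur_mt$traces[[length(cur_mt$traces) + 1]] <<- cur_pts
    cur_pf <<- NULL; cur_pts <<- NULL
  }
  flush_mt <- function() {
    flush_pf()
    if (!is.null(cur_mt)) ends[[length(ends) + 1]] <<- cur_mt
    cur_mt <<- NULL
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (line == "") next
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "MT") {
      flush_mt()
      if (length(tok) < 4)
        stop_mtdyn("malformed MT header at line ", ln, ": ", line)
      cur_mt <- list(mt_id = tok[2], n_pf = as.integer(tok[3]),
                     polarity = tok[4], traces = list())
    } else if (tok[1] == "PF") {
      if (is.null(cur_mt))
        stop_mtdyn("PF record before any MT header at line ", ln)
      flush_pf()
      cur_pf <- tok[2]
      cur_pts <- matrix(numeric(0), 0, 3,
                        dimnames = list(NULL, c("x", "y", "z")))
    } else {
      xyz <- suppressWarnings(as.numeric(tok))
      if (length(xyz) != 3 || any(is.na(xyz)))
        stop_mtdyn("non-numeric coordinate line at line ", ln,
                   " (last good line: ", ln - 1, "): ", line)
      if (is.null(cur_pf))
        stop_mtdyn("coordinate line outside a PF block at line ", ln)
      cur_pts <- rbind(cur_pts, xyz)
    }
  }
  flush_mt()
  if (length(ends) == 0) stop_mtdyn("no MT records in ", path)
  lapply(ends, function(e) { class(e) <- "pf_end"; e })
}

#' Estimate the microtubule axis from in-wall trace roots
#'
#' The root of every trace lies inside the microtubule wall, where
#' protofilaments run parallel to the axis, so the axis is estimated as
#' the mean of the per-trace root-segment directions (first to `n_root`-th
#' point), oriented root to tip.
#'
#' @param traces List of n x 3 matrices.
#' @param n_root Root points per trace spanning the direction estimate
#'   (default 3).
#' @return Unit 3-vector.
#' @export
estimate_axis <- function(traces, n_root = 3) {
  dirs <- t(vapply(traces, function(m) {
    j <- min(n_root, nrow(m))
    unit_vector(m[j, ] - m[1, ])
  }, numeric(3)))
  unit_vector(colMeans(dirs))
}

#' Find the wall-exit point of a protofilament trace
#'
#' Returns the first index `k` such that the segment direction from point
#' `k` to `k + 1` deviates from the microtubule axis by more than
#' `straightness_tol` degrees — the first point that deviates from being
#' completely straight. If no segment deviates the trace is fully blunt and
#' the last index is returned.
#'
#' @param trace n x 3 matrix, root to tip, nm.
#' @param mt_axis Unit 3-vector.
#' @param straightness_tol Degrees (default 10).
#' @return Integer index into the trace rows.
#' @export
find_wall_exit <- function(trace, mt_axis, straightness_tol = 10) {
  if (nrow(trace) < 3) stop_mtdyn("trace needs >= 3 points")
  mt_axis <- unit_vector(mt_axis)
  segs <- diff(trace)
  lens <- sqrt(rowSums(segs^2))
  if (any(lens == 0)) stop_mtdyn("consecutive duplicate points in trace")
  cosang <- pmin(1, pmax(-1, (segs %*% mt_axis) / lens))
  ang <- deg(acos(cosang))
  dev <- which(ang > straightness_tol)
  if (length(dev) == 0) nrow(trace) else dev[1]
}

#' Flared length of a protofilament
#'
#' Protofilament length measured from the last segment within the wall to
#' the tip: the summed Euclidean segment lengths from the start of the
#' segment ending at the wall-exit point through the final point. A blunt
#' trace (wall exit at the last point) therefore reports the length of its
#' final in-wall segment — one sampling step under the blunt third-point
#' convention.
#'
#' @param trace n x 3 matrix.
#' @param wall_exit_index Index from [find_wall_exit()].
#' @return Length, nm.
#' @export
flared_length <- function(trace, wall_exit_index) {
  k <- wall_exit_index
  if (k < 1 || k > nrow(trace)) stop_mtdyn("invalid wall_exit_index")
  a <- max(1, k - 1)
  segs <- diff(trace[a:nrow(trace), , drop = FALSE])
  sum(sqrt(rowSums(segs^2)))
}

#' Local curvature along a protofilament flare
#'
#' At each interior vertex of the flare (points beyond the wall exit), the
#' curvature is the turning angle between the adjacent segments, in
#' degrees, divided by the mean of the two adjacent segment lengths. For a
#' polyline inscribed in a circle of radius R this converges to
#' `(180 / pi) / R` deg/nm as the discretization refines.
#'
#' @param trace n x 3 matrix.
#' @param wall_exit_index Index from [find_wall_exit()].
#' @return List with `values` (deg/nm, one per interior flare vertex) and
#'   `mean`; both `NA` when the flare has fewer than 3 points.
#' @export
local_curvature <- function(trace, wall_exit_index) {
  k <- wall_exit_index
  flare <- trace[k:nrow(trace), , drop = FALSE]
  if (nrow(flare) < 3)
    return(list(values = NA_real_, mean = NA_real_))
  segs <- diff(flare)
  lens <- sqrt(rowSums(segs^2))
  vals <- vapply(seq_len(nrow(segs) - 1), function(i) {
    u <- segs[i, ] / lens[i]; v <- segs[i + 1, ] / lens[i + 1]
    ang <- deg(acos(pmin(1, pmax(-1, sum(u * v)))))
    ang / mean(lens[c(i, i + 1)])
  }, numeric(1))
  list(values = vals, mean = mean(vals))
}

#' Raggedness of a microtubule end
#'
#' The sample standard deviation (n - 1 denominator) of the axial
#' coordinates of the per-protofilament wall-exit points, after projection
#' onto the microtubule axis.
#'
#' @param exit_points m x 3 matrix of wall-exit points (>= 3
#'   protofilaments).
#' @param mt_axis Unit 3-vector.
#' @return Raggedness, nm; `NA` if fewer than 3 protofilaments.
#' @export
raggedness <- function(exit_points, mt_axis) {
  if (is.null(dim(exit_points)) || nrow(exit_points) < 3)
    return(NA_real_)
  ax <- unit_vector(mt_axis)
  stats::sd(as.vector(exit_points %*% ax))
}

#' Per-protofilament and per-MT flare geometry of one traced end
#'
#' Applies [find_wall_exit()], [flared_length()] and [local_curvature()]
#' to every protofilament and aggregates: per-MT flared-length s.d.,
#' raggedness, and the unweighted mean of per-protofilament mean
#' curvatures. All metrics are invariant under rigid rotation and
#' translation of the whole end.
#'
#' @param traces A `pf_end` object or list of n x 3 matrices (>= 3).
#' @param mt_axis Unit 3-vector, or `NULL` to estimate with
#'   [estimate_axis()].
#' @param straightness_tol Degrees (default 10).
#' @param polarity Supplied polarity label (default "plus").
#' @return Object of class `"mt_end_geometry"`: `per_pf` data frame
#'   (`pf`, `wall_exit_index`, `wall_exit_axial`, `flared_length`,
#'   `mean_curvature`), and per-MT scalars `length_sd`, `raggedness`,
#'   `mean_curvature`, `n_pf`, `polarity`, `corked`.
#' @export
summarize_end <- function(traces, mt_axis = NULL, straightness_tol = 10,
                          polarity = "plus") {
  corked <- NA
  mt_id <- NA
  if (inherits(traces, "pf_end")) {
    corked <- traces$corked %||% NA
    mt_id <- traces$mt_id %||% NA
    if (!is.null(traces$axis) && is.null(mt_axis)) mt_axis <- traces$axis
    polarity <- traces$polarity %||% polarity
    traces <- traces$traces
  }
  if (length(traces) < 3) stop_mtdyn("need >= 3 protofilament traces")
  if (is.null(mt_axis)) mt_axis <- estimate_axis(traces)
  mt_axis <- unit_vector(mt_axis)

  k <- vapply(traces, find_wall_exit, integer(1),
              mt_axis = mt_axis, straightness_tol = straightness_tol)
  exit_pts <- t(vapply(seq_along(traces), function(i)
    traces[[i]][k[i], ], numeric(3)))
  lens <- vapply(seq_along(traces), function(i)
    flared_length(traces[[i]], k[i]), numeric(1))
  curv <- vapply(seq_along(traces), function(i)
    local_curvature(traces[[i]], k[i])$mean, numeric(1))

  per_pf <- data.frame(pf = seq_along(traces),
                       wall_exit_index = k,
                       wall_exit_axial = as.vector(exit_pts %*% mt_axis),
                       flared_length = lens,
                       mean_curvature = curv)
  structure(
    list(per_pf = per_pf,
         length_sd = stats::sd(lens),
         raggedness = raggedness(exit_pts, mt_axis),
         mean_curvature = mean(curv, na.rm = TRUE),
         n_pf = length(traces),
         mt_id = mt_id, polarity = polarity, corked = corked,
         axis = mt_axis),
    class = "mt_end_geometry")
}

#' @export
print.mt_end_geometry <- function(x, ...) {
  cat("<mt_end_geometry> ", x$n_pf, " protofilaments\n", sep = "")
  cat(sprintf("  median flared length: %.1f nm, length sd: %.2f nm\n",
              stats::median(x$per_pf$flared_length), x$length_sd))
  cat(sprintf("  mean local curvature: %.3f deg/nm, raggedness: %.2f nm\n",
              x$mean_curvature, x$raggedness))
  invisible(x)
}

#' Summarize a batch of traced ends into per-pf and per-MT tables
#'
#' @param ends List of `pf_end` objects (or trace lists).
#' @param ... Passed to [summarize_end()].
#' @return List with `per_pf` and `per_mt` data frames, each carrying an
#'   `mt` column (and `corked` when known).
#' @export
summarize_ends <- function(ends, ...) {
  geoms <- lapply(ends, summarize_end, ...)
  per_pf <- do.call(rbind, lapply(seq_along(geoms), function(i) {
    df <- geoms[[i]]$per_pf
    df$mt <- i
    df$corked <- geoms[[i]]$corked
    df
  }))
  per_mt <- do.call(rbind, lapply(seq_along(geoms), function(i) {
    g <- geoms[[i]]
    data.frame(mt = i, n_pf = g$n_pf, length_sd = g$length_sd,
               raggedness = g$raggedness, mean_curvature = g$mean_curvature,
               median_length = stats::median(g$per_pf$flared_length),
               corked = g$corked)
  }))
  list(per_pf = per_pf, per_mt = per_mt)
}
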
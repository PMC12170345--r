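#' Rank-based group comparisons
#'
#' Two groups: two-sided Mann-Whitney U test (exact when sample sizes
#' permit and there are no ties, normal approximation otherwise). Three or
#' more groups: Kruskal-Wallis H test followed by Dunn's post hoc pairwise
#' z-tests on the joint ranks (with tie correction), either all pairs or
#' every group versus a stated control, with multiplicity adjustment
#' (Holm by default).
#'
#' @param values Numeric vector of observations.
#' @param group Factor or vector of group labels, same length.
#' @param control Optional control group label; Dunn comparisons are then
#'   restricted to control-vs-other.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()]
#'   (default "holm").
#' @return Object of class `"group_comparison"`: for two groups, fields
#'   `method`, `statistic` (U), `p_value`; for more, `method`, `statistic`
#'   (H), `df`, `p_value` and a `posthoc` data frame (`group1`, `group2`,
#'   `z`, `p_unadjusted`, `p_adjusted`).
#' @export
compare_groups <- function(values, group, control = NULL,
                           p_adjust = "holm") {
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2) stop_mtdyn("need >= 2 groups")
  if (any(tapply(values, group, length) < 1)) stop_mtdyn("empty group")

  if (all(values == values[1])) {
    # no variation anywhere: nothing to detect
    out <- list(method = if (k == 2) "Mann-Whitney" else "Kruskal-Wallis",
                statistic = 0, df = if (k == 2) NULL else k - 1,
                p_value = 1, posthoc = NULL, groups = levels(group))
    class(out) <- "group_comparison"
    return(out)
  }

  if (k == 2) {
    lv <- levels(group)
    wt <- suppressWarnings(
      stats::wilcox.test(values[group == lv[1]], values[group == lv[2]],
                         alternative = "two.sided"))
    out <- list(method = "Mann-Whitney", statistic = unname(wt$statistic),
                p_value = wt$p.value, posthoc = NULL, groups = lv)
    class(out) <- "group_comparison"
    return(out)
  }

  kw <- stats::kruskal.test(values, group)
  posthoc <- dunn_test(values, group, control = control,
                       p_adjust = p_adjust)
  out <- list(method = "Kruskal-Wallis + Dunn",
              statistic = unname(kw$statistic),
              df = unname(kw$parameter),
              p_value = kw$p.value,
              posthoc = posthoc, groups = levels(group))
  class(out) <- "group_comparison"
  out
}

#' Dunn's post hoc test on joint ranks
#'
#' Pairwise z statistics after a Kruskal-Wallis test:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) * (1/n_i + 1/n_j))` where
#' `Rbar` are mean joint ranks and `T = sum(t^3 - t) / (12 (N - 1))` is the
#' tie correction over tie-group sizes `t`. Two-sided p-values from the
#' normal distribution, adjusted for multiplicity.
#'
#' @inheritParams compare_groups
#' @return Data frame: `group1`, `group2`, `z`, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
dunn_test <- function(values, group, control = NULL, p_adjust = "holm") {
  group <- factor(group)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, group, mean)
  n <- tapply(r, group, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(group)
  pairs <- utils::combn(lv, 2)
  if (!is.null(control)) {
    if (!control %in% lv) stop_mtdyn("control group not found")
    keep <- pairs[1, ] == control | pairs[2, ] == control
    pairs <- pairs[, keep, drop = FALSE]
  }
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
               (1 / n[[p[1]]] + 1 / n[[p[2]]]))
    if (se == 0) return(0)
    (rbar[[p[1]]] - rbar[[p[2]]]) / se
  })
  p_un <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_unadjusted = p_un,
             p_adjusted = stats::p.adjust(p_un, method = p_adjust),
             stringsAsFactors = FALSE)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$method, "\n", sep = "")
  if (x$method == "Mann-Whitney") {
    cat(sprintf("  U = %g, two-sided p = %.4g\n", x$statistic, x$p_value))
  } else {
    cat(sprintf("  H = %.4g (df = %s), p = %.4g\n", x$statistic,
                x$df %||% NA, x$p_value))
    if (!is.null(x$posthoc)) {
      cat("  Dunn post hoc:\n")
      print(x$posthoc, row.names = FALSE)
    }
  }
  invisible(x)
}
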
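#' Actual vs calculated RTM on observed paired data
#'
#' The empirical regression-to-the-mean workflow for a cutoff-selected
#' subgroup of paired pre/post measurements:
#'
#' * **actual** — the subgroup's observed pre-test mean, post-test mean
#'   and mean change (the empirical RTM effect, since no intervention took
#'   place in the data this method expects);
#' * **calculated** — the normal-theory expectations from [rtm()],
#'   parameterised by the *whole-sample* pre-test mean, pre-test SD and
#'   pre-post correlation (population quantities, not subgroup ones);
#' * **difference** — actual minus calculated, the discrepancy that
#'   appears when the data depart from bivariate normality.
#'
#' Every quantity carries a bootstrap standard error and confidence
#' interval. Whole subject rows are resampled with replacement from the
#' full sample and the complete pipeline — summary statistics, selection,
#' both methods — is recomputed per resample, so the intervals reflect the
#' variability of the selection step as well.
#'
#' @param s a [paired_sample()] (or a data frame with `pre`/`post`
#'   columns, which is converted).
#' @param cutoff pre-test cutoff defining the selected subgroup.
#' @param direction `"above"` or `"below"`: side of the cutoff selected.
#' @param boundary_inclusive whether the boundary value joins the selected
#'   group (default `TRUE`).
#' @param resamples bootstrap resamples, default 1000.
#' @param ci_level confidence level, default 0.95.
#' @param ci_method `"normal_approx"` (default) or `"percentile"`.
#' @param seed integer seed for the bootstrap; caller's RNG restored.
#' @return An object of class `"rtm_empirical"`: list with `panels` (a
#'   data frame with columns `panel` (actual/calculated/difference),
#'   `quantity` (pre_test/post_test/rtm), `estimate`, `se`, `lower`,
#'   `upper`), `summary` (whole-sample mean/sd/rho/n), `n_selected`,
#'   `n_complement`, `calculated` (the underlying `"rtm"` object),
#'   `cutoff`, `direction`, `boundary_inclusive`, `boot` (configuration
#'   and drop count) and `manifest`.
#' @examples
#' s <- generate_skewed_pairs(n = 500, seed = 4)
#' fit <- rtm_empirical(s, cutoff = 44.25, direction = "below",
#'                      resamples = 200, seed = 9)
#' fit
#' @seealso [rtm_boot()] for bootstrapping an arbitrary statistic.
#' @export
rtm_empirical <- function(s, cutoff, direction = c("above", "below"),
                          boundary_inclusive = TRUE, resamples = 1000L,
                          ci_level = 0.95,
                          ci_method = c("normal_approx", "percentile"),
                          seed = NULL) {
  direction <- match.arg(direction)
  ci_method <- match.arg(ci_method)
  if (!inherits(s, "paired_sample")) {
    stopifnot(is.data.frame(s), all(c("pre", "post") %in% names(s)))
    s <- paired_sample(s$pre, s$post, id = s[["id"]])
  }
  resamples <- as.integer(resamples)
  if (is.na(resamples) || resamples < 1L)
    stop("'resamples' must be an integer >= 1", call. = FALSE)
  if (ci_method == "percentile" && resamples < 2L)
    stop("percentile intervals need at least 2 resamples", call. = FALSE)
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop("'ci_level' must be in (0, 1)", call. = FALSE)

  quantities <- c("pre_test", "post_test", "rtm")
  pipeline <- function(x) {
    sm <- summarize_sample(x)
    if (is.na(sm[["rho"]])) stop("degenerate post-test")
    grp <- select_group(x, cutoff, direction, boundary_inclusive)
    act <- actual_rtm(grp$selected)
    calc <- rtm(mean = sm[["mean"]], sd = sm[["sd"]], rho = sm[["rho"]],
                cutoff = cutoff, direction = direction,
                boundary_inclusive = boundary_inclusive)
    act_v <- c(act[["pre_mean"]], act[["post_mean"]], act[["rtm"]])
    calc_v <- c(calc$expected_pre, calc$expected_post, calc$rtm_effect)
    c(act_v, calc_v, act_v - calc_v)
  }

  point <- pipeline(s)
  calc_fit <- {
    sm <- summarize_sample(s)
    rtm(sm[["mean"]], sm[["sd"]], sm[["rho"]], cutoff, direction,
        boundary_inclusive = boundary_inclusive)
  }
  grp <- select_group(s, cutoff, direction, boundary_inclusive)

  n <- nrow(s)
  boot_vals <- with_seed(seed, {
    vapply(seq_len(resamples), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      rs <- s[idx, , drop = FALSE]
      class(rs) <- class(s)
      tryCatch(pipeline(rs), error = function(e) rep(NA_real_, 9L))
    }, numeric(9))
  })
  n_dropped <- sum(is.na(boot_vals[1L, ]))
  if (n_dropped > 0.10 * resamples)
    stop(sprintf(paste0("pipeline undefined on %d of %d resamples ",
                        "(> 10%%): the cutoff leaves the selected group ",
                        "empty too often for a stable bootstrap"),
                 n_dropped, resamples), call. = FALSE)
  ok <- boot_vals[, !is.na(boot_vals[1L, ]), drop = FALSE]
  se <- if (ncol(ok) >= 2L) apply(ok, 1L, stats::sd) else rep(NA_real_, 9L)

  ci <- matrix(NA_real_, nrow = 9L, ncol = 2L)
  for (i in seq_len(9L)) {
    ci[i, ] <- switch(ci_method,
      normal_approx = normal_approx_ci(point[i], se[i], ci_level),
      percentile = percentile_ci(ok[i, ], ci_level))
  }

  panels <- data.frame(
    panel = rep(c("actual", "calculated", "difference"), each = 3L),
    quantity = rep(quantities, times = 3L),
    estimate = point, se = se, lower = ci[, 1L], upper = ci[, 2L],
    row.names = NULL)

  structure(list(
    panels = panels,
    summary = summarize_sample(s),
    n_selected = nrow(grp$selected),
    n_complement = nrow(grp$complement),
    calculated = calc_fit,
    cutoff = cutoff, direction = direction,
    boundary_inclusive = boundary_inclusive,
    boot = list(resamples = resamples, ci_level = ci_level,
                ci_method = ci_method, seed = seed, n_dropped = n_dropped),
    manifest = run_manifest("rtm_empirical",
                            list(cutoff = cutoff, direction = direction,
                                 boundary_inclusive = boundary_inclusive,
                                 resamples = resamples,
                                 ci_level = ci_level,
                                 ci_method = ci_method),
                            seed = seed)),
    class = "rtm_empirical")
}

#' @export
print.rtm_empirical <- function(x, digits = 2L, ...) {
  cat("Actual vs calculated regression-to-the-mean\n\n")
  sm <- x$summary
  cat(sprintf("  sample: n = %d (pre-test mean %.2f, sd %.2f, pre-post r %.3f)\n",
              as.integer(sm[["n"]]), sm[["mean"]], sm[["sd"]], sm[["rho"]]))
  cat(sprintf("  selected: pre-test %s %.2f, n = %d\n\n",
              if (x$direction == "above") {
                if (x$boundary_inclusive) ">=" else ">"
              } else if (x$boundary_inclusive) "<=" else "<",
              x$cutoff, x$n_selected))
  p <- x$panels
  fmt <- function(v) formatC(v, format = "f", digits = digits, width = 9)
  cat(sprintf("  %-12s %-10s %9s %9s %9s %9s\n", "panel", "quantity",
              "mean", "se", "lower", "upper"))
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-12s %-10s %s %s %s %s\n", p$panel[i], p$quantity[i],
                fmt(p$estimate[i]), fmt(p$se[i]), fmt(p$lower[i]),
                fmt(p$upper[i])))
  cat(sprintf("\n  bootstrap: %d resamples (%d dropped), %s %g%% CIs\n",
              x$boot$resamples, x$boot$n_dropped, x$boot$ci_method,
              100 * x$boot$ci_level))
  invisible(x)
}

#' @export
summary.rtm_empirical <- function(object, ...) object$panels

#' @export
coef.rtm_empirical <- function(object, ...) {
  p <- object$panels
  stats::setNames(p$estimate, paste(p$panel, p$quantity, sep = "_"))
}

#' Plot the observed and expected subgroup means
#'
#' Pre- and post-test means of the selected subgroup with their bootstrap
#' confidence intervals, observed (actual) alongside the normal-theory
#' (calculated) expectation, with the whole-sample mean as a reference
#' line — the usual way an RTM drift is displayed.
#'
#' @param x an `"rtm_empirical"` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.rtm_empirical <- function(x, ...) {
  p <- x$panels[x$panels$panel != "difference" &
                  x$panels$quantity != "rtm", ]
  xpos <- c(0.9, 1.9, 1.1, 2.1)  # actual pre/post, calculated pre/post
  est <- c(p$estimate[p$panel == "actual"],
           p$estimate[p$panel == "calculated"])
  lo <- c(p$lower[p$panel == "actual"], p$lower[p$panel == "calculated"])
  hi <- c(p$upper[p$panel == "actual"], p$upper[p$panel == "calculated"])
  ylim <- range(lo, hi, x$summary[["mean"]], finite = TRUE)
  graphics::plot(xpos, est, xlim = c(0.5, 2.5), ylim = ylim,
                 xaxt = "n", xlab = "", ylab = "outcome",
                 pch = c(15, 15, 1, 1), ...)
  graphics::axis(1, at = c(1, 2), labels = c("pre-test", "post-test"))
  graphics::arrows(xpos, lo, xpos, hi, angle = 90, code = 3,
                   length = 0.04)
  graphics::abline(h = x$summary[["mean"]], lty = 3)
  graphics::legend("topleft", pch = c(15, 1), bty = "n",
                   legend = c("actual", "calculated"))
  invisible(x)
}
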
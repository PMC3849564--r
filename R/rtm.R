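#' Normal-theory regression-to-the-mean estimator
#'
#' Computes the expected regression-to-the-mean (RTM) effect for a subgroup
#' selected by a cutoff on a noisy pre-test measure, under the classical
#' bivariate-normal model. The population is characterised by the pre-test
#' mean \eqn{\mu}, pre-test standard deviation \eqn{\sigma} and the
#' pre-post correlation \eqn{\rho}; the subgroup is everyone whose pre-test
#' falls above (or below) the cutoff \eqn{\kappa}.
#'
#' The total pre-test variance decomposes into a between-subject component
#' \eqn{\delta^2 = \rho\sigma^2} (stable individual differences) and a
#' within-subject component \eqn{\gamma^2 = \sigma^2(1-\rho)} (biological
#' fluctuation plus measurement error). Selection on a single noisy
#' measurement captures subjects whose within-subject noise happened to push
#' them past the cutoff, so on re-measurement the subgroup mean drifts back
#' toward \eqn{\mu} by
#' \deqn{RTM = C(z)\,\frac{\gamma^2/n}{\sqrt{\gamma^2/n + \delta^2}}}
#' where \eqn{C(z) = \phi(z)/(1-\Phi(z))} is the Mills-ratio factor of the
#' standardized cutoff \eqn{z} and \eqn{n} is the number of pre-test
#' measurements averaged before selection. For \eqn{n = 1} this reduces to
#' \eqn{C\sigma(1-\rho)}.
#'
#' Expected subgroup means are \eqn{\mu \pm C\sigma^*} (pre-test) and
#' \eqn{\mu \pm C\sigma^*\rho^*} (post-test), adding when selection is above
#' the cutoff and subtracting when below, with \eqn{\sigma^*} the pooled SD
#' \eqn{\sqrt{\gamma^2/n + \delta^2}} and \eqn{\rho^* = \delta^2/\sigma^{*2}}
#' the reliability of the mean of \eqn{n} pre-tests (\eqn{\sigma^* = \sigma}
#' and \eqn{\rho^* = \rho} when \eqn{n = 1}).
#'
#' @param mean pre-test population mean \eqn{\mu}, in outcome units.
#' @param sd pre-test population standard deviation \eqn{\sigma}; must be
#'   strictly positive.
#' @param rho pre-test/post-test correlation \eqn{\rho} in \[-1, 1\]. The
#'   variance decomposition assumes \eqn{\rho \ge 0}; a negative value
#'   triggers a warning, the components are reported as `NA`, and the
#'   effect is still computed as \eqn{C\sigma(1-\rho)} (single pre-test
#'   only).
#' @param cutoff selection cutoff \eqn{\kappa}, in outcome units.
#' @param direction `"above"` if the selected ("high-risk") group has
#'   pre-test values above the cutoff, `"below"` otherwise.
#' @param n_pretests number of pre-test measurements averaged before
#'   selection; `1` (the default) is the ordinary single-screen design.
#' @param boundary_inclusive logical; whether the boundary value itself
#'   belongs to the selected group. Does not affect the continuous
#'   normal-theory quantities, but is carried along so that empirical
#'   selection with [select_group()] uses a consistent rule.
#'
#' @return An object of class `"rtm"`: a list with components
#'   `mean`, `sd`, `rho`, `cutoff`, `direction`, `n_pretests`,
#'   `z` (standardized cutoff), `c_factor` (Mills-ratio factor),
#'   `pooled_sd`, `effective_rho`, `components` (named vector:
#'   within-subject \eqn{\gamma^2/n}, between-subject \eqn{\delta^2},
#'   pooled variance), `expected_pre`, `expected_post`, `rtm_effect`
#'   (non-negative magnitude) and `toward` (`"down"` or `"up"`, the
#'   direction of the expected drift toward the mean).
#'
#' @examples
#' # A health-score example: scores of 0-100, subgroup below 44.25
#' fit <- rtm(mean = 53.12, sd = 8.27, rho = 0.742,
#'            cutoff = 44.25, direction = "below")
#' fit
#' coef(fit)
#'
#' # Screening on the average of 3 pre-tests shrinks the effect
#' rtm(53.12, 8.27, 0.742, 44.25, "below", n_pretests = 3)$rtm_effect
#' @seealso [rtm_empirical()] for the actual-vs-calculated comparison on
#'   observed paired data; [simulate.rtm()] to draw cohorts from the
#'   implied bivariate normal.
#' @export
rtm <- function(mean, sd, rho, cutoff, direction = c("above", "below"),
                n_pretests = 1L, boundary_inclusive = TRUE) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("'sd' must be a single strictly positive number", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      rho < -1 || rho > 1)
    stop("'rho' must be a single number in [-1, 1]", call. = FALSE)
  n_pretests <- as.integer(n_pretests)
  if (is.na(n_pretests) || n_pretests < 1L)
    stop("'n_pretests' must be an integer >= 1", call. = FALSE)

  if (rho < 0) {
    warning("rho < 0: the between-/within-subject variance decomposition ",
            "assumes rho >= 0; components are reported as NA and the RTM ",
            "effect is computed as C*sigma*(1-rho)", call. = FALSE)
    if (n_pretests > 1L)
      stop("multi-pretest adjustment requires rho >= 0", call. = FALSE)
    z <- standardized_cutoff(mean, sd, cutoff, direction)
    cc <- mills_ratio(z)
    sgn <- if (direction == "above") 1 else -1
    pre <- mean + sgn * cc * sd
    post <- mean + sgn * cc * sd * rho
    comp <- c(within_subject = NA_real_, between_subject = NA_real_,
              pooled = NA_real_)
    out <- list(mean = mean, sd = sd, rho = rho, cutoff = cutoff,
                direction = direction, n_pretests = 1L,
                boundary_inclusive = boundary_inclusive,
                z = z, c_factor = cc, pooled_sd = sd, effective_rho = rho,
                components = comp,
                expected_pre = pre, expected_post = post,
                rtm_effect = cc * sd * (1 - rho),
                toward = if (direction == "above") "down" else "up",
                call = match.call())
    class(out) <- "rtm"
    return(out)
  }

  comp <- variance_components(sd = sd, rho = rho, n_pretests = n_pretests)
  pooled_sd <- sqrt(comp[["pooled"]])
  eff_rho <- comp[["between_subject"]] / comp[["pooled"]]

  z <- standardized_cutoff(mean, pooled_sd, cutoff, direction)
  cc <- mills_ratio(z)
  sgn <- if (direction == "above") 1 else -1
  pre <- mean + sgn * cc * pooled_sd
  post <- mean + sgn * cc * pooled_sd * eff_rho
  effect <- cc * comp[["within_subject"]] / pooled_sd

  out <- list(mean = mean, sd = sd, rho = rho, cutoff = cutoff,
              direction = direction, n_pretests = n_pretests,
              boundary_inclusive = boundary_inclusive,
              z = z, c_factor = cc, pooled_sd = pooled_sd,
              effective_rho = eff_rho, components = comp,
              expected_pre = pre, expected_post = post,
              rtm_effect = effect,
              toward = if (direction == "above") "down" else "up",
              call = match.call())
  class(out) <- "rtm"
  out
}

#' Standardized cutoff score
#'
#' Distance of the selection cutoff from the population mean in SD units,
#' oriented so that larger values always mean a more extreme selected
#' group: \eqn{z = (\kappa-\mu)/\sigma} when selecting above the cutoff
#' and \eqn{z = (\mu-\kappa)/\sigma} when selecting below.
#'
#' @param mean,sd pre-test population mean and SD (`sd > 0`).
#' @param cutoff selection cutoff, same units.
#' @param direction `"above"` or `"below"`.
#' @return The standardized cutoff, a single number.
#' @examples
#' standardized_cutoff(53.12, 8.27, 44.25, "below")  # 1.0725
#' @export
standardized_cutoff <- function(mean, sd, cutoff,
                                direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("'sd' must be a single strictly positive number", call. = FALSE)
  if (direction == "above") (cutoff - mean) / sd else (mean - cutoff) / sd
}

#' Mills-ratio factor
#'
#' The inverse Mills ratio \eqn{C(z) = \phi(z)/(1-\Phi(z))} of the standard
#' normal: the expected standardized value of a normal variable truncated
#' below at `z`, which drives all expected subgroup means. Evaluated on the
#' log scale so it remains finite and accurate far into the upper tail,
#' where the naive ratio would divide by an underflowed zero.
#'
#' @param z standardized cutoff (finite, vectorised).
#' @return `C(z)`, strictly positive and strictly increasing in `z`.
#' @examples
#' mills_ratio(0)        # dnorm(0) / 0.5 = 0.7979
#' mills_ratio(40)       # ~ 40.02, no overflow
#' @export
mills_ratio <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("'z' must be finite numeric", call. = FALSE)
  exp(stats::dnorm(z, log = TRUE) -
        stats::pnorm(z, lower.tail = FALSE, log.p = TRUE))
}

#' Within-/between-subject variance decomposition
#'
#' Splits the pre-test variance \eqn{\sigma^2} into the between-subject
#' component \eqn{\delta^2 = \rho\sigma^2} and the within-subject component
#' \eqn{\gamma^2 = \sigma^2(1-\rho)}. When selection is based on the mean
#' of `n_pretests` measurements the effective within-subject variance is
#' \eqn{\gamma^2/n}, so the pooled variance is \eqn{\gamma^2/n + \delta^2}.
#'
#' @param sd pre-test SD (`> 0`).
#' @param rho pre-post correlation; must be in \[0, 1\] for the
#'   decomposition to yield valid (non-negative) variances.
#' @param n_pretests number of averaged pre-tests, integer `>= 1`.
#' @return Named numeric vector with elements `within_subject`
#'   (\eqn{\gamma^2/n}), `between_subject` (\eqn{\delta^2}) and `pooled`
#'   (their sum), all in squared outcome units.
#' @examples
#' variance_components(sd = 1350, rho = 0.25)
#' @export
variance_components <- function(sd, rho, n_pretests = 1L) {
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("'sd' must be a single strictly positive number", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 1)
    stop("variance decomposition requires rho in [0, 1]", call. = FALSE)
  n_pretests <- as.integer(n_pretests)
  if (is.na(n_pretests) || n_pretests < 1L)
    stop("'n_pretests' must be an integer >= 1", call. = FALSE)
  delta2 <- rho * sd^2
  gamma2 <- sd^2 * (1 - rho) / n_pretests
  c(within_subject = gamma2, between_subject = delta2,
    pooled = gamma2 + delta2)
}

#' @export
print.rtm <- function(x, digits = 4L, ...) {
  cat("Normal-theory regression-to-the-mean estimate\n\n")
  cat(sprintf("  population: mean %s, sd %s, pre-post correlation %s\n",
              format(x$mean, digits = digits), format(x$sd, digits = digits),
              format(x$rho, digits = digits)))
  cat(sprintf("  selection:  pre-test %s %s%s\n",
              if (x$direction == "above") {
                if (x$boundary_inclusive) ">=" else ">"
              } else if (x$boundary_inclusive) "<=" else "<",
              format(x$cutoff, digits = digits),
              if (x$n_pretests > 1L)
                sprintf(" (mean of %d pre-tests)", x$n_pretests) else ""))
  cat(sprintf("\n  z = %s, C = %s\n", format(x$z, digits = digits),
              format(x$c_factor, digits = digits)))
  cat(sprintf("  expected pre-test mean:  %s\n",
              format(x$expected_pre, digits = digits)))
  cat(sprintf("  expected post-test mean: %s\n",
              format(x$expected_post, digits = digits)))
  cat(sprintf("  expected RTM effect:     %s (subgroup mean drifts %s)\n",
              format(x$rtm_effect, digits = digits),
              if (x$toward == "down") "down toward the mean"
              else "up toward the mean"))
  invisible(x)
}

#' @export
summary.rtm <- function(object, ...) {
  structure(list(fit = object), class = "summary.rtm")
}

#' @export
print.summary.rtm <- function(x, digits = 4L, ...) {
  print(x$fit, digits = digits)
  comp <- x$fit$components
  if (!anyNA(comp)) {
    cat("\n  variance components (squared outcome units):\n")
    cat(sprintf("    within-subject  %s\n    between-subject %s\n    pooled          %s\n",
                format(comp[["within_subject"]], digits = digits),
                format(comp[["between_subject"]], digits = digits),
                format(comp[["pooled"]], digits = digits)))
    cat(sprintf("  pooled sd %s, effective reliability %s\n",
                format(x$fit$pooled_sd, digits = digits),
                format(x$fit$effective_rho, digits = digits)))
  }
  invisible(x)
}

#' @export
coef.rtm <- function(object, ...) {
  c(z = object$z, c_factor = object$c_factor,
    expected_pre = object$expected_pre,
    expected_post = object$expected_post,
    rtm_effect = object$rtm_effect)
}

#' @export
as.data.frame.rtm <- function(x, ...) {
  data.frame(mean = x$mean, sd = x$sd, rho = x$rho, cutoff = x$cutoff,
             direction = x$direction, n_pretests = x$n_pretests,
             z = x$z, c_factor = x$c_factor,
             expected_pre = x$expected_pre,
             expected_post = x$expected_post,
             rtm_effect = x$rtm_effect,
             within_subject = x$components[["within_subject"]],
             between_subject = x$components[["between_subject"]],
             pooled = x$components[["pooled"]])
}

#' Simulate paired cohorts from a fitted RTM model
#'
#' Draws paired pre/post cohorts from the bivariate normal distribution
#' implied by the model's population parameters (equal means, equal SDs,
#' correlation `rho`). Useful for checking the closed-form estimate against
#' brute-force simulation.
#'
#' @param object an `"rtm"` object.
#' @param nsim number of cohorts to draw.
#' @param seed optional integer seed; the caller's RNG state is restored
#'   afterwards.
#' @param n cohort size (pairs per cohort).
#' @param ... unused.
#' @return A list of `nsim` [paired_sample()] data frames.
#' @examples
#' fit <- rtm(5000, 1350, 0.25, 6136.2, "above")
#' cohort <- simulate(fit, nsim = 1, seed = 1, n = 5000)[[1]]
#' mean(cohort$pre[cohort$pre >= 6136.2]) -
#'   mean(cohort$post[cohort$pre >= 6136.2])  # close to fit$rtm_effect
#' @export
simulate.rtm <- function(object, nsim = 1, seed = NULL, n = 1000L, ...) {
  with_seed(seed,
    lapply(seq_len(nsim), function(i)
      generate_normal_pairs(n = n, mean = object$mean, sd = object$sd,
                            rho = object$rho)))
}

#' Pre-test score correction for baseline adjustment
#'
#' Shrinks an individual's pre-test score toward the treatment-group mean
#' by the group's pre-post correlation: \eqn{x_{adj} = \bar x + \rho(x -
#' \bar x)}. The adjusted score is the individual's expected "true"
#' baseline once regression to the mean is accounted for, and can be used
#' as the baseline covariate in an ANCOVA.
#'
#' @param x individual pre-test value(s); vectorised.
#' @param group_mean treatment-group pre-test mean \eqn{\bar x}.
#' @param rho that group's pre-post correlation, in \[-1, 1\].
#' @return Adjusted pre-test score(s).
#' @examples
#' adjust_pretest(30, group_mean = 50, rho = 0.742)  # 35.16
#' @export
adjust_pretest <- function(x, group_mean, rho) {
  if (!is.numeric(rho) || length(rho) != 1L || rho < -1 || rho > 1)
    stop("'rho' must be a single number in [-1, 1]", call. = FALSE)
  group_mean + rho * (x - group_mean)
}

#' Net treatment effect after subtracting the RTM effect
#'
#' Subtracts a calculated RTM effect (with its confidence interval) from an
#' observed pre-post change to give the change attributable to the
#' intervention itself. Both quantities must be on the same scale with the
#' same sign convention (improvement positive).
#'
#' @param observed_change observed pre-post change in the treated group.
#' @param rtm_effect calculated RTM effect to remove (magnitude, same sign
#'   convention), or an `"rtm"` object.
#' @param rtm_ci optional length-2 numeric: confidence interval for the
#'   RTM effect. Bounds may be given in either order.
#' @return A list with `net` (point estimate), `ci` (interval for the net
#'   effect, `NULL` if `rtm_ci` was not supplied) and `sign_convention`.
#' @examples
#' net_effect(10, 3.38, rtm_ci = c(1.54, 5.22))
#' @export
net_effect <- function(observed_change, rtm_effect, rtm_ci = NULL) {
  if (inherits(rtm_effect, "rtm")) rtm_effect <- rtm_effect$rtm_effect
  stopifnot(is.numeric(observed_change), length(observed_change) == 1L,
            is.numeric(rtm_effect), length(rtm_effect) == 1L)
  ci <- NULL
  if (!is.null(rtm_ci)) {
    stopifnot(is.numeric(rtm_ci), length(rtm_ci) == 2L)
    ci <- sort(observed_change - rtm_ci)
    names(ci) <- c("lower", "upper")
  }
  list(net = observed_change - rtm_effect, ci = ci,
       sign_convention = "improvement positive; net = observed - RTM")
}
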
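#' Monte Carlo scenario for validating the RTM estimator
#'
#' Describes one simulation study: repeated bivariate-normal cohorts of
#' paired "costs", a quantile-based cutoff splitting each cohort into
#' high- and low-risk tiers, and a comparison of the observed ("actual")
#' tier-mean change against the closed-form ("calculated") prediction.
#' Defaults reproduce the reference design: cohorts of 10,000 pairs with
#' means of $5,000, SDs of $1,350, correlations 0.25/0.50/0.75 and the
#' top-quintile boundary (the 80th percentile, about $6,136) as cutoff.
#'
#' @param n_obs cohort size (default 10000).
#' @param mean,sd marginal mean and SD of the cost distribution
#'   (defaults 5000 and 1350).
#' @param rho pre-post correlation(s); a vector fans out into one
#'   scenario block per value (default `c(0.25, 0.50, 0.75)`).
#' @param n_reps replications per correlation (default 10000; reduce for
#'   desk-scale runs).
#' @param cutoff_quantile quantile defining the high-risk boundary
#'   (default 0.80).
#' @param seed integer master seed; each replication draws from a
#'   substream derived from `(seed, replication index)`, so results do
#'   not depend on execution order.
#' @return A list of class `"rtm_scenario"`.
#' @export
rtm_scenario <- function(n_obs = 10000L, mean = 5000, sd = 1350,
                         rho = c(0.25, 0.50, 0.75), n_reps = 10000L,
                         cutoff_quantile = 0.80, seed = 1L) {
  stopifnot(is.numeric(n_obs), n_obs >= 10, is.numeric(sd), sd > 0,
            is.numeric(rho), all(rho >= 0 & rho < 1),
            is.numeric(n_reps), n_reps >= 1,
            is.numeric(cutoff_quantile),
            cutoff_quantile > 0, cutoff_quantile < 1)
  structure(list(n_obs = as.integer(n_obs), mean = mean, sd = sd,
                 rho = rho, n_reps = as.integer(n_reps),
                 cutoff_quantile = cutoff_quantile,
                 seed = as.integer(seed)),
            class = "rtm_scenario")
}

#' Read a simulation scenario from YAML or JSON
#'
#' Accepts the keys of [rtm_scenario()] (`n_obs`, `mean`, `sd`, `rho`,
#' `n_reps`, `cutoff_quantile`, `seed`); unknown keys are an error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return An `"rtm_scenario"`.
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed to read YAML scenarios",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("n_obs", "mean", "sd", "rho", "n_reps", "cutoff_quantile",
             "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown scenario key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(rtm_scenario, cfg)
}

#' Draw one simulated cohort
#'
#' One bivariate-normal cohort of the scenario, using the substream
#' derived from `(scenario seed, rep_index)` so the same pair of values
#' always reproduces the same cohort.
#'
#' @param scn an [rtm_scenario()].
#' @param rep_index replication number (>= 1).
#' @param rho the correlation to use (defaults to the scenario's first).
#' @return A [paired_sample()].
#' @export
draw_cohort <- function(scn, rep_index, rho = scn$rho[1L]) {
  stopifnot(inherits(scn, "rtm_scenario"), rep_index >= 1)
  # offset the substream by the rho index so scenario blocks don't share
  # random streams
  k <- match(rho, scn$rho)
  offset <- if (is.na(k)) 0L else (k - 1L) * 1000003L
  generate_normal_pairs(scn$n_obs, scn$mean, scn$sd, rho,
                        seed = substream_seed(scn$seed,
                                              rep_index + offset))
}

#' Empirical quantile-boundary cutoff
#'
#' The minimum value among the observations at or above the `q`-th
#' empirical quantile — i.e. the smallest member of the top `(1-q)`
#' fraction (rank-based, not interpolated). For `q = 0.8` this is the
#' boundary of the highest quintile; in large normal samples it
#' approaches \eqn{\mu + \Phi^{-1}(q)\,\sigma}.
#'
#' @param x non-empty numeric vector.
#' @param q quantile in (0, 1), default 0.80.
#' @return The cutoff value.
#' @examples
#' quintile_cutoff(1:10, 0.8)  # 9: smallest of the top fifth {9, 10}
#' @export
quintile_cutoff <- function(x, q = 0.80) {
  if (length(x) == 0L) stop("empty vector", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("'q' must be in (0, 1)", call. = FALSE)
  n <- length(x)
  m <- ceiling(n * (1 - q))        # size of the top group
  m <- max(1L, min(n, m))
  sort(x, partial = n - m + 1L)[n - m + 1L]
}

#' One replication of the Monte Carlo study
#'
#' Draws a cohort, sets the cutoff at the empirical quantile boundary of
#' its pre-test values, and returns the actual and calculated RTM effects
#' for both tiers. "Actual" is the observed tier mean change (high tier:
#' pre minus post, a decrease; low tier: post minus pre, an increase).
#' "Calculated" applies the closed-form estimator with the replication's
#' empirical cutoff and either the true scenario parameters (default) or
#' the cohort's estimated summary statistics.
#'
#' @param scn an [rtm_scenario()].
#' @param rep_index replication number.
#' @param rho correlation for this block (defaults to the scenario's
#'   first).
#' @param parameterization `"true"` (scenario parameters; default) or
#'   `"estimated"` (per-cohort sample summaries).
#' @return Named numeric vector `cutoff`, `actual_high`,
#'   `calculated_high`, `actual_low`, `calculated_low`.
#' @export
run_replication <- function(scn, rep_index, rho = scn$rho[1L],
                            parameterization = c("true", "estimated")) {
  parameterization <- match.arg(parameterization)
  cohort <- draw_cohort(scn, rep_index, rho = rho)
  kappa <- quintile_cutoff(cohort$pre, scn$cutoff_quantile)

  hi <- cohort$pre >= kappa
  if (!any(hi) || all(hi))
    stop("degenerate tier split (cohort too small?)", call. = FALSE)
  actual_high <- mean(cohort$pre[hi]) - mean(cohort$post[hi])
  actual_low <- mean(cohort$post[!hi]) - mean(cohort$pre[!hi])

  if (parameterization == "true") {
    mu <- scn$mean; sg <- scn$sd; r <- rho
  } else {
    sm <- summarize_sample(cohort)
    mu <- sm[["mean"]]; sg <- sm[["sd"]]; r <- sm[["rho"]]
  }
  calc_high <- rtm(mu, sg, r, kappa, "above")$rtm_effect
  calc_low <- rtm(mu, sg, r, kappa, "below")$rtm_effect

  c(cutoff = kappa, actual_high = actual_high,
    calculated_high = calc_high, actual_low = actual_low,
    calculated_low = calc_low)
}

#' Run the Monte Carlo validation study
#'
#' Repeats [run_replication()] `n_reps` times for each correlation in the
#' scenario and aggregates each cell (tier × method) to its mean over
#' replications, the standard error of that mean (SD of the replication
#' values / sqrt(n_reps)) and a normal 95% confidence interval — a
#' machine-readable version of the reference simulation table.
#'
#' @param scn an [rtm_scenario()].
#' @param parameterization passed to [run_replication()].
#' @param ci_level confidence level for the cell means (default 0.95).
#' @return An object of class `"rtm_study"`: list with `cells` (data
#'   frame: `rho`, `tier` (high/low), `method` (actual/calculated),
#'   `mean`, `se`, `lower`, `upper`), `mean_cutoff` (per `rho`),
#'   `scenario` and `manifest`. With `n_reps = 1` the SE and CI are `NA`
#'   with a warning.
#' @examples
#' scn <- rtm_scenario(n_obs = 2000, rho = 0.25, n_reps = 20, seed = 7)
#' run_study(scn)
#' @export
run_study <- function(scn, parameterization = c("true", "estimated"),
                      ci_level = 0.95) {
  stopifnot(inherits(scn, "rtm_scenario"))
  parameterization <- match.arg(parameterization)
  if (scn$n_reps == 1L)
    warning("n_reps = 1: standard errors and intervals are undefined",
            call. = FALSE)
  zq <- stats::qnorm((1 + ci_level) / 2)

  cells <- NULL
  cutoffs <- numeric(length(scn$rho))
  for (k in seq_along(scn$rho)) {
    rho <- scn$rho[k]
    reps <- vapply(seq_len(scn$n_reps), function(i)
      run_replication(scn, i, rho = rho,
                      parameterization = parameterization),
      numeric(5))
    cutoffs[k] <- mean(reps["cutoff", ])
    for (cell in c("actual_high", "calculated_high", "actual_low",
                   "calculated_low")) {
      v <- reps[cell, ]
      m <- mean(v)
      se <- if (scn$n_reps > 1L) stats::sd(v) / sqrt(scn$n_reps)
            else NA_real_
      cells <- rbind(cells, data.frame(
        rho = rho,
        tier = if (grepl("high", cell)) "high" else "low",
        method = if (grepl("actual", cell)) "actual" else "calculated",
        mean = m, se = se,
        lower = m - zq * se, upper = m + zq * se))
    }
  }
  rownames(cells) <- NULL
  structure(list(cells = cells,
                 mean_cutoff = stats::setNames(cutoffs,
                                               as.character(scn$rho)),
                 scenario = scn,
                 parameterization = parameterization,
                 manifest = run_manifest("run_study",
                                         unclass(scn), seed = scn$seed)),
            class = "rtm_study")
}

#' @export
print.rtm_study <- function(x, digits = 2L, ...) {
  scn <- x$scenario
  cat(sprintf(paste0("Monte Carlo RTM study: %d cohorts of %d pairs, ",
                     "cutoff at the %.0fth percentile\n"),
              scn$n_reps, scn$n_obs, 100 * scn$cutoff_quantile))
  cat(sprintf("  population: mean %s, sd %s; calculated method uses %s parameters\n\n",
              format(scn$mean), format(scn$sd), x$parameterization))
  fmt <- function(v) formatC(v, format = "f", digits = digits, width = 10)
  cat(sprintf("  %-6s %-5s %-11s %10s %10s %10s %10s\n", "rho", "tier",
              "method", "mean", "se", "lower", "upper"))
  p <- x$cells
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-6s %-5s %-11s %s %s %s %s\n",
                format(p$rho[i]), p$tier[i], p$method[i], fmt(p$mean[i]),
                fmt(p$se[i]), fmt(p$lower[i]), fmt(p$upper[i])))
  cat(sprintf("\n  mean empirical cutoff(s): %s\n",
              paste(sprintf("%s (rho=%s)",
                            formatC(x$mean_cutoff, format = "f",
                                    digits = digits),
                            names(x$mean_cutoff)), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.rtm_study <- function(x, ...) x$cells
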
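test_that("standardized cutoff orients z toward the selected tail", {
  # cutoff at the 80th percentile of the population: z is the 0.8 normal
  # quantile whichever way we compute it
  kappa <- 5000 + qnorm(0.80) * 1350
  expect_equal(standardized_cutoff(5000, 1350, kappa, "above"),
               qnorm(0.80), tolerance = 1e-12)
  expect_equal(standardized_cutoff(53.12, 8.27, 53.12, "below"), 0)
  expect_equal(standardized_cutoff(53.12, 8.27, 44.25, "below"),
               (53.12 - 44.25) / 8.27, tolerance = 1e-12)
  expect_error(standardized_cutoff(0, 0, 1, "above"), "positive")
  expect_error(standardized_cutoff(0, -2, 1, "below"), "positive")
})

test_that("Mills-ratio factor matches the density/CDF ratio and is stable", {
  expect_equal(mills_ratio(0), dnorm(0) / 0.5, tolerance = 1e-12)
  expect_equal(mills_ratio(qnorm(0.8)), dnorm(qnorm(0.8)) / 0.2,
               tolerance = 1e-12)
  expect_equal(mills_ratio(1.0725), dnorm(1.0725) / pnorm(-1.0725),
               tolerance = 1e-12)
  expect_error(mills_ratio(Inf), "finite")
  expect_error(mills_ratio(NA_real_), "finite")

  # strictly increasing and bounded below by z on a wide grid, finite far
  # into the tail where the naive ratio would be 0/0
  grid <- seq(-8, 8, by = 0.25)
  cvals <- mills_ratio(grid)
  expect_true(all(diff(cvals) > 0))
  expect_true(all(cvals > grid))
  expect_true(all(cvals > 0))
  expect_true(is.finite(mills_ratio(40)))
  expect_equal(mills_ratio(40), 40 + 1 / 40, tolerance = 1e-3)
})

test_that("variance decomposition splits sigma^2 by the correlation", {
  vc <- variance_components(sd = 1350, rho = 0.25)
  expect_equal(vc[["within_subject"]], 1350^2 * 0.75)
  expect_equal(vc[["between_subject"]], 0.25 * 1350^2)
  expect_equal(vc[["pooled"]],
               vc[["within_subject"]] + vc[["between_subject"]])
  expect_equal(vc[["pooled"]], 1350^2)
  expect_equal(variance_components(8.27, 0.742)[["pooled"]], 8.27^2)

  # averaging many pre-tests kills the within-subject share
  vc_many <- variance_components(1350, 0.25, n_pretests = 100000L)
  expect_equal(vc_many[["pooled"]], 0.25 * 1350^2, tolerance = 1e-4)
  expect_error(variance_components(1350, -0.1), "rho")
})

test_that("the three single-pretest formulations agree to 1e-10 relative", {
  set.seed(42)
  for (i in 1:50) {
    mu <- runif(1, -100, 100)
    sg <- runif(1, 0.5, 50)
    rho <- runif(1, 0, 0.99)
    kappa <- mu + runif(1, -2.5, 2.5) * sg
    dir <- sample(c("above", "below"), 1)
    fit <- rtm(mu, sg, rho, kappa, dir)
    z <- standardized_cutoff(mu, sg, kappa, dir)
    expect_equal(fit$rtm_effect, mills_ratio(z) * sg * (1 - rho),
                 tolerance = 1e-10)
    expect_equal(fit$rtm_effect,
                 abs(fit$expected_post - fit$expected_pre),
                 tolerance = 1e-10)
    expect_equal(fit$rtm_effect,
                 fit$c_factor * fit$components[["within_subject"]] /
                   fit$pooled_sd,
                 tolerance = 1e-10)
  }
})

test_that("perfect correlation means no regression to the mean", {
  fit <- rtm(5000, 1350, 1, 6136, "above")
  expect_equal(fit$rtm_effect, 0)
  expect_equal(fit$expected_pre, fit$expected_post)
})

test_that("zero correlation regresses all the way back to the mean", {
  fit <- rtm(53.12, 8.27, 0, 44.25, "below")
  expect_equal(fit$expected_post, 53.12)
})

test_that("expected subgroup pre-test mean matches the truncated-normal
           mean by numerical integration", {
  for (z in c(-1.5, -0.5, 0, 0.8416, 1.0725, 2.5)) {
    mu <- 5000; sg <- 1350
    kappa <- mu + z * sg
    fit <- rtm(mu, sg, 0.5, kappa, "above")
    oracle <- mu + sg * truncated_normal_mean(z)
    expect_equal(fit$expected_pre, oracle, tolerance = 1e-6)
  }
  # below-direction selection mirrors the reflected truncation
  fit <- rtm(53.12, 8.27, 0.742, 44.25, "below")
  z <- (53.12 - 44.25) / 8.27
  oracle <- 53.12 - 8.27 * truncated_normal_mean(z)
  expect_equal(fit$expected_pre, oracle, tolerance = 1e-6)
})

test_that("RTM shrinks as the correlation rises and grows with cutoff
           extremity", {
  effects <- sapply(seq(0, 0.95, by = 0.05), function(r)
    rtm(5000, 1350, r, 6500, "above")$rtm_effect)
  expect_true(all(diff(effects) < 0))

  by_kappa <- sapply(seq(4000, 8000, by = 500), function(k)
    rtm(5000, 1350, 0.5, k, "above")$rtm_effect)
  expect_true(all(diff(by_kappa) > 0))
})

test_that("selection above mu+a mirrors selection below mu-a", {
  for (a in c(0.3, 1, 2.2)) {
    up <- rtm(50, 10, 0.4, 50 + a * 10, "above")
    down <- rtm(50, 10, 0.4, 50 - a * 10, "below")
    expect_equal(up$rtm_effect, down$rtm_effect, tolerance = 1e-12)
    expect_equal(up$expected_pre - 50, 50 - down$expected_pre,
                 tolerance = 1e-12)
    expect_identical(up$toward, "down")
    expect_identical(down$toward, "up")
  }
})

test_that("multi-pretest screening shrinks the RTM effect monotonically", {
  fits <- lapply(c(1L, 2L, 3L, 5L, 10L, 100L), function(n)
    rtm(53.12, 8.27, 0.742, 44.25, "below", n_pretests = n))
  effects <- sapply(fits, `[[`, "rtm_effect")
  expect_true(all(diff(effects) < 0))
  expect_lt(effects[length(effects)], 0.05 * effects[1])

  # n = 1 is bit-for-bit the single-pretest formula
  expect_identical(fits[[1]]$rtm_effect,
                   rtm(53.12, 8.27, 0.742, 44.25, "below")$rtm_effect)
  # the subgroup-mean identity holds for every n
  for (f in fits)
    expect_equal(f$rtm_effect, abs(f$expected_post - f$expected_pre),
                 tolerance = 1e-10)
  # pooled sd shrinks toward the between-subject sd (first-order term
  # (1-rho)/(2*n*rho) ~ 0.002 at n = 100)
  expect_equal(fits[[6]]$pooled_sd, sqrt(0.742) * 8.27, tolerance = 5e-3)
})

test_that("negative correlation warns, refuses components, still computes", {
  expect_warning(fit <- rtm(50, 10, -0.3, 40, "below"), "rho < 0")
  expect_true(all(is.na(fit$components)))
  z <- (50 - 40) / 10
  expect_equal(fit$rtm_effect, mills_ratio(z) * 10 * 1.3,
               tolerance = 1e-12)
  suppressWarnings(
    expect_error(rtm(50, 10, -0.3, 40, "below", n_pretests = 2),
                 "rho >= 0"))
})

test_that("invalid population parameters are rejected", {
  expect_error(rtm(50, 0, 0.5, 40, "below"), "positive")
  expect_error(rtm(50, 10, 1.2, 40, "below"), "\\[-1, 1\\]")
  expect_error(rtm(50, 10, 0.5, 40, "below", n_pretests = 0), ">= 1")
})

test_that("pre-test correction shrinks toward the group mean", {
  expect_equal(adjust_pretest(30, group_mean = 50, rho = 0.742),
               50 + 0.742 * (30 - 50))
  expect_equal(adjust_pretest(50, 50, 0.6), 50)
  expect_equal(adjust_pretest(c(30, 70), 50, 1), c(30, 70))
  expect_error(adjust_pretest(30, 50, 1.5), "\\[-1, 1\\]")
})

test_that("net effect subtracts the RTM point estimate and interval", {
  out <- net_effect(10, 3.38, rtm_ci = c(1.54, 5.22))
  expect_equal(out$net, 6.62)
  expect_equal(unname(out$ci), c(4.78, 8.46))
  expect_equal(net_effect(7, 0, rtm_ci = c(0, 0))$net, 7)
  expect_equal(net_effect(3.38, 3.38)$net, 0)
  # accepts a fitted rtm object directly
  fit <- rtm(53.12, 8.27, 0.742, 44.25, "below")
  expect_equal(net_effect(10, fit)$net, 10 - fit$rtm_effect)
})

test_that("rtm methods expose the estimate coherently", {
  fit <- rtm(53.12, 8.27, 0.742, 44.25, "below")
  cf <- coef(fit)
  expect_named(cf, c("z", "c_factor", "expected_pre", "expected_post",
                     "rtm_effect"))
  df <- as.data.frame(fit)
  expect_equal(df$rtm_effect, fit$rtm_effect)
  expect_output(print(fit), "expected RTM effect")
  expect_output(print(summary(fit)), "variance components")

  cohorts <- simulate(fit, nsim = 2, seed = 11, n = 500)
  expect_length(cohorts, 2)
  expect_s3_class(cohorts[[1]], "paired_sample")
  again <- simulate(fit, nsim = 2, seed = 11, n = 500)
  expect_identical(cohorts, again)
})
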
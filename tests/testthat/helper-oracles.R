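# Independent oracles used across test files.

# Mean of a standard normal truncated below at z, by numerical
# integration (kept free of the package's Mills-ratio code path).
truncated_normal_mean <- function(z) {
  num <- integrate(function(x) x * dnorm(x), lower = z, upper = Inf,
                   rel.tol = 1e-12)$value
  num / pnorm(z, lower.tail = FALSE)
}

# Closed-form single-pretest RTM magnitude, written independently of rtm()
analytic_rtm <- function(sd, rho, z) {
  dnorm(z) / pnorm(z, lower.tail = FALSE) * sd * (1 - rho)
}
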
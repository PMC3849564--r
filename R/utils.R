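# RNG discipline: seeding inside package functions must not disturb the
# caller's random stream.

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Per-replication substream: a deterministic, collision-averse map from
# (seed, index) to a 31-bit seed, so replications are independent of
# execution order.
#' @keywords internal
#' @noRd
substream_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271) %% 2147483647
  x <- (x + as.double(index) * 69621) %% 2147483647
  as.integer(x)
}

#' @keywords internal
#' @noRd
run_manifest <- function(command, params, seed = NULL) {
  list(command = command,
       params = params,
       seed = seed,
       package = "rtmest",
       version = as.character(utils::packageVersion("rtmest")),
       rng_kind = RNGkind()[1L],
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
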
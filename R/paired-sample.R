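#' Paired pre/post sample
#'
#' Assembles per-subject pre- and post-test measurements into the common
#' data-frame representation used throughout the package (class
#' `"paired_sample"`, columns `id`, `pre`, `post`). Rows with a missing
#' pre- or post-test value are dropped; the number dropped is reported via
#' a message and stored in the `"n_dropped"` attribute.
#'
#' @param pre,post numeric vectors of equal length, same outcome scale.
#' @param id optional subject identifiers (default `1:n`).
#' @return A `"paired_sample"` data frame with attribute `n_dropped`.
#' @examples
#' paired_sample(pre = c(10, 20), post = c(14, 22))
#' @export
paired_sample <- function(pre, post, id = NULL) {
  stopifnot(is.numeric(pre), is.numeric(post))
  if (length(pre) != length(post))
    stop("'pre' and 'post' must have equal length", call. = FALSE)
  if (is.null(id)) id <- seq_along(pre)
  if (length(id) != length(pre))
    stop("'id' must match the length of 'pre'/'post'", call. = FALSE)
  keep <- is.finite(pre) & is.finite(post)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(sprintf("dropped %d row(s) with missing pre or post values",
                    n_dropped))
  out <- data.frame(id = id[keep], pre = as.numeric(pre[keep]),
                    post = as.numeric(post[keep]))
  if (nrow(out) < 2L)
    stop("a paired sample needs at least 2 complete rows", call. = FALSE)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("paired_sample", "data.frame")
  out
}

#' Read a paired sample from CSV
#'
#' Expects a header with columns `id`, `pre`, `post` (extra columns are
#' ignored; `id` is optional). The decimal mark is `.`.
#'
#' @param path file path.
#' @param sep field delimiter, default comma.
#' @return A [paired_sample()].
#' @export
read_paired_csv <- function(path, sep = ",") {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                      stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!all(c("pre", "post") %in% names(df)))
    stop("'", path, "' must have header columns 'pre' and 'post' ",
         "(found: ", paste(names(df), collapse = ", "), ")", call. = FALSE)
  for (col in c("pre", "post")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("non-numeric '", col, "' value at data line ",
           if (length(bad)) bad[1L] else "?", " of '", path, "'",
           call. = FALSE)
    }
  }
  paired_sample(df$pre, df$post,
                id = if ("id" %in% names(df)) df$id else NULL)
}

#' Write a paired sample to CSV
#'
#' @param s a [paired_sample()].
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_paired_csv <- function(s, path, sep = ",") {
  utils::write.table(as.data.frame(s)[c("id", "pre", "post")], path,
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Whole-sample summary statistics
#'
#' The pre-test mean, pre-test SD (denominator `n - 1`) and Pearson
#' pre-post correlation of a paired sample. These are the \eqn{\mu},
#' \eqn{\sigma}, \eqn{\rho} that parameterise the normal-theory
#' ("calculated") RTM method: population-level quantities estimated from
#' the whole sample, never from the selected subgroup.
#'
#' @param s a [paired_sample()].
#' @return Named numeric vector `mean`, `sd`, `rho`, `n`.
#' @examples
#' s <- paired_sample(pre = c(0, 2), post = c(0, 2))
#' summarize_sample(s)  # mean 1, sd sqrt(2), rho 1
#' @export
summarize_sample <- function(s) {
  stopifnot(inherits(s, "paired_sample"))
  if (nrow(s) < 2L) stop("need at least 2 rows", call. = FALSE)
  sdv <- stats::sd(s$pre)
  if (sdv == 0) stop("pre-test values have zero variance", call. = FALSE)
  rho <- if (stats::sd(s$post) == 0) NA_real_ else stats::cor(s$pre, s$post)
  c(mean = mean(s$pre), sd = sdv, rho = rho, n = nrow(s))
}

#' Split a paired sample at a pre-test cutoff
#'
#' Partitions subjects into the selected ("high-risk") group and its
#' complement using the pre-test value only — selection never looks at the
#' post-test. Row order is preserved within each part.
#'
#' @param s a [paired_sample()].
#' @param cutoff pre-test cutoff.
#' @param direction `"above"` or `"below"`: which side is selected.
#' @param boundary_inclusive whether ties at the cutoff join the selected
#'   group (default `TRUE`).
#' @return A list with elements `selected` and `complement`, each a
#'   `"paired_sample"` (the complement may have fewer than 2 rows and is
#'   returned as a plain subset in that case).
#' @examples
#' s <- paired_sample(pre = c(1, 5, 9), post = c(1, 5, 9))
#' select_group(s, cutoff = 5, direction = "above")$selected$pre  # 5 9
#' @export
select_group <- function(s, cutoff, direction = c("above", "below"),
                         boundary_inclusive = TRUE) {
  direction <- match.arg(direction)
  stopifnot(inherits(s, "paired_sample"), is.numeric(cutoff),
            length(cutoff) == 1L)
  sel <- if (direction == "above") {
    if (boundary_inclusive) s$pre >= cutoff else s$pre > cutoff
  } else {
    if (boundary_inclusive) s$pre <= cutoff else s$pre < cutoff
  }
  if (!any(sel))
    stop("selected group is empty for cutoff ", cutoff, " (", direction,
         ")", call. = FALSE)
  subset_ps <- function(keep) {
    out <- s[keep, , drop = FALSE]
    attr(out, "n_dropped") <- 0L
    class(out) <- c("paired_sample", "data.frame")
    out
  }
  list(selected = subset_ps(sel), complement = subset_ps(!sel))
}

#' Observed ("actual") RTM effect of a subgroup
#'
#' The pre-test mean, post-test mean and absolute mean change of a
#' (typically cutoff-selected) subgroup. For a group selected for extreme
#' values, this observed change is the empirical regression-to-the-mean
#' effect when no intervention took place.
#'
#' @param selected a non-empty `"paired_sample"` subgroup.
#' @return Named numeric vector `pre_mean`, `post_mean`, `rtm`
#'   (`rtm = |post_mean - pre_mean|`), plus `direction` attribute-free
#'   sign in `change` (`post_mean - pre_mean`).
#' @examples
#' g <- paired_sample(pre = c(10, 20), post = c(14, 22))
#' actual_rtm(g)  # pre 15, post 18, rtm 3
#' @export
actual_rtm <- function(selected) {
  stopifnot(inherits(selected, "data.frame"))
  if (nrow(selected) == 0L) stop("empty group", call. = FALSE)
  pre_m <- mean(selected$pre)
  post_m <- mean(selected$post)
  c(pre_mean = pre_m, post_mean = post_m, rtm = abs(post_m - pre_m),
    change = post_m - pre_m)
}
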
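#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a bootstrap result
#'
#' One row per alpha level with the confidence interval and significance
#' flag.
#'
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return A tibble: `alpha`, `lower`, `upper`, `significant`,
#'   `observed_diff`.
#' @export
tidy.bootstrap_result <- function(x, ...) {
  dplyr::mutate(x$ci, observed_diff = x$observed_diff)
}

#' One-row summary of a bootstrap result
#'
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return A one-row tibble: `observed_diff`, `n_x`, `n_y`, `n_resamples`,
#'   `seed`, `stars`.
#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble::tibble(
    observed_diff = x$observed_diff, n_x = x$n_x, n_y = x$n_y,
    n_resamples = x$n_resamples, seed = x$seed,
    stars = significance_stars(x)
  )
}

#' Tidy a paired test
#'
#' @param x A `paired_test` from [paired_t()].
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `p_value`, `df`, `mean_diff`,
#'   `tail`, `method`, `degenerate`.
#' @export
tidy.paired_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p_value = x$p_value, df = x$df,
    mean_diff = x$mean_diff, tail = x$tail, method = x$method,
    degenerate = x$degenerate
  )
}

#' @rdname tidy.paired_test
#' @export
glance.paired_test <- function(x, ...) tidy.paired_test(x)
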
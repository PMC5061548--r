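#' Tidy a copy-number estimate
#'
#' @param x A [estimate_copy_number()] result.
#' @param ... Unused.
#' @return One row: `minimum`, `average`, `ci_low`, `ci_high`, `maximum`,
#'   `n_unsampled`, `ancient_mode`.
#' @export
tidy.copy_number_estimate <- function(x, ...) {
  tibble(minimum = x$minimum, average = x$average, ci_low = x$ci[1],
         ci_high = x$ci[2], maximum = x$maximum,
         n_unsampled = sum(x$unsampled$unsampled),
         ancient_mode = x$ancient_mode)
}

#' @rdname tidy.copy_number_estimate
#' @export
glance.copy_number_estimate <- function(x, ...) {
  tidy(x) |> mutate(envelope = sprintf("%d-%d", .data$minimum, .data$maximum))
}

#' Tidy a trend correlation
#'
#' @param x A [correlate_series()] result.
#' @param ... Unused.
#' @return One row: `estimate`, `method`, `n`, `p_value`, `n_perm`.
#' @export
tidy.trend_correlation <- function(x, ...) {
  tibble(estimate = x$estimate, method = x$method, n = x$n,
         p_value = x$p_value, n_perm = x$n_perm)
}

#' @rdname tidy.trend_correlation
#' @export
glance.trend_correlation <- function(x, ...) tidy(x)

#' Tidy a reconciliation
#'
#' @param x A [reconcile_lca()] result.
#' @param ... Unused.
#' @return The node mapping tibble with duplication flags.
#' @export
tidy.reconciliation <- function(x, ...) x$mapping

#' @rdname tidy.reconciliation
#' @export
glance.reconciliation <- function(x, ...) {
  tibble(n_duplications = x$n_duplications, n_losses = x$n_losses)
}
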
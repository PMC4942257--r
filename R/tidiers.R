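#' Tidy a differential-firing test
#'
#' Returns the post-hoc pair table (empty when the omnibus test was not
#' significant), one row per route pair.
#'
#' @param x A `differential_test`.
#' @param ... Unused.
#' @return Tibble: `pair`, `route_a`, `route_b`, `estimate`, `p_adj`.
#' @export
tidy.differential_test <- function(x, ...) {
  if (is.null(x$posthoc))
    return(tibble::tibble(pair = character(), route_a = integer(),
                          route_b = integer(), estimate = numeric(),
                          p_adj = numeric()))
  x$posthoc
}

#' Glance at a differential-firing test
#'
#' @param x A `differential_test`.
#' @param ... Unused.
#' @return One-row tibble: `method`, `statistic`, `df1`, `df2`, `p_value`,
#'   `n_trials`, `converged`.
#' @export
glance.differential_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 df1 = as.numeric(x$df1), df2 = as.numeric(x$df2),
                 p_value = x$p_value, n_trials = sum(x$n_per_route),
                 converged = x$converged)
}

#' Tidy a decoding result
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return Tibble with one row per (trajectory route, goal vector) cell:
#'   `route`, `goal`, `match_pct`, and `p_value` when a shuffle null has
#'   been run.
#' @export
tidy.decoding_result <- function(x, ...) {
  m <- x$match_matrix
  out <- tibble::tibble(
    route = rep(rownames(m), times = ncol(m)),
    goal = rep(colnames(m), each = nrow(m)),
    match_pct = as.vector(m))
  if (!is.null(x$p_matrix)) out$p_value <- as.vector(x$p_matrix)
  out
}

#' Glance at a decoding result
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return One-row tibble: `n_trials`, `n_cells`, `pct_correct` (overall),
#'   `n_skipped`, `n_shuffles`.
#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(n_trials = sum(x$counts),
                 n_sessions = length(x$sessions),
                 n_cells = ncol(x$sessions[[1]]$R),
                 pct_correct = 100 * sum(diag(x$counts)) / sum(x$counts),
                 n_skipped = x$n_skipped,
                 n_shuffles = x$n_shuffles %||% NA_integer_)
}
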
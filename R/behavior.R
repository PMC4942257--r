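#' Score win-stay blocks
#'
#' Splits each block at its first correct trial and reports the error counts
#' and mean trial durations before and after it: `errors_pre` counts the
#' search trials before the rewarded goal box was discovered, `errors_post`
#' the confusion errors made afterwards.
#'
#' @param trials Trial table (from [simulate_session()] or
#'   [read_session()]); needs `block_id`, `rewarded_route`, `route_id`,
#'   `correct`, `t_start`, `t_end`.
#' @return Tibble with one row per block: `block_id`, `rewarded_route`,
#'   `n_trials`, `n_correct`, `errors_pre`, `errors_post`,
#'   `mean_time_pre`, `mean_time_post` (s; `NA` and a warning when a block
#'   has no correct trial).
#' @export
score_blocks <- function(trials) {
  stopifnot(all(c("block_id", "rewarded_route", "route_id", "correct",
                  "t_start", "t_end") %in% names(trials)))
  out <- purrr::map_dfr(split(trials, trials$block_id), function(b) {
    b <- b[order(b$t_start), ]
    dur <- b$t_end - b$t_start
    first <- which(b$correct)[1]
    if (is.na(first)) {
      warning("block ", b$block_id[1], " has no correct trial")
      return(tibble::tibble(
        block_id = b$block_id[1], rewarded_route = b$rewarded_route[1],
        n_trials = nrow(b), n_correct = 0L,
        errors_pre = sum(!b$correct), errors_post = NA_integer_,
        mean_time_pre = mean(dur), mean_time_post = NA_real_))
    }
    pre <- seq_len(first - 1)
    post <- seq(first, nrow(b))
    tibble::tibble(
      block_id = b$block_id[1], rewarded_route = b$rewarded_route[1],
      n_trials = nrow(b), n_correct = sum(b$correct),
      errors_pre = length(pre),
      errors_post = sum(!b$correct[post]),
      mean_time_pre = if (length(pre)) mean(dur[pre]) else NA_real_,
      mean_time_post = mean(dur[post]))
  })
  tibble::as_tibble(out)
}

#' Confusion-error pair counts
#'
#' Groups post-identification errors into the six unordered route pairs
#' {chosen route, rewarded route}: taking Route 1 when Route 2 was rewarded
#' and taking Route 2 when Route 1 was rewarded both count toward pair 1-2.
#' Inflated counts for pair 2-3 indicate that the two routes to the shared
#' Centre Goal Box are the hardest to discriminate.
#'
#' @param trials Trial table; only errors after the block's first correct
#'   trial are counted (requires `post_first_correct`, or computes it from
#'   trial order).
#' @return Tibble with six rows: `pair`, `route_a`, `route_b`, `count`, and
#'   attribute `"total_errors_post"`.
#' @export
confusion_pairs <- function(trials) {
  if (is.null(trials$post_first_correct)) {
    trials <- dplyr::mutate(
      dplyr::group_by(trials[order(trials$t_start), ], .data$block_id),
      post_first_correct = cumsum(.data$correct) > 0 | .data$correct)
    trials <- dplyr::ungroup(trials)
  }
  err <- trials[trials$post_first_correct & !trials$correct, ]
  if (any(err$route_id == err$rewarded_route))
    stop("error trial with chosen route equal to rewarded route",
         call. = FALSE)
  pairs <- utils::combn(1:4, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    n <- sum((err$route_id == a & err$rewarded_route == b) |
               (err$route_id == b & err$rewarded_route == a))
    tibble::tibble(pair = paste(a, b, sep = "-"), route_a = a, route_b = b,
                   count = n)
  })
  attr(out, "total_errors_post") <- nrow(err)
  out
}
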
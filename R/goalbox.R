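#' Goal-box population vectors per route
#'
#' For each cell, computes the mean firing rate inside the destination goal
#' box of each route, pooled over that route's correct trials (goal-phase
#' window: box entry to trial end). The four resulting vectors -- Left box
#' at the end of Route 1, Centre box at the end of Routes 2 and 3, Right box
#' at the end of Route 4 -- share cell ordering, so if the Centre Goal Box
#' is represented as one place regardless of approach, the two Centre
#' vectors should agree.
#'
#' @param cells Named list of spike trains (tibbles with `t`).
#' @param session A session object (`trajectory`, `trials`, `layout`).
#' @return Tibble of class `boxroute_vectors`: `cell_id` plus columns
#'   `left_r1`, `centre_r2`, `centre_r3`, `right_r4` (Hz). Cells never
#'   sampled in a box get `NA` there (excluded pairwise downstream).
#' @export
boxroute_vectors <- function(cells, session) {
  traj <- session$trajectory
  trials <- session$trials
  box_of <- c("left_goal_box", "centre_goal_box", "centre_goal_box",
              "right_goal_box")
  labels <- c("left_r1", "centre_r2", "centre_r3", "right_r4")
  dt <- stats::median(diff(traj$t))

  windows <- lapply(1:4, function(r) {
    tr <- trials[trials$route_id == r & trials$correct & !is.na(trials$t_goal), ]
    cbind(tr$t_goal, tr$t_end)
  })
  time_in <- vapply(windows, function(w)
    if (nrow(w)) sum(w[, 2] - w[, 1]) else 0, numeric(1))

  rate_of <- function(sp, w) {
    if (nrow(w) == 0) return(NA_real_)
    tot <- sum(w[, 2] - w[, 1])
    if (tot <= 0) return(NA_real_)
    n <- sum(vapply(seq_len(nrow(w)), function(i)
      sum(sp$t >= w[i, 1] & sp$t < w[i, 2]), numeric(1)))
    n / tot
  }
  out <- purrr::map_dfr(seq_along(cells), function(ci) {
    sp <- cells[[ci]]
    rates <- vapply(1:4, function(r) rate_of(sp, windows[[r]]), numeric(1))
    tibble::tibble(cell_id = names(cells)[ci] %||% as.character(ci),
                   left_r1 = rates[1], centre_r2 = rates[2],
                   centre_r3 = rates[3], right_r4 = rates[4])
  })
  attr(out, "time_in_box") <- stats::setNames(time_in, labels)
  class(out) <- c("boxroute_vectors", class(out))
  out
}

boxroute_labels <- c("left_r1", "centre_r2", "centre_r3", "right_r4")

#' Spearman correlations between goal-box population vectors
#'
#' Rank correlation for each unordered pair of the four box/route vectors
#' (six values); cells with missing entries are excluded pairwise, and
#' constant vectors yield `NA` with a warning.
#'
#' @param vectors A [boxroute_vectors()] tibble (>= 10 cells).
#' @return Tibble: `pair`, `label_a`, `label_b`, `rho`, `n`.
#' @export
boxroute_correlations <- function(vectors) {
  stopifnot(all(boxroute_labels %in% names(vectors)))
  if (nrow(vectors) < 10)
    warning("fewer than 10 cells; correlations are unstable")
  pairs <- utils::combn(boxroute_labels, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- vectors[[pairs[1, j]]]; b <- vectors[[pairs[2, j]]]
    ok <- stats::complete.cases(a, b)
    rho <- if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      warning("constant or empty vector: correlation undefined")
      NA_real_
    } else {
      stats::cor(a[ok], b[ok], method = "spearman")
    }
    tibble::tibble(pair = paste(pairs[1, j], pairs[2, j], sep = ":"),
                   label_a = pairs[1, j], label_b = pairs[2, j],
                   rho = rho, n = sum(ok))
  })
}

#' Shuffle test of goal-box vector similarity
#'
#' For each pair (A, B), the observed Spearman correlation is compared with
#' a null built by correlating A against vectors whose entry for each cell
#' is drawn at random from that cell's rates over the three labels other
#' than A's own -- shuffling route identity while preserving cell order.
#' The p-value is one minus the Epanechnikov-smoothed CDF percentile of the
#' observed correlation in the shuffle distribution: small p means the pair
#' is more similar than chance.
#'
#' @param vectors A [boxroute_vectors()] tibble.
#' @param n_shuffles Number of shuffles (10000 default).
#' @param seed RNG seed.
#' @param bw Optional bandwidth for the smoothed CDF.
#' @return The [boxroute_correlations()] tibble with `p_value` added.
#' @export
boxroute_shuffle_test <- function(vectors, n_shuffles = 10000, seed = NULL,
                                  bw = NULL) {
  if (n_shuffles < 100) warning("fewer than 100 shuffles; p-values are coarse")
  obs <- suppressWarnings(boxroute_correlations(vectors))
  mat <- as.matrix(vectors[, boxroute_labels])
  with_seed(seed, {
    obs$p_value <- vapply(seq_len(nrow(obs)), function(j) {
      a_lab <- obs$label_a[j]
      a <- vectors[[a_lab]]
      pool <- mat[, setdiff(boxroute_labels, a_lab), drop = FALSE]
      ok <- stats::complete.cases(a, pool)
      a <- a[ok]; pool <- pool[ok, , drop = FALSE]
      if (length(a) < 3 || is.na(obs$rho[j])) return(NA_real_)
      n <- length(a)
      rho_null <- vapply(seq_len(n_shuffles), function(s) {
        pick <- sample.int(3, n, replace = TRUE)
        stats::cor(a, pool[cbind(seq_len(n), pick)], method = "spearman")
      }, numeric(1))
      1 - epanechnikov_cdf(obs$rho[j], rho_null, bw)
    }, numeric(1))
  })
  obs
}
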
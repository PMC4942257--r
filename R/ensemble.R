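#' Cosine similarity between two population vectors
#'
#' \eqn{\langle x, y\rangle / (\|x\| \|y\|)}; for nonnegative firing-rate
#' vectors the value lies in \[0, 1\]. Undefined (NA, flagged by a warning)
#' when either vector is all zero.
#'
#' @param x,y Numeric vectors of equal length, same cell ordering.
#' @return Scalar similarity.
#' @examples
#' cosine_similarity(c(1, 0, 1), c(1, 1, 0))  # 0.5
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y))
    stop("population vectors must have the same length", call. = FALSE)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warning("zero population vector: cosine similarity undefined")
    return(NA_real_)
  }
  sum(x * y) / (nx * ny)
}

#' Per-trial population vectors for one sector
#'
#' Combines per-cell [sector_trial_stats()] rows into the trial-by-cell
#' firing-rate matrix used by the decoder.
#'
#' @param cell_stats Tibble with columns `cell_id`, `trial_id`, `route_id`,
#'   `firing_rate` (e.g. bound rows of per-cell [sector_trial_stats()]).
#' @return A list of class `population_vectors`: `rates` (trials x cells
#'   matrix), `trials` (tibble `trial_id`, `route_id`), `cell_ids`.
#' @export
trial_population_vectors <- function(cell_stats) {
  stopifnot(all(c("cell_id", "trial_id", "route_id", "firing_rate") %in%
                  names(cell_stats)))
  wide <- tidyr::pivot_wider(
    cell_stats[, c("cell_id", "trial_id", "route_id", "firing_rate")],
    names_from = "cell_id", values_from = "firing_rate", values_fill = 0)
  wide <- dplyr::arrange(wide, .data$trial_id)
  rates <- as.matrix(wide[, -(1:2), drop = FALSE])
  structure(list(rates = rates,
                 trials = wide[, c("trial_id", "route_id")],
                 cell_ids = colnames(rates)),
            class = "population_vectors")
}

# Leave-one-out route-average goal matrices, one 4 x n_cells matrix per
# trial (rows = routes present).
loo_goal_matrices <- function(pv, routes_used) {
  R <- pv$rates
  route <- pv$trials$route_id
  lapply(seq_len(nrow(R)), function(i) {
    t(vapply(routes_used, function(r) {
      sel <- route == r
      n <- sum(sel)
      s <- colSums(R[sel, , drop = FALSE])
      if (route[i] == r) (s - R[i, ]) / (n - 1) else s / n
    }, numeric(ncol(R))))
  })
}

#' Leave-one-out goal population vectors
#'
#' Route-average population vectors against which a held-out trial is
#' compared; the held-out trial is excluded from its own route's average.
#'
#' @param pv A [trial_population_vectors()] object of at least `min_cells`
#'   cells.
#' @param held_out_trial A `trial_id` present in `pv`.
#' @param min_cells Minimum ensemble size (6).
#' @return Matrix routes x cells (rownames `route_1`.. for routes with at
#'   least 2 trials; routes with fewer are excluded with a warning).
#' @export
goal_population_vectors <- function(pv, held_out_trial, min_cells = 6) {
  stopifnot(inherits(pv, "population_vectors"))
  if (ncol(pv$rates) < min_cells)
    stop("ensemble must contain at least ", min_cells, " place cells",
         call. = FALSE)
  i <- match(held_out_trial, pv$trials$trial_id)
  if (is.na(i)) stop("held_out_trial not found", call. = FALSE)
  n_per <- table(pv$trials$route_id)
  used <- as.integer(names(n_per)[n_per >= 2])
  if (length(used) < length(n_per))
    warning("routes with fewer than 2 trials excluded from goal vectors")
  g <- loo_goal_matrices(pv, used)[[i]]
  rownames(g) <- paste0("route_", used)
  g
}

# Decode every trial given optional per-neuron route permutation
# (perm: n_routes x n_cells integer matrix). Returns match counts matrix
# and the per-trial log.
decode_core <- function(Mlist, R, route, routes_used, perm = NULL,
                        want_log = FALSE) {
  nr <- length(routes_used)
  nc <- ncol(R)
  counts <- matrix(0, nr, nr)
  log_rows <- if (want_log) vector("list", nrow(R)) else NULL
  col_idx <- rep(seq_len(nc), each = nr)
  rnorm_tr <- sqrt(rowSums(R^2))
  skipped <- 0L
  for (i in seq_len(nrow(R))) {
    if (rnorm_tr[i] == 0) { skipped <- skipped + 1L; next }
    M <- Mlist[[i]]
    if (!is.null(perm)) M <- matrix(M[cbind(as.vector(perm), col_idx)], nr)
    gn <- sqrt(rowSums(M^2))
    sims <- as.numeric(M %*% R[i, ]) / (gn * rnorm_tr[i])
    sims[gn == 0] <- -1
    best <- which(sims == max(sims))
    best_g <- if (length(best) > 1) best[sample.int(length(best), 1)] else best
    ri <- match(route[i], routes_used)
    counts[ri, best_g] <- counts[ri, best_g] + 1
    if (want_log) {
      log_rows[[i]] <- tibble::tibble(
        route_id = route[i], matched_route = routes_used[best_g],
        correct_match = routes_used[best_g] == route[i],
        sim_correct = sims[ri],
        sim_matched = sims[best_g])
    }
  }
  list(counts = counts, log = log_rows, skipped = skipped)
}

#' Decode routes from population vectors by cosine similarity
#'
#' Each trial's population vector is compared with the four leave-one-out
#' route-average ("goal") vectors and matched to the one with the highest
#' cosine similarity (ties broken uniformly at random under `seed`). The
#' match matrix row r gives the percentage of route-r trials matched to
#' each goal vector; rows sum to 100.
#'
#' @param pv A [trial_population_vectors()] object (error trials should be
#'   excluded upstream).
#' @param min_cells Minimum ensemble size (6).
#' @param seed RNG seed for tie-breaking.
#' @return Object of class `decoding_result`: `match_matrix` (percent),
#'   `counts`, `log` (per-trial tibble), `routes`, `n_skipped`.
#' @export
decode_trials <- function(pv, min_cells = 6, seed = NULL) {
  stopifnot(inherits(pv, "population_vectors"))
  if (ncol(pv$rates) < min_cells)
    stop("ensemble must contain at least ", min_cells, " place cells",
         call. = FALSE)
  n_per <- table(pv$trials$route_id)
  used <- as.integer(names(n_per)[n_per >= 2])
  keep <- pv$trials$route_id %in% used
  R <- pv$rates[keep, , drop = FALSE]
  route <- pv$trials$route_id[keep]
  pv_used <- list(rates = R, trials = pv$trials[keep, ])
  Mlist <- loo_goal_matrices(pv_used, used)
  out <- with_seed(seed,
                   decode_core(Mlist, R, route, used, want_log = TRUE))
  log <- dplyr::bind_cols(
    pv$trials[keep, ][!sqrt(rowSums(R^2)) == 0, "trial_id"],
    dplyr::bind_rows(out$log))
  pct <- sweep(out$counts, 1, pmax(rowSums(out$counts), 1), "/") * 100
  dimnames(pct) <- list(paste0("route_", used), paste0("goal_", used))
  structure(list(match_matrix = pct, counts = out$counts, log = log,
                 routes = used, n_skipped = out$skipped,
                 pv = pv_used, Mlist = Mlist,
                 sessions = list(list(Mlist = Mlist, R = R, route = route,
                                      used = used))),
            class = "decoding_result")
}

#' Decode routes pooling several sessions' ensembles
#'
#' Runs the leave-one-out decoder on each session's population vectors and
#' pools the match counts over sessions before forming percentages, as in
#' the original multi-session analysis; the pooled percentages are what the
#' shuffle null is applied to. All sessions must share the same set of
#' decodable routes.
#'
#' @param pvs List of [trial_population_vectors()] objects, one per
#'   session (cells may differ between sessions).
#' @param min_cells Minimum ensemble size per session (6).
#' @param seed RNG seed for tie-breaking.
#' @return A `decoding_result` whose `match_matrix` pools all sessions;
#'   `per_session` holds the individual results.
#' @export
decode_sessions <- function(pvs, min_cells = 6, seed = NULL) {
  stopifnot(length(pvs) >= 1)
  res <- purrr::imap(pvs, function(pv, i)
    decode_trials(pv, min_cells = min_cells,
                  seed = if (is.null(seed)) NULL else seed + i))
  used <- res[[1]]$routes
  if (!all(purrr::map_lgl(res, ~identical(.x$routes, used))))
    stop("sessions decode different route sets; cannot pool", call. = FALSE)
  counts <- Reduce(`+`, purrr::map(res, "counts"))
  pct <- sweep(counts, 1, pmax(rowSums(counts), 1), "/") * 100
  dimnames(pct) <- dimnames(res[[1]]$match_matrix)
  structure(list(match_matrix = pct, counts = counts,
                 log = purrr::imap_dfr(res, ~dplyr::mutate(.x$log,
                                                           session = .y)),
                 routes = used,
                 n_skipped = sum(purrr::map_int(res, "n_skipped")),
                 per_session = res,
                 sessions = purrr::map(res, ~.x$sessions[[1]])),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result>: match percentages (rows = trajectory route)\n")
  print(round(x$match_matrix, 1))
  if (!is.null(x$p_matrix)) {
    cat("shuffle p-values:\n")
    print(signif(x$p_matrix, 3))
  }
  invisible(x)
}

# Epanechnikov-kernel smoothed empirical CDF evaluated at x.
epanechnikov_cdf <- function(x, samples, bw = NULL) {
  if (is.null(bw)) bw <- stats::bw.nrd0(samples)
  if (!is.finite(bw) || bw <= 0) bw <- 1e-9
  u <- pmin(pmax((x - samples) / bw, -1), 1)
  mean(0.5 + 0.75 * u - 0.25 * u^3)
}

#' Shuffle null for population-vector decoding
#'
#' Repeats the decoding after shuffling, independently for each neuron, the
#' identity of the route (but not of the neuron) in the goal vectors: each
#' neuron's four route-average rates are permuted among the routes. For
#' pooled multi-session results ([decode_sessions()]) every session gets an
#' independent per-neuron shuffle and the match counts are pooled exactly as
#' for the observed data. The p-value for cell (r, g) of the match matrix is
#' one minus the Epanechnikov-kernel smoothed CDF of the observed match
#' percentage within the shuffle distribution (bandwidth: Silverman's rule
#' unless given), so small p means more matches than expected by chance.
#'
#' @param decoded A [decode_trials()] result.
#' @param n_shuffles Number of shuffles (10000 default).
#' @param seed RNG seed.
#' @param bw Optional kernel bandwidth for the smoothed CDF.
#' @return The `decoding_result` with `p_matrix` and `shuffle_matrices`
#'   (n_shuffles x route x goal array) added.
#' @export
shuffle_null <- function(decoded, n_shuffles = 10000, seed = NULL, bw = NULL) {
  stopifnot(inherits(decoded, "decoding_result"))
  if (n_shuffles < 100) warning("fewer than 100 shuffles; p-values are coarse")
  used <- decoded$routes
  nr <- length(used)
  shuff <- with_seed(seed, {
    arr <- array(NA_real_, c(n_shuffles, nr, nr))
    for (s in seq_len(n_shuffles)) {
      cnt <- matrix(0, nr, nr)
      for (ses in decoded$sessions) {
        perm <- vapply(seq_len(ncol(ses$R)), function(j) sample.int(nr),
                       integer(nr))
        cnt <- cnt + decode_core(ses$Mlist, ses$R, ses$route, used,
                                 perm = perm)$counts
      }
      arr[s, , ] <- sweep(cnt, 1, pmax(rowSums(cnt), 1), "/") * 100
    }
    arr
  })
  p <- matrix(NA_real_, nr, nr, dimnames = dimnames(decoded$match_matrix))
  for (i in seq_len(nr)) for (j in seq_len(nr)) {
    p[i, j] <- 1 - epanechnikov_cdf(decoded$match_matrix[i, j],
                                    shuff[, i, j], bw)
  }
  decoded$p_matrix <- p
  decoded$n_shuffles <- n_shuffles
  decoded$shuffle_matrices <- shuff
  decoded
}

#' Within-block trend of decoding performance
#'
#' Tests whether decoding changes across a block of trials: Spearman rank
#' correlations between the within-block trial position and (a) the
#' correct-match indicator and (b) the cosine similarity to the correct
#' goal vector. Positions beyond the mean block length (12.5 trials) are
#' truncated.
#'
#' @param decoded A [decode_trials()] result.
#' @param trials Trial table with `trial_id` and `trial_in_block`.
#' @param max_position Positions greater than this are dropped (12).
#' @return Tibble with rows `match` and `similarity`: `rho`, `p_value`, `n`.
#' @export
within_block_trend <- function(decoded, trials, max_position = 12) {
  d <- dplyr::inner_join(decoded$log,
                         trials[, c("trial_id", "trial_in_block")],
                         by = "trial_id")
  d <- d[d$trial_in_block <= max_position, ]
  if (length(unique(d$trial_in_block)) < 3) {
    warning("fewer than 3 distinct block positions")
    return(tibble::tibble(measure = c("match", "similarity"),
                          rho = NA_real_, p_value = NA_real_, n = nrow(d)))
  }
  safe_spearman <- function(x, y) {
    if (stats::sd(y) == 0 || stats::sd(x) == 0)
      return(c(rho = 0, p = 1))   # constant series carry no trend
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }
  m <- safe_spearman(d$trial_in_block, as.numeric(d$correct_match))
  s <- safe_spearman(d$trial_in_block, d$sim_correct)
  tibble::tibble(measure = c("match", "similarity"),
                 rho = unname(c(m["rho"], s["rho"])),
                 p_value = unname(c(m["p"], s["p"])), n = nrow(d))
}
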
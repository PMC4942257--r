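#' Synthetic cell populations embodying the route and goal hypotheses
#'
#' Convenience constructors for the cell populations used in the recovery
#' and decoding analyses. All cells have Gaussian fields jittered around
#' the start-box centre (the sector with the longest dwell), a 4 Hz peak
#' over a 0.2 Hz baseline, and a gain of 4 on the preferred condition --
#' the effect size used throughout the package's validation analyses.
#'
#' * `route_coded_population()`: cell i prefers route `((i-1) mod 4) + 1`
#'   (raised `route_gains` entry) -- the route-specific hypothesis.
#' * `goal_coded_population()`: cell i prefers goal `((i-1) mod 3) + 1`
#'   (raised `goal_gains` entry), so routes 2 and 3 share the centre
#'   pattern -- the goal-dependent hypothesis.
#' * `null_population()`: no modulation; used for type-I calibration.
#' * `goalbox_population()`: place fields in the three goal boxes with
#'   independent lognormal per-cell peaks (a route-invariant goal-box code)
#'   plus a route-gained start-box field (route-dependent approach firing);
#'   the fixture for the goal-box similarity analysis.
#'
#' @param n_cells Number of cells.
#' @param gain Multiplicative gain on the preferred route/goal.
#' @param field_jitter Uniform half-width (cm) of field-centre jitter.
#' @param seed RNG seed for the field positions (and box peaks).
#' @return Named list of [cell_spec()] objects.
#' @name populations
NULL

#' @rdname populations
#' @export
route_coded_population <- function(n_cells = 12, gain = 4, field_jitter = 6,
                                   seed = 1) {
  with_seed(seed, {
    specs <- purrr::map(seq_len(n_cells), function(i) {
      g <- rep(1, 4); g[((i - 1) %% 4) + 1] <- gain
      cell_spec(stats::runif(2, -field_jitter, field_jitter),
                field_width = 10, peak_rate = 4, route_gains = g,
                baseline_rate = 0.2)
    })
    stats::setNames(specs, sprintf("cell%03d", seq_len(n_cells)))
  })
}

#' @rdname populations
#' @export
goal_coded_population <- function(n_cells = 12, gain = 4, field_jitter = 6,
                                  seed = 1) {
  with_seed(seed, {
    specs <- purrr::map(seq_len(n_cells), function(i) {
      gg <- rep(1, 3); gg[((i - 1) %% 3) + 1] <- gain
      cell_spec(stats::runif(2, -field_jitter, field_jitter),
                field_width = 10, peak_rate = 4, goal_gains = gg,
                baseline_rate = 0.2)
    })
    stats::setNames(specs, sprintf("cell%03d", seq_len(n_cells)))
  })
}

#' @rdname populations
#' @export
null_population <- function(n_cells = 1, field_jitter = 6, seed = 1) {
  with_seed(seed, {
    specs <- purrr::map(seq_len(n_cells), function(i)
      cell_spec(stats::runif(2, -field_jitter, field_jitter),
                field_width = 10, peak_rate = 4, baseline_rate = 0.2))
    stats::setNames(specs, sprintf("cell%03d", seq_len(n_cells)))
  })
}

#' @rdname populations
#' @export
goalbox_population <- function(n_cells = 60, gain = 4, seed = 1) {
  layout <- build_maze_layout()
  boxes <- layout$sector_table
  box_centres <- rbind(
    unlist(boxes[boxes$sector == "left_goal_box", c("cx", "cy")]),
    unlist(boxes[boxes$sector == "centre_goal_box", c("cx", "cy")]),
    unlist(boxes[boxes$sector == "right_goal_box", c("cx", "cy")]))
  with_seed(seed, {
    specs <- purrr::map(seq_len(n_cells), function(i) {
      g <- rep(1, 4); g[((i - 1) %% 4) + 1] <- gain
      centres <- rbind(box_centres, c(0, 0))
      peaks <- c(stats::rlnorm(3, log(3), 0.8), stats::runif(1, 1, 5))
      cell_spec(centres, field_width = 8, peak_rate = peaks,
                route_gains = g, baseline_rate = 0.1)
    })
    stats::setNames(specs, sprintf("cell%03d", seq_len(n_cells)))
  })
}
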
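# Shared fixtures, built lazily once per test run.
.fx <- new.env(parent = emptyenv())

fx_maze <- function() {
  if (is.null(.fx$maze)) .fx$maze <- build_maze_layout()
  .fx$maze
}

# One standard recording-like session (4 blocks x 11 post-identification
# trials, ~11 trials/route), with sectors pre-assigned.
fx_session <- function() {
  if (is.null(.fx$session)) {
    s <- simulate_session(fx_maze(), session_config(seed = 21))
    s$trajectory <- assign_sectors(s$trajectory, fx_maze())
    .fx$session <- s
  }
  .fx$session
}

# Start-box place cell with optional route/goal gains; returns its
# start-box per-trial stats on the standard session.
fx_startbox_stats <- function(route_gains = c(1, 1, 1, 1),
                              goal_gains = c(1, 1, 1), seed = 1,
                              sector = "start_box") {
  spec <- cell_spec(c(0, 0), field_width = 10, peak_rate = 4,
                    route_gains = route_gains, goal_gains = goal_gains,
                    baseline_rate = 0.2)
  sp <- simulate_place_cell(spec, fx_session()$trajectory, seed = seed)
  sector_trial_stats(sp, fx_session(), sector)
}

# Hand-made minimal rate_map object for closed-form checks.
fx_manual_map <- function(rate, occupancy = NULL) {
  rate <- as.matrix(rate)
  if (is.null(occupancy)) occupancy <- matrix(1, nrow(rate), ncol(rate))
  structure(list(rate = rate, occupancy = occupancy,
                 visited = !is.na(rate),
                 x_centres = seq_len(nrow(rate)),
                 y_centres = seq_len(ncol(rate)),
                 params = smoothing_params(), n_spikes = NA,
                 mean_rate = NA),
            class = "rate_map")
}

# Feature cluster with exact sample moments: mean 0, covariance identity
# (2d points at +/- c e_i), so Mahalanobis == squared Euclidean exactly.
fx_identity_cluster <- function(d) {
  c0 <- sqrt((2 * d - 1) / 2)
  rbind(diag(c0, d), diag(-c0, d))
}

# Deterministic per-trial stats table for ANCOVA-level tests.
fx_random_stats <- function(n_per_route = 10, seed = 1, effect = rep(0, 4)) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    route <- rep(1:4, each = n_per_route)
    n <- length(route)
    tibble::tibble(
      trial_id = seq_len(n), route_id = route,
      time_s = runif(n, 5, 9),
      mean_x = rnorm(n, 0, 2), mean_y = rnorm(n, 0, 2),
      mean_speed = runif(n, 1, 4),
      firing_rate = rgamma(n, shape = 4, rate = 1) + effect[route],
      n_spikes = NA_integer_)
  })
}
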
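#' Specification of a synthetic place cell
#'
#' Describes a place cell as one or more Gaussian place fields whose in-field
#' rate is modulated multiplicatively by the route the animal is running
#' (`route_gains`, length 4) and/or by the goal it is heading to
#' (`goal_gains`, named left/centre/right). Because routes 2 and 3 share the
#' Centre Goal Box, the centre goal gain applies identically to both -- a
#' purely goal-coding cell is `goal_gains = c(left, centre, right)` with all
#' `route_gains` equal, and a route-specific cell raises a single route gain.
#'
#' @param field_centers Matrix (or length-2 vector) of field centres, cm.
#' @param field_width Gaussian field radius sigma, cm.
#' @param peak_rate In-field peak rate(s), Hz; recycled over fields.
#' @param route_gains Multiplier per route, length 4, all >= 0.
#' @param goal_gains Multiplier per goal (left, centre, right), all >= 0.
#' @param baseline_rate Position-independent baseline rate, Hz.
#' @return A list of class `cell_spec`.
#' @export
cell_spec <- function(field_centers, field_width = 8, peak_rate = 10,
                      route_gains = c(1, 1, 1, 1),
                      goal_gains = c(1, 1, 1),
                      baseline_rate = 0.1) {
  if (is.null(dim(field_centers))) field_centers <- matrix(field_centers, ncol = 2)
  stopifnot(ncol(field_centers) == 2, length(route_gains) == 4,
            length(goal_gains) == 3)
  if (any(c(route_gains, goal_gains, peak_rate, baseline_rate, field_width) < 0))
    stop("rates, widths and gains must be >= 0", call. = FALSE)
  structure(list(field_centers = field_centers, field_width = field_width,
                 peak_rate = rep_len(peak_rate, nrow(field_centers)),
                 route_gains = route_gains,
                 goal_gains = stats::setNames(goal_gains,
                                              c("left", "centre", "right")),
                 baseline_rate = baseline_rate),
            class = "cell_spec")
}

# Intensity (Hz) of the cell at each trajectory sample. The route/goal gain
# modulates the approach (hold and run phases of a trial); firing during the
# goal-box dwell and the inter-trial carry is unmodulated, so goal-box
# firing is route-invariant by construction.
cell_intensity <- function(spec, traj) {
  field <- rep(0, nrow(traj))
  for (f in seq_len(nrow(spec$field_centers))) {
    d2 <- (traj$x - spec$field_centers[f, 1])^2 +
      (traj$y - spec$field_centers[f, 2])^2
    field <- field + spec$peak_rate[f] * exp(-d2 / (2 * spec$field_width^2))
  }
  gain <- rep(1, nrow(traj))
  mod <- !is.na(traj$route_id)
  if (!is.null(traj$phase)) mod <- mod & traj$phase != "goal"
  r <- traj$route_id[mod]
  gain[mod] <- spec$route_gains[r] * spec$goal_gains[route_goal_map[r]]
  spec$baseline_rate + field * gain
}

#' Simulate an inhomogeneous-Poisson place-cell spike train
#'
#' Draws spikes from an inhomogeneous Poisson process whose intensity is the
#' cell's Gaussian field rate at the animal's current position, multiplied by
#' the route and goal gains of the current trial, plus a baseline:
#' \deqn{\lambda(t) = b + p\, e^{-\|pos(t)-c\|^2/(2\sigma^2)}\,
#'   g_{route(t)}\, g_{goal(t)}.}
#' Sampling is by thinning against the maximum intensity, with \eqn{\lambda}
#' interpolated linearly between tracking samples.
#'
#' @param spec A [cell_spec()].
#' @param traj Trajectory tibble (`t, x, y, route_id`) from
#'   [simulate_session()].
#' @param seed RNG seed.
#' @return Tibble of class `spike_train` with column `t` (spike times, s) and
#'   attribute `"intensity_integral"` (the expected spike count
#'   \eqn{\int \lambda\, dt} over the session).
#' @export
simulate_place_cell <- function(spec, traj, seed = NULL) {
  stopifnot(inherits(spec, "cell_spec"), is.data.frame(traj))
  if (nrow(traj) < 2) stop("trajectory must be nonempty", call. = FALSE)
  lam <- cell_intensity(spec, traj)
  lam_max <- max(lam) * 1.001 + 1e-9
  t0 <- traj$t[1]; t1 <- traj$t[nrow(traj)]
  dt <- diff(traj$t)
  integral <- sum((lam[-1] + lam[-length(lam)]) / 2 * dt)
  spikes <- with_seed(seed, {
    n_cand <- stats::rpois(1, lam_max * (t1 - t0))
    cand <- sort(stats::runif(n_cand, t0, t1))
    lam_c <- stats::approx(traj$t, lam, xout = cand)$y
    cand[stats::runif(n_cand) < lam_c / lam_max]
  })
  structure(tibble::tibble(t = spikes), class = c("spike_train", "tbl_df",
                                                  "tbl", "data.frame"),
            intensity_integral = integral)
}

#' Simulate a spike-feature cloud with known separation
#'
#' Generates a Gaussian cluster of spike feature vectors plus a set of
#' non-cluster ("noise") spikes whose mean is displaced from the cluster mean
#' by a given Mahalanobis distance in the metric of the cluster covariance.
#' This is the ground-truth fixture for the cluster-quality metrics: larger
#' `separation` must raise the isolation distance and lower the L-ratio.
#'
#' @param n_cluster Number of cluster spikes (must exceed `dim`).
#' @param n_noise Number of non-cluster spikes.
#' @param separation Mahalanobis distance between cluster and noise means.
#' @param dim Feature-space dimension (8 matches four-channel tetrode pairs
#'   of features).
#' @param seed RNG seed.
#' @return A list of class `feature_cloud`: `cluster_points`, `noise_points`
#'   (matrices), and ground-truth `mean`, `covariance`, `noise_mean`.
#' @export
simulate_feature_cloud <- function(n_cluster = 200, n_noise = 400,
                                   separation = 8, dim = 8, seed = NULL) {
  if (n_cluster <= dim)
    stop("n_cluster must exceed the feature dimension", call. = FALSE)
  with_seed(seed, {
    a <- matrix(stats::rnorm(dim * dim), dim)
    sigma <- crossprod(a) / dim + diag(dim)
    ch <- chol(sigma)
    mu <- stats::rnorm(dim)
    u <- stats::rnorm(dim); u <- u / sqrt(sum(u^2))
    shift <- separation * as.numeric(u %*% ch)   # Mahalanobis length = separation
    cluster <- sweep(matrix(stats::rnorm(n_cluster * dim), n_cluster) %*% ch,
                     2, mu, "+")
    noise <- sweep(matrix(stats::rnorm(n_noise * dim), n_noise) %*% ch,
                   2, mu + shift, "+")
    structure(list(cluster_points = cluster, noise_points = noise,
                   mean = mu, covariance = sigma, noise_mean = mu + shift),
              class = "feature_cloud")
  })
}
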
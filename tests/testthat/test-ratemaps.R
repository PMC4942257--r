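test_that("Gaussian kernel has its closed form and symmetry", {
  expect_equal(gaussian_kernel(0), 1)
  expect_equal(gaussian_kernel(1), exp(-0.5))
  u <- seq(-3, 3, by = 0.5)
  expect_equal(gaussian_kernel(-u), gaussian_kernel(u))
})

test_that("rate map reduces to n/T for a stationary animal and 0 without spikes", {
  traj <- tibble::tibble(t = seq(0, 10, by = 0.02), x = 0, y = 0)
  bbox <- c(-13.75, 13.75, -13.75, 13.75)  # grid centred so one bin sits at 0
  m0 <- compute_rate_map(numeric(0), traj, bbox = bbox)
  expect_true(all(m0$rate[m0$visited] == 0))
  expect_true(all(is.na(m0$rate[!m0$visited])))

  spikes <- seq(0.5, 9.5, length.out = 20)
  m <- compute_rate_map(spikes, traj, bbox = bbox)
  centre_bin <- c(which(m$x_centres == 0), which(m$y_centres == 0))
  expect_equal(m$rate[centre_bin[1], centre_bin[2]], 20 / 10,
               tolerance = 0.01)
})

test_that("rate map equals a brute-force double-loop oracle to 1e-10", {
  set.seed(9)
  traj <- tibble::tibble(t = cumsum(runif(300, 0.01, 0.05)),
                         x = runif(300, 0, 25), y = runif(300, 0, 25))
  spikes <- sort(runif(40, min(traj$t), max(traj$t)))
  params <- smoothing_params(h = 2.5, bin_size = 2.5, visit_radius = 5)
  bbox <- c(0, 25, 0, 25)
  m <- compute_rate_map(spikes, traj, params, bbox = bbox)
  expect_equal(length(m$x_centres), 10)

  sx <- approx(traj$t, traj$x, xout = spikes)$y
  sy <- approx(traj$t, traj$y, xout = spikes)$y
  dt <- c(diff(traj$t), 0); dt[length(dt)] <- dt[length(dt) - 1]
  for (i in seq_along(m$x_centres)) for (j in seq_along(m$y_centres)) {
    bx <- m$x_centres[i]; by <- m$y_centres[j]
    d2p <- (traj$x - bx)^2 + (traj$y - by)^2
    vis <- any(d2p <= params$visit_radius^2)
    expect_identical(m$visited[i, j], vis)
    if (vis) {
      num <- sum(exp(-((sx - bx)^2 + (sy - by)^2) / (2 * params$h^2)))
      den <- sum(exp(-d2p / (2 * params$h^2)) * dt)
      expect_equal(m$rate[i, j], num / den, tolerance = 1e-10)
    }
  }
})

test_that("homogeneous firing over a covered arena recovers the rate", {
  set.seed(3)
  n <- 600 / 0.02
  traj <- tibble::tibble(t = seq(0.02, 600, by = 0.02),
                         x = runif(n, 0, 30), y = runif(n, 0, 30))
  r <- 3
  spikes <- sort(runif(r * 600, 0, 600))
  m <- compute_rate_map(spikes, traj, bbox = c(0, 30, 0, 30))
  expect_lt(abs(mean(m$rate[m$visited]) - r) / r, 0.1)
})

test_that("rate map estimator is symmetric under time reversal", {
  set.seed(5)
  tt <- seq(0, 30, by = 0.02)
  traj <- tibble::tibble(t = tt, x = 15 + 10 * sin(tt / 3),
                         y = 15 + 10 * cos(tt / 5))
  spikes <- sort(runif(50, 0, 30))
  fwd <- compute_rate_map(spikes, traj, bbox = c(0, 30, 0, 30))
  rev_traj <- tibble::tibble(t = max(tt) - rev(tt), x = rev(traj$x),
                             y = rev(traj$y))
  rev_spikes <- sort(max(tt) - spikes)
  bwd <- compute_rate_map(rev_spikes, rev_traj, bbox = c(0, 30, 0, 30))
  expect_equal(fwd$rate, bwd$rate, tolerance = 1e-10)
})

test_that("enlarging the visit radius never shrinks the visited set", {
  set.seed(6)
  traj <- tibble::tibble(t = seq(0, 20, by = 0.02),
                         x = runif(1001, 0, 30), y = runif(1001, 0, 30))
  v1 <- compute_rate_map(numeric(0), traj, smoothing_params(visit_radius = 3),
                         bbox = c(0, 30, 0, 30))$visited
  v2 <- compute_rate_map(numeric(0), traj, smoothing_params(visit_radius = 6),
                         bbox = c(0, 30, 0, 30))$visited
  expect_true(all(v2[v1]))
})

test_that("spatial information matches closed forms and its invariances", {
  # uniform rate over uniform occupancy -> 0 bits/spike
  expect_equal(spatial_information(fx_manual_map(matrix(2, 3, 3))), 0)

  # four equally occupied bins, rates (4R, 0, 0, 0) -> 2 bits/spike
  m4 <- fx_manual_map(matrix(c(4, 0, 0, 0), 2, 2))
  expect_equal(spatial_information(m4), 2)

  # invariant under rate rescaling; nonnegative for random maps
  set.seed(2)
  for (i in 1:10) {
    r <- matrix(rexp(16), 4, 4)
    m <- fx_manual_map(r, occupancy = matrix(runif(16, 0.5, 2), 4, 4))
    si <- spatial_information(m)
    expect_gte(si, 0)
    expect_equal(spatial_information(fx_manual_map(3.7 * r, m$occupancy)), si)
  }

  expect_warning(si0 <- spatial_information(fx_manual_map(matrix(0, 2, 2))),
                 "all-zero")
  expect_equal(si0, 0)
})

test_that("place-field counting finds bumps and respects its thresholds", {
  grid <- expand.grid(x = 1:20, y = 1:20)
  bump <- function(cx, cy) matrix(5 * exp(-((grid$x - cx)^2 +
                                              (grid$y - cy)^2) / 8), 20, 20)
  expect_equal(count_place_fields(fx_manual_map(bump(10, 10)))$n_fields, 1)
  two <- bump(5, 5) + bump(15, 15)
  expect_equal(count_place_fields(fx_manual_map(two))$n_fields, 2)
  expect_equal(count_place_fields(fx_manual_map(matrix(0, 5, 5)))$n_fields, 0)
  # raising min_bins can only reduce the count
  expect_lte(count_place_fields(fx_manual_map(two), min_bins = 30)$n_fields, 2)
})

test_that("sector activity profile flags start-box over-representation", {
  maze <- fx_maze()
  sess <- fx_session()
  # cells firing only in the start box: counts (N, 0, ..., 0), strong
  # negative distance correlation
  cells <- purrr::map(1:6, function(i) {
    spec <- cell_spec(c(0, 0), field_width = 6, peak_rate = 8,
                      baseline_rate = 0)
    simulate_place_cell(spec, sess$trajectory, seed = 40 + i)
  })
  names(cells) <- paste0("c", 1:6)
  prof <- sector_activity_profile(cells, sess$trajectory, maze)
  counts <- prof$profile$active_cells
  expect_equal(counts[prof$profile$sector == "start_box"], 6)
  expect_true(all(counts[!prof$profile$sector %in%
                           c("start_box", "central_stem")] == 0))
  expect_lt(prof$distance_cor$estimate, -0.5)
  expect_equal(prof$distance_cor$df, 12)

  # a cell above threshold everywhere is active in all 14 sectors
  unif <- cell_spec(c(0, 55), field_width = 120, peak_rate = 3,
                    baseline_rate = 2)
  sp <- simulate_place_cell(unif, sess$trajectory, seed = 77)
  prof2 <- sector_activity_profile(list(u = sp), sess$trajectory, maze)
  expect_equal(sum(prof2$profile$active_cells), 14)
})
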
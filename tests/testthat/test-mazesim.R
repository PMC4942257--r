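test_that("canonical layout satisfies the maze invariants", {
  maze <- fx_maze()
  expect_length(maze$sectors, 14)
  expect_equal(nrow(maze$sector_table), 14)

  # enclosures have a 25 x 25 cm bounding box; alleys 20 x 10
  sb <- maze$sectors$start_box
  expect_equal(diff(range(sb[, 1])), 25)
  expect_equal(diff(range(sb[, 2])), 25)
  cs <- maze$sectors$central_stem
  expect_equal(diff(range(cs[, 1])), 10)
  expect_equal(diff(range(cs[, 2])), 20)

  # route structure: shared prefix, shared stems, shared centre goal
  for (r in maze$routes)
    expect_equal(r$sectors[1:3], c("start_box", "central_stem",
                                   "choice_point"))
  expect_equal(maze$routes[[1]]$sectors[4], maze$routes[[2]]$sectors[4])
  expect_equal(maze$routes[[3]]$sectors[4], maze$routes[[4]]$sectors[4])
  expect_equal(dplyr::last(maze$routes[[2]]$sectors),
               dplyr::last(maze$routes[[3]]$sectors))
  expect_equal(dplyr::last(maze$routes[[2]]$sectors), "centre_goal_box")

  # centerlines lie inside the union of their route's sectors
  for (r in maze$routes) {
    cl <- r$centerline
    for (seg in seq_len(nrow(cl) - 1)) {
      f <- seq(0.01, 0.99, length.out = 25)
      px <- cl[seg, 1] + f * (cl[seg + 1, 1] - cl[seg, 1])
      py <- cl[seg, 2] + f * (cl[seg + 1, 2] - cl[seg, 2])
      hit <- sector_at(px, py, maze)
      expect_false(anyNA(hit))
      expect_true(all(hit %in% r$sectors))
    }
  }

  expect_error(build_maze_layout(box_size = -1), "positive")
})

test_that("sector assignment agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  maze <- fx_maze()
  set.seed(4)
  pts <- data.frame(x = runif(400, -80, 80), y = runif(400, -20, 125))
  mine <- sector_at(pts$x, pts$y, maze)
  for (nm in names(maze$sectors)) {
    poly <- maze$sectors[[nm]]
    oracle <- mgcv::in.out(rbind(poly, poly[1, ]), as.matrix(pts))
    # interior points (not on any boundary, which random draws avoid a.s.)
    expect_equal(!is.na(mine) & mine == nm, oracle, ignore_attr = TRUE)
  }
})

test_that("session generator is deterministic and follows the task design", {
  a <- simulate_session(fx_maze(), session_config(seed = 5))
  b <- simulate_session(fx_maze(), session_config(seed = 5))
  expect_identical(a$trials, b$trials)
  expect_identical(a$trajectory, b$trajectory)

  # no-error model: 4 blocks x 11 trials, all correct
  cfg0 <- session_config(error_model = list(search = FALSE, p_post = 0),
                         seed = 2)
  s0 <- simulate_session(fx_maze(), cfg0)
  expect_equal(nrow(s0$trials), 44)
  expect_true(all(s0$trials$correct))

  # with search, errors occur before the first correct trial of a block
  s1 <- fx_session()
  pre <- s1$trials[!s1$trials$post_first_correct, ]
  expect_true(all(!pre$correct))
  blocks <- split(s1$trials, s1$trials$block_id)
  for (b in blocks) {
    expect_gte(sum(b$post_first_correct), 11)
    expect_true(b$correct[which(b$post_first_correct)[1]])
  }
  expect_error(simulate_session(fx_maze(),
                                session_config(route_schedule = integer(0))),
               "empty")
})

test_that("trajectories are time-monotone, gap-free and stay in the maze", {
  maze <- fx_maze()
  for (i in 1:8) {
    set.seed(i)
    cfg <- session_config(
      n_blocks = sample(2:4, 1),
      route_schedule = sample(1:4),
      error_model = list(search = sample(c(TRUE, FALSE), 1),
                         p_post = runif(1, 0, 0.3)),
      speed_profile = runif(1, 15, 35),
      seed = 100 + i)
    s <- simulate_session(maze, cfg)
    expect_true(all(diff(s$trajectory$t) > 0))
    expect_lte(max(diff(s$trajectory$t)), 3 / cfg$position_rate)
    expect_false(anyNA(sector_at(s$trajectory$x, s$trajectory$y, maze)))
    # one row per trial, consistent windows
    expect_true(all(s$trials$t_end > s$trials$t_start))
    expect_true(all(diff(s$trials$t_start) > 0))
  }
})

test_that("spike generator realises the programmed intensity", {
  traj <- fx_session()$trajectory
  spec2 <- cell_spec(c(0, 0), field_width = 10, peak_rate = 4,
                     route_gains = c(1, 4, 1, 1), baseline_rate = 0.2)

  # same seed, identical trains
  expect_identical(simulate_place_cell(spec2, traj, seed = 3),
                   simulate_place_cell(spec2, traj, seed = 3))

  # route-2 gain raises start-box rates on route 2 (one-sided rank test)
  st <- fx_startbox_stats(route_gains = c(1, 4, 1, 1), seed = 4)
  wt <- wilcox.test(st$firing_rate[st$route_id == 2],
                    st$firing_rate[st$route_id == 1],
                    alternative = "greater", exact = FALSE)
  expect_lt(wt$p.value, 0.01)

  # mean spike count matches the intensity integral within 3 SE
  spec0 <- cell_spec(c(0, 0), field_width = 10, peak_rate = 4,
                     baseline_rate = 0.2)
  counts <- vapply(1:100, function(i)
    nrow(simulate_place_cell(spec0, traj, seed = 200 + i)), numeric(1))
  expected <- attr(simulate_place_cell(spec0, traj, seed = 1),
                   "intensity_integral")
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("empirical in-region rate converges to the programmed intensity", {
  # stationary dwell: constant position inside the field for 600 s
  traj <- tibble::tibble(t = seq(0, 600, by = 0.02), x = 0, y = 0,
                         trial_id = NA_integer_, route_id = NA_integer_,
                         phase = "hold")
  spec <- cell_spec(c(0, 0), field_width = 10, peak_rate = 5,
                    baseline_rate = 0)
  sp <- simulate_place_cell(spec, traj, seed = 8)
  expect_lt(abs(nrow(sp) / 600 - 5) / 5, 0.1)
})

test_that("feature clouds are reproducible and separation drives isolation", {
  expect_identical(simulate_feature_cloud(50, 100, 6, seed = 2),
                   simulate_feature_cloud(50, 100, 6, seed = 2))
  expect_error(simulate_feature_cloud(5, 10, 6, dim = 8), "exceed")

  meds <- vapply(c(0, 4, 8, 12), function(s)
    median(vapply(1:10, function(i) {
      fc <- simulate_feature_cloud(200, 400, separation = s, seed = i)
      isolation_distance(fc$cluster_points, fc$noise_points)
    }, numeric(1))), numeric(1))
  expect_true(all(diff(meds) > 0))
  # at zero separation the n_c-th order statistic sits near the chi2 median
  expect_lt(meds[1], qchisq(0.7, 8))
  expect_gt(meds[1], qchisq(0.3, 8))
})
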
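# Hand-built session whose single trial runs straight up the central stem
# (1 cm per 0.025 s sample => 40 cm/s), for arithmetic-level checks.
fx_stem_session <- function() {
  y <- seq(0, 45, by = 1)
  traj <- tibble::tibble(t = 0.025 * seq_along(y), x = 0, y = y,
                         trial_id = 1L, route_id = 1L, phase = "run")
  trials <- tibble::tibble(trial_id = 1L, block_id = 1L, trial_in_block = 1L,
                           post_first_correct = TRUE, rewarded_route = 1L,
                           route_id = 1L, goal = "left", correct = TRUE,
                           t_start = 0, t_run = 0, t_goal = NA_real_,
                           t_end = max(traj$t))
  list(trajectory = assign_sectors(traj, fx_maze()), trials = trials,
       layout = fx_maze())
}

test_that("sector trial statistics compute rate, position and speed", {
  sess <- fx_stem_session()
  # central stem spans y in (12.5, 32.5]: 20 samples at 0.025 s
  in_t <- sess$trajectory$t[sess$trajectory$sector == "central_stem"]
  spikes <- in_t[1:6]   # 6 spikes while in the stem
  st <- sector_trial_stats(spikes, sess, "central_stem")
  expect_equal(nrow(st), 1)
  expect_equal(st$time_s, 0.5)
  expect_equal(st$n_spikes, 6L)
  expect_equal(st$firing_rate, 12)      # 6 spikes / 0.5 s
  expect_equal(st$mean_speed, 40)       # 20 cm / 0.5 s
  expect_equal(st$mean_x, 0)

  # 6 spikes over 2 s -> 3 Hz on a slower fixture
  slow <- sess
  slow$trajectory$t <- slow$trajectory$t * 4
  slow$trials$t_end <- max(slow$trajectory$t)
  st2 <- sector_trial_stats(spikes * 4, slow, "central_stem")
  expect_equal(st2$firing_rate, 3)
  expect_equal(st2$mean_speed, 10)

  # a trial that never enters the sector contributes no row
  expect_equal(nrow(sector_trial_stats(spikes, sess, "left_goal_box")), 0)
})

test_that("boundary spikes follow the half-open sector convention", {
  y <- seq(0, 45, by = 0.5)   # passes exactly through the edge at y = 12.5
  traj <- tibble::tibble(t = 0.025 * seq_along(y), x = 0, y = y,
                         trial_id = 1L, route_id = 1L, phase = "run")
  trials <- fx_stem_session()$trials
  trials$t_end <- max(traj$t)
  sess <- list(trajectory = assign_sectors(traj, fx_maze()), trials = trials,
               layout = fx_maze())
  # spike interpolates exactly onto the start box / central stem edge
  # (y = 12.5): it must be counted in exactly one of the two sectors
  t_edge <- sess$trajectory$t[sess$trajectory$y == 12.5]
  st_box <- sector_trial_stats(t_edge, sess, "start_box")
  st_stem <- sector_trial_stats(t_edge, sess, "central_stem")
  n_box <- if (nrow(st_box)) st_box$n_spikes else 0L
  n_stem <- if (nrow(st_stem)) st_stem$n_spikes else 0L
  expect_equal(n_box + n_stem, 1L)
  # and consistently with the sample-assignment convention
  side <- sector_at(0, 12.5, fx_maze())
  expect_equal(if (side == "start_box") n_box else n_stem, 1L)
})

test_that("the >1 Hz activity rule pools within routes and is strict", {
  mk <- function(route_rates) {
    purrr::imap_dfr(route_rates, function(r, i)
      tibble::tibble(trial_id = i, route_id = i, n_spikes = round(r * 10),
                     time_s = 10, firing_rate = r, mean_x = 0, mean_y = 0,
                     mean_speed = 1))
  }
  expect_true(is_active_in_sector(mk(c(0.2, 1.5, 0.3, 0.1))))
  expect_false(is_active_in_sector(mk(c(1, 1, 1, 1))))   # strictly >
  inactive <- is_active_in_sector(empty_stats <- mk(numeric(0)))
  expect_false(inactive)
  expect_match(attr(inactive, "reason"), "no trials")
})

test_that("ranked ANCOVA equals a brute-force implementation to 1e-8", {
  for (i in 1:20) {
    st <- fx_random_stats(n_per_route = sample(6:12, 1), seed = 1000 + i)
    res <- ranked_ancova(st, alpha = 1)   # always produce post-hocs

    # independent oracle: explicit ranks, normal-equations regression,
    # textbook one-way ANOVA
    rdv <- rank(st$firing_rate, ties.method = "average")
    X <- cbind(1, rank(st$mean_x, ties.method = "average"),
               rank(st$mean_y, ties.method = "average"),
               rank(st$mean_speed, ties.method = "average"))
    beta <- solve(t(X) %*% X, t(X) %*% rdv)
    r <- as.numeric(rdv - X %*% beta)
    g <- factor(st$route_id)
    gm <- tapply(r, g, mean); ni <- tapply(r, g, length)
    ssb <- sum(ni * (gm - mean(r))^2)
    ssw <- sum((r - gm[g])^2)
    f_oracle <- (ssb / (nlevels(g) - 1)) / (ssw / (length(r) - nlevels(g)))
    expect_equal(res$statistic, f_oracle, tolerance = 1e-8)

    # post-hoc agrees with stats::TukeyHSD on the residual ANOVA
    th <- TukeyHSD(aov(r ~ g))$g
    ours <- res$posthoc
    for (k in seq_len(nrow(ours))) {
      nm <- paste(ours$route_b[k], ours$route_a[k], sep = "-")
      expect_equal(ours$p_adj[k], th[nm, "p adj"], tolerance = 1e-6)
    }
  }
})

test_that("ranked ANCOVA is invariant to monotone transforms and handles ties", {
  st <- fx_random_stats(seed = 31)
  f0 <- ranked_ancova(st)$statistic
  st2 <- st; st2$firing_rate <- exp(st$firing_rate / 2)
  expect_equal(ranked_ancova(st2)$statistic, f0)

  # constant rates: F = 0, p = 1, no post-hoc
  st3 <- st; st3$firing_rate <- 2
  res <- ranked_ancova(st3)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_null(res$posthoc)

  # collinear covariates are dropped with a warning, not an error
  st4 <- st; st4$mean_y <- st4$mean_x
  expect_warning(res4 <- ranked_ancova(st4), "collinear")
  expect_true(is.finite(res4$statistic))
})

test_that("permutation ANCOVA p-value follows the #(F_shuff >= F_obs)/k rule", {
  # overwhelming effect: no shuffle reaches the observed F -> p = 0
  st <- fx_random_stats(seed = 41, effect = c(0, 30, 0, 0))
  res <- permutation_ancova(st, k = 300, seed = 1)
  expect_equal(res$p_value, 0)

  # duplicating every row strengthens a true effect
  st_half <- fx_random_stats(n_per_route = 6, seed = 42,
                             effect = c(0, 3, 0, 0))
  st_dup <- dplyr::bind_rows(st_half, st_half)
  f1 <- permutation_ancova(st_half, k = 100, seed = 2)$statistic
  f2 <- permutation_ancova(st_dup, k = 100, seed = 2)$statistic
  expect_gt(f2, f1)

  expect_warning(permutation_ancova(st, k = 50, seed = 1), "100")
})

test_that("permutation p-values are uniform under the null", {
  ps <- vapply(1:150, function(i) {
    st <- fx_random_stats(n_per_route = 8, seed = 5000 + i)
    permutation_ancova(st, k = 400, seed = i)$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("Poisson GLM detects route modulation and stays quiet under equality", {
  st <- fx_startbox_stats(route_gains = c(1, 4, 1, 1), seed = 6)
  res <- poisson_glm_differential(st)
  expect_lt(res$p_value, 0.001)
  expect_equal(classify_route_goal(res)$label, "route_specific_2")

  # equal rates: omnibus not significant
  st0 <- st
  st0$n_spikes <- rep(20L, nrow(st0))
  st0$time_s <- rep(5, nrow(st0))
  st0$firing_rate <- st0$n_spikes / st0$time_s
  res0 <- poisson_glm_differential(st0)
  expect_gt(res0$p_value, 0.5)
  expect_null(res0$posthoc)
})

test_that("GLM and ranked ANCOVA isolate the same route on gained cells", {
  hits <- vapply(1:25, function(i) {
    st <- fx_startbox_stats(route_gains = c(1, 4, 1, 1), seed = 600 + i)
    a <- classify_route_goal(ranked_ancova(st))$label
    b <- classify_route_goal(poisson_glm_differential(st))$label
    a == "route_specific_2" && b == "route_specific_2"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("route/goal classification implements the pattern definitions", {
  mk_result <- function(sig_pairs, means = NULL) {
    pairs <- t(combn(1:4, 2))
    ph <- tibble::tibble(
      pair = paste(pairs[, 1], pairs[, 2], sep = "-"),
      route_a = pairs[, 1], route_b = pairs[, 2],
      estimate = 1,
      p_adj = ifelse(pair %in% sig_pairs, 0.001, 0.5))
    structure(list(posthoc = ph, means = means, converged = TRUE),
              class = "differential_test")
  }
  expect_equal(classify_route_goal(mk_result(c("1-2", "1-3", "1-4")))$label,
               "route_specific_1")
  expect_equal(classify_route_goal(
    mk_result(c("1-2", "2-4", "1-3", "3-4")))$label, "goal_dependent")
  expect_equal(classify_route_goal(mk_result("1-2"))$label, "unclassified")
  # no post-hoc -> unclassified, flagged
  none <- structure(list(posthoc = NULL, converged = TRUE),
                    class = "differential_test")
  expect_equal(classify_route_goal(none)$label, "unclassified")
  expect_match(classify_route_goal(none)$reason, "post-hoc")
})

test_that("pattern chi-squares match the hand formula", {
  # exact rational fixture: counts (2,4,6,8,0), E = 4 each
  res <- population_pattern_tests(c(2, 4, 6, 8, 0))
  expect_equal(res$statistic[res$test == "five_way_uniform"],
               (4 + 0 + 4 + 16 + 16) / 4)
  # centre = 4 + 6 + 0 = 10, outer = 10 -> X2 = 0
  expect_equal(res$statistic[res$test == "centre_vs_outer"], 0)
  expect_equal(res$df, c(4, 1))

  # perfectly uniform counts -> 0
  resu <- population_pattern_tests(rep(7, 5))
  expect_equal(resu$statistic[1], 0)

  expect_error(population_pattern_tests(rep(0, 5)), "zero")
})

test_that("pattern summary reports the percentage split", {
  s <- pattern_summary(c(1, 2, 3, 4, 10))
  expect_equal(s$n, 20)
  expect_equal(s$pct_route_dependent, 50)
  expect_equal(s$pct_goal_dependent, 50)
  expect_equal(s$pct_centre_preferring, 75)
})
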
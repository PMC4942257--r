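# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stationary AR(1) noise, sd 1, used to give jitter and speed fluctuations
# a realistic correlation time.
ar1_noise <- function(n, phi = 0.95) {
  if (n == 0) return(numeric(0))
  as.numeric(stats::filter(stats::rnorm(n, sd = sqrt(1 - phi^2)), phi,
                           method = "recursive",
                           init = stats::rnorm(1)))
}

#' Configuration for a simulated win-stay session
#'
#' Bundles the behavioural and tracking parameters of one simulated session.
#' Defaults reflect the recorded task: blocks of 11 trials after the rewarded
#' goal is found (at least 6 of them correct), a 6--9 s start-box hold between
#' trials, 50 Hz position sampling, and a 25 cm/s running speed, which yields
#' the observed ~5.4 s start-to-goal travel times.
#'
#' The error model has three components: `search` (logical) -- whether the
#' rewarded goal must be discovered by elimination at the start of each block,
#' with the first search choice following the win-stay rule (the previously
#' rewarded goal); `p_post` -- probability of a wrong-route choice on trials
#' after the rewarded goal has been identified; `sibling_weight` -- relative
#' weight of confusing the two central routes (2 and 3, which share the Centre
#' Goal Box) when a post-identification error occurs.
#'
#' @param n_blocks Number of trial blocks.
#' @param trials_per_block Trials per block from the first correct trial
#'   onward (the first correct trial counts as the first of these).
#' @param min_correct_per_block Minimum correct trials required per block.
#' @param route_schedule Rewarded route id per block, values in 1..4.
#' @param error_model List with `search`, `p_post`, `sibling_weight`.
#' @param inter_trial_hold Length-2 range (s) of the start-box hold.
#' @param position_rate Tracking rate, Hz.
#' @param speed_profile Mean running speed, cm/s.
#' @param seed RNG seed for the session.
#' @return A list of class `session_config`.
#' @export
session_config <- function(n_blocks = 4,
                           trials_per_block = 11,
                           min_correct_per_block = 6,
                           route_schedule = c(1, 2, 4, 3),
                           error_model = list(search = TRUE, p_post = 0.05,
                                              sibling_weight = 4),
                           inter_trial_hold = c(6, 9),
                           position_rate = 50,
                           speed_profile = 25,
                           seed = 1L) {
  if (length(route_schedule) == 0)
    stop("route_schedule must not be empty", call. = FALSE)
  if (!all(route_schedule %in% 1:4))
    stop("route_schedule values must be in 1..4", call. = FALSE)
  if (trials_per_block < min_correct_per_block)
    stop("trials_per_block must be >= min_correct_per_block", call. = FALSE)
  if (position_rate <= 0) stop("position_rate must be > 0", call. = FALSE)
  em <- utils::modifyList(list(search = TRUE, p_post = 0.05, sibling_weight = 4),
                          as.list(error_model))
  n_blocks <- min(n_blocks, length(route_schedule) * 1000L)
  structure(list(n_blocks = n_blocks, trials_per_block = trials_per_block,
                 min_correct_per_block = min_correct_per_block,
                 route_schedule = rep_len(route_schedule, n_blocks),
                 error_model = em, inter_trial_hold = inter_trial_hold,
                 position_rate = position_rate, speed_profile = speed_profile,
                 seed = seed),
            class = "session_config")
}

route_goal_map <- c("left", "centre", "centre", "right")

# Which central route is open given the rewarded route (the transparent
# barrier blocks the centre-box entrance furthest from the rewarded box).
open_centre_route <- function(rewarded) if (rewarded <= 2) 2L else 3L

# Draw the sequence of (route, correct) choices for one block.
draw_block_choices <- function(rewarded, belief_goal, em, trials_per_block) {
  centre_open <- open_centre_route(rewarded)
  goal_route <- c(left = 1L, centre = centre_open, right = 4L)
  rewarded_goal <- route_goal_map[rewarded]
  routes <- integer(0)
  if (isTRUE(em$search)) {
    tried <- character(0)
    choice <- belief_goal
    while (choice != rewarded_goal) {
      routes <- c(routes, goal_route[[choice]])
      tried <- c(tried, choice)
      remaining <- setdiff(c("left", "centre", "right"), tried)
      choice <- if (length(remaining) == 1) remaining else
        sample(remaining, 1)
    }
  }
  # post-identification trials (first correct trial is the first of these)
  post <- integer(trials_per_block)
  for (i in seq_len(trials_per_block)) {
    if (i > 1 && stats::runif(1) < em$p_post) {
      wrong <- setdiff(1:4, rewarded)
      w <- ifelse(vapply(wrong, function(r)
        setequal(c(r, rewarded), c(2L, 3L)), logical(1)),
        em$sibling_weight, 1)
      post[i] <- if (length(wrong) == 1) wrong else
        sample(wrong, 1, prob = w)
    } else {
      post[i] <- rewarded
    }
  }
  list(routes = c(routes, post),
       post_first_correct = c(rep(FALSE, length(routes)),
                              rep(TRUE, trials_per_block)))
}

# Arc-length parameterisation of a piecewise-linear centerline.
centerline_point <- function(cl, s) {
  seg <- sqrt(rowSums(diff(cl)^2))
  cum <- c(0, cumsum(seg))
  s <- pmin(pmax(s, 0), cum[length(cum)])
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg))
  f <- (s - cum[idx]) / seg[idx]
  p <- cl[idx, , drop = FALSE] + f * (cl[idx + 1, , drop = FALSE] -
                                        cl[idx, , drop = FALSE])
  d <- (cl[idx + 1, , drop = FALSE] - cl[idx, , drop = FALSE]) / seg[idx]
  list(p = p, dir = d)
}

#' Simulate a win-stay maze session
#'
#' Generates the trajectory and trial table of one session: for each block the
#' rewarded goal is fixed, the animal searches for it (win-stay start, then
#' elimination over unvisited goals), and then completes the block with
#' occasional confusion errors biased toward the two central routes. Runs
#' follow the chosen route's centerline with autocorrelated speed and lateral
#' jitter; holds are spent in the start box; correct trials end with a reward
#' dwell in the goal box. Error runs toward the blocked central route are
#' truncated at the barrier. Between trials the carry back to the start box is
#' included (phase `"hold"`, `trial_id` `NA`) so position sampling is gap-free.
#'
#' @param layout A [build_maze_layout()] object.
#' @param config A [session_config()].
#' @return A list of class `maze_session` with
#'   * `trajectory`: tibble `t, x, y, trial_id, route_id, phase`,
#'   * `trials`: tibble with one row per trial (`trial_id`, `block_id`,
#'     `trial_in_block`, `post_first_correct`, `rewarded_route`, `route_id`,
#'     `goal`, `correct`, `t_start`, `t_run`, `t_goal`, `t_end`),
#'   * `layout`, `config`.
#' @examples
#' sess <- simulate_session(build_maze_layout(),
#'                          session_config(seed = 7))
#' dplyr::count(sess$trials, route_id, correct)
#' @export
simulate_session <- function(layout, config) {
  stopifnot(inherits(layout, "maze_layout"), inherits(config, "session_config"))
  with_seed(config$seed, {
    dt <- 1 / config$position_rate
    belief <- sample(c("left", "centre", "right"), 1)  # no prior reward yet
    blocks <- vector("list", config$n_blocks)
    for (b in seq_len(config$n_blocks)) {
      rewarded <- config$route_schedule[b]
      blocks[[b]] <- draw_block_choices(rewarded, belief, config$error_model,
                                        config$trials_per_block)
      blocks[[b]]$rewarded <- rewarded
      belief <- route_goal_map[rewarded]
    }

    traj_parts <- list()
    trial_rows <- list()
    t_now <- 0
    trial_id <- 0L
    start_centre <- c(0, 0)

    jitter2d <- function(n, centre, sd = 2, rmax = 8) {
      x <- centre[1] + sd * ar1_noise(n)
      y <- centre[2] + sd * ar1_noise(n)
      r <- sqrt((x - centre[1])^2 + (y - centre[2])^2)
      shrink <- ifelse(r > rmax, rmax / r, 1)
      cbind(centre[1] + (x - centre[1]) * shrink,
            centre[2] + (y - centre[2]) * shrink)
    }

    emit <- function(n, xy, trial, route, phase) {
      tt <- t_now + dt * seq_len(n)
      t_now <<- t_now + dt * n
      traj_parts[[length(traj_parts) + 1L]] <<- tibble::tibble(
        t = tt, x = xy[, 1], y = xy[, 2],
        trial_id = trial, route_id = route, phase = phase)
    }

    for (b in seq_len(config$n_blocks)) {
      bl <- blocks[[b]]
      for (k in seq_along(bl$routes)) {
        trial_id <- trial_id + 1L
        route <- bl$routes[k]
        rewarded <- bl$rewarded
        correct <- route == rewarded
        blocked <- route %in% 2:3 && route != open_centre_route(rewarded)
        cl <- layout$routes[[route]]$centerline
        total_len <- sum(sqrt(rowSums(diff(cl)^2)))
        run_len <- if (blocked) total_len - layout$box_size / 2 - 1 else total_len

        t_start <- t_now
        # hold in start box
        n_hold <- round(stats::runif(1, config$inter_trial_hold[1],
                                     config$inter_trial_hold[2]) / dt)
        emit(n_hold, jitter2d(n_hold, start_centre), trial_id, route, "hold")

        # run along the centerline
        t_run <- t_now
        v_mean <- config$speed_profile
        n_max <- ceiling(run_len / (0.3 * v_mean) / dt)
        v <- pmax(8, pmin(v_mean * exp(0.15 * ar1_noise(n_max)), 2.5 * v_mean))
        s <- cumsum(v * dt)
        n_run <- which(s >= run_len)[1]
        if (is.na(n_run)) n_run <- n_max
        s <- s[seq_len(n_run)]
        cp <- centerline_point(cl, s)
        lat <- pmax(-3, pmin(1.2 * ar1_noise(n_run), 3))
        xy <- cp$p + lat * cbind(-cp$dir[, 2], cp$dir[, 1])
        emit(n_run, xy, trial_id, route, "run")

        # goal-box dwell (skipped when the barrier stops the run)
        t_goal <- NA_real_
        if (!blocked) {
          t_goal <- t_now
          dwell <- if (correct) stats::runif(1, 3, 5) else stats::runif(1, 1, 2)
          n_goal <- round(dwell / dt)
          goal_centre <- cl[nrow(cl), ]
          emit(n_goal, jitter2d(n_goal, goal_centre), trial_id, route, "goal")
        }
        t_end <- t_now

        trial_rows[[trial_id]] <- tibble::tibble(
          trial_id = trial_id, block_id = b, trial_in_block = k,
          post_first_correct = bl$post_first_correct[k],
          rewarded_route = rewarded, route_id = route,
          goal = route_goal_map[route], correct = correct,
          t_start = t_start, t_run = t_run, t_goal = t_goal, t_end = t_end)

        # carry back to the start box along the reversed path
        s_back <- seq(min(run_len, total_len), 0, by = -75 * dt)
        if (length(s_back) > 1) {
          cpb <- centerline_point(cl, s_back[-1])
          emit(length(s_back) - 1L, cpb$p, NA_integer_, NA_integer_, "hold")
        }
      }
    }

    structure(list(trajectory = dplyr::bind_rows(traj_parts),
                   trials = dplyr::bind_rows(trial_rows),
                   layout = layout, config = config),
              class = "maze_session")
  })
}

#' @export
print.maze_session <- function(x, ...) {
  cat(sprintf("<maze_session>: %d trials in %d blocks, %.0f s, %d cells\n",
              nrow(x$trials), max(x$trials$block_id),
              max(x$trajectory$t),
              length(x$spikes %||% list())))
  invisible(x)
}
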
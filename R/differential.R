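#' Per-trial firing and covariates within a maze sector
#'
#' For every trial that traverses the given sector, computes the firing rate
#' (spikes in sector / time in sector), the mean x and y position, and the
#' mean running speed (path length in sector / time in sector). Spike
#' positions are obtained by linear interpolation of the trajectory at spike
#' times, and sector membership of spikes and samples uses the same
#' half-open polygon convention, so boundary spikes are assigned
#' deterministically. These rows are the input to the differential-firing
#' tests, with route as the factor and position/speed as covariates.
#'
#' @param spikes Spike train tibble (`t`) or numeric spike times.
#' @param session A [simulate_session()] object, or a list with
#'   `trajectory`, `trials`, `layout`.
#' @param sector Sector name (see `layout$sector_table$sector`).
#' @param include_errors Include error trials? Default `FALSE`.
#' @return Tibble with one row per trial entering the sector: `trial_id`,
#'   `route_id`, `n_spikes`, `time_s`, `firing_rate`, `mean_x`, `mean_y`,
#'   `mean_speed`.
#' @export
sector_trial_stats <- function(spikes, session, sector,
                               include_errors = FALSE) {
  st <- if (is.data.frame(spikes)) spikes$t else as.numeric(spikes)
  traj <- session$trajectory
  trials <- session$trials
  if (is.null(traj$sector)) traj <- assign_sectors(traj, session$layout)
  dt <- stats::median(diff(traj$t))

  keep_trials <- if (include_errors) trials$trial_id else
    trials$trial_id[trials$correct]

  in_sec <- !is.na(traj$sector) & traj$sector == sector &
    !is.na(traj$trial_id) & traj$trial_id %in% keep_trials
  if (!any(in_sec)) return(empty_sector_stats())

  # distance travelled attributed to a sample = step from the previous
  # sample, counted while the current sample is inside the sector
  step <- c(0, sqrt(diff(traj$x)^2 + diff(traj$y)^2))
  same_trial <- c(FALSE, diff(traj$trial_id) == 0)
  seg <- ifelse(in_sec & !is.na(same_trial) & same_trial, step, 0)

  pos <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(trial_id = traj$trial_id[in_sec],
                                   x = traj$x[in_sec], y = traj$y[in_sec],
                                   seg = seg[in_sec]),
                    .data$trial_id),
    n = dplyr::n(), mean_x = mean(.data$x), mean_y = mean(.data$y),
    path = sum(.data$seg), .groups = "drop")

  # spike membership: interpolated position -> sector; time -> trial
  if (length(st)) {
    sx <- stats::approx(traj$t, traj$x, xout = st, rule = 2)$y
    sy <- stats::approx(traj$t, traj$y, xout = st, rule = 2)$y
    ssec <- sector_at(sx, sy, session$layout)
    stri <- traj$trial_id[pmax(1L, findInterval(st, traj$t))]
    sp_tab <- table(factor(stri[!is.na(ssec) & ssec == sector],
                           levels = pos$trial_id))
  } else {
    sp_tab <- stats::setNames(rep(0L, nrow(pos)), pos$trial_id)
  }

  out <- dplyr::left_join(pos,
                          trials[, c("trial_id", "route_id")], by = "trial_id")
  out$time_s <- out$n * dt
  out$n_spikes <- as.integer(sp_tab[as.character(out$trial_id)])
  out$firing_rate <- out$n_spikes / out$time_s
  out$mean_speed <- out$path / out$time_s
  dplyr::select(out, "trial_id", "route_id", "n_spikes", "time_s",
                "firing_rate", "mean_x", "mean_y", "mean_speed")
}

empty_sector_stats <- function() {
  tibble::tibble(trial_id = integer(), route_id = integer(),
                 n_spikes = integer(), time_s = numeric(),
                 firing_rate = numeric(), mean_x = numeric(),
                 mean_y = numeric(), mean_speed = numeric())
}

#' Activity rule for inclusion in the differential analysis
#'
#' A cell is analysed in a sector only if its pooled mean rate there exceeds
#' `threshold_hz` (strictly) on at least one route: all spikes emitted in the
#' sector on that route's traversals divided by all time spent there.
#'
#' @param stats A [sector_trial_stats()] tibble.
#' @param threshold_hz Activity threshold, Hz.
#' @return Logical scalar (`FALSE`, with a `reason` attribute, when there
#'   are no trials).
#' @export
is_active_in_sector <- function(stats, threshold_hz = 1) {
  if (nrow(stats) == 0)
    return(structure(FALSE, reason = "no trials traverse the sector"))
  pooled <- dplyr::summarise(dplyr::group_by(stats, .data$route_id),
                             rate = sum(.data$n_spikes) / sum(.data$time_s))
  any(pooled$rate > threshold_hz)
}

# Shared input checks; returns the stats filtered to usable routes.
check_diff_input <- function(stats, min_trials) {
  n_per <- table(stats$route_id)
  keep <- names(n_per)[n_per >= min_trials]
  stats <- stats[stats$route_id %in% as.integer(keep), ]
  if (length(unique(stats$route_id)) < 2)
    stop("need at least two routes with enough trials", call. = FALSE)
  stats
}

rank_mid <- function(x) rank(x, ties.method = "average")

# Residuals of y regressed on covariate matrix (with intercept), dropping
# collinear columns via pivoted QR.
resid_on_covs <- function(y, covs) {
  X <- cbind(1, covs)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
    warning("rank-deficient covariate matrix; collinear covariate dropped")
    qrx <- qr(X)
  }
  qr.resid(qrx, y)
}

oneway_anova <- function(res, group) {
  g <- factor(group)
  n <- length(res)
  k <- nlevels(g)
  m <- tapply(res, g, mean)
  ni <- tapply(res, g, length)
  grand <- mean(res)
  ssb <- sum(ni * (m - grand)^2)
  ssw <- sum((res - m[g])^2)
  df1 <- k - 1; df2 <- n - k
  mse <- ssw / df2
  f <- if (ssw <= 0) (if (ssb <= 0) 0 else Inf) else (ssb / df1) / mse
  p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
  list(f = f, df1 = df1, df2 = df2, mse = mse, p = p, means = m, n = ni)
}

# Six pairwise comparisons of marginal means with Tukey-Kramer (default) or
# Sidak-adjusted t tests; `aov` is the result of oneway_anova().
pairwise_marginal_means <- function(aov, adjust = c("tukey", "sidak")) {
  adjust <- match.arg(adjust)
  lev <- names(aov$means)
  pairs <- utils::combn(lev, 2)
  k <- length(lev)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diff <- aov$means[[a]] - aov$means[[b]]
    se2 <- aov$mse * (1 / aov$n[[a]] + 1 / aov$n[[b]])
    if (adjust == "tukey") {
      q <- abs(diff) / sqrt(se2 / 2)
      p <- stats::ptukey(q, k, aov$df2, lower.tail = FALSE)
    } else {
      tt <- abs(diff) / sqrt(se2)
      p_raw <- 2 * stats::pt(tt, aov$df2, lower.tail = FALSE)
      p <- 1 - (1 - p_raw)^ncol(pairs)
    }
    tibble::tibble(pair = paste(a, b, sep = "-"),
                   route_a = as.integer(a), route_b = as.integer(b),
                   estimate = diff, p_adj = min(p, 1))
  })
}

new_differential_test <- function(method, statistic, df1, df2, p_value,
                                  posthoc, means, n_per_route, alpha,
                                  converged = TRUE) {
  structure(list(method = method, statistic = statistic, df1 = df1,
                 df2 = df2, p_value = p_value, posthoc = posthoc,
                 means = means, n_per_route = n_per_route, alpha = alpha,
                 converged = converged),
            class = "differential_test")
}

#' @export
print.differential_test <- function(x, ...) {
  cat(sprintf("<differential_test: %s> F(%s, %s) = %.3f, p = %.4g\n",
              x$method, format(x$df1), format(x$df2), x$statistic,
              x$p_value))
  if (!is.null(x$posthoc)) {
    cat("post-hoc pairs with p <", x$alpha, ":",
        paste(x$posthoc$pair[x$posthoc$p_adj < x$alpha], collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Ranked ANCOVA test of route-modulated firing
#'
#' The primary differential-firing test: firing rate and the covariates
#' (mean x, mean y, mean speed) are replaced by mid-ranks; the ranked rate
#' is regressed on the ranked covariates (ignoring route); and the
#' regression residuals are submitted to a one-way ANOVA against route.
#' If the omnibus test is significant at `alpha`, the six pairwise
#' comparisons of the residual marginal means between routes are run with
#' Tukey--Kramer (default) or Sidak adjustment.
#'
#' @param stats A [sector_trial_stats()] tibble.
#' @param alpha Omnibus significance level gating the post-hoc tests.
#' @param adjust Post-hoc multiplicity adjustment.
#' @param min_trials Minimum trials per route for a route to enter the test.
#' @return A `differential_test` object (see [tidy()][generics::tidy]
#'   methods): omnibus F with df, p-value, and (when significant) the
#'   post-hoc pair table.
#' @export
ranked_ancova <- function(stats, alpha = 0.05, adjust = c("tukey", "sidak"),
                          min_trials = 5) {
  adjust <- match.arg(adjust)
  stats <- check_diff_input(stats, min_trials)
  n_per <- table(stats$route_id)
  if (stats::sd(stats$firing_rate) == 0) {
    return(new_differential_test("ranked_ancova", 0, NA, NA, 1, NULL,
                                 NULL, n_per, alpha))
  }
  rdv <- rank_mid(stats$firing_rate)
  rcov <- cbind(rank_mid(stats$mean_x), rank_mid(stats$mean_y),
                rank_mid(stats$mean_speed))
  res <- resid_on_covs(rdv, rcov)
  a <- oneway_anova(res, stats$route_id)
  posthoc <- if (a$p < alpha) pairwise_marginal_means(a, adjust) else NULL
  new_differential_test("ranked_ancova", a$f, a$df1, a$df2, a$p, posthoc,
                        a$means, n_per, alpha)
}

# F statistic of the route factor in a parametric ANCOVA of y on covariates
# plus route, computed for many response vectors at once (columns of Y).
ancova_f <- function(Y, covs, route) {
  Y <- as.matrix(Y)
  g <- factor(route)
  X0 <- cbind(1, covs)
  X1 <- cbind(X0, stats::model.matrix(~g)[, -1, drop = FALSE])
  q0 <- qr.Q(qr(X0)); q1 <- qr.Q(qr(X1))
  tot <- colSums(Y^2)
  rss0 <- tot - colSums(crossprod(q0, Y)^2)
  rss1 <- tot - colSums(crossprod(q1, Y)^2)
  df1 <- nlevels(g) - 1
  df2 <- nrow(Y) - ncol(X1)
  list(f = ((rss0 - rss1) / df1) / (rss1 / df2), df1 = df1, df2 = df2)
}

#' Permutation ANCOVA test of route-modulated firing
#'
#' Computes the parametric ANCOVA F statistic for the route factor (firing
#' rate on covariates plus route) and compares it with the distribution of F
#' obtained by randomly shuffling the firing rates against the fixed
#' route/covariate design. The p-value is the fraction of shuffled F values
#' at least as large as the observed one, so its resolution is `1/k` and an
#' observed F above every shuffle reports p = 0.
#'
#' @inheritParams ranked_ancova
#' @param k Number of shuffles (5000 default).
#' @param seed RNG seed for the shuffles.
#' @return A `differential_test` object (post-hoc table not defined for
#'   this method).
#' @export
permutation_ancova <- function(stats, k = 5000, seed = NULL, alpha = 0.05,
                               min_trials = 5) {
  if (k < 100) warning("fewer than 100 shuffles; p-value resolution is poor")
  stats <- check_diff_input(stats, min_trials)
  covs <- cbind(stats$mean_x, stats$mean_y, stats$mean_speed)
  y <- stats$firing_rate
  obs <- ancova_f(y, covs, stats$route_id)
  f_shuff <- with_seed(seed, {
    Y <- vapply(seq_len(k), function(i) y[sample.int(length(y))],
                numeric(length(y)))
    ancova_f(Y, covs, stats$route_id)$f
  })
  p <- sum(f_shuff >= obs$f) / k
  new_differential_test("permutation_ancova", obs$f, obs$df1, obs$df2, p,
                        NULL, NULL, table(stats$route_id), alpha)
}

#' Poisson GLM test of route-modulated firing
#'
#' Fits a log-link Poisson regression of in-sector spiking on route
#' (categorical) plus the position/speed covariates. By default the response
#' is the per-trial spike count with log time-in-sector as offset (the
#' Poisson-faithful form); `dv = "rate"` fits the firing rate directly for
#' literal replication. The omnibus route effect is the likelihood-ratio
#' (deviance-reduction) statistic for the route term, referred to an F
#' distribution with estimated dispersion so the test stays calibrated at
#' session-sized trial counts; when significant at `alpha`, six pairwise
#' Mann--Whitney U tests compare raw rates between routes.
#'
#' @inheritParams ranked_ancova
#' @param dv `"counts"` (with log-exposure offset) or `"rate"`.
#' @param p_adjust Adjustment for the six Mann--Whitney p-values
#'   (`"none"`, the literal reading, or `"sidak"`).
#' @return A `differential_test` object; `converged = FALSE` flags fits
#'   that did not converge (such cells are excluded from population counts).
#' @export
poisson_glm_differential <- function(stats, alpha = 0.05,
                                     dv = c("counts", "rate"),
                                     p_adjust = c("none", "sidak"),
                                     min_trials = 5) {
  dv <- match.arg(dv)
  p_adjust <- match.arg(p_adjust)
  stats <- check_diff_input(stats, min_trials)
  g <- factor(stats$route_id)
  dat <- data.frame(mean_x = stats$mean_x, mean_y = stats$mean_y,
                    mean_speed = stats$mean_speed, route = g)
  if (dv == "counts") {
    dat$y <- stats$n_spikes
    dat$off <- log(stats$time_s)
    fit1 <- suppressWarnings(stats::glm(y ~ mean_x + mean_y + mean_speed +
                                          route + offset(off),
                                        family = stats::poisson(), data = dat))
    fit0 <- suppressWarnings(stats::glm(y ~ mean_x + mean_y + mean_speed +
                                          offset(off),
                                        family = stats::poisson(), data = dat))
  } else {
    dat$y <- stats$firing_rate
    fit1 <- suppressWarnings(stats::glm(y ~ mean_x + mean_y + mean_speed +
                                          route,
                                        family = stats::quasipoisson(),
                                        data = dat))
    fit0 <- suppressWarnings(stats::glm(y ~ mean_x + mean_y + mean_speed,
                                        family = stats::quasipoisson(),
                                        data = dat))
  }
  df1 <- nlevels(g) - 1
  lr <- fit0$deviance - fit1$deviance
  # deviance-reduction F test with estimated dispersion: the likelihood-ratio
  # statistic referred to an F distribution, which keeps the test calibrated
  # at session-sized trial counts
  disp <- sum(stats::residuals(fit1, "pearson")^2) / fit1$df.residual
  p <- stats::pf((lr / df1) / max(disp, 1e-12), df1, fit1$df.residual,
                 lower.tail = FALSE)
  posthoc <- NULL
  if (is.finite(p) && p < alpha) {
    lev <- levels(g)
    pairs <- utils::combn(lev, 2)
    posthoc <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      ra <- stats$firing_rate[g == a]; rb <- stats$firing_rate[g == b]
      wt <- suppressWarnings(stats::wilcox.test(ra, rb, exact = FALSE))
      pp <- wt$p.value
      if (p_adjust == "sidak") pp <- 1 - (1 - pp)^ncol(pairs)
      tibble::tibble(pair = paste(a, b, sep = "-"),
                     route_a = as.integer(a), route_b = as.integer(b),
                     estimate = stats::median(ra) - stats::median(rb),
                     p_adj = min(pp, 1))
    })
  }
  means <- tapply(stats$firing_rate, g, mean)
  new_differential_test("poisson_glm", lr, df1, fit1$df.residual, p, posthoc,
                        means, table(stats$route_id), alpha,
                        converged = fit1$converged && fit0$converged)
}

#' Classify a differential cell as route-specific or goal-dependent
#'
#' Applies the route/goal pattern definitions to a significant
#' differential-firing result: a cell is *route-specific for route k* when
#' its firing on route k differs (post-hoc p < `alpha`) from each of the
#' other three routes, and *goal-dependent* when routes 2 and 3 (the two
#' routes to the Centre Goal Box) each differ from routes 1 and 4 while not
#' differing from each other. Anything else is unclassified.
#'
#' @param result A `differential_test` with a post-hoc table.
#' @param alpha Pairwise significance level.
#' @return A list of class `route_pattern`: `label` (one of
#'   `"route_specific_1"`..`"route_specific_4"`, `"goal_dependent"`,
#'   `"unclassified"`), `route` (integer or NA), `reason`.
#' @export
classify_route_goal <- function(result, alpha = 0.05) {
  ph <- result$posthoc
  if (is.null(ph) || nrow(ph) == 0 || !isTRUE(result$converged)) {
    return(structure(list(label = "unclassified", route = NA_integer_,
                          reason = "no post-hoc table"),
                     class = "route_pattern"))
  }
  sig <- function(a, b) {
    row <- ph[(ph$route_a == a & ph$route_b == b) |
                (ph$route_a == b & ph$route_b == a), ]
    nrow(row) == 1 && is.finite(row$p_adj) && row$p_adj < alpha
  }
  have <- sort(unique(c(ph$route_a, ph$route_b)))
  goal_ok <- all(c(2, 3, 1, 4) %in% have) &&
    sig(2, 1) && sig(2, 4) && sig(3, 1) && sig(3, 4) && !sig(2, 3)
  if (goal_ok) {
    return(structure(list(label = "goal_dependent", route = NA_integer_,
                          reason = "routes 2 and 3 differ from 1 and 4 only"),
                     class = "route_pattern"))
  }
  qualifies <- vapply(have, function(k)
    all(vapply(setdiff(have, k), function(j) sig(k, j), logical(1))) &&
      length(have) == 4,
    logical(1))
  if (any(qualifies)) {
    ks <- have[qualifies]
    if (length(ks) > 1 && !is.null(result$means)) {
      dev <- abs(result$means[as.character(ks)] -
                   mean(unlist(result$means)))
      ks <- ks[which.max(dev)]
    }
    k <- ks[1]
    return(structure(list(label = paste0("route_specific_", k),
                          route = as.integer(k),
                          reason = "one route differs from the other three"),
                     class = "route_pattern"))
  }
  structure(list(label = "unclassified", route = NA_integer_,
                 reason = "post-hoc pattern matches neither definition"),
            class = "route_pattern")
}

#' Population-level pattern chi-square tests
#'
#' Given the counts of classified cells
#' (route-specific for routes 1--4 plus goal-dependent), computes
#' (a) the 5-category Pearson goodness-of-fit statistic against a uniform
#' distribution over the five patterns, and (b) the 2-category test of
#' centre-preferring cells (route 2 + route 3 + goal-dependent) versus
#' outer-preferring cells (routes 1 + 4) against 50/50.
#'
#' @param counts Numeric length 5: counts for route 1, route 2, route 3,
#'   route 4, and goal-dependent cells (names optional).
#' @return Tibble with rows `five_way_uniform` and `centre_vs_outer`:
#'   `statistic`, `df`, `n`, `p_value`.
#' @examples
#' population_pattern_tests(c(9, 13, 18, 6, 2))
#' @export
population_pattern_tests <- function(counts) {
  stopifnot(length(counts) == 5, all(counts >= 0))
  if (sum(counts) == 0) stop("zero expected counts", call. = FALSE)
  t1 <- suppressWarnings(stats::chisq.test(counts, p = rep(1 / 5, 5)))
  centre <- counts[2] + counts[3] + counts[5]
  outer <- counts[1] + counts[4]
  t2 <- suppressWarnings(stats::chisq.test(c(centre, outer), p = c(0.5, 0.5)))
  tibble::tibble(
    test = c("five_way_uniform", "centre_vs_outer"),
    statistic = c(unname(t1$statistic), unname(t2$statistic)),
    df = c(unname(t1$parameter), unname(t2$parameter)),
    n = c(sum(counts), centre + outer),
    p_value = c(t1$p.value, t2$p.value))
}

#' Summary percentages of a pattern count vector
#'
#' @param counts As in [population_pattern_tests()].
#' @return One-row tibble: total cells, percentage route-dependent,
#'   percentage goal-dependent, and percentage preferring the centre goal
#'   (routes 2, 3, or goal-dependent).
#' @export
pattern_summary <- function(counts) {
  stopifnot(length(counts) == 5)
  total <- sum(counts)
  tibble::tibble(
    n = total,
    pct_route_dependent = 100 * sum(counts[1:4]) / total,
    pct_goal_dependent = 100 * counts[5] / total,
    pct_centre_preferring = 100 * (counts[2] + counts[3] + counts[5]) / total)
}
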
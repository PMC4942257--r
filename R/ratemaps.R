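#' Gaussian smoothing kernel
#'
#' The unnormalised Gaussian kernel `exp(-u^2 / 2)` used by the firing rate
#' map estimator; the caller supplies `u` as distance divided by the
#' smoothing factor `h`.
#'
#' @param u Dimensionless distance(s).
#' @return Kernel weight(s) in (0, 1].
#' @examples
#' gaussian_kernel(0)   # 1
#' gaussian_kernel(1)   # exp(-0.5)
#' @export
gaussian_kernel <- function(u) exp(-u^2 / 2)

#' Smoothing parameters for firing rate maps
#'
#' @param h Gaussian smoothing factor, cm (2.5 cm default).
#' @param bin_size Grid bin size, cm; by default equal to `h`.
#' @param visit_radius Bins with no tracking sample within this distance of
#'   their centre are masked as never visited (5 cm default).
#' @return A list of class `smoothing_params`.
#' @export
smoothing_params <- function(h = 2.5, bin_size = 2.5, visit_radius = 5) {
  stopifnot(h > 0, bin_size > 0, visit_radius > 0)
  structure(list(h = h, bin_size = bin_size, visit_radius = visit_radius),
            class = "smoothing_params")
}

#' Occupancy-normalised Gaussian-kernel firing rate map
#'
#' Estimates the spatial firing rate on a square grid as the ratio of
#' kernel-weighted spike counts to the kernel-weighted occupancy time:
#' \deqn{\lambda(x) = \sum_i g\!\left(\frac{s_i - x}{h}\right) \Big/
#'   \int_0^T g\!\left(\frac{y(t) - x}{h}\right) dt,}
#' where \eqn{s_i} are spike positions (linear interpolation of the
#' trajectory at spike times), \eqn{y(t)} the tracked path, and
#' \eqn{g} the Gaussian kernel. The occupancy integral is evaluated by the
#' rectangle rule over tracking samples. Bins whose centre has no tracking
#' sample within `visit_radius` are masked as unvisited.
#'
#' @param spikes Spike train: tibble with column `t`, or a numeric vector of
#'   spike times (s).
#' @param traj Trajectory tibble with columns `t`, `x`, `y`.
#' @param params A [smoothing_params()].
#' @param bbox Optional bounding box `c(xmin, xmax, ymin, ymax)`; defaults to
#'   the trajectory extent padded by one visit radius.
#' @return An object of class `rate_map`: list with `rate`, `occupancy`
#'   (seconds, raw dwell), `visited` (matrices, bins x-by-y), `x_centres`,
#'   `y_centres`, `params`, and `mean_rate` (spikes per second of tracked
#'   time).
#' @export
compute_rate_map <- function(spikes, traj, params = smoothing_params(),
                             bbox = NULL) {
  st <- if (is.data.frame(spikes)) spikes$t else as.numeric(spikes)
  if (!is.data.frame(traj) || nrow(traj) < 2)
    stop("trajectory must have at least two samples", call. = FALSE)
  dt <- c(diff(traj$t), 0)
  dt[length(dt)] <- dt[length(dt) - 1]
  sx <- stats::approx(traj$t, traj$x, xout = st, rule = 2)$y
  sy <- stats::approx(traj$t, traj$y, xout = st, rule = 2)$y

  if (is.null(bbox)) {
    pad <- params$visit_radius
    bbox <- c(min(traj$x) - pad, max(traj$x) + pad,
              min(traj$y) - pad, max(traj$y) + pad)
  }
  xc <- seq(bbox[1] + params$bin_size / 2, bbox[2], by = params$bin_size)
  yc <- seq(bbox[3] + params$bin_size / 2, bbox[4], by = params$bin_size)
  grid <- cbind(rep(xc, times = length(yc)), rep(yc, each = length(xc)))
  nb <- nrow(grid)

  num <- numeric(nb); den <- numeric(nb)
  occ <- numeric(nb); visited <- logical(nb)
  h2 <- 2 * params$h^2
  vr2 <- params$visit_radius^2
  # nearest-bin index of each tracking sample, for the raw occupancy
  ix <- pmin(pmax(1L, findInterval(traj$x, c(-Inf, xc[-1] - params$bin_size / 2,
                                             Inf))), length(xc))
  iy <- pmin(pmax(1L, findInterval(traj$y, c(-Inf, yc[-1] - params$bin_size / 2,
                                             Inf))), length(yc))
  occ_tab <- tapply(dt, list((iy - 1L) * length(xc) + ix), sum)
  occ[as.integer(names(occ_tab))] <- occ_tab

  chunk <- 256L
  for (lo in seq(1L, nb, by = chunk)) {
    hi <- min(lo + chunk - 1L, nb)
    gx <- grid[lo:hi, 1]; gy <- grid[lo:hi, 2]
    d2p <- outer(gx, traj$x, "-")^2 + outer(gy, traj$y, "-")^2
    den[lo:hi] <- as.numeric(exp(-d2p / h2) %*% dt)
    visited[lo:hi] <- matrixStats_rowAnys(d2p <= vr2)
    if (length(st)) {
      d2s <- outer(gx, sx, "-")^2 + outer(gy, sy, "-")^2
      num[lo:hi] <- rowSums(exp(-d2s / h2))
    }
  }
  rate <- ifelse(visited, num / den, NA_real_)
  structure(list(
    rate = matrix(rate, length(xc)),
    occupancy = matrix(occ, length(xc)),
    visited = matrix(visited, length(xc)),
    x_centres = xc, y_centres = yc, params = params,
    n_spikes = length(st),
    mean_rate = length(st) / sum(dt)
  ), class = "rate_map")
}

matrixStats_rowAnys <- function(m) rowSums(m) > 0 # logical matrix row-any

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map>: %d x %d bins (%.3g cm), %d spikes, peak %.3g Hz\n",
              length(x$x_centres), length(x$y_centres), x$params$bin_size,
              x$n_spikes, suppressWarnings(max(x$rate, na.rm = TRUE))))
  invisible(x)
}

#' Spatial information content (bits per spike)
#'
#' Computes \eqn{\sum_i P_i (R_i/R) \log_2 (R_i/R)} over visited bins, where
#' \eqn{P_i} is the raw occupancy probability of bin \eqn{i}, \eqn{R_i} its
#' firing rate, and \eqn{R = \sum_i P_i R_i} the occupancy-weighted mean
#' rate. Terms with \eqn{R_i = 0} contribute zero. The measure is invariant
#' to rate rescaling and is zero iff the rate is constant over visited bins.
#'
#' @param map A [compute_rate_map()] result.
#' @return Spatial information in bits per spike (0 for an all-zero map,
#'   with a warning).
#' @export
spatial_information <- function(map) {
  stopifnot(inherits(map, "rate_map"))
  v <- map$visited & !is.na(map$rate)
  p <- map$occupancy[v]
  p <- p / sum(p)
  r <- map$rate[v]
  rbar <- sum(p * r)
  if (rbar <= 0) {
    warning("all-zero rate map: spatial information set to 0")
    return(0)
  }
  ratio <- r / rbar
  sum(ifelse(ratio > 0, p * ratio * log2(ratio), 0))
}

#' Count distinguishable place fields in a rate map
#'
#' A field is a 4-connected component of visited bins whose rate is at least
#' `threshold_fraction` of the map peak, containing at least `min_bins` bins.
#'
#' @param map A [compute_rate_map()] result.
#' @param threshold_fraction Fraction of the peak rate defining in-field bins.
#' @param min_bins Minimum component size counted as a field.
#' @return List with `n_fields` and `field_label` (integer matrix; 0 outside
#'   fields).
#' @export
count_place_fields <- function(map, threshold_fraction = 0.2, min_bins = 4) {
  stopifnot(inherits(map, "rate_map"))
  r <- map$rate
  r[is.na(r)] <- 0
  peak <- max(r)
  lab <- matrix(0L, nrow(r), ncol(r))
  if (peak <= 0) return(list(n_fields = 0L, field_label = lab))
  mask <- r >= threshold_fraction * peak & r > 0
  nf <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      # flood fill the component
      comp <- matrix(c(i, j), ncol = 2)
      lab[i, j] <- -1L
      head <- 1L
      while (head <= nrow(comp)) {
        ci <- comp[head, 1]; cj <- comp[head, 2]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          ni <- ci + d[1]; nj <- cj + d[2]
          if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
              mask[ni, nj] && lab[ni, nj] == 0L) {
            lab[ni, nj] <- -1L
            comp <- rbind(comp, c(ni, nj))
          }
        }
        head <- head + 1L
      }
      if (nrow(comp) >= min_bins) {
        nf <- nf + 1L
        lab[comp] <- nf
      } else {
        lab[comp] <- 0L
      }
    }
  }
  list(n_fields = nf, field_label = lab)
}

#' Per-sector activity profile and distance correlation
#'
#' Tabulates, for each of the 14 maze sectors, how many cells are active
#' there (pooled mean rate above `active_hz` on at least one route), the mean
#' firing rate and running speed, and the sector's distance rank from the
#' start box; then reports the Pearson correlation (with n - 2 df) between
#' distance rank and active-cell count. A strongly negative correlation is
#' the signature of start-area over-representation.
#'
#' @param cells Named list of spike trains (tibbles with `t`).
#' @param traj Trajectory tibble; a `sector` column is added if absent.
#' @param layout A [build_maze_layout()] object.
#' @param active_hz Activity threshold, Hz (strictly greater than).
#' @return List with `profile` (tibble, 14 rows) and `distance_cor` (tibble:
#'   `estimate`, `statistic`, `df`, `p_value`).
#' @export
sector_activity_profile <- function(cells, traj, layout, active_hz = 1) {
  stopifnot(length(cells) >= 1)
  if (is.null(traj$sector)) traj <- assign_sectors(traj, layout)
  dt <- stats::median(diff(traj$t))
  step <- c(sqrt(diff(traj$x)^2 + diff(traj$y)^2), 0)
  sec_tab <- layout$sector_table

  per_route_time <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(traj, !is.na(.data$sector), !is.na(.data$route_id)),
                    .data$sector, .data$route_id),
    time_s = dplyr::n() * dt, .groups = "drop")

  active_mat <- vapply(cells, function(sp) {
    sx <- stats::approx(traj$t, traj$x, xout = sp$t, rule = 2)$y
    sy <- stats::approx(traj$t, traj$y, xout = sp$t, rule = 2)$y
    ssec <- sector_at(sx, sy, layout)
    sroute <- traj$route_id[pmax(1L, findInterval(sp$t, traj$t))]
    cnt <- table(factor(ssec, sec_tab$sector)[!is.na(sroute)],
                 factor(sroute[!is.na(sroute)], 1:4))
    out <- rep(FALSE, nrow(sec_tab))
    for (i in seq_len(nrow(sec_tab))) {
      for (r in 1:4) {
        tm <- per_route_time$time_s[per_route_time$sector == sec_tab$sector[i] &
                                      per_route_time$route_id == r]
        if (length(tm) == 1 && tm > 0 &&
            cnt[sec_tab$sector[i], as.character(r)] / tm > active_hz) {
          out[i] <- TRUE; break
        }
      }
    }
    out
  }, logical(nrow(sec_tab)))

  occ <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(traj, !is.na(.data$sector)), .data$sector),
    time_s = dplyr::n() * dt,
    speed = sum(step[dplyr::cur_group_rows()]) / (dplyr::n() * dt),
    .groups = "drop")

  spike_rate <- vapply(sec_tab$sector, function(s) {
    tot <- sum(vapply(cells, function(sp) {
      sx <- stats::approx(traj$t, traj$x, xout = sp$t, rule = 2)$y
      sy <- stats::approx(traj$t, traj$y, xout = sp$t, rule = 2)$y
      sum(sector_at(sx, sy, layout) == s, na.rm = TRUE)
    }, numeric(1)))
    tm <- occ$time_s[occ$sector == s]
    if (length(tm) == 0 || tm == 0) NA_real_ else tot / tm / length(cells)
  }, numeric(1))

  profile <- dplyr::left_join(sec_tab, occ, by = "sector")
  profile$active_cells <- as.integer(rowSums(active_mat))
  profile$mean_rate <- spike_rate
  profile <- tibble::as_tibble(profile)

  dc <- if (stats::sd(profile$active_cells) == 0) {
    tibble::tibble(estimate = NA_real_, statistic = NA_real_,
                   df = nrow(profile) - 2, p_value = NA_real_)
  } else {
    ct <- stats::cor.test(profile$distance_rank, profile$active_cells)
    tibble::tibble(estimate = unname(ct$estimate),
                   statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p_value = ct$p.value)
  }
  list(profile = profile, distance_cor = dc)
}
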
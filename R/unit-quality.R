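#' Energy of a sampled waveform
#'
#' The sum of squared moduli of the samples, one of the features used for
#' spike sorting.
#'
#' @param x Numeric (or complex) vector of waveform samples.
#' @return Scalar energy.
#' @examples
#' spike_energy(c(1, -2, 2))  # 9
#' @export
spike_energy <- function(x) {
  if (length(x) == 0) stop("waveform must be nonempty", call. = FALSE)
  sum(Mod(x)^2)
}

# Squared Mahalanobis distances of points to the cluster centre, in the
# metric of the cluster's sample covariance.
cluster_mahalanobis <- function(cluster_points, points) {
  mu <- colMeans(cluster_points)
  sigma <- stats::cov(cluster_points)
  if (!all(is.finite(sigma)) || rcond_est(sigma) < 1e-12)
    stop("cluster covariance is singular; metrics undefined", call. = FALSE)
  stats::mahalanobis(points, mu, sigma)
}

rcond_est <- function(m) {
  ev <- tryCatch(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) c(0, 1))
  if (min(ev) <= 0) 0 else min(ev) / max(ev)
}

#' Isolation distance of a spike cluster
#'
#' For a cluster of `n_c` spikes, the squared Mahalanobis distance (in the
#' cluster's own covariance metric) of the `n_c`-th closest non-cluster
#' spike to the cluster centre. Higher values indicate better isolation.
#' Undefined (NA, with a `reason` attribute) when there are fewer
#' non-cluster spikes than cluster spikes.
#'
#' @param cluster_points Matrix of cluster spike features (n_c x d).
#' @param noncluster_points Matrix of non-cluster spike features (m x d).
#' @return Scalar isolation distance, or `NA` when undefined.
#' @export
isolation_distance <- function(cluster_points, noncluster_points) {
  cluster_points <- as.matrix(cluster_points)
  noncluster_points <- as.matrix(noncluster_points)
  n_c <- nrow(cluster_points)
  if (nrow(noncluster_points) < n_c) {
    return(structure(NA_real_,
                     reason = "fewer non-cluster spikes than cluster spikes"))
  }
  d2 <- cluster_mahalanobis(cluster_points, noncluster_points)
  sort(d2)[n_c]
}

#' L and L-ratio of a spike cluster
#'
#' `L` sums, over all non-cluster spikes, the upper-tail chi-squared
#' probability of their squared Mahalanobis distance to the cluster centre
#' (`df` defaults to the feature dimension; 8 for tetrode feature sets).
#' `L_ratio` is `L` divided by the cluster size. Smaller values indicate
#' better isolation.
#'
#' @inheritParams isolation_distance
#' @param df Chi-squared degrees of freedom; defaults to the feature
#'   dimension.
#' @return List with `L` and `l_ratio`.
#' @export
l_ratio <- function(cluster_points, noncluster_points, df = NULL) {
  cluster_points <- as.matrix(cluster_points)
  noncluster_points <- as.matrix(noncluster_points)
  if (is.null(df)) df <- ncol(cluster_points)
  d2 <- cluster_mahalanobis(cluster_points, noncluster_points)
  L <- sum(stats::pchisq(d2, df, lower.tail = FALSE))
  list(L = L, l_ratio = L / nrow(cluster_points))
}

#' Signal-to-noise ratio of a unit
#'
#' Signal and noise amplitudes are measured across the same impedance, so
#' the ratio reduces to the squared ratio of mean amplitudes,
#' `(mu_signal / mu_noise)^2`.
#'
#' @param mean_signal_amplitude Mean peak amplitude of the unit's waveforms.
#' @param mean_noise_amplitude Mean amplitude of the accompanying noise
#'   cluster; must be positive.
#' @return Scalar S/N.
#' @export
signal_to_noise <- function(mean_signal_amplitude, mean_noise_amplitude) {
  if (any(mean_noise_amplitude <= 0))
    stop("mean noise amplitude must be positive", call. = FALSE)
  (mean_signal_amplitude / mean_noise_amplitude)^2
}

#' Quality metrics for one cluster
#'
#' Convenience wrapper computing isolation distance, L-ratio, S/N and peak
#' amplitude for a feature cloud or a pair of feature matrices.
#'
#' @param cluster_points,noncluster_points Feature matrices, or pass a
#'   [simulate_feature_cloud()] object as the first argument.
#' @param df Chi-squared df for the L-ratio (default: feature dimension).
#' @param signal_amplitude,noise_amplitude Optional mean amplitudes for S/N.
#' @return One-row tibble: `n_c`, `isolation_distance`, `L`, `l_ratio`,
#'   `snr`.
#' @export
cluster_quality <- function(cluster_points, noncluster_points = NULL,
                            df = NULL, signal_amplitude = NA,
                            noise_amplitude = NA) {
  if (inherits(cluster_points, "feature_cloud")) {
    noncluster_points <- cluster_points$noise_points
    cluster_points <- cluster_points$cluster_points
  }
  lr <- l_ratio(cluster_points, noncluster_points, df)
  tibble::tibble(
    n_c = nrow(cluster_points),
    isolation_distance = as.numeric(isolation_distance(cluster_points,
                                                       noncluster_points)),
    L = lr$L, l_ratio = lr$l_ratio,
    snr = if (is.na(noise_amplitude)) NA_real_ else
      signal_to_noise(signal_amplitude, noise_amplitude))
}

#' Place-cell classification criteria
#'
#' @param min_width Minimum waveform width, microseconds (exclusive).
#' @param rate_low,rate_high Open interval of acceptable mean firing rates,
#'   Hz.
#' @param min_info Minimum spatial information, bits per spike (exclusive).
#' @return A list of class `place_cell_criteria`.
#' @export
place_cell_criteria <- function(min_width = 250, rate_low = 0.1,
                                rate_high = 5, min_info = 0.5) {
  stopifnot(rate_low < rate_high)
  structure(list(min_width = min_width, rate_low = rate_low,
                 rate_high = rate_high, min_info = min_info),
            class = "place_cell_criteria")
}

#' Classify a unit as a place cell
#'
#' A unit is accepted as a place cell iff its waveform width exceeds 250
#' microseconds, its mean maze firing rate lies strictly between 0.1 and 5
#' Hz, and its spatial information exceeds 0.5 bits/spike (all inequalities
#' strict; boundary values are rejected).
#'
#' @param width_us Waveform width, microseconds.
#' @param mean_rate_hz Mean firing rate on the maze, Hz.
#' @param info_bits Spatial information, bits per spike.
#' @param criteria A [place_cell_criteria()].
#' @return List with `accept` (logical) and `reasons` (character vector of
#'   failed criteria, empty when accepted).
#' @export
classify_place_cell <- function(width_us, mean_rate_hz, info_bits,
                                criteria = place_cell_criteria()) {
  if (any(c(width_us, mean_rate_hz, info_bits) < 0) ||
      any(is.na(c(width_us, mean_rate_hz, info_bits))))
    stop("width, rate and information must be nonnegative numbers",
         call. = FALSE)
  reasons <- character(0)
  if (!(width_us > criteria$min_width)) reasons <- c(reasons, "width")
  if (!(mean_rate_hz > criteria$rate_low && mean_rate_hz < criteria$rate_high))
    reasons <- c(reasons, "rate")
  if (!(info_bits > criteria$min_info)) reasons <- c(reasons, "information")
  list(accept = length(reasons) == 0, reasons = reasons)
}

#' Iterative Grubbs outlier removal
#'
#' Repeatedly applies the two-sided single-outlier Grubbs test at level
#' `alpha`, removing the most extreme point, until no rejection (or fewer
#' than 3 points remain). The critical value uses the standard t-based form.
#'
#' @param x Numeric vector.
#' @param alpha Significance level per iteration.
#' @return List with `kept` (values), `keep` (logical index into the input),
#'   `n_removed`.
#' @export
grubbs_prune <- function(x, alpha = 0.05) {
  keep <- rep(TRUE, length(x)) & !is.na(x)
  repeat {
    xx <- x[keep]
    n <- length(xx)
    if (n < 3 || stats::sd(xx) == 0) break
    dev <- abs(xx - mean(xx)) / stats::sd(xx)
    g <- max(dev)
    tcrit <- stats::qt(alpha / (2 * n), n - 2, lower.tail = FALSE)
    gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (g <= gcrit) break
    drop_idx <- which(keep)[which.max(dev)]
    keep[drop_idx] <- FALSE
  }
  list(kept = x[keep], keep = keep, n_removed = sum(!keep & !is.na(x)))
}

#' Association between cluster quality and differential firing
#'
#' Checks whether differential firing could be an artefact of cluster
#' quality: (1) two-sample Kolmogorov--Smirnov tests comparing each quality
#' metric's distribution between differential and non-differential cells;
#' (2) Spearman correlations between each metric and the per-cell-per-sector
#' ANCOVA F statistic, computed after iterative Grubbs outlier removal on
#' both variables.
#'
#' @param data Tibble with one row per cell x sector: quality `metrics`
#'   columns, an `f_statistic` column, and a logical `differential` column.
#' @param metrics Character vector of metric column names.
#' @param alpha Grubbs level per iteration.
#' @return List of tibbles `ks` (metric, D, p_value) and `spearman` (metric,
#'   rho, p_value, n_used, n_removed). Metrics with fewer than 10 paired
#'   observations after pruning are flagged with `NA`.
#' @export
quality_effect_association <- function(data,
                                       metrics = c("isolation_distance",
                                                   "l_ratio", "snr",
                                                   "peak_amplitude"),
                                       alpha = 0.05) {
  stopifnot(all(c(metrics, "f_statistic", "differential") %in% names(data)))
  ks <- purrr::map_dfr(metrics, function(m) {
    a <- data[[m]][data$differential]
    b <- data[[m]][!data$differential]
    kt <- suppressWarnings(stats::ks.test(a, b))
    tibble::tibble(metric = m, D = unname(kt$statistic), p_value = kt$p.value)
  })
  spearman <- purrr::map_dfr(metrics, function(m) {
    ok <- stats::complete.cases(data[[m]], data$f_statistic)
    xm <- data[[m]][ok]; fs <- data$f_statistic[ok]
    km <- grubbs_prune(xm, alpha)$keep & grubbs_prune(fs, alpha)$keep
    n_used <- sum(km)
    if (n_used < 10) {
      return(tibble::tibble(metric = m, rho = NA_real_, p_value = NA_real_,
                            n_used = n_used, n_removed = sum(!km)))
    }
    ct <- suppressWarnings(stats::cor.test(xm[km], fs[km],
                                           method = "spearman"))
    tibble::tibble(metric = m, rho = unname(ct$estimate),
                   p_value = ct$p.value, n_used = n_used,
                   n_removed = sum(!km))
  })
  list(ks = ks, spearman = spearman)
}
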
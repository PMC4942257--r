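#' Write a session to a directory
#'
#' Serialises a session in plain-text formats: `position.tsv` (columns `t`,
#' `x`, `y`; seconds and cm), one `spikes_<cell>.tsv` per cell (column
#' `t`), `trials.json` (the trial manifest, including phase boundary
#' times), and `truth.json` (simulation ground truth, when present) so
#' recovery tests can compare against the generator.
#'
#' @param session A `maze_session` (optionally with `spikes`, a named list
#'   of spike trains, and `truth`, a serialisable list).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(session$trajectory[, c("t", "x", "y")],
                   file.path(dir, "position.tsv"))
  jsonlite::write_json(session$trials, file.path(dir, "trials.json"),
                       digits = NA, auto_unbox = FALSE, na = "null")
  for (nm in names(session$spikes %||% list())) {
    readr::write_tsv(tibble::tibble(t = session$spikes[[nm]]$t),
                     file.path(dir, sprintf("spikes_%s.tsv", nm)))
  }
  if (!is.null(session$truth)) {
    jsonlite::write_json(session$truth, file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE, na = "null",
                         force = TRUE)
  }
  invisible(dir)
}

#' Read a session from a directory
#'
#' Reads the layout produced by [write_session()], validates it (strictly
#' increasing timestamps, non-overlapping trials), reconstructs the
#' per-sample trial, route and phase labels from the manifest times, and
#' drops (with a warning) spikes outside the tracked time span.
#'
#' @param dir Directory containing `position.tsv`, `trials.json`, and
#'   `spikes_*.tsv` files.
#' @param layout Maze layout to attach; defaults to [build_maze_layout()].
#' @return A list of class `maze_session` with `trajectory`, `trials`,
#'   `spikes` (named list), `layout`, and `n_spikes_dropped`.
#' @export
read_session <- function(dir, layout = build_maze_layout()) {
  pos_file <- file.path(dir, "position.tsv")
  man_file <- file.path(dir, "trials.json")
  if (!file.exists(man_file)) stop("missing trial manifest trials.json",
                                   call. = FALSE)
  traj <- readr::read_tsv(pos_file, show_col_types = FALSE)
  bad <- which(diff(traj$t) <= 0)
  if (length(bad))
    stop("non-monotone timestamps in position.tsv at line ", bad[1] + 2,
         call. = FALSE)
  trials <- tibble::as_tibble(jsonlite::fromJSON(man_file))
  trials$trial_id <- as.integer(trials$trial_id)
  trials$block_id <- as.integer(trials$block_id)
  trials$trial_in_block <- as.integer(trials$trial_in_block)
  trials$rewarded_route <- as.integer(trials$rewarded_route)
  trials$route_id <- as.integer(trials$route_id)
  trials <- trials[order(trials$t_start), ]
  if (any(trials$t_start[-1] < trials$t_end[-nrow(trials)] - 1e-9))
    stop("overlapping trials in manifest", call. = FALSE)

  # reconstruct per-sample labels from the manifest windows, which are
  # half-open (t_start, t_end]; a 1 microsecond tolerance absorbs the last
  # ulp lost by the JSON round trip (samples are tens of ms apart)
  tol <- 1e-6
  idx <- findInterval(traj$t, trials$t_start + tol, left.open = TRUE)
  in_trial <- idx >= 1 & traj$t <= trials$t_end[pmax(idx, 1)] + tol
  traj$trial_id <- ifelse(in_trial, trials$trial_id[pmax(idx, 1)], NA_integer_)
  traj$route_id <- ifelse(in_trial, trials$route_id[pmax(idx, 1)], NA_integer_)
  phase <- rep("hold", nrow(traj))
  tr <- pmax(idx, 1)
  phase[in_trial & traj$t >= trials$t_run[tr] + tol] <- "run"
  goal_t <- ifelse(is.na(trials$t_goal), Inf, trials$t_goal)
  phase[in_trial & traj$t >= goal_t[tr] + tol] <- "goal"
  traj$phase <- phase

  spike_files <- sort(list.files(dir, pattern = "^spikes_.*\\.tsv$",
                                 full.names = TRUE))
  dropped <- 0L
  spikes <- stats::setNames(lapply(spike_files, function(f) {
    s <- readr::read_tsv(f, show_col_types = FALSE)
    out <- s$t >= traj$t[1] & s$t <= traj$t[nrow(traj)]
    dropped <<- dropped + sum(!out)
    tibble::tibble(t = s$t[out])
  }), sub("^spikes_(.*)\\.tsv$", "\\1", basename(spike_files)))
  if (dropped > 0)
    warning(dropped, " spike(s) outside the tracked time span dropped")

  structure(list(trajectory = traj, trials = trials, spikes = spikes,
                 layout = layout, n_spikes_dropped = dropped),
            class = "maze_session")
}

#' Simulate a complete session with a cell population
#'
#' Convenience wrapper combining [simulate_session()] with a population of
#' [simulate_place_cell()] spike trains and the ground-truth labels needed
#' by the recovery analyses.
#'
#' @param config A [session_config()].
#' @param cell_specs Named list of [cell_spec()]s; names become cell ids.
#' @param layout Maze layout.
#' @return A `maze_session` with `spikes` (named list) and `truth`
#'   (`cell_labels`: the generator's route/goal label per cell).
#' @export
simulate_population_session <- function(config, cell_specs,
                                        layout = build_maze_layout()) {
  sess <- simulate_session(layout, config)
  sess$trajectory <- assign_sectors(sess$trajectory, layout)
  sess$spikes <- purrr::imap(cell_specs, function(sp, nm) {
    simulate_place_cell(sp, sess$trajectory,
                        seed = derive_seed(config$seed,
                                           match(nm, names(cell_specs))))
  })
  sess$truth <- list(cell_labels = purrr::map_chr(cell_specs, spec_label))
  sess
}

# Generator-side route/goal label of a cell spec.
spec_label <- function(spec) {
  rg <- spec$route_gains
  gg <- spec$goal_gains
  if (stats::sd(rg) == 0 && gg[["centre"]] != gg[["left"]] &&
      gg[["centre"]] != gg[["right"]] && gg[["left"]] == gg[["right"]])
    return("goal_dependent")
  if (sum(rg != stats::median(rg)) == 1 && stats::sd(gg) == 0)
    return(paste0("route_specific_", which(rg != stats::median(rg))))
  if (stats::sd(rg) == 0 && stats::sd(gg) == 0) return("null")
  "other"
}

#' Run the full analysis pipeline on a session
#'
#' Orchestrates the analyses in the order of the original study: per-cell
#' sector statistics and the activity rule, differential-firing tests per
#' analysed sector with route/goal classification and population pattern
#' chi-squares, population-vector decoding with shuffle null for the start
#' box and central stem, the goal-box similarity analysis, and behavioural
#' scoring. Writes per-module CSVs plus `summary.json` into `out_dir` and
#' returns the summary. Deterministic given `seed` (stage seeds are derived
#' from it).
#'
#' @param session A `maze_session` with `spikes`.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param method Differential test: `"ranked"`, `"permutation"` or `"glm"`.
#' @param alpha Significance level for omnibus and post-hoc tests.
#' @param n_shuffles Shuffle count for ensemble and goal-box nulls.
#' @param k Shuffle count for the permutation ANCOVA.
#' @param seed Pipeline seed.
#' @return A list of class `pipeline_result`: `cell_sector` (per cell x
#'   sector test table), `pattern_counts`, `pattern_tests`, `decoding`
#'   (per sector), `goalbox`, `behavior`, `summary`.
#' @export
run_pipeline <- function(session, out_dir = NULL,
                         method = c("ranked", "permutation", "glm"),
                         alpha = 0.05, n_shuffles = 1000, k = 1000,
                         seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(session, "maze_session"), length(session$spikes) > 0)
  if (is.null(session$trajectory$sector))
    session$trajectory <- assign_sectors(session$trajectory, session$layout)
  sectors <- c("start_box", "central_stem", "left_stem", "right_stem")

  test_fun <- switch(method,
    ranked = function(st) ranked_ancova(st, alpha = alpha),
    permutation = function(st) permutation_ancova(st, k = k,
                                                  seed = derive_seed(seed, 2),
                                                  alpha = alpha),
    glm = function(st) poisson_glm_differential(st, alpha = alpha))

  cell_sector <- purrr::map_dfr(names(session$spikes), function(nm) {
    purrr::map_dfr(sectors, function(sec) {
      st <- sector_trial_stats(session$spikes[[nm]], session, sec)
      active <- isTRUE(is_active_in_sector(st))
      row <- tibble::tibble(cell_id = nm, sector = sec, active = active,
                            statistic = NA_real_, p_value = NA_real_,
                            differential = FALSE,
                            label = NA_character_)
      if (!active) return(row)
      res <- tryCatch(test_fun(st), error = function(e) NULL)
      if (is.null(res)) return(row)
      row$statistic <- res$statistic
      row$p_value <- res$p_value
      row$differential <- is.finite(res$p_value) && res$p_value < alpha
      if (row$differential && !is.null(res$posthoc))
        row$label <- classify_route_goal(res, alpha)$label
      row
    })
  })

  # pattern counts over cells differential in start box or central stem
  core <- cell_sector[cell_sector$sector %in% c("start_box", "central_stem") &
                        cell_sector$differential & !is.na(cell_sector$label), ]
  lab_per_cell <- purrr::map_chr(split(core, core$cell_id), function(d) {
    lab <- d$label[d$label != "unclassified"]
    if (length(lab) == 0) "unclassified" else lab[which.max(
      d$statistic[d$label != "unclassified"])]
  })
  counts <- c(sum(lab_per_cell == "route_specific_1"),
              sum(lab_per_cell == "route_specific_2"),
              sum(lab_per_cell == "route_specific_3"),
              sum(lab_per_cell == "route_specific_4"),
              sum(lab_per_cell == "goal_dependent"))
  pattern_tests <- if (sum(counts) > 0) population_pattern_tests(counts)
                   else NULL

  # ensemble decoding (start box and central stem)
  decoding <- list()
  if (length(session$spikes) >= 6) {
    for (sec in c("start_box", "central_stem")) {
      all_stats <- purrr::imap_dfr(session$spikes, function(sp, nm) {
        st <- sector_trial_stats(sp, session, sec)
        st$cell_id <- nm
        st
      })
      pv <- trial_population_vectors(all_stats)
      dec <- decode_trials(pv, seed = derive_seed(seed, 3))
      decoding[[sec]] <- shuffle_null(dec, n_shuffles = n_shuffles,
                                      seed = derive_seed(seed, 4))
    }
  }

  gb_vec <- boxroute_vectors(session$spikes, session)
  goalbox <- boxroute_shuffle_test(gb_vec, n_shuffles = n_shuffles,
                                   seed = derive_seed(seed, 5))
  behav <- list(blocks = score_blocks(session$trials),
                confusion = confusion_pairs(session$trials))

  summary <- list(
    n_cells = length(session$spikes),
    method = method,
    n_active_per_sector = purrr::map_int(
      split(cell_sector$active, cell_sector$sector), sum),
    n_differential_per_sector = purrr::map_int(
      split(cell_sector$differential, cell_sector$sector), sum),
    pattern_counts = stats::setNames(as.list(counts),
                                     c("route_1", "route_2", "route_3",
                                       "route_4", "goal")),
    pattern_tests = pattern_tests,
    decode_match = purrr::map(decoding, "match_matrix"),
    decode_p = purrr::map(decoding, "p_matrix"),
    goalbox = goalbox,
    total_errors_post = attr(behav$confusion, "total_errors_post"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(cell_sector, file.path(out_dir, "cell_sector.csv"))
    readr::write_csv(goalbox, file.path(out_dir, "goalbox.csv"))
    readr::write_csv(behav$blocks, file.path(out_dir, "behavior_blocks.csv"))
    readr::write_csv(behav$confusion,
                     file.path(out_dir, "behavior_confusion.csv"))
    for (sec in names(decoding)) {
      readr::write_csv(tibble::as_tibble(decoding[[sec]]$match_matrix),
                       file.path(out_dir, paste0("decode_match_", sec, ".csv")))
      readr::write_csv(tibble::as_tibble(decoding[[sec]]$p_matrix),
                       file.path(out_dir, paste0("decode_p_", sec, ".csv")))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE,
                         na = "null")
  }
  structure(list(cell_sector = cell_sector, pattern_counts = counts,
                 pattern_tests = pattern_tests, decoding = decoding,
                 goalbox = goalbox, behavior = behav, summary = summary),
            class = "pipeline_result")
}
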
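#' Per-position detectability report
#'
#' One row per (viewpoint, threshold): mean FD over plants, sample SD and the
#' number of plants — the per-position summary layout of a recording session.
#'
#' @param table a `visibility_table`.
#' @param viewpoints integer labels or a `viewpoint_set`; defaults to the
#'   labels present in the table.
#' @param thresholds FV thresholds, default a single 50 (the conventional
#'   "at most half occluded" criterion).
#' @return data.frame with columns `viewpoint_label`, `threshold`, `mean_fd`,
#'   `sd_fd`, `n_plants`.
#' @export
position_report <- function(table, viewpoints = NULL, thresholds = 50) {
  stopifnot(inherits(table, "visibility_table"))
  labels <- if (is.null(viewpoints)) table$viewpoint_labels
            else if (inherits(viewpoints, "viewpoint_set")) viewpoints$label
            else as.integer(viewpoints)
  rows <- list()
  for (lab in sort(labels)) for (th in thresholds) {
    r <- aggregate_fd(table, lab, th)
    rows[[length(rows) + 1]] <- data.frame(
      viewpoint_label = lab, threshold = th, mean_fd = r$mean_fd,
      sd_fd = r$sd_fd, n_plants = r$n_plants)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-plant detectability report
#'
#' @inheritParams position_report
#' @return data.frame with columns `viewpoint_label`, `threshold`, `plant_id`,
#'   `fd`.
#' @export
plant_report <- function(table, viewpoints = NULL, thresholds = 50) {
  stopifnot(inherits(table, "visibility_table"))
  labels <- if (is.null(viewpoints)) table$viewpoint_labels
            else if (inherits(viewpoints, "viewpoint_set")) viewpoints$label
            else as.integer(viewpoints)
  rows <- list()
  for (lab in sort(labels)) for (th in thresholds) {
    r <- aggregate_fd(table, lab, th)
    rows[[length(rows) + 1]] <- data.frame(
      viewpoint_label = lab, threshold = th,
      plant_id = names(r$per_plant), fd = as.numeric(r$per_plant))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flatten a combination report for export
#'
#' @param report a `combination_report` (or list of them, concatenated).
#' @return data.frame with columns `threshold`, `k`, `max_fd`,
#'   `n_argmax_subsets`, `example_subset` (labels joined by dashes) and
#'   `positions_needed`.
#' @export
combination_table <- function(report) {
  if (inherits(report, "combination_report")) report <- list(report)
  out <- do.call(rbind, lapply(report, function(r) {
    data.frame(
      threshold = r$threshold,
      k = r$by_size$k,
      max_fd = r$by_size$max_fd,
      n_argmax_subsets = r$by_size$n_argmax,
      example_subset = vapply(r$argmax, function(a)
        if (length(a)) subset_key(a[[1]]) else "", character(1)),
      positions_needed = r$positions_needed
    )
  }))
  rownames(out) <- NULL
  out
}

#' Positions-needed summary across thresholds
#'
#' For each FV threshold: the global maximum combined FD and the smallest
#' number of positions that attains it.
#'
#' @param reports list of `combination_report`, one per threshold.
#' @return data.frame with columns `threshold`, `max_fd`, `positions_needed`.
#' @export
positions_needed_table <- function(reports) {
  if (inherits(reports, "combination_report")) reports <- list(reports)
  out <- do.call(rbind, lapply(reports, function(r) data.frame(
    threshold = r$threshold, max_fd = r$global_max_fd,
    positions_needed = r$positions_needed)))
  rownames(out) <- NULL
  out
}

.ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Run the simulation step of the pipeline
#'
#' Simulates one recording session and writes `visibility.csv`,
#' `registry.csv`, `viewpoints.csv`, `scene.json` and a copy of the resolved
#' configuration (`config.yaml`) to the output directory, so a run is fully
#' reproducible from its persisted config.
#'
#' @param config list with elements `out_dir` (required), and optionally
#'   `params` (passed to [scene_params()]), `viewpoints` (a `viewpoint_set`
#'   or path to a viewpoint file; default canonical), `n_rays` (default 400)
#'   and `seed` (default 1).
#' @return Invisibly, a list of the written file paths plus the simulated
#'   session object.
#' @export
run_simulate <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  out <- .ensure_dir(config$out_dir)
  vp <- config$viewpoints
  vp <- if (is.null(vp)) canonical_viewpoints()
        else if (is.character(vp)) read_viewpoints(vp)
        else validate_viewpoints(vp)
  params <- do.call(scene_params, if (is.null(config$params)) list()
                                  else config$params)
  n_rays <- if (is.null(config$n_rays)) 400 else config$n_rays
  seed <- if (is.null(config$seed)) 1 else config$seed

  sess <- simulate_session(params, vp, n_rays = n_rays, seed = seed)
  paths <- list(
    visibility = file.path(out, "visibility.csv"),
    registry = file.path(out, "registry.csv"),
    viewpoints = file.path(out, "viewpoints.csv"),
    scene = file.path(out, "scene.json"),
    config = file.path(out, "config.yaml"))
  write_visibility_table(sess$table, paths$visibility, paths$registry)
  write_viewpoints(vp, paths$viewpoints)
  write_scene_json(sess$scene, paths$scene)
  yaml::write_yaml(list(step = "simulate", params = params,
                        n_rays = n_rays, seed = seed), paths$config)
  invisible(c(paths, list(session = sess)))
}

#' Run the per-position analysis step
#'
#' Reads a visibility table, registry and viewpoint definitions and writes
#' the per-position FD report (`per_position.csv`: one row per viewpoint and
#' threshold with mean FD, sample SD and n) and the per-plant breakdown
#' (`per_plant.csv`).
#'
#' @param config list with `visibility`, `registry`, `viewpoints` (paths),
#'   `out_dir`, and optionally `thresholds` (default 50).
#' @return Invisibly, the per-position report data.frame.
#' @export
run_analyze <- function(config) {
  for (f in c("visibility", "registry", "viewpoints", "out_dir"))
    if (is.null(config[[f]])) stop("config$", f, " is required")
  out <- .ensure_dir(config$out_dir)
  vp <- read_viewpoints(config$viewpoints)
  tab <- read_visibility_table(config$visibility, config$registry,
                               viewpoint_labels = vp$label)
  thresholds <- if (is.null(config$thresholds)) 50 else config$thresholds
  pos <- position_report(tab, vp, thresholds)
  utils::write.csv(pos, file.path(out, "per_position.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(plant_report(tab, vp, thresholds),
                   file.path(out, "per_plant.csv"),
                   row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(step = "analyze", thresholds = thresholds),
                   file.path(out, "config_analyze.yaml"))
  invisible(pos)
}

#' Run the viewpoint-combination step
#'
#' Exhaustively scans all non-empty viewpoint subsets (or runs the greedy
#' cover when `greedy = TRUE`) for each threshold, and writes the
#' maximum-FD-per-size table (`combinations.csv`) and the positions-needed
#' summary (`positions_needed.csv`).
#'
#' @param config list with `visibility`, `registry`, `viewpoints` (paths),
#'   `out_dir`, and optionally `thresholds` (default 50), `greedy` (default
#'   FALSE) and `cap` (exhaustive ceiling, default 20).
#' @return Invisibly, the list of `combination_report`s (or greedy
#'   trajectories).
#' @export
run_combine <- function(config) {
  for (f in c("visibility", "registry", "viewpoints", "out_dir"))
    if (is.null(config[[f]])) stop("config$", f, " is required")
  out <- .ensure_dir(config$out_dir)
  vp <- read_viewpoints(config$viewpoints)
  tab <- read_visibility_table(config$visibility, config$registry,
                               viewpoint_labels = vp$label)
  thresholds <- if (is.null(config$thresholds)) 50 else config$thresholds
  greedy <- isTRUE(config$greedy)
  cap <- if (is.null(config$cap)) 20 else config$cap

  if (greedy) {
    res <- lapply(thresholds, function(th) {
      tr <- greedy_cover(tab, vp, th)
      tr$threshold <- th
      tr
    })
    utils::write.csv(do.call(rbind, res), file.path(out, "greedy.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    res <- lapply(thresholds, function(th)
      max_fd_by_size(tab, vp, th, cap = cap))
    utils::write.csv(combination_table(res),
                     file.path(out, "combinations.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(positions_needed_table(res),
                     file.path(out, "positions_needed.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  yaml::write_yaml(list(step = "combine", thresholds = thresholds,
                        greedy = greedy, cap = cap),
                   file.path(out, "config_combine.yaml"))
  invisible(res)
}
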
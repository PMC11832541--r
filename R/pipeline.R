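#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis with the main-analysis
#' defaults: 4 dropped initial volumes, 50-volume windows at step 1, a 5-95%
#' density grid in 5% steps, vertex-disjoint path semantics, signed edge
#' ranking, a 2.5 mm motion-exclusion threshold and a 0.30 BFR subgroup
#' cut. The supplementary variant (100-volume windows, chronological age in
#' every model) is reachable by changing `window_volumes` /
#' `include_chron_age` only.
#'
#' @param window_volumes Sliding-window length in volumes (default 50).
#' @param step_volumes Window step (default 1).
#' @param drop_initial Leading volumes to discard per session (default 4).
#' @param density_start,density_stop,density_step Density grid (defaults
#'   0.05, 0.95, 0.05).
#' @param path_mode `"vertex"` or `"edge"` disjoint-path semantics.
#' @param rank_mode `"signed"` or `"absolute"` edge ranking.
#' @param motion_threshold_mm Motion exclusion threshold (default 2.5).
#' @param bfr_group_cut BFR threshold for the subgroup display (default 0.30).
#' @param include_chron_age Named logical vector per model id; default age
#'   only in the brain-age model.
#' @param seed Integer seed recorded with the run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_volumes = 50L, step_volumes = 1L,
                            drop_initial = 4L,
                            density_start = 0.05, density_stop = 0.95,
                            density_step = 0.05,
                            path_mode = c("vertex", "edge"),
                            rank_mode = c("signed", "absolute"),
                            motion_threshold_mm = 2.5,
                            bfr_group_cut = 0.30,
                            include_chron_age = c(thickness = FALSE,
                                                  gm_volume = FALSE,
                                                  brain_age = TRUE),
                            seed = 1L) {
  path_mode <- match.arg(path_mode)
  rank_mode <- match.arg(rank_mode)
  stop_if_not_scalar_count(window_volumes, "window_volumes", min = 2L)
  stop_if_not_scalar_count(step_volumes, "step_volumes")
  stop_if_not_scalar_count(drop_initial, "drop_initial", min = 0L)
  if (motion_threshold_mm <= 0) stop("'motion_threshold_mm' must be positive")
  if (bfr_group_cut <= 0 || bfr_group_cut >= 1) {
    stop("'bfr_group_cut' must lie strictly between 0 and 1")
  }
  grid <- density_grid(density_start, density_stop, density_step)
  if (!all(c("thickness", "gm_volume", "brain_age") %in%
           names(include_chron_age))) {
    stop("'include_chron_age' needs entries thickness, gm_volume, brain_age")
  }
  structure(
    list(window_volumes = as.integer(window_volumes),
         step_volumes = as.integer(step_volumes),
         drop_initial = as.integer(drop_initial),
         density_start = density_start, density_stop = density_stop,
         density_step = density_step,
         grid = grid,
         path_mode = path_mode, rank_mode = rank_mode,
         motion_threshold_mm = motion_threshold_mm,
         bfr_group_cut = bfr_group_cut,
         include_chron_age = include_chron_age,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "Pipeline config: window %d/step %d, drop %d, grid %.2f-%.2f/%.2f, %s paths, %s ranking\n",
    x$window_volumes, x$step_volumes, x$drop_initial, x$density_start,
    x$density_stop, x$density_step, x$path_mode, x$rank_mode))
  invisible(x)
}

#' Write / read a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  keep <- setdiff(names(config), "grid")
  lst <- unclass(config)[keep]
  lst$include_chron_age <- as.list(lst$include_chron_age)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$include_chron_age <- unlist(lst$include_chron_age)
  do.call(pipeline_config, lst)
}

#' Run the full analysis pipeline
#'
#' Executes timeseries trimming, sliding-window dynamic FC, redundancy
#' labeling, the BFR score, motion exclusion, GM-volume normalization,
#' cognitive PCA with elbow selection, and the three moderation regressions.
#' Identical config and inputs give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param timeseries Per-subject list of session [regional_ts()] lists, or a
#'   [gen_cohort()] result (in which case `subjects` / `cognitive_scores`
#'   default to the cohort's).
#' @param subjects Subject table (see [read_subject_table()]).
#' @param cognitive_scores Subjects x 13 matrix of raw test scores, rows
#'   aligned with `subjects`.
#' @return List with `bfr_table` (subject_id, bfr, n_windows), `profiles`,
#'   `pca` (a `cognitive_components`), `fits` (per brain-change
#'   `moderation_fit`), `records` (the analysis data.frame), `splits`, and
#'   `manifest`.
#' @export
run_pipeline <- function(config, timeseries, subjects = NULL,
                         cognitive_scores = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(timeseries, "synthetic_cohort")) {
    subjects <- subjects %||% timeseries$subjects
    cognitive_scores <- cognitive_scores %||% timeseries$cognitive_scores
    ts_list <- timeseries$timeseries
    names(ts_list) <- timeseries$subjects$subject_id
  } else {
    ts_list <- timeseries
  }
  if (is.null(subjects) || is.null(cognitive_scores)) {
    stop("'subjects' and 'cognitive_scores' are required")
  }
  if (is.null(names(ts_list))) {
    stop("'timeseries' must be a named per-subject list")
  }
  if (!setequal(names(ts_list), subjects$subject_id)) {
    stop("subject IDs in timeseries and subject table do not match")
  }
  rownames(cognitive_scores) <- rownames(cognitive_scores) %||%
    subjects$subject_id

  retained <- exclude_by_motion(subjects, config$motion_threshold_mm)

  profiles <- lapply(retained$subject_id, function(sid) {
    stacks <- lapply(ts_list[[sid]], function(ts) {
      ts <- drop_initial_volumes(ts, config$drop_initial)
      build_stack(ts, config$window_volumes, config$step_volumes)
    })
    bfr_score(stacks, config$grid, config$rank_mode, config$path_mode)
  })
  names(profiles) <- retained$subject_id
  bfr_table <- data.frame(
    subject_id = retained$subject_id,
    bfr = vapply(profiles, `[[`, numeric(1), "bfr"),
    n_windows = vapply(profiles, `[[`, integer(1), "n_windows"),
    row.names = NULL)

  cog <- cognitive_scores[retained$subject_id, , drop = FALSE]
  pca <- cognitive_pca(cog)

  records <- data.frame(
    retained,
    gm_volume_norm = normalize_gm_volume(retained$gm_volume, retained$tiv),
    bfr = bfr_table$bfr,
    pca$retained_scores,
    row.names = NULL)

  fits <- lapply(c(thickness = "thickness", gm_volume = "gm_volume",
                   brain_age = "brain_age"), function(bc) {
    fit_moderation(records, bc,
                   include_chron_age = config$include_chron_age[[bc]])
  })

  splits <- list(
    thickness_mean = mean_split(records$cortical_thickness),
    gm_volume_mean = mean_split(records$gm_volume_norm),
    bfr_threshold = threshold_split(records$bfr, config$bfr_group_cut,
                                    outcome = records$PC1,
                                    bc = records$cortical_thickness))

  manifest <- list(
    config = unclass(config)[setdiff(names(config), "grid")],
    n_subjects_input = nrow(subjects),
    n_subjects_retained = nrow(retained),
    n_regions = ncol(ts_list[[1]][[1]]$values),
    n_windows_per_subject = unique(bfr_table$n_windows),
    n_components_retained = pca$n_retained,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  list(bfr_table = bfr_table, profiles = profiles, pca = pca, fits = fits,
       records = records, splits = splits, manifest = manifest)
}
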
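# Result serialization: trajectory CSV, metrics CSV, summary JSON, task dump.

#' Write a trajectory table to CSV
#'
#' One row per timestep with the per-step record (states, actions, internal
#' state before/after, drive, reward, action probabilities and value
#' snapshots). Accepts a single-episode trajectory or a bound trial table.
#'
#' @param traj trajectory data frame (from \code{\link{run_episode}} or
#'   \code{\link{bind_trial}}).
#' @param path output file.
#' @param trial optional trial index column to prepend.
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, trial = NA_integer_) {
  out <- cbind(trial = trial, as.data.frame(traj))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write per-replicate metrics to CSV
#'
#' @param result a \code{condition_result} from \code{\link{run_condition}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_metrics_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}

#' Write a condition summary (mean, SD, n per metric) to JSON
#'
#' @inheritParams write_metrics_csv
#' @return the path, invisibly.
#' @export
write_summary_json <- function(result, path) {
  summ <- summarize_condition(result)
  jsonlite::write_json(
    list(condition = result$condition[1], metrics = summ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Dump a task specification to JSON (run provenance)
#'
#' @param task an \code{hrl_task}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_task_json <- function(task, path) {
  stopifnot(inherits(task, "hrl_task"))
  spec <- list(
    name = task$name, states = task$states,
    actions = apply(task$actions, 1, function(r) as.list(stats::na.omit(r))),
    next_state = task$next_state, intake = task$intake, cost = task$cost,
    terminal = task$terminal, initial_state = task$states[task$initial_state],
    initial_H = task$initial_H, episode_length = task$episode_length,
    step_cap = task$step_cap)
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
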
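# Plain-text round-tripping of trial records, policies and landscapes:
# tidy CSV for the tables, a JSON sidecar for the generating configuration.

task_to_list <- function(task) {
  task[c("drifts", "weights", "d_correct", "d_incorrect", "reward",
         "prior_up")]
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Write and read trial-record tables
#'
#' `write_trials()` saves a trial table as CSV (cue sequences serialised as
#' `+`/`-` strings) with a JSON sidecar (`<path>.json`) recording the task
#' and any extra metadata. `read_trials()` loads the CSV back and validates
#' the record invariants: cues are `+`/`-` strings of length `decision_t`,
#' and `correct` equals `response == world`.
#'
#' @param trials Trial-record tibble.
#' @param path Output CSV path.
#' @param task Optional [task_config()] stored in the sidecar.
#' @param meta Optional named list merged into the sidecar.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns the validated tibble.
#' @export
write_trials <- function(trials, path, task = NULL, meta = list()) {
  stopifnot(is.data.frame(trials))
  readr::write_csv(trials, path)
  side <- c(list(kind = "waitgo_trials", n_trials = nrow(trials)), meta)
  if (!is.null(task)) side$task <- task_to_list(task)
  write_sidecar(path, side)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      cues = readr::col_character(),
      world = readr::col_character(),
      response = readr::col_character()
    )
  )
  trials$cues[is.na(trials$cues)] <- ""
  if (!all(c("cues", "decision_t", "response", "world", "correct") %in%
           names(trials))) {
    abort("not a trial-record table: required columns are missing.")
  }
  if (any(nchar(trials$cues) != trials$decision_t)) {
    abort("invalid records: cue strings do not match `decision_t`.")
  }
  if (any(grepl("[^+-]", trials$cues))) {
    abort("invalid records: cue strings may only contain '+' and '-'.")
  }
  if (any(trials$correct != (trials$response == trials$world))) {
    abort("invalid records: `correct` contradicts response vs world.")
  }
  trials
}

#' Export a policy or boundary as tidy CSV
#'
#' `write_policy()` writes the long `(t, x, action)` action map;
#' `write_boundary()` writes the `(t, theta)` trace; `write_landscape()`
#' writes the long `(slope_deg, intercept, reward_rate)` grid. Each carries
#' a JSON sidecar with the task, horizon and gain where available.
#'
#' @param policy A `waitgo_policy`.
#' @param boundary A `waitgo_boundary`.
#' @param landscape A `waitgo_landscape`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "waitgo_policy"))
  readr::write_csv(tidy(policy), path)
  meta <- list(kind = "waitgo_policy", t_max = policy$t_max,
               gain = policy$gain, source = policy$source)
  if (!is.null(policy$task)) meta$task <- task_to_list(policy$task)
  write_sidecar(path, meta)
  invisible(path)
}

#' @rdname write_policy
#' @export
write_boundary <- function(boundary, path) {
  stopifnot(inherits(boundary, "waitgo_boundary"))
  readr::write_csv(as_tibble(boundary), path)
  write_sidecar(path, list(kind = "waitgo_boundary",
                           gain = attr(boundary, "gain")))
  invisible(path)
}

#' @rdname write_policy
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "waitgo_landscape"))
  readr::write_csv(as_tibble(landscape), path)
  meta <- list(kind = "waitgo_landscape", t_max = attr(landscape, "t_max"),
               argmax = attr(landscape, "argmax"))
  task <- attr(landscape, "task")
  if (!is.null(task)) meta$task <- task_to_list(task)
  write_sidecar(path, meta)
  invisible(path)
}
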
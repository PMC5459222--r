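# Experiment presets: the task parameter sets of the six expanded-judgment
# experiments, expressed in ISI units (millisecond parameters are divided by
# the ISI once, here).

preset_names <- c("exp1", "exp2a", "exp2b", "exp2c", "exp2d", "exp3")

#' Task presets for the six experiments
#'
#' Returns the full configuration of one experiment: per-condition
#' [task_config()] objects (easy and difficult single-difficulty tasks and
#' the 50/50 mixed task), per-condition block durations, and the ISI used to
#' convert the published millisecond parameters into ISI units.
#'
#' The six presets:
#' \describe{
#'   \item{exp1}{drifts 0.20/0, ISI 200 ms, `D_C` = 3 s = 15 units, `D_I` =
#'     10 s = 50 units.}
#'   \item{exp2a}{drifts 0.22/0, ISI 200 ms, `D_I` = 50 units, `D_C` =
#'     `D_I`/3.}
#'   \item{exp2b}{as exp2a at ISI 50 ms (delays unchanged in ISI units).}
#'   \item{exp2c}{as exp2a with `D_C` = `D_I` = 50 units.}
#'   \item{exp2d}{as exp2c at ISI 50 ms.}
#'   \item{exp3}{drifts 0.40/0.10, ISI 50 ms, `D_C` = `D_I` = 3.5 s = 70
#'     units.}
#' }
#' Block durations follow the published session structure (easy 240 s,
#' difficult and mixed 300 s, two testing blocks per condition), converted
#' at the preset's ISI.
#'
#' @param name One of `"exp1"`, `"exp2a"`, `"exp2b"`, `"exp2c"`, `"exp2d"`,
#'   `"exp3"`.
#' @return A list of class `waitgo_preset`: `name`, `isi_ms`, `tasks`
#'   (named list: easy/difficult/mixed), `durations` (named, ISI units per
#'   block), `n_blocks`, `drifts`, `d_correct`, `d_incorrect`.
#' @examples
#' experiment_preset("exp2a")$tasks$easy
#' @export
experiment_preset <- function(name = preset_names) {
  name <- arg_match(name)
  par <- switch(
    name,
    exp1  = list(isi = 200, eps = c(0.20, 0),   dc = 15,     di = 50),
    exp2a = list(isi = 200, eps = c(0.22, 0),   dc = 50 / 3, di = 50),
    exp2b = list(isi = 50,  eps = c(0.22, 0),   dc = 50 / 3, di = 50),
    exp2c = list(isi = 200, eps = c(0.22, 0),   dc = 50,     di = 50),
    exp2d = list(isi = 50,  eps = c(0.22, 0),   dc = 50,     di = 50),
    exp3  = list(isi = 50,  eps = c(0.40, 0.10), dc = 70,    di = 70)
  )
  sec <- 1000 / par$isi  # ISI units per second
  tasks <- list(
    easy = task_config(par$eps[1], d_correct = par$dc, d_incorrect = par$di),
    difficult = task_config(par$eps[2], d_correct = par$dc,
                            d_incorrect = par$di),
    mixed = task_config(par$eps, d_correct = par$dc, d_incorrect = par$di)
  )
  structure(
    list(
      name = name, isi_ms = par$isi, tasks = tasks,
      durations = c(easy = 240 * sec, difficult = 300 * sec,
                    mixed = 300 * sec),
      n_blocks = 2L,
      drifts = par$eps, d_correct = par$dc, d_incorrect = par$di
    ),
    class = "waitgo_preset"
  )
}

#' @export
print.waitgo_preset <- function(x, ...) {
  cat("<waitgo_preset> ", x$name, " (ISI ", x$isi_ms, " ms)\n", sep = "")
  cat("  drifts ", paste(x$drifts, collapse = "/"),
      ", D_C = ", format(x$d_correct), ", D_I = ", format(x$d_incorrect),
      " ISI units\n", sep = "")
  cat("  block durations (units): ",
      paste(names(x$durations), "=", round(x$durations), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
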
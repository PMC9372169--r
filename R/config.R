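#' Run configuration for the command-line pipeline
#'
#' A plain-list description of one inverse-filter run: input paths,
#' channel selection, how to obtain the UIR, the
#' [inverse_filter_config()] fields, output paths and a seed.  Round
#' trips through YAML unchanged.
#'
#' @param input Input file path(s) (EDF or delimited text).
#' @param channels Optional channel labels to process.
#' @param uir_file Path to a stored UIR (see [write_uir()]); or
#' @param characterize_from Path to a step/calibration recording plus
#' @param characterize_mode its mode (`"measured_step"` or
#'   `"calibration_square"`).
#' @param filter Named list of [inverse_filter_config()] arguments.
#' @param output Output path.
#' @param seed Integer seed for any stochastic step.
#' @param force Override the minimum-length guard.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = character(), channels = NULL,
                       uir_file = NULL, characterize_from = NULL,
                       characterize_mode = "calibration_square",
                       filter = list(), output = NULL, seed = 1L,
                       force = FALSE) {
  structure(
    list(input = input, channels = channels, uir_file = uir_file,
         characterize_from = characterize_from,
         characterize_mode = characterize_mode, filter = filter,
         output = output, seed = as.integer(seed), force = isTRUE(force)),
    class = "run_config"
  )
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(run_config, obj[!vapply(obj, is.null, TRUE)])
}

#' Read a signal file by extension
#'
#' Dispatches to [read_edf()] for `.edf` and [read_text_ts()]
#' otherwise; always returns a named list of [time_series()].
#'
#' @param path Input file.
#' @param channels Optional channel selection (EDF only).
#' @return Named list of `time_series`.
#' @export
read_signal_file <- function(path, channels = NULL) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    read_edf(path, channels)
  } else {
    ts <- read_text_ts(path)
    stats::setNames(list(ts), ts$label)
  }
}
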
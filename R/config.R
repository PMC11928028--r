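# JSON configuration loading/saving with typo-safe validation.

#' Load and validate a run configuration
#'
#' Reads a JSON configuration with optional blocks \code{hh} (fields of
#' \code{\link{hh_params}}), \code{fdf} (fields of \code{\link{fdf_params}}),
#' \code{template} (fields of \code{\link{trace_template}}), \code{stimulus}
#' (\code{schedule} data frame + \code{total_duration}) and a top-level
#' \code{seed}. Unknown keys anywhere are rejected, and all violations are
#' aggregated into a single error report.
#'
#' @param path JSON file path.
#' @return object of class \code{run_config}: the validated blocks as
#'   constructed parameter objects.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("load_config(): no such file: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known_blocks <- c("hh", "fdf", "template", "stimulus", "seed")
  errors <- character(0)
  bad <- setdiff(names(raw), known_blocks)
  if (length(bad)) {
    errors <- c(errors, sprintf("unknown top-level key(s): %s",
                                paste(bad, collapse = ", ")))
  }
  out <- list(seed = raw$seed %||% 1L)
  if (!is.null(raw$seed) &&
      (!is.numeric(raw$seed) || length(raw$seed) != 1)) {
    errors <- c(errors, "'seed' must be a single number")
  }
  build <- function(name, ctor, args) {
    tryCatch(do.call(ctor, as.list(args)),
             error = function(e) {
               errors <<- c(errors, sprintf("[%s] %s", name, conditionMessage(e)))
               NULL
             })
  }
  if (!is.null(raw$hh)) out$hh <- build("hh", hh_params, raw$hh)
  if (!is.null(raw$fdf)) out$fdf <- build("fdf", fdf_params, raw$fdf)
  if (!is.null(raw$template)) out$template <- build("template", trace_template, raw$template)
  if (!is.null(raw$stimulus)) {
    out$stimulus <- build("stimulus", stimulus_program,
                          list(schedule = as.data.frame(raw$stimulus$schedule),
                               total_duration = raw$stimulus$total_duration))
  }
  if (length(errors)) {
    stopf("invalid configuration '%s':\n  - %s", path,
          paste(errors, collapse = "\n  - "))
  }
  structure(out, class = "run_config")
}

#' Save a run configuration to JSON
#'
#' Inverse of \code{\link{load_config}}: \code{save_config} then
#' \code{load_config} reproduces the configuration.
#'
#' @param config a \code{run_config} (or a plain list of blocks).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  ser <- list()
  if (!is.null(config$seed)) ser$seed <- config$seed
  for (blk in c("hh", "fdf", "template")) {
    if (!is.null(config[[blk]])) ser[[blk]] <- unclass(config[[blk]])
  }
  if (!is.null(config$stimulus)) {
    ser$stimulus <- list(schedule = config$stimulus$schedule,
                         total_duration = config$stimulus$total_duration)
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
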
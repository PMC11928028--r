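# ThT trace container and CSV round-trip

#' Construct a ThT fluorescence trace
#'
#' A ThT trace is the common currency between the simulators, the analysis
#' functions and the synthetic-data generator: a time-stamped fluorescence
#' proxy for membrane potential (ThT is a Nernstian dye, so brighter means
#' more hyperpolarized).
#'
#' @param times time stamps in minutes, strictly increasing.
#' @param intensity fluorescence intensities (arbitrary units, >= 0), same
#'   length as \code{times}.
#' @param label free-text provenance tag.
#' @param normalized logical; if \code{TRUE} the trace has been min-max
#'   rescaled so that \code{max(intensity) == 1} and \code{min(intensity) == 0}.
#' @param dynamic_range optional max/min ratio of the raw (pre-normalization)
#'   intensity; used by \code{\link{detect_peaks}} to flag non-responsive
#'   traces whose apparent structure is only rescaled noise.
#' @return an object of class \code{tht_trace}.
#' @export
tht_trace <- function(times, intensity, label = "", normalized = FALSE,
                      dynamic_range = NULL) {
  times <- as.numeric(times); intensity <- as.numeric(intensity)
  if (length(times) == 0L) stopf("tht_trace(): empty time vector")
  if (length(times) != length(intensity)) {
    stopf("tht_trace(): times (%d) and intensity (%d) lengths differ",
          length(times), length(intensity))
  }
  if (any(!is.finite(times)) || any(!is.finite(intensity))) {
    stopf("tht_trace(): non-finite values")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stopf("tht_trace(): times must be strictly increasing")
  }
  if (any(intensity < -1e-12)) stopf("tht_trace(): negative intensity")
  if (isTRUE(normalized) && abs(max(intensity) - 1) > 1e-8) {
    stopf("tht_trace(): normalized trace must have max intensity 1")
  }
  structure(
    list(times = times, intensity = pmax(intensity, 0),
         label = as.character(label)[1], normalized = isTRUE(normalized),
         dynamic_range = if (is.null(dynamic_range)) NULL else as.numeric(dynamic_range)),
    class = "tht_trace")
}

#' @export
print.tht_trace <- function(x, ...) {
  cat(sprintf("ThT trace '%s': %d samples, t = [%.3g, %.3g] min, %s\n",
              x$label, length(x$times), min(x$times), max(x$times),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' @export
length.tht_trace <- function(x) length(x$times)

#' Write a ThT trace to CSV
#'
#' Two columns (\code{time_min}, \code{intensity}) preceded by \code{#}
#' comment lines carrying the label, normalization flag, optional extra
#' metadata and the package version. Full double precision is kept so that
#' \code{write_trace_csv()} then \code{\link{read_trace_csv}} is an identity.
#'
#' @param trace a \code{\link{tht_trace}}.
#' @param path output file path.
#' @param meta optional named character vector of extra \code{# key: value}
#'   header lines (e.g. variant, seed).
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path, meta = NULL) {
  stopifnot(inherits(trace, "tht_trace"))
  hdr <- c(sprintf("# label: %s", trace$label),
           sprintf("# normalized: %s", trace$normalized))
  if (!is.null(trace$dynamic_range)) {
    hdr <- c(hdr, sprintf("# dynamic_range: %.17g", trace$dynamic_range))
  }
  if (length(meta)) {
    hdr <- c(hdr, sprintf("# %s: %s", names(meta), as.character(meta)))
  }
  hdr <- c(hdr, sprintf("# package: biofilmwave %s",
                        as.character(utils::packageVersion("biofilmwave"))))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_min,intensity", con)
  writeLines(sprintf("%.17g,%.17g", trace$times, trace$intensity), con)
  invisible(path)
}

#' Read a ThT trace from CSV
#'
#' @param path CSV file written by \code{\link{write_trace_csv}} (or any
#'   two-column \code{time_min,intensity} CSV with optional \code{#} headers).
#' @return a \code{\link{tht_trace}}.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stopf("read_trace_csv(): no such file: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  get_meta <- function(key) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(m)) trimws(sub(sprintf("^# %s:", key), "", m[1])) else NULL
  }
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  for (col in c("time_min", "intensity")) {
    if (!col %in% names(df)) stopf("read_trace_csv(): missing column '%s'", col)
  }
  dr <- get_meta("dynamic_range")
  tht_trace(df$time_min, df$intensity,
            label = get_meta("label") %||% "",
            normalized = identical(get_meta("normalized"), "TRUE"),
            dynamic_range = if (is.null(dr)) NULL else as.numeric(dr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
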
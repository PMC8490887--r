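# Plain-text I/O: CSV time series, YAML configuration, flat keyed state
# snapshots, and the run manifest every artifact-producing script emits.

#' Write / read an influent or observation series as CSV
#'
#' UTF-8, header row, '.' decimal separator.
#'
#' @param x data frame.
#' @param path file path.
#' @return `read_series_csv` returns the data frame; a missing required
#'   column is a named error.
#' @export
write_series_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_series_csv
#' @param required columns that must be present.
#' @export
read_series_csv <- function(path, required = c("day")) {
  x <- utils::read.csv(path, fileEncoding = "UTF-8")
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  x
}

#' Save / restore a plant state snapshot
#'
#' Flat keyed text (`name value` per line, full double precision) so a
#' run can resume or a calibration can restart from a recorded state.
#'
#' @param y full plant state (length 107).
#' @param path file path.
#' @return `read_state_snapshot` returns the named state vector.
#' @export
write_state_snapshot <- function(y, path) {
  stopifnot(length(y) == 107L)
  writeLines(sprintf("%s %.17g", plant_state_names(), as.numeric(y)), path)
  invisible(path)
}

#' @rdname write_state_snapshot
#' @export
read_state_snapshot <- function(path) {
  ln <- strsplit(trimws(readLines(path)), " +")
  y <- stats::setNames(vapply(ln, function(z) as.numeric(z[2]), numeric(1)),
                       vapply(ln, `[`, "", 1))
  if (!identical(names(y), plant_state_names()))
    stop("snapshot does not match the plant state layout")
  y
}

#' Write a run manifest
#'
#' Records command, configuration, seed, package version, input/output
#' file checksums and wall-clock bounds for an artifact-producing run, as
#' YAML next to the outputs.
#'
#' @param path manifest file path.
#' @param command short command/stage name.
#' @param seed integer seed used (or `NA`).
#' @param inputs,outputs character vectors of file paths (existing files
#'   are checksummed).
#' @param extra named list of extra fields.
#' @param started POSIXct start time.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, seed = NA_integer_,
                           inputs = character(), outputs = character(),
                           extra = list(), started = Sys.time()) {
  sums <- function(fs) {
    fs <- fs[file.exists(fs)]
    if (!length(fs)) return(NULL)
    as.list(stats::setNames(unname(tools::md5sum(fs)), basename(fs)))
  }
  m <- c(list(command = command,
              package = "adplant",
              version = as.character(utils::packageVersion("adplant")),
              seed = if (is.na(seed)) "none" else as.integer(seed),
              started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
              finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              inputs = sums(inputs), outputs = sums(outputs)),
         extra)
  yaml::write_yaml(m, path)
  invisible(m)
}
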
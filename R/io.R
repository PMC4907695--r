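# Plain-text readers and writers for the pipeline's tabular interchange
# formats. All round-trip to within 1e-12.

#' Write / read an intensity trace as CSV
#'
#' Columns `frame`, `time_s`, `donor_counts`, `acceptor_counts`.
#'
#' @param trace An `intensity_trace`.
#' @param path File path.
#' @return `read_trace_csv` returns an `intensity_trace`;
#'   `write_trace_csv` returns `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  utils::write.csv(as.data.frame(trace)[, c("frame", "time_s",
                                            "donor_counts",
                                            "acceptor_counts")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- read_csv_checked(path, c("frame", "time_s", "donor_counts",
                                "acceptor_counts"))
  if (nrow(d) >= 2) {
    attr(d, "frame_period") <- d$time_s[2] - d$time_s[1]
  }
  class(d) <- c("intensity_trace", "data.frame")
  d
}

#' Write / read a FRET-efficiency list as single-column CSV
#'
#' @param efficiencies Numeric vector.
#' @param path File path.
#' @export
write_efficiency_csv <- function(efficiencies, path) {
  utils::write.csv(data.frame(E = efficiencies), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_efficiency_csv
#' @export
read_efficiency_csv <- function(path) {
  read_csv_checked(path, "E")$E
}

#' Write / read a histogram as CSV
#'
#' Columns `bin_lo`, `bin_hi`, `frequency`; condition and replicate are
#' stored as extra columns.
#'
#' @param histogram A `fret_histogram`.
#' @param path File path.
#' @export
write_histogram_csv <- function(histogram, path) {
  stopifnot(inherits(histogram, "fret_histogram"))
  e <- histogram$bin_edges
  utils::write.csv(
    data.frame(bin_lo = e[-length(e)], bin_hi = e[-1],
               frequency = histogram$counts,
               condition = histogram$condition,
               replicate = histogram$replicate),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  d <- read_csv_checked(path, c("bin_lo", "bin_hi", "frequency"))
  h <- build_histogram(numeric(0), c(d$bin_lo, d$bin_hi[nrow(d)]),
                       condition = if ("condition" %in% names(d))
                         as.character(d$condition[1]) else NA_character_,
                       replicate = if ("replicate" %in% names(d))
                         d$replicate[1] else NA_integer_)
  h$counts <- as.numeric(d$frequency)
  h
}

#' Write / read a titration series as CSV
#'
#' Columns `s` (nM) and `F`; `E0` is stored in a `# E0:` comment line.
#'
#' @param series A `titration_series`.
#' @param path File path.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(is.data.frame(series))
  con <- file(path, "w")
  on.exit(close(con))
  e0 <- attr(series, "E0")
  if (!is.null(e0)) writeLines(sprintf("# E0: %.15g", e0), con)
  utils::write.csv(as.data.frame(series)[, c("s", "F")], con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  first <- readLines(path, n = 1)
  e0 <- NULL
  if (grepl("^# E0:", first)) {
    e0 <- as.numeric(sub("^# E0:", "", first))
  }
  d <- read_csv_checked(path, c("s", "F"), comment.char = "#")
  attr(d, "E0") <- e0
  class(d) <- c("titration_series", "data.frame")
  d
}

read_csv_checked <- function(path, required_cols, ...) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  d <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, ...),
    error = function(e) {
      stop(errorCondition(paste0("parse error in ", path, ": ",
                                 conditionMessage(e)),
                          class = c("lgfret_parse", "error")))
    })
  missing <- setdiff(required_cols, names(d))
  if (length(missing)) {
    stop(errorCondition(
      paste0("parse error in ", path, ": missing column(s) ",
             paste(missing, collapse = ", ")),
      class = c("lgfret_parse", "error")))
  }
  if (nrow(d) == 0) warning("empty CSV: ", path)
  d
}

#' Write a results bundle as JSON
#'
#' @param results Named list of results (numbers, vectors, data frames).
#' @param path Output path.
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_results_json
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
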
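#' Construct a pupil trace
#'
#' A pupil trace is a tibble with one row per sample and columns `time`
#' (seconds), `pupil` (mm diameter or device area units) and `valid`
#' (logical; `FALSE` marks a missing sample, e.g. during a blink).
#' Sampling rate, measurement unit and a run label travel as attributes,
#' so the object pipes through dplyr verbs like any tibble while the
#' package's own functions can recover its metadata.
#'
#' @param time Numeric vector of sample times in seconds, strictly
#'   increasing with a uniform step of `1/rate`.
#' @param pupil Numeric vector of pupil sizes, same length as `time`.
#'   `NA` entries are treated as missing samples.
#' @param rate Sampling rate in Hz.
#' @param unit Measurement unit: `"mm"` (diameter) or `"area_au"`
#'   (device area units).
#' @param valid Logical vector flagging usable samples. Defaults to
#'   `!is.na(pupil)`.
#' @param run_id Character label for the recording run.
#' @param validate Check that mm values lie in the physiological
#'   (0, 12) mm range (default TRUE). Disable when constructing
#'   derived traces such as band-passed (zero-mean) signals.
#'
#' @return A tibble of class `pupil_trace`.
#' @export
#' @examples
#' tr <- pupil_trace(seq(0, 1, by = 0.01), rnorm(101, 4, 0.1), rate = 100)
#' trace_rate(tr)
pupil_trace <- function(time, pupil, rate, unit = c("mm", "area_au"),
                        valid = NULL, run_id = "run", validate = TRUE) {
  unit <- match.arg(unit)
  time <- as.numeric(time)
  pupil <- as.numeric(pupil)
  if (length(time) != length(pupil)) {
    stop("`time` and `pupil` must have the same length", call. = FALSE)
  }
  if (is.null(valid)) valid <- !is.na(pupil)
  valid <- as.logical(valid) & !is.na(pupil)
  if (length(valid) != length(time)) {
    stop("`valid` must have the same length as `time`", call. = FALSE)
  }
  check_uniform_time(time, rate)
  if (unit == "mm" && validate) {
    finite <- pupil[valid & is.finite(pupil)]
    if (length(finite) && (any(finite <= 0) || any(finite >= 12))) {
      stop("mm-unit pupil values must lie in (0, 12) mm", call. = FALSE)
    }
  }
  out <- tibble::tibble(time = time, pupil = pupil, valid = valid)
  new_pupil_trace(out, rate = rate, unit = unit, run_id = run_id)
}

new_pupil_trace <- function(df, rate, unit, run_id,
                            edge_sec = attr(df, "edge_sec")) {
  class(df) <- unique(c("pupil_trace", class(tibble::as_tibble(df))))
  attr(df, "rate") <- rate
  attr(df, "unit") <- unit
  attr(df, "run_id") <- run_id
  attr(df, "edge_sec") <- edge_sec
  df
}

check_uniform_time <- function(time, rate, tol = 1e-6) {
  if (length(time) < 2) return(invisible(TRUE))
  dev <- abs(diff(time) - 1 / rate)
  if (max(dev) >= tol) {
    stop("timestamps are not uniform at the stated rate (max deviation ",
         format(max(dev)), " s)", call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname pupil_trace
#' @param x A `pupil_trace`.
#' @export
trace_rate <- function(x) attr(x, "rate")

#' @rdname pupil_trace
#' @export
trace_unit <- function(x) attr(x, "unit")

#' @rdname pupil_trace
#' @export
trace_run_id <- function(x) attr(x, "run_id")

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf("# pupil trace '%s': %d samples @ %g Hz [%s], %d invalid\n",
              trace_run_id(x), nrow(x), trace_rate(x), trace_unit(x),
              sum(!x$valid)))
  NextMethod()
}

#' Read a pupil trace from delimited text
#'
#' Reads a TSV or CSV file with columns `time_s`, `pupil` and an optional
#' `valid` (0/1) column. The delimiter (tab or comma) is auto-detected
#' from the header line. Blank or non-numeric pupil cells become invalid
#' samples; timestamps are validated against the stated sampling rate.
#'
#' @param path Path to the file.
#' @param rate Sampling rate in Hz the timestamps must conform to.
#' @param unit Measurement unit of the `pupil` column.
#' @param run_id Run label; defaults to the file name.
#' @param validate Check the physiological mm range (default TRUE);
#'   disable for derived traces such as band-passed signals.
#' @return A [pupil_trace()].
#' @export
read_pupil_trace <- function(path, rate, unit = c("mm", "area_au"),
                             run_id = NULL, validate = TRUE) {
  unit <- match.arg(unit)
  df <- read_delimited(path)
  need <- c("time_s", "pupil")
  if (!all(need %in% names(df))) {
    stop("trace file must have columns `time_s` and `pupil`", call. = FALSE)
  }
  time <- suppressWarnings(as.numeric(df$time_s))
  if (anyNA(time)) stop("non-numeric timestamps in trace file", call. = FALSE)
  pupil <- suppressWarnings(as.numeric(df$pupil))
  valid <- !is.na(pupil)
  if ("valid" %in% names(df)) {
    valid <- valid & (suppressWarnings(as.numeric(df$valid)) != 0)
    valid[is.na(valid)] <- FALSE
  }
  if (is.null(run_id)) run_id <- basename(path)
  pupil_trace(time, pupil, rate = rate, unit = unit, valid = valid,
              run_id = run_id, validate = validate)
}

read_delimited <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          blank.lines.skip = TRUE, na.strings = c("NA", ""))
  tibble::as_tibble(df)
}

#' Write a pupil trace to delimited text
#'
#' @param trace A [pupil_trace()].
#' @param path Output file path; extension `.csv` selects comma,
#'   anything else tab.
#' @return `path`, invisibly.
#' @export
write_pupil_trace <- function(trace, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(time_s = sprintf("%.9f", trace$time),
                   pupil = ifelse(is.na(trace$pupil), "",
                                  sprintf("%.9f", trace$pupil)),
                   valid = as.integer(trace$valid))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write an event (trial) table
#'
#' Event files are TSV/CSV with columns `onset_s`, `duration_s`,
#' `condition` and optional `rt_s`. Onsets must be strictly increasing.
#'
#' @param path File path.
#' @return A tibble with columns `onset`, `duration`, `condition` and
#'   (if present) `rt`.
#' @export
read_events <- function(path) {
  df <- read_delimited(path)
  need <- c("onset_s", "duration_s", "condition")
  if (!all(need %in% names(df))) {
    stop("event file must have columns `onset_s`, `duration_s`, `condition`",
         call. = FALSE)
  }
  out <- tibble::tibble(
    onset = as.numeric(df$onset_s),
    duration = as.numeric(df$duration_s),
    condition = as.character(df$condition)
  )
  if ("rt_s" %in% names(df)) out$rt <- as.numeric(df$rt_s)
  if (is.unsorted(out$onset, strictly = TRUE)) {
    stop("trial onsets must be strictly increasing", call. = FALSE)
  }
  out
}

#' @rdname read_events
#' @param events Tibble with columns `onset`, `duration`, `condition`.
#' @export
write_events <- function(events, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(onset_s = events$onset, duration_s = events$duration,
                   condition = events$condition)
  if ("rt" %in% names(events)) df$rt_s <- events$rt
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a blink table
#'
#' Blink tables are TSV/CSV with columns `onset_s` and `offset_s`, plus
#' any artifact-window columns (`pre_start_s`, `post_end_s`) present.
#'
#' @param path File path.
#' @return A tibble with columns `onset`, `offset` (seconds) and, when
#'   present in the file, `pre_start`, `post_end`.
#' @export
read_blinks <- function(path) {
  df <- read_delimited(path)
  if (!all(c("onset_s", "offset_s") %in% names(df))) {
    stop("blink file must have columns `onset_s` and `offset_s`",
         call. = FALSE)
  }
  out <- tibble::tibble(onset = as.numeric(df$onset_s),
                        offset = as.numeric(df$offset_s))
  if ("pre_start_s" %in% names(df)) out$pre_start <- as.numeric(df$pre_start_s)
  if ("post_end_s" %in% names(df)) out$post_end <- as.numeric(df$post_end_s)
  out
}

#' @rdname read_blinks
#' @param blinks Tibble with columns `onset`, `offset`.
#' @export
write_blinks <- function(blinks, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(onset_s = blinks$onset, offset_s = blinks$offset)
  if ("pre_start" %in% names(blinks)) df$pre_start_s <- blinks$pre_start
  if ("post_end" %in% names(blinks)) df$post_end_s <- blinks$post_end
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert device area units to millimetre diameter
#'
#' Eye trackers in area mode report pupil size in arbitrary area units.
#' Given the calibration factor `scale` (area units per square
#' millimetre), each sample is converted to physical area and then to
#' the diameter of the circle of that area,
#' \eqn{d = 2\sqrt{(A/\mathrm{scale})/\pi}}.
#'
#' `convention = "legacy_radius"` reproduces a convention found in some
#' existing toolboxes that omits the factor of 2 (so the returned value
#' is geometrically a radius); it is provided only for compatibility
#' with results produced under that convention.
#'
#' @param trace A [pupil_trace()] in `area_au` units.
#' @param scale Area units per mm^2; must be positive.
#' @param convention `"standard"` (geometric diameter, default) or
#'   `"legacy_radius"`.
#' @return A [pupil_trace()] in mm.
#' @export
#' @examples
#' tr <- pupil_trace(c(0, 0.01), c(pi, 4 * pi), rate = 100, unit = "area_au")
#' area_to_diameter(tr, scale = 1)$pupil  # 2, 4
area_to_diameter <- function(trace, scale,
                             convention = c("standard", "legacy_radius")) {
  convention <- match.arg(convention)
  stopifnot(inherits(trace, "pupil_trace"))
  if (trace_unit(trace) != "area_au") {
    stop("`trace` must be in area_au units", call. = FALSE)
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("`scale` must be a positive scalar", call. = FALSE)
  }
  a <- trace$pupil
  if (any(a[!is.na(a)] < 0)) stop("negative area values", call. = FALSE)
  d <- sqrt((a / scale) / pi)
  if (convention == "standard") d <- 2 * d
  out <- trace
  out$pupil <- d
  attr(out, "unit") <- "mm"
  out
}
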
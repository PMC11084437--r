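#' Uniformly sampled recording
#'
#' Container for a uniformly sampled single-channel recording: an
#' intracellular action-potential trace (mV), an extracellular
#' microelectrode-array electrogram (uV), an ECG lead (uV), or a
#' fluorescence Ca2+ ratio trace (ratio units). The time of sample `i`
#' (0-based) is `t0_s + i / rate_hz`.
#'
#' @param samples Numeric vector of finite samples, length >= 2.
#' @param rate_hz Sampling frequency in Hz (> 0).
#' @param modality One of `"ap"`, `"mea"`, `"ecg"`, `"ca"`.
#' @param t0_s Start time in seconds of the first sample.
#' @param units Unit string carried verbatim (e.g. `"mV"`, `"uV"`, `"ratio"`).
#' @param meta Named list of free-form metadata.
#'
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(samples, rate_hz, modality,
                          t0_s = 0, units = NULL, meta = list()) {
  modality <- match.arg(modality, c("ap", "mea", "ecg", "ca"))
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("a voltage_trace needs at least 2 samples")
  bad <- which(!is.finite(samples))
  if (length(bad))
    stop("non-finite sample at index ", bad[1L], " (1-based)")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0)
    stop("rate_hz must be a single positive number")
  if (is.null(units))
    units <- switch(modality, ap = "mV", mea = "uV", ecg = "uV", ca = "ratio")
  structure(
    list(samples = samples, rate_hz = as.numeric(rate_hz),
         t0_s = as.numeric(t0_s), modality = modality,
         units = units, meta = meta),
    class = "voltage_trace")
}

#' Sample times of a trace
#'
#' @param trace A [voltage_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "voltage_trace"))
  trace$t0_s + (seq_along(trace$samples) - 1L) / trace$rate_hz
}

#' Duration of a trace in seconds
#' @param trace A [voltage_trace()].
#' @return Length of the sampled interval in seconds.
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$rate_hz

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> modality=%s  n=%d  rate=%g Hz  duration=%.3f s  units=%s\n",
              x$modality, length(x$samples), x$rate_hz,
              trace_duration(x), x$units))
  invisible(x)
}

#' @export
plot.voltage_trace <- function(x, ...) {
  graphics::plot(trace_times(x), x$samples, type = "l",
                 xlab = "time (s)", ylab = x$units, ...)
  invisible(x)
}

#' Ordered beat times with derived inter-beat intervals
#'
#' Beat (or spike / R-wave) times must be strictly increasing; the IBI
#' sequence is the successive difference of the beat times.
#'
#' @param beat_times_s Strictly increasing numeric vector of beat times (s).
#' @param source_modality Modality the beats were detected from
#'   (`"ap"`, `"mea"`, `"ecg"`, `"ca"`).
#' @param duration_s Optional recording duration in seconds (used by
#'   occurrence-rate and fractional-duration computations); defaults to the
#'   beat-time span.
#'
#' @return An object of class `beat_series` with elements `beat_times_s`,
#'   `ibis_s`, `source_modality`, `duration_s`.
#' @export
beat_series <- function(beat_times_s, source_modality = "ap", duration_s = NULL) {
  source_modality <- match.arg(source_modality, c("ap", "mea", "ecg", "ca"))
  beat_times_s <- as.numeric(beat_times_s)
  if (length(beat_times_s) && any(!is.finite(beat_times_s)))
    stop("beat times must be finite")
  if (length(beat_times_s) > 1L && any(diff(beat_times_s) <= 0))
    stop("beat times must be strictly increasing")
  if (is.null(duration_s))
    duration_s <- if (length(beat_times_s) > 1L)
      diff(range(beat_times_s)) else 0
  structure(
    list(beat_times_s = beat_times_s,
         ibis_s = if (length(beat_times_s) > 1L) diff(beat_times_s) else numeric(),
         source_modality = source_modality,
         duration_s = as.numeric(duration_s)),
    class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats (%s), mean IBI %.3f s over %.1f s\n",
              length(x$beat_times_s), x$source_modality,
              if (length(x$ibis_s)) mean(x$ibis_s) else NA_real_,
              x$duration_s))
  invisible(x)
}

#' Per-recording cohort table
#'
#' One row per recording/cell, a `group` column with labels drawn from a
#' declared finite set, and named numeric feature columns (missing values
#' allowed).
#'
#' @param df A data.frame with a `group` column.
#' @param groups Character vector of allowed group labels; defaults to the
#'   labels present.
#' @return A `cohort_table` (a classed data.frame).
#' @export
cohort_table <- function(df, groups = NULL) {
  if (!is.data.frame(df) || !"group" %in% names(df))
    stop("cohort_table needs a data.frame with a 'group' column")
  if (is.null(groups)) groups <- unique(as.character(df$group))
  if (!all(df$group %in% groups))
    stop("group labels outside the declared set: ",
         paste(setdiff(unique(df$group), groups), collapse = ", "))
  feat <- setdiff(names(df), "group")
  num_ok <- vapply(df[feat], function(x) is.numeric(x) || is.logical(x), logical(1))
  if (length(feat) && !all(num_ok))
    stop("non-numeric feature columns: ", paste(feat[!num_ok], collapse = ", "))
  structure(as.data.frame(df), groups = groups,
            class = c("cohort_table", "data.frame"))
}

# ---- file I/O ---------------------------------------------------------------

#' Read a trace from a delimited text file
#'
#' The file carries its metadata in leading comment lines of the form
#' `# key=value`; `rate_hz` and `modality` are required, `units` and `t0_s`
#' optional. The data block has a header line and one or two columns
#' (`time_s,value` or just `value`).
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"tsv"` (inferred from the extension by default).
#'   `"hdf5"` is recognised but not supported and raises an error.
#' @return A [voltage_trace()].
#' @export
read_trace <- function(path, format = c("auto", "csv", "tsv", "hdf5")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  if (format == "hdf5")
    stop("HDF5 traces are not supported by this build; convert to csv/tsv")
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[trimws(substr(kv, 1, eq - 1))]] <- trimws(substr(kv, eq + 1, nchar(kv)))
  }
  if (is.null(meta$rate_hz))
    stop("metadata line '# rate_hz=' is required in ", path)
  if (is.null(meta$modality))
    stop("metadata line '# modality=' is required in ", path)
  sep <- if (format == "tsv") "\t" else ","
  dat <- utils::read.table(text = lines[!grepl("^#", lines)], sep = sep,
                           header = TRUE, colClasses = "numeric")
  vals <- dat[[ncol(dat)]]
  bad <- which(!is.finite(vals))
  if (length(bad))
    stop("non-finite sample at data row ", bad[1L], " in ", path)
  if (ncol(dat) >= 2L) {
    tm <- dat[[1L]]
    nm <- which(diff(tm) <= 0)
    if (length(nm))
      stop("non-monotone time column at data row ", nm[1L] + 1L, " in ", path)
  }
  voltage_trace(vals, rate_hz = as.numeric(meta$rate_hz),
                modality = meta$modality,
                t0_s = if (is.null(meta$t0_s)) 0 else as.numeric(meta$t0_s),
                units = meta$units,
                meta = meta[setdiff(names(meta),
                                    c("rate_hz", "modality", "t0_s", "units"))])
}

#' Write a trace to a delimited text file
#'
#' Writes the metadata comment header followed by a `time_s,value` block.
#' Samples are written with full precision so a read/write round trip is
#' bit-for-bit exact.
#'
#' @param trace A [voltage_trace()].
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path, format = c("csv", "tsv")) {
  stopifnot(inherits(trace, "voltage_trace"))
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate_hz=%s", format(trace$rate_hz, digits = 17)),
               sprintf("# units=%s", trace$units),
               sprintf("# modality=%s", trace$modality),
               sprintf("# t0_s=%s", format(trace$t0_s, digits = 17))), con)
  writeLines(paste("time_s", "value", sep = sep), con)
  writeLines(paste(sprintf("%.17g", trace_times(trace)),
                   sprintf("%.17g", trace$samples), sep = sep), con)
  invisible(path)
}

#' Write a cohort table with per-group mean +/- SD summary
#'
#' Writes the rows as delimited text with a header, then appends a
#' commented summary block with per-group mean, sample SD (n-1 denominator)
#' and n for every numeric feature.
#'
#' @param table A [cohort_table()].
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path, sep = "\t") {
  stopifnot(inherits(table, "cohort_table"))
  if (nrow(table) == 0L) stop("empty cohort table")
  groups <- attr(table, "groups")
  n_by_group <- table(factor(table$group, levels = groups))
  if (any(n_by_group == 0L))
    stop("empty group(s): ",
         paste(names(n_by_group)[n_by_group == 0L], collapse = ", "))
  utils::write.table(table, path, sep = sep, row.names = FALSE, quote = FALSE)
  feat <- setdiff(names(table), "group")
  con <- file(path, "a")
  on.exit(close(con))
  writeLines("# summary: group feature mean sd n", con)
  for (g in groups) {
    for (f in feat) {
      x <- table[[f]][table$group == g]
      x <- x[is.finite(x)]
      writeLines(sprintf("# %s %s %.6g %.6g %d", g, f,
                         mean(x), stats::sd(x), length(x)), con)
    }
  }
  invisible(path)
}

#' Read back the data block written by [write_results()]
#'
#' @param path Path written by [write_results()].
#' @param sep Field separator used when writing.
#' @return A [cohort_table()].
#' @export
read_results <- function(path, sep = "\t") {
  lines <- readLines(path)
  dat <- utils::read.table(text = lines[!grepl("^#", lines)], sep = sep,
                           header = TRUE, stringsAsFactors = FALSE)
  cohort_table(dat)
}
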
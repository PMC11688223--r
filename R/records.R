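# Spike-train records and interspike-interval extraction.
#
# Spike times are stored in seconds (the acquisition unit: 20-second epochs
# at 300 microsecond resolution); interval sequences and everything
# downstream are in milliseconds.

#' Construct and validate a spike-train record
#'
#' @param spike_times numeric vector of spike times in seconds, strictly
#'   increasing, all within `[0, duration]`.
#' @param record_id identifier string.
#' @param duration record length in seconds.
#' @param resolution acquisition quantum in seconds; two spikes may not fall
#'   in the same quantum.
#' @return an object of class `"spike_train_record"`.
#' @export
spike_train_record <- function(spike_times, record_id = "record",
                               duration = 20, resolution = 3e-4) {
  stopifnot(is.numeric(spike_times), duration > 0, resolution > 0)
  if (anyNA(spike_times)) stop("spike times contain NA")
  if (length(spike_times)) {
    d <- diff(spike_times)
    bad <- which(d <= 0)
    if (length(bad)) {
      stop(sprintf("spike times not strictly increasing at index %d (%.6f -> %.6f s)",
                   bad[1] + 1L, spike_times[bad[1]], spike_times[bad[1] + 1L]))
    }
    if (spike_times[1] < 0 || spike_times[length(spike_times)] > duration + resolution / 2) {
      stop("spike times fall outside [0, duration]")
    }
    near <- which(d < resolution - 1e-12)
    if (length(near)) {
      stop(sprintf("spikes %d and %d are closer than the %.0f microsecond quantum",
                   near[1], near[1] + 1L, resolution * 1e6))
    }
  }
  structure(list(record_id = as.character(record_id),
                 spike_times = as.numeric(spike_times),
                 duration = duration, resolution = resolution),
            class = "spike_train_record")
}

#' @export
print.spike_train_record <- function(x, ...) {
  cat(sprintf("<spike_train_record> %s: %d spikes over %g s (quantum %g us)\n",
              x$record_id, length(x$spike_times), x$duration,
              x$resolution * 1e6))
  invisible(x)
}

#' Read a spike-train record from disk
#'
#' Accepts either plain text (one spike time in seconds per line) or a
#' headered CSV with columns `record_id,time_s`.  Malformed lines are
#' reported with their line number; unsorted or quantum-colliding times are
#' rejected by the record validator.
#'
#' @param path file to read.
#' @param record_id identifier; defaults to the file name (or the CSV's
#'   `record_id` column).
#' @inheritParams spike_train_record
#' @return a `"spike_train_record"`.
#' @seealso [write_record()]
#' @export
load_record <- function(path, record_id = NULL, duration = 20,
                        resolution = 3e-4) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty record file: ", path)
  if (grepl("record_id", lines[1], fixed = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("record_id", "time_s") %in% names(df))) {
      stop("CSV record needs 'record_id' and 'time_s' columns: ", path)
    }
    if (is.null(record_id)) record_id <- df$record_id[1]
    times <- as.numeric(df$time_s)
    if (anyNA(times)) stop("non-numeric time_s value in ", path)
  } else {
    times <- suppressWarnings(as.numeric(lines))
    if (anyNA(times)) {
      stop(sprintf("malformed spike time at line %d of %s: '%s'",
                   which(is.na(times))[1], path, lines[which(is.na(times))[1]]))
    }
    if (is.null(record_id)) {
      record_id <- sub("\\.[^.]*$", "", basename(path))
    }
  }
  spike_train_record(times, record_id = record_id, duration = duration,
                     resolution = resolution)
}

#' Write a spike-train record as plain text
#'
#' One spike time in seconds per line, printed with enough digits that
#' [load_record()] round-trips the times exactly.
#'
#' @param record a `"spike_train_record"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "spike_train_record"))
  writeLines(sprintf("%.17g", record$spike_times), path)
  invisible(path)
}

#' Load a directory of spike-train records via its manifest
#'
#' Reads `manifest.csv` (columns `record_id, path`; paths relative to the
#' manifest's directory or absolute) and loads every listed record.
#'
#' @param dir directory containing `manifest.csv`, or a path to a manifest
#'   file.
#' @inheritParams spike_train_record
#' @return named list of `"spike_train_record"` objects.
#' @seealso [write_population()]
#' @export
load_population_dir <- function(dir, duration = 20, resolution = 3e-4) {
  manifest <- if (grepl("\\.csv$", dir)) dir else file.path(dir, "manifest.csv")
  if (!file.exists(manifest)) stop("no manifest found at ", manifest)
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("record_id", "path") %in% names(man))) {
    stop("manifest needs 'record_id' and 'path' columns")
  }
  root <- dirname(manifest)
  recs <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(root, p)
    load_record(p, record_id = man$record_id[i], duration = duration,
                resolution = resolution)
  })
  names(recs) <- man$record_id
  recs
}

#' Extract the interspike-interval sequence of a record
#'
#' @param record a `"spike_train_record"` with at least two spikes.
#' @return an object of class `"isi_sequence"`: `record_id`, `intervals`
#'   (ms, in order), `n`.
#' @export
intervals_from_spikes <- function(record) {
  stopifnot(inherits(record, "spike_train_record"))
  if (length(record$spike_times) < 2) {
    stop(sprintf("record '%s' has fewer than 2 spikes", record$record_id))
  }
  structure(list(record_id = record$record_id,
                 intervals = diff(record$spike_times) * 1000,
                 n = length(record$spike_times) - 1L),
            class = "isi_sequence")
}

#' @export
print.isi_sequence <- function(x, ...) {
  cat(sprintf("<isi_sequence> %s: %d intervals, mean %.3f ms\n",
              x$record_id, x$n, mean(x$intervals)))
  invisible(x)
}

.sample_intervals <- function(x) {
  if (inherits(x, "isi_sequence")) x$intervals
  else if (inherits(x, "empirical_distribution")) x$intervals
  else if (inherits(x, "spike_train_record")) intervals_from_spikes(x)$intervals
  else if (is.numeric(x)) as.numeric(x)
  else stop("expected intervals, an isi_sequence, or an empirical_distribution")
}

#' Summary statistics of an interval sequence
#'
#' Mean, sample standard deviation, coefficient of variation CV = sd/mean,
#' and the moment coefficient of skewness
#' \eqn{m_3 / m_2^{3/2}} (bias-uncorrected central-moment ratio).  CV is near
#' 0 for clock-like firing and near 1 for Poisson-like firing.
#'
#' @param x intervals (ms), an `"isi_sequence"`, or an
#'   `"empirical_distribution"`; at least 2 values.
#' @return named list with `mean`, `sd`, `cv`, `skewness`, `n`.  For a
#'   zero-variance sequence `cv` is 0 and `skewness` is `NA`.
#' @export
summary_stats <- function(x) {
  v <- .sample_intervals(x)
  n <- length(v)
  if (n < 2) stop("need at least 2 intervals for summary statistics")
  m <- mean(v)
  s <- stats::sd(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) {
    return(list(mean = m, sd = 0, cv = 0, skewness = NA_real_, n = n))
  }
  list(mean = m, sd = s, cv = s / m,
       skewness = mean((v - m)^3) / m2^1.5, n = n)
}
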
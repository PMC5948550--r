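#' Construct an accelerometer recording
#'
#' Bundles a matrix of raw triaxial ADC frames with its sample rate and trial
#' metadata. The y axis is the vertical axis of the waist-worn device and reads
#' approximately -1 G (-256 bits with the default 13-bit, +/-16 G configuration)
#' when the wearer stands upright.
#'
#' @param frames integer matrix with one row per frame and columns ax, ay, az
#'   (raw ADC bits).
#' @param sample_rate sampling rate in Hz (25 or 200 for SisFall-style data).
#' @param subject_code subject identifier, e.g. `"SA03"`; may be empty.
#' @param activity_code activity identifier, e.g. `"D03"` or `"F05"`. Codes
#'   starting with `"F"` are falls.
#' @param trial trial number within subject/activity, or `NA`.
#' @param adc_bits ADC resolution used to validate the frame range.
#'
#' @return An object of class `accel_recording`: a list with elements `frames`,
#'   `sample_rate`, `subject_code`, `activity_code`, `trial` and `is_fall`.
#' @export
new_recording <- function(frames, sample_rate, subject_code = "",
                          activity_code = "", trial = NA_integer_,
                          adc_bits = 13L) {
  frames <- as.matrix(frames)
  if (ncol(frames) != 3L) stop("frames must have 3 columns (ax, ay, az)")
  if (nrow(frames) == 0L) stop("recording has no frames")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a single positive number")
  }
  lim <- 2^(adc_bits - 1L)
  if (any(frames < -lim | frames > lim - 1L)) {
    stop(sprintf("frame components outside the %d-bit ADC range [%d, %d]",
                 adc_bits, -lim, lim - 1L))
  }
  colnames(frames) <- c("ax", "ay", "az")
  structure(
    list(frames = frames, sample_rate = sample_rate,
         subject_code = subject_code, activity_code = activity_code,
         trial = trial, is_fall = startsWith(activity_code, "F")),
    class = "accel_recording"
  )
}

#' @export
print.accel_recording <- function(x, ...) {
  dur <- nrow(x$frames) / x$sample_rate
  cat(sprintf("<accel_recording> %d frames @ %g Hz (%.1f s)\n",
              nrow(x$frames), x$sample_rate, dur))
  if (nzchar(x$activity_code)) {
    cat(sprintf("  activity %s (%s)  subject %s  trial %s\n",
                x$activity_code, if (x$is_fall) "fall" else "ADL",
                if (nzchar(x$subject_code)) x$subject_code else "?",
                if (is.na(x$trial)) "?" else x$trial))
  }
  invisible(x)
}

#' Parse trial metadata from a SisFall-style file name
#'
#' File names of the form `"F05_SA03_R01.txt"` encode activity, subject and
#' trial. Names that do not match leave the fields empty.
#'
#' @param name file name (path components and extension are ignored).
#' @return list with `activity_code`, `subject_code`, `trial`.
#' @export
parse_recording_name <- function(name) {
  base <- sub("\\.[A-Za-z0-9]+$", "", basename(name))
  m <- regmatches(base,
                  regexec("^([A-Za-z][0-9]+)_([A-Za-z]+[0-9]+)_R([0-9]+)", base))[[1]]
  if (length(m) == 4L) {
    list(activity_code = m[2], subject_code = m[3], trial = as.integer(m[4]))
  } else {
    list(activity_code = "", subject_code = "", trial = NA_integer_)
  }
}

#' Read a SisFall-dialect accelerometer recording
#'
#' One frame per line, integer tokens separated by commas or semicolons
#' (trailing separators and surrounding whitespace are tolerated). SisFall
#' files carry nine sensor columns; the first accelerometer occupies the first
#' three, which is the default `column_map`.
#'
#' @param path path to the text file.
#' @param column_map 1-based column indices of ax, ay, az within a line.
#' @param sample_rate sampling rate of the file in Hz.
#' @return An [new_recording()] object, with metadata parsed from the file name
#'   when it follows the `"<activity>_<subject>_R<trial>"` convention.
#' @export
read_recording <- function(path, column_map = c(1L, 2L, 3L), sample_rate = 200) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty recording: ", path)
  toks <- strsplit(lines, "[,;]")
  need <- max(column_map)
  frames <- matrix(NA_integer_, nrow = length(lines), ncol = 3L)
  for (i in seq_along(toks)) {
    tok <- trimws(toks[[i]])
    tok <- tok[nzchar(tok)]
    if (length(tok) < need) {
      stop(sprintf("%s: line %d has %d fields, expected at least %d",
                   basename(path), line_no[i], length(tok), need))
    }
    sel <- tok[column_map]
    ok <- grepl("^[+-]?[0-9]+$", sel)
    if (!all(ok)) {
      stop(sprintf("%s: line %d: malformed integer token '%s'",
                   basename(path), line_no[i], sel[!ok][1]))
    }
    frames[i, ] <- as.integer(sel)
  }
  meta <- parse_recording_name(path)
  new_recording(frames, sample_rate,
                subject_code = meta$subject_code,
                activity_code = meta$activity_code,
                trial = meta$trial)
}

#' Write a recording in the SisFall text dialect
#'
#' @param recording an [new_recording()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  f <- recording$frames
  writeLines(paste(f[, 1], f[, 2], f[, 3], sep = ","), path)
  invisible(path)
}

#' Convert raw ADC bits to gravities
#'
#' Linear two's-complement scaling: `bits * (2 * range_g) / 2^adc_bits`. With
#' the device configuration used throughout (13 bits over +/-16 G) one gravity
#' is exactly 256 bits. All pipeline arithmetic stays in bits; this conversion
#' exists for reporting and plotting only.
#'
#' @param bits raw ADC value(s).
#' @param adc_bits ADC resolution (>= 2).
#' @param range_g full-scale range in G (> 0).
#' @return acceleration in G.
#' @export
bits_to_g <- function(bits, adc_bits = 13L, range_g = 16) {
  stopifnot(adc_bits >= 2, range_g > 0)
  bits * (2 * range_g) / 2^adc_bits
}

#' @rdname bits_to_g
#' @param g acceleration in G.
#' @export
g_to_bits <- function(g, adc_bits = 13L, range_g = 16) {
  stopifnot(adc_bits >= 2, range_g > 0)
  g * 2^adc_bits / (2 * range_g)
}

#' Write a per-sample pipeline trace as CSV
#'
#' One row per 25 Hz sample: index, raw bits, the four Kalman states, J1, J2,
#' J3 and the event flag. Numbers are printed with 17 significant digits so
#' that reading the file back reproduces the doubles bit-exactly.
#'
#' @param trace data frame as produced by [run_file()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  cols <- c("index", "ax", "ay", "az", "x1", "x2", "x3", "x4",
            "j1", "j2", "j3", "event")
  missing_cols <- setdiff(cols, names(trace))
  if (length(missing_cols)) {
    stop("trace is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  fmt <- vapply(cols, function(cn) {
    v <- trace[[cn]]
    if (is.integer(v) || cn %in% c("index", "ax", "ay", "az", "event")) {
      format(v, scientific = FALSE, trim = TRUE)
    } else {
      sprintf("%.17g", v)
    }
  }, character(nrow(trace)))
  if (nrow(trace) == 1L) fmt <- matrix(fmt, nrow = 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  writeLines(apply(fmt, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Read back a trace written by [write_trace()]
#'
#' @param path CSV path.
#' @return data frame with the trace columns.
#' @export
read_trace <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write detection events as JSON
#'
#' @param events data frame of events from [run_file()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  jsonlite::write_json(events, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
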
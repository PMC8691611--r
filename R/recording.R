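#' Raw triaxial acceleration recording
#'
#' Container for a uniformly sampled triaxial accelerometer recording in
#' units of g. This is the entry point of the pipeline: all preprocessed
#' dataset types are derived from it with [build_datasets()].
#'
#' @param x,y,z Numeric vectors of per-axis acceleration in g, equal length.
#' @param fs Sampling frequency in Hz (default 10, the usual actigraphy
#'   configuration for multi-day wrist recordings).
#' @param range_g Sensor full scale in g; samples must lie in
#'   `[-range_g, range_g]` (default 8).
#' @param subject_id Opaque subject label.
#' @param start_time Optional POSIXct acquisition start.
#'
#' @return An object of class `raw_recording` with fields `x`, `y`, `z`,
#'   `fs`, `sampling_interval`, `range_g`, `subject_id`, `start_time`.
#' @export
#' @examples
#' rec <- raw_recording(c(0, 0), c(0, 0), c(1, 1), fs = 10)
#' rec$sampling_interval
raw_recording <- function(x, y, z, fs = 10, range_g = 8,
                          subject_id = NA_character_, start_time = NULL) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(x)
  if (length(y) != n || length(z) != n)
    shape_error("axes must have equal length")
  if (n < 1) size_error("recording must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    parameter_error("fs must be a positive scalar")
  if (anyNA(x) || anyNA(y) || anyNA(z))
    format_error("recording contains missing samples")
  amax <- max(abs(x), abs(y), abs(z))
  if (amax > range_g)
    range_error(sprintf("sample magnitude %.3f g exceeds sensor range %.1f g",
                        amax, range_g))
  structure(
    list(x = x, y = y, z = z, fs = fs, sampling_interval = 1 / fs,
         range_g = range_g, subject_id = subject_id, start_time = start_time),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d samples @ %g Hz (%.1f min), range +/-%g g, subject %s\n",
              length(x$x), x$fs, length(x$x) / x$fs / 60, x$range_g,
              x$subject_id))
  invisible(x)
}

#' @export
length.raw_recording <- function(x) length(x$x)

#' Read a raw recording from CSV or the packaged binary container
#'
#' CSV files carry either three numeric columns (x, y, z in g) or four
#' (time in seconds first); a header row is detected automatically. The
#' time column, when present, is used only to validate uniform sampling
#' (tolerance 1% of the sampling interval). The binary container is the
#' package's own format: an ASCII magic `"ACTB"`, a uint8 version, float64
#' sampling frequency, float64 range, uint32 sample count, then interleaved
#' x, y, z little-endian float32 samples in g.
#'
#' @param path File to read.
#' @param format `"csv"` or `"binary"`.
#' @param fs Sampling frequency in Hz, required for CSV input (ignored for
#'   binary, which stores it).
#' @param range_g Sensor range override.
#' @param subject_id Subject label; defaults to the file stem.
#' @param scale Multiplicative conversion applied to CSV samples (use it to
#'   convert ADC counts to g); default 1.
#' @return A [raw_recording()].
#' @export
read_recording <- function(path, format = c("csv", "binary"), fs = 10,
                           range_g = 8, subject_id = NULL, scale = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "csv") {
    first <- readLines(path, n = 1L)
    has_header <- is.na(suppressWarnings(
      as.numeric(strsplit(first, ",")[[1]][1])))
    dat <- utils::read.csv(path, header = has_header)
    if (!ncol(dat) %in% c(3L, 4L))
      format_error(sprintf("expected 3 or 4 columns, found %d", ncol(dat)))
    if (!all(vapply(dat, is.numeric, logical(1))))
      format_error("non-numeric values in acceleration columns")
    if (ncol(dat) == 4L) {
      tcol <- dat[[1]]
      dt <- diff(tcol)
      if (length(dt) > 0 && any(abs(dt - 1 / fs) > 0.01 / fs))
        sampling_error("timestamps deviate from uniform sampling by more than 1% of the sampling interval")
      dat <- dat[-1]
    }
    raw_recording(dat[[1]] * scale, dat[[2]] * scale, dat[[3]] * scale,
                  fs = fs, range_g = range_g, subject_id = subject_id)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- rawToChar(readBin(con, "raw", 4L))
    if (!identical(magic, "ACTB")) format_error("bad magic in binary container")
    version <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
    if (version != 1L) format_error(sprintf("unsupported container version %d", version))
    fs_file <- readBin(con, "double", 1L, endian = "little")
    range_file <- readBin(con, "double", 1L, endian = "little")
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(n) != 1L || is.na(n) || n < 1L)
      format_error("corrupt sample count in binary header")
    xyz <- readBin(con, "double", 3L * n, size = 4L, endian = "little")
    if (length(xyz) != 3L * n) format_error("truncated binary payload")
    m <- matrix(xyz, ncol = 3L, byrow = TRUE)
    raw_recording(m[, 1], m[, 2], m[, 3], fs = fs_file, range_g = range_file,
                  subject_id = subject_id)
  }
}

#' Write a raw recording to CSV or the binary container
#'
#' @param rec A [raw_recording()].
#' @param path Output file.
#' @param format `"csv"` (t, x, y, z columns with header) or `"binary"`
#'   (see [read_recording()] for the layout).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv", "binary")) {
  stopifnot(inherits(rec, "raw_recording"))
  format <- match.arg(format)
  if (format == "csv") {
    n <- length(rec$x)
    dat <- data.frame(t = (seq_len(n) - 1) / rec$fs,
                      x = rec$x, y = rec$y, z = rec$z)
    ok <- tryCatch({utils::write.csv(dat, path, row.names = FALSE); TRUE},
                   error = function(e) FALSE)
    if (!ok) io_error(sprintf("cannot write %s", path))
  } else {
    con <- tryCatch(file(path, "wb"), error = function(e) NULL)
    if (is.null(con)) io_error(sprintf("cannot write %s", path))
    on.exit(close(con))
    writeBin(charToRaw("ACTB"), con)
    writeBin(as.raw(1L), con)
    writeBin(as.double(rec$fs), con, endian = "little")
    writeBin(as.double(rec$range_g), con, endian = "little")
    writeBin(length(rec$x), con, size = 4L, endian = "little")
    interleaved <- as.vector(rbind(rec$x, rec$y, rec$z))
    writeBin(interleaved, con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Write an activity series to CSV with metadata header
#'
#' The file begins with `#`-prefixed key-value rows recording the metric,
#' source dataset kind, epoch length, threshold (value and mode, when the
#' metric uses one) and axial combination, followed by `epoch,value` rows.
#' [read_activity()] restores the series and its metadata.
#'
#' @param series An [activity_series] as produced by [compute_activity()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_activity <- function(series, path) {
  stopifnot(inherits(series, "activity_series"))
  if (length(series$values) == 0) size_error("activity series is empty")
  hdr <- c(
    sprintf("# metric: %s", series$metric),
    sprintf("# dataset: %s", series$dataset_kind),
    sprintf("# epoch_s: %.10g", series$epoch_s),
    sprintf("# combination: %s",
            if (is.null(series$combination)) "none" else series$combination))
  if (!is.null(series$threshold)) {
    hdr <- c(hdr,
             sprintf("# threshold_g: %.17g", series$threshold$value),
             sprintf("# threshold_mode: %s", series$threshold$mode))
  }
  ok <- tryCatch({
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines("epoch,value", con)
    writeLines(sprintf("%d,%.17g", seq_along(series$values), series$values), con)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) io_error(sprintf("cannot write %s", path))
  invisible(path)
}

#' Read an activity series written by [write_activity()]
#'
#' @param path File to read.
#' @return An [activity_series].
#' @export
read_activity <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^# ", "", ml)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  body <- lines[!grepl("^# ", lines)]
  dat <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("epoch", "value") %in% names(dat)))
    format_error("activity CSV must carry epoch,value columns")
  thr <- NULL
  if (!is.null(meta$threshold_g)) {
    thr <- threshold_spec(as.numeric(meta$threshold_g),
                          mode = meta$threshold_mode,
                          source_kind = meta$dataset)
  }
  activity_series(dat$value, metric = meta$metric, dataset_kind = meta$dataset,
                  epoch_s = as.numeric(meta$epoch_s), threshold = thr,
                  combination = if (identical(meta$combination, "none")) NULL
                                else meta$combination)
}
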
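#' Preprocessed dataset series
#'
#' One 1-D series derived from a raw recording, tagged with its kind in the
#' dataset taxonomy:
#'
#' * `UFX`, `UFY`, `UFZ` - unfiltered axial accelerations (together: UFXYZ);
#' * `UFM` - unfiltered vector magnitude, carries the 1 g gravity offset;
#' * `UFNM` - normalized magnitude `|UFM - 1 g|`, gravity removed without
#'   filtering;
#' * `FX`, `FY`, `FZ` - band-pass-filtered axial accelerations (FXYZ);
#' * `FMpre` - magnitude of the filtered axial signals;
#' * `FMpost` - band-pass filter applied to the magnitude UFM;
#' * `HFEN_M` - magnitude of high-pass-filtered (0.2 Hz, order 4) axial
#'   signals, the special conditioning the HFEN metric requires.
#'
#' @param values Numeric series in g.
#' @param kind Taxonomy tag (one of the kinds above).
#' @param fs Sampling frequency in Hz.
#' @param lineage Human-readable description of the preprocessing applied.
#' @return A `dataset_series` object.
#' @export
dataset_series <- function(values, kind, fs, lineage = "") {
  kinds <- c("UFX", "UFY", "UFZ", "UFM", "UFNM",
             "FX", "FY", "FZ", "FMpre", "FMpost", "HFEN_M")
  if (!kind %in% kinds)
    parameter_error(sprintf("unknown dataset kind '%s'", kind))
  if (kind %in% c("UFM", "UFNM", "FMpre", "HFEN_M") && any(values < 0))
    range_error(sprintf("%s is a magnitude series and must be nonnegative", kind))
  structure(list(values = as.numeric(values), kind = kind, fs = fs,
                 lineage = lineage),
            class = "dataset_series")
}

#' @export
print.dataset_series <- function(x, ...) {
  cat(sprintf("<dataset_series %s> %d samples @ %g Hz; %s\n",
              x$kind, length(x$values), x$fs, x$lineage))
  invisible(x)
}

#' Elementwise Euclidean norm of three axial series
#'
#' @param x,y,z Equal-length numeric vectors.
#' @return `sqrt(x^2 + y^2 + z^2)`, elementwise.
#' @export
magnitude <- function(x, y, z) {
  if (length(y) != length(x) || length(z) != length(x))
    shape_error("axes must have equal length")
  sqrt(x^2 + y^2 + z^2)
}

#' Gravity-normalized magnitude
#'
#' Removes the static 1 g gravity component from an unfiltered magnitude
#' series without filtering: `UFNM = |UFM - 1 g|`. For a stationary device
#' the magnitude of the acceleration vector is 1 g regardless of
#' orientation, so the result is zero at rest and keeps sub-0.25 Hz
#' movement components that a band-pass filter would discard.
#'
#' @param ufm Unfiltered magnitude series in g (nonnegative).
#' @return Normalized magnitude series, nonnegative.
#' @export
normalize_ufnm <- function(ufm) {
  if (any(ufm < 0)) range_error("UFM values must be nonnegative")
  abs(ufm - 1)
}

#' Build all preprocessed dataset types from a raw recording
#'
#' Produces the full taxonomy: the three unfiltered axial series, UFM,
#' UFNM, the three band-pass-filtered axial series, FMpre (magnitude of
#' filtered axes), FMpost (filter applied to UFM) and HFEN_M (magnitude of
#' high-pass-filtered axes). FMpre and FMpost differ in general because the
#' nonlinear magnitude does not commute with linear filtering.
#'
#' @param rec A [raw_recording()].
#' @param spec Band-pass [filter_spec()] for the F* series.
#' @param hfen_spec High-pass filter spec for the HFEN conditioning
#'   (default 0.2 Hz cut-off, order 4).
#' @return Named list of [dataset_series] objects
#'   (`UFX`...`FMpost`, `HFEN_M`).
#' @export
#' @examples
#' rec <- raw_recording(rnorm(200, 0, 0.01), rnorm(200, 0, 0.01),
#'                      1 + rnorm(200, 0, 0.01))
#' ds <- build_datasets(rec)
#' names(ds)
build_datasets <- function(rec, spec = filter_spec(),
                           hfen_spec = filter_spec("highpass",
                                                   low_cut_hz = 0.2,
                                                   order = 4,
                                                   mode = spec$mode)) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$fs
  fdesc <- sprintf("butterworth %s %g-%g Hz order %d (%s)", spec$kind,
                   spec$low_cut_hz, spec$high_cut_hz, spec$order, spec$mode)
  fx <- butterworth_filter(rec$x, spec, fs)
  fy <- butterworth_filter(rec$y, spec, fs)
  fz <- butterworth_filter(rec$z, spec, fs)
  ufm <- magnitude(rec$x, rec$y, rec$z)
  hx <- butterworth_filter(rec$x, hfen_spec, fs)
  hy <- butterworth_filter(rec$y, hfen_spec, fs)
  hz <- butterworth_filter(rec$z, hfen_spec, fs)
  list(
    UFX = dataset_series(rec$x, "UFX", fs, "raw x axis"),
    UFY = dataset_series(rec$y, "UFY", fs, "raw y axis"),
    UFZ = dataset_series(rec$z, "UFZ", fs, "raw z axis"),
    UFM = dataset_series(ufm, "UFM", fs, "magnitude of raw axes"),
    UFNM = dataset_series(normalize_ufnm(ufm), "UFNM", fs,
                          "|magnitude of raw axes - 1 g|"),
    FX = dataset_series(fx, "FX", fs, paste("x axis;", fdesc)),
    FY = dataset_series(fy, "FY", fs, paste("y axis;", fdesc)),
    FZ = dataset_series(fz, "FZ", fs, paste("z axis;", fdesc)),
    FMpre = dataset_series(magnitude(fx, fy, fz), "FMpre", fs,
                           paste("magnitude of filtered axes;", fdesc)),
    FMpost = dataset_series(butterworth_filter(ufm, spec, fs), "FMpost", fs,
                            paste("filtered magnitude;", fdesc)),
    HFEN_M = dataset_series(magnitude(hx, hy, hz), "HFEN_M", fs,
                            sprintf("magnitude of highpass %g Hz order %d filtered axes",
                                    hfen_spec$low_cut_hz, hfen_spec$order)))
}
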
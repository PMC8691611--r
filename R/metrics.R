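#' Epoch parameters
#'
#' Activity metrics reduce each non-overlapping epoch of `epoch_length_s`
#' seconds to one activity value; 60 s is the common choice in actigraphy
#' and the default here.
#'
#' @param epoch_length_s Epoch length T_e in seconds (default 60).
#' @param fs Sampling frequency in Hz.
#' @return An `epoch_params` object with `epoch_length_s` and
#'   `samples_per_epoch` (n = T_e * fs).
#' @export
epoch_params <- function(epoch_length_s = 60, fs = 10) {
  n <- epoch_length_s * fs
  if (abs(n - round(n)) > 1e-9)
    parameter_error("epoch length must be an integer multiple of the sampling interval")
  n <- as.integer(round(n))
  if (n < 2) parameter_error("an epoch must contain at least 2 samples")
  structure(list(epoch_length_s = epoch_length_s, samples_per_epoch = n,
                 fs = fs),
            class = "epoch_params")
}

#' Epoch-sampled activity series
#'
#' One activity value per epoch, tagged with the metric, the source dataset
#' kind and the parameters used, so that downstream comparison code can
#' check alignment and provenance.
#'
#' @param values Numeric vector, one value per epoch.
#' @param metric Metric identifier (`"PIMr"`, `"PIMs"`, `"ZCM"`, `"TAT"`,
#'   `"MAD"`, `"ENMO"`, `"HFEN"`, `"AI"`).
#' @param dataset_kind Source dataset taxonomy tag.
#' @param epoch_s Epoch length in seconds.
#' @param threshold Optional [threshold_spec()] (ZCM/TAT).
#' @param combination Optional axial combination tag (`"sum"`, `"sum_sq"`,
#'   `"vm3"`).
#' @return An `activity_series` object.
#' @export
activity_series <- function(values, metric, dataset_kind, epoch_s = 60,
                            threshold = NULL, combination = NULL) {
  structure(list(values = as.numeric(values), metric = metric,
                 dataset_kind = dataset_kind, epoch_s = epoch_s,
                 threshold = threshold, combination = combination),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  thr <- if (is.null(x$threshold)) ""
         else sprintf(", threshold %.4g g (%s)", x$threshold$value, x$threshold$mode)
  comb <- if (is.null(x$combination)) "" else sprintf(", combination %s", x$combination)
  cat(sprintf("<activity_series %s(%s)> %d epochs of %g s%s%s\n",
              x$metric, x$dataset_kind, length(x$values), x$epoch_s, thr, comb))
  invisible(x)
}

#' @export
length.activity_series <- function(x) length(x$values)

#' Split a series into non-overlapping epochs
#'
#' Windows of `samples_per_epoch` consecutive samples starting at sample 1;
#' a trailing remainder shorter than one epoch is dropped.
#'
#' @param values Numeric series (or a [dataset_series]).
#' @param ep An [epoch_params()].
#' @return A matrix with one column per epoch.
#' @export
epochs <- function(values, ep) {
  if (inherits(values, "dataset_series")) values <- values$values
  n <- ep$samples_per_epoch
  if (length(values) < n)
    size_error(sprintf("series of %d samples is shorter than one epoch (%d samples)",
                       length(values), n))
  k <- length(values) %/% n
  matrix(values[seq_len(k * n)], nrow = n)
}

#' Proportional Integration Method for one epoch
#'
#' Numerical integral of the epoch: the Riemann sum `T_s * sum(x)` or the
#' composite Simpson 3/8 rule. With Simpson 3/8, intervals left over when
#' the epoch's interval count is not divisible by 3 are closed with the
#' trapezoid rule.
#'
#' @param x Epoch samples.
#' @param t_s Sampling interval in seconds.
#' @param rule `"riemann"` or `"simpson38"`.
#' @return The activity value (integral, g*s).
#' @export
pim <- function(x, t_s, rule = c("riemann", "simpson38")) {
  rule <- match.arg(rule)
  if (rule == "riemann") return(t_s * sum(x))
  m <- length(x) - 1L            # number of intervals
  n3 <- (m %/% 3L) * 3L          # intervals covered by full 3/8 blocks
  total <- 0
  if (n3 > 0) {
    idx <- seq(1L, n3 - 2L, by = 3L)
    total <- sum(3 * t_s / 8 *
                 (x[idx] + 3 * x[idx + 1L] + 3 * x[idx + 2L] + x[idx + 3L]))
  }
  if (m > n3) {
    tail_idx <- seq(n3 + 1L, m)
    total <- total + sum(t_s / 2 * (x[tail_idx] + x[tail_idx + 1L]))
  }
  total
}

#' Zero Crossing Method for one epoch
#'
#' Counts sign changes of `x - threshold` between consecutive samples.
#' Samples exactly on the threshold inherit the side of the previous
#' strictly-off-threshold sample (leading on-threshold samples are
#' ignored), so a flat touch of the level is not counted as two crossings.
#'
#' @param x Epoch samples.
#' @param threshold Threshold level in g (scalar or [threshold_spec()]).
#' @return Integer crossing count in `[0, length(x) - 1]`.
#' @export
zcm <- function(x, threshold) {
  t <- threshold_value(threshold)
  s <- sign(x - t)
  nz <- s != 0
  if (!any(nz)) return(0L)
  s <- s[nz]                    # on-threshold samples inherit the previous side
  sum(s[-1] != s[-length(s)])
}

#' Time Above Threshold for one epoch
#'
#' Total time the signal spends strictly above the threshold:
#' `T_s * #(x > threshold)` seconds.
#'
#' @param x Epoch samples.
#' @param threshold Threshold level in g (scalar or [threshold_spec()]).
#' @param t_s Sampling interval in seconds.
#' @return Time in seconds, in `[0, length(x) * t_s]`.
#' @export
tat <- function(x, threshold, t_s) {
  t_s * sum(x > threshold_value(threshold))
}

#' Mean Amplitude Deviation for one epoch
#'
#' Mean absolute deviation of the epoch from its own mean:
#' `mean(|x - mean(x)|)`. Being offset-invariant, it removes gravity by
#' construction and is the only metric applicable to every dataset type.
#'
#' @param x Epoch samples.
#' @return The activity value in g.
#' @export
mad_epoch <- function(x) {
  mean(abs(x - mean(x)))
}

#' Euclidean Norm Minus One for one epoch
#'
#' Mean of the part of the magnitude exceeding 1 g:
#' `mean(pmax(r - 1, 0))`. Only meaningful on a magnitude series that still
#' carries gravity (UFM) - the metric removes the 1 g offset itself.
#'
#' @param r Epoch of UFM magnitude samples in g.
#' @return The activity value in g.
#' @export
enmo <- function(r) {
  mean(pmax(r - 1, 0))
}

#' High-pass Filtered Euclidean Norm for one epoch
#'
#' Mean of the magnitudes of high-pass-filtered axial accelerations.
#' Gravity is already removed by the 0.2 Hz order-4 high-pass applied per
#' axis before the magnitude, so no offset subtraction is needed.
#'
#' @param r_f Epoch of HFEN_M magnitude samples in g.
#' @return The activity value in g.
#' @export
hfen <- function(r_f) {
  mean(r_f)
}

#' Noise model for the Activity Index
#'
#' Holds the systematic noise variance: the per-axis acceleration variance
#' observed while the device is not moving, averaged over the three axes.
#'
#' @param variance Systematic noise variance in g^2.
#' @param source Description of the still segments used to estimate it.
#' @return A `noise_model` object.
#' @export
noise_model <- function(variance, source = "unspecified") {
  if (variance < 0) parameter_error("noise variance must be nonnegative")
  structure(list(variance = variance, source = source), class = "noise_model")
}

#' Activity Index for one epoch
#'
#' Averages the per-axis sample variances over the three axes after
#' subtracting the systematic noise variance, floored at zero:
#' `max(mean(var_m - noise), 0)`. The `sqrt` variant takes the square root
#' of that floored term, matching the scaling used in the original Activity
#' Index literature; the linear variant is the default.
#'
#' @param ex,ey,ez Aligned axial epoch windows.
#' @param noise A [noise_model()].
#' @param variant `"linear"` or `"sqrt"`.
#' @return The activity value (g^2, or g for the sqrt variant).
#' @export
activity_index <- function(ex, ey, ez, noise, variant = c("linear", "sqrt")) {
  variant <- match.arg(variant)
  if (length(ey) != length(ex) || length(ez) != length(ex))
    shape_error("axial epochs must have equal length")
  v <- max((stats::var(ex) - noise$variance +
            stats::var(ey) - noise$variance +
            stats::var(ez) - noise$variance) / 3, 0)
  if (variant == "sqrt") sqrt(v) else v
}

#' Estimate the systematic noise variance from still segments
#'
#' Splits the recording into epochs, ranks them by total axial variance and
#' keeps the stillest fraction (`quantile`, default the lowest 1%); the
#' systematic noise variance is the mean over those epochs of the per-axis
#' variance average. On free-living recordings the stillest epochs are the
#' device-at-rest segments, so the estimate tracks the sensor noise floor
#' rather than movement.
#'
#' @param rec A [raw_recording()].
#' @param ep An [epoch_params()].
#' @param quantile Fraction of stillest epochs to keep (default 0.01).
#' @return A [noise_model()].
#' @export
estimate_noise_variance <- function(rec, ep = epoch_params(fs = rec$fs),
                                    quantile = 0.01) {
  stopifnot(inherits(rec, "raw_recording"))
  ex <- epochs(rec$x, ep); ey <- epochs(rec$y, ep); ez <- epochs(rec$z, ep)
  k <- ncol(ex)
  if (k < 10) size_error("need at least 10 epochs to estimate the noise floor")
  vx <- apply(ex, 2, stats::var)
  vy <- apply(ey, 2, stats::var)
  vz <- apply(ez, 2, stats::var)
  total <- vx + vy + vz
  cut <- stats::quantile(total, quantile, names = FALSE)
  sel <- total <= cut
  noise_model(mean((vx[sel] + vy[sel] + vz[sel]) / 3),
              source = sprintf("stillest %d of %d epochs (quantile %.3g)",
                               sum(sel), k, quantile))
}

# Applicability matrix: which metric may run on which dataset kind.
# PIM on FX/FY/FZ/FMpost requires rectification (handled in
# compute_activity); PIM/ZCM/TAT are not applicable to raw axial data
# because the orientation-dependent gravity share cannot be removed there.
.metric_datasets <- list(
  PIMr = c("UFM", "UFNM", "FMpre", "FMpost", "FX", "FY", "FZ"),
  PIMs = c("UFM", "UFNM", "FMpre", "FMpost", "FX", "FY", "FZ"),
  ZCM  = c("UFM", "UFNM", "FMpre", "FMpost", "FX", "FY", "FZ"),
  TAT  = c("UFM", "UFNM", "FMpre", "FMpost", "FX", "FY", "FZ"),
  MAD  = c("UFM", "UFNM", "FMpre", "FMpost", "FX", "FY", "FZ",
           "UFX", "UFY", "UFZ"),
  ENMO = "UFM",
  HFEN = "HFEN_M",
  AI   = c("UFXYZ", "FXYZ"))

#' Metric applicability matrix
#'
#' Which activity metric may be computed on which preprocessed dataset
#' kind. `ENMO` needs the gravity-bearing magnitude (UFM), `HFEN` its
#' specially high-pass-conditioned magnitude, `AI` the axial triples, and
#' the level-crossing and integration metrics need gravity either removed
#' or representable as a constant offset.
#'
#' @return A data frame with columns `metric` and `dataset`.
#' @export
applicability <- function() {
  data.frame(
    metric = rep(names(.metric_datasets), lengths(.metric_datasets)),
    dataset = unlist(.metric_datasets, use.names = FALSE),
    stringsAsFactors = FALSE)
}

check_applicable <- function(metric, dataset_kind) {
  allowed <- .metric_datasets[[metric]]
  if (is.null(allowed))
    parameter_error(sprintf("unknown metric '%s'", metric))
  if (!dataset_kind %in% allowed)
    applicability_error(sprintf(
      "%s is not applicable to %s; allowed datasets: %s",
      metric, dataset_kind, paste(allowed, collapse = ", ")))
  invisible(TRUE)
}

#' Compute an activity series from a preprocessed dataset
#'
#' Applies one activity metric per epoch, enforcing the applicability
#' matrix (see [applicability()]). For PIM on the zero-centred datasets
#' (FX/FY/FZ, FMpost) the samples are rectified (absolute values) before
#' integration, the standard technical correction for integrating signed
#' data. `AI` takes the three axial series of a triple (`UFXYZ` or `FXYZ`)
#' and a noise model instead of a single series.
#'
#' @param series A [dataset_series], or for `AI` a list of the three axial
#'   [dataset_series] (x, y, z order).
#' @param metric Metric identifier: `"PIMr"`, `"PIMs"`, `"ZCM"`, `"TAT"`,
#'   `"MAD"`, `"ENMO"`, `"HFEN"` or `"AI"`.
#' @param ep An [epoch_params()]; its sampling rate must match the series.
#' @param threshold [threshold_spec()] or scalar level in g, required for
#'   ZCM and TAT.
#' @param noise [noise_model()], required for AI.
#' @param ai_variant `"linear"` (default) or `"sqrt"`, see
#'   [activity_index()].
#' @param rectify Override the automatic rectification decision for
#'   level-crossing metrics (used by the full-rectification comparison);
#'   `NULL` keeps the default behavior (rectify PIM input on zero-centred
#'   datasets, never for other metrics).
#' @param baseline_subtract For PIM on UFM only: subtract the integral of
#'   the constant 1 g gravity offset (`n * T_s`) from each epoch, clipped
#'   at zero (default FALSE: the plain integral of the magnitude).
#' @return An [activity_series].
#' @export
#' @examples
#' rec <- raw_recording(rnorm(1200, 0, 0.05), rnorm(1200, 0, 0.05),
#'                      1 + rnorm(1200, 0, 0.05))
#' ds <- build_datasets(rec)
#' ep <- epoch_params(60, fs = 10)
#' compute_activity(ds$UFM, "ENMO", ep)
compute_activity <- function(series, metric, ep,
                             threshold = NULL, noise = NULL,
                             ai_variant = c("linear", "sqrt"),
                             rectify = NULL, baseline_subtract = FALSE) {
  ai_variant <- match.arg(ai_variant)
  t_s <- 1 / ep$fs
  if (metric == "AI") {
    if (!is.list(series) || length(series) != 3 ||
        !all(vapply(series, inherits, logical(1), "dataset_series")))
      parameter_error("AI requires a list of the three axial dataset_series")
    kinds <- vapply(series, function(s) s$kind, character(1))
    triple <- if (all(kinds == c("UFX", "UFY", "UFZ"))) "UFXYZ"
              else if (all(kinds == c("FX", "FY", "FZ"))) "FXYZ"
              else applicability_error(
                "AI requires the axial triple UFX/UFY/UFZ or FX/FY/FZ")
    check_applicable("AI", triple)
    if (is.null(noise)) parameter_error("AI requires a noise model")
    ex <- epochs(series[[1]], ep); ey <- epochs(series[[2]], ep)
    ez <- epochs(series[[3]], ep)
    vals <- vapply(seq_len(ncol(ex)), function(i)
      activity_index(ex[, i], ey[, i], ez[, i], noise, ai_variant),
      numeric(1))
    return(activity_series(vals, "AI", triple, ep$epoch_length_s))
  }
  stopifnot(inherits(series, "dataset_series"))
  check_applicable(metric, series$kind)
  if (metric %in% c("ZCM", "TAT") && is.null(threshold))
    parameter_error(sprintf("%s requires a threshold", metric))
  x <- series$values
  zero_centred <- series$kind %in% c("FX", "FY", "FZ", "FMpost")
  do_rectify <- if (is.null(rectify))
    metric %in% c("PIMr", "PIMs") && zero_centred else isTRUE(rectify)
  if (do_rectify) x <- abs(x)
  e <- epochs(x, ep)
  vals <- switch(metric,
    PIMr = apply(e, 2, pim, t_s = t_s, rule = "riemann"),
    PIMs = apply(e, 2, pim, t_s = t_s, rule = "simpson38"),
    ZCM  = apply(e, 2, zcm, threshold = threshold),
    TAT  = apply(e, 2, tat, threshold = threshold, t_s = t_s),
    MAD  = apply(e, 2, mad_epoch),
    ENMO = apply(e, 2, enmo),
    HFEN = apply(e, 2, hfen),
    parameter_error(sprintf("unknown metric '%s'", metric)))
  if (baseline_subtract && metric %in% c("PIMr", "PIMs") && series$kind == "UFM")
    vals <- pmax(vals - ep$samples_per_epoch * t_s, 0)
  thr <- if (metric %in% c("ZCM", "TAT")) as_threshold_spec(threshold, series$kind)
  activity_series(vals, metric, series$kind, ep$epoch_length_s, threshold = thr)
}
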
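#' Level-crossing threshold with provenance
#'
#' ZCM and TAT compare the signal against a threshold level. The threshold
#' carries its provenance: a fixed value, the SD-adaptive rule, or one step
#' of a cumulative sweep. For the gravity-bearing UFM dataset thresholds
#' are offset by the constant 1 g; every other dataset starts from 0 g.
#'
#' @param value Threshold level in g.
#' @param mode `"fixed"`, `"sd_adaptive"` or `"sweep"`.
#' @param source_kind Dataset taxonomy tag the threshold was derived for.
#' @return A `threshold_spec` object with fields `value`, `mode`,
#'   `base_offset`, `source_kind`.
#' @export
threshold_spec <- function(value, mode = c("fixed", "sd_adaptive", "sweep"),
                           source_kind = NA_character_) {
  mode <- match.arg(mode)
  base <- if (identical(source_kind, "UFM")) 1 else 0
  if (value < base)
    parameter_error(sprintf("threshold %.4g g below the %s base offset %g g",
                            value, source_kind, base))
  structure(list(value = value, mode = mode, base_offset = base,
                 source_kind = source_kind),
            class = "threshold_spec")
}

threshold_value <- function(threshold) {
  if (inherits(threshold, "threshold_spec")) threshold$value
  else if (is.numeric(threshold) && length(threshold) == 1) threshold
  else parameter_error("threshold must be a scalar or a threshold_spec")
}

as_threshold_spec <- function(threshold, source_kind) {
  if (inherits(threshold, "threshold_spec")) threshold
  else threshold_spec(threshold_value(threshold), "fixed", source_kind)
}

#' SD-adaptive threshold for ZCM and TAT
#'
#' Sets the level to the standard deviation of the whole dataset
#' (population SD over the full recording, not per epoch), plus 1 g for the
#' UFM dataset whose values sit on the constant gravity offset. The SD of a
#' free-living recording sits above the sensor noise floor and scales with
#' the subject's overall movement intensity, making it an adaptive,
#' near-optimal level for both level-crossing metrics.
#'
#' @param series A [dataset_series].
#' @return A [threshold_spec()] with mode `"sd_adaptive"`.
#' @export
#' @examples
#' s <- dataset_series(abs(rnorm(1000, 0, 0.1)), "UFNM", fs = 10)
#' sd_threshold(s)
sd_threshold <- function(series) {
  stopifnot(inherits(series, "dataset_series"))
  v <- series$values
  if (length(v) < 2) size_error("need at least 2 samples for an SD threshold")
  n <- length(v)
  sdev <- sqrt(sum((v - mean(v))^2) / n)   # population SD of the dataset
  base <- if (series$kind == "UFM") 1 else 0
  if (sdev == 0)
    warning("constant series: SD threshold degenerates to the base offset",
            call. = FALSE)
  threshold_spec(base + sdev, "sd_adaptive", series$kind)
}

#' Cumulative threshold sweep for a level-crossing metric
#'
#' Computes the ZCM or TAT activity series at thresholds
#' `base_offset + k * step_g` for `k = 1..n_steps`, where the base offset
#' is 1 g for UFM and 0 g otherwise. The default step of 0.05 g matches
#' the grid used to map how the choice of level shapes the activity signal.
#'
#' @param series A [dataset_series] (one of the ZCM/TAT-applicable kinds).
#' @param metric `"ZCM"` or `"TAT"`.
#' @param ep An [epoch_params()].
#' @param step_g Threshold increment in g (default 0.05).
#' @param n_steps Number of steps.
#' @return List of [activity_series], one per threshold, in increasing
#'   threshold order.
#' @export
threshold_sweep <- function(series, metric = c("ZCM", "TAT"),
                            ep, step_g = 0.05, n_steps = 20) {
  metric <- match.arg(metric)
  if (step_g <= 0) parameter_error("step_g must be positive")
  base <- if (series$kind == "UFM") 1 else 0
  lapply(seq_len(n_steps), function(k) {
    thr <- threshold_spec(base + k * step_g, "sweep", series$kind)
    compute_activity(series, metric, ep, threshold = thr)
  })
}

#' Correlation of a threshold sweep against reference activity signals
#'
#' For every sweep member, the Pearson correlation with each reference
#' activity series, and additionally with the sweep metric computed at the
#' SD-adaptive threshold (reference id `"SD"`). A zero-variance activity
#' signal yields `NA` with a flag rather than being dropped.
#'
#' @param sweep List of [activity_series] from [threshold_sweep()].
#' @param references Named list of reference [activity_series] (e.g.
#'   `list(ENMO = ..., HFEN = ...)`).
#' @param sd_reference Optional [activity_series] computed at the
#'   SD-adaptive threshold, added as reference `"SD"`.
#' @return Data frame with columns `threshold`, `reference`, `r`,
#'   `degenerate` (TRUE where a constant signal made r undefined).
#' @export
sweep_correlation_curve <- function(sweep, references, sd_reference = NULL) {
  if (!is.null(sd_reference)) references <- c(references, list(SD = sd_reference))
  if (is.null(names(references)) || any(names(references) == ""))
    parameter_error("references must be a named list")
  n_ep <- length(sweep[[1]]$values)
  for (r in references)
    if (length(r$values) != n_ep)
      alignment_error("sweep and reference series must share the epoch grid")
  rows <- lapply(sweep, function(a) {
    thr <- a$threshold$value
    do.call(rbind, lapply(names(references), function(nm) {
      b <- references[[nm]]
      degenerate <- stats::sd(a$values) == 0 || stats::sd(b$values) == 0
      data.frame(threshold = thr, reference = nm,
                 r = if (degenerate) NA_real_ else
                   stats::cor(a$values, b$values),
                 degenerate = degenerate, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
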
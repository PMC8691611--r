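#' Combine three per-axis activity series into one indicator
#'
#' When a metric is applied per axis, one activity value per epoch can be
#' derived from the three axial values by their sum, the sum of their
#' squares, or the Euclidean norm VM3 = sqrt(ax^2 + ay^2 + az^2).
#'
#' Inputs must share the metric, the epoch grid and the preprocessing
#' lineage (all unfiltered or all band-pass-filtered axes).
#'
#' @param ax,ay,az [activity_series] for the x, y and z axes.
#' @param method `"sum"`, `"sum_sq"` or `"vm3"`.
#' @return An [activity_series] with the `combination` field set.
#' @export
#' @examples
#' ax <- activity_series(c(3, 1), "ZCM", "FX")
#' ay <- activity_series(c(4, 2), "ZCM", "FY")
#' az <- activity_series(c(12, 3), "ZCM", "FZ")
#' combine_axial(ax, ay, az, "vm3")$values
combine_axial <- function(ax, ay, az, method = c("sum", "sum_sq", "vm3")) {
  method <- match.arg(method)
  for (a in list(ax, ay, az)) stopifnot(inherits(a, "activity_series"))
  if (length(ay$values) != length(ax$values) ||
      length(az$values) != length(ax$values))
    alignment_error("axial activity series must share the epoch grid")
  if (ax$metric != ay$metric || ax$metric != az$metric)
    alignment_error("axial activity series must share the metric")
  if (ax$epoch_s != ay$epoch_s || ax$epoch_s != az$epoch_s)
    alignment_error("axial activity series must share the epoch length")
  kinds <- c(ax$dataset_kind, ay$dataset_kind, az$dataset_kind)
  triple <- if (all(kinds == c("UFX", "UFY", "UFZ"))) "UFXYZ"
            else if (all(kinds == c("FX", "FY", "FZ"))) "FXYZ"
            else alignment_error("expected the axial kinds UFX/UFY/UFZ or FX/FY/FZ in order")
  vals <- switch(method,
    sum    = ax$values + ay$values + az$values,
    sum_sq = ax$values^2 + ay$values^2 + az$values^2,
    vm3    = sqrt(ax$values^2 + ay$values^2 + az$values^2))
  activity_series(vals, ax$metric, triple, ax$epoch_s,
                  combination = method)
}

#' Per-axis activity with axis-wise SD-adaptive thresholds
#'
#' Convenience wrapper: computes one metric on the three axial series of a
#' dataset collection, deriving the ZCM/TAT threshold from each axis's own
#' SD (the adaptive rule applied axis-wise; recorded in each series'
#' threshold provenance).
#'
#' @param datasets Named list from [build_datasets()].
#' @param metric Axial metric (`"PIMr"`, `"PIMs"`, `"ZCM"`, `"TAT"`,
#'   `"MAD"`).
#' @param ep An [epoch_params()].
#' @param filtered Use the filtered axes FX/FY/FZ (default) or the raw axes
#'   (MAD only).
#' @return List with elements `x`, `y`, `z` of [activity_series].
#' @export
axial_activity <- function(datasets, metric, ep, filtered = TRUE) {
  keys <- if (filtered) c("FX", "FY", "FZ") else c("UFX", "UFY", "UFZ")
  out <- lapply(keys, function(k) {
    s <- datasets[[k]]
    thr <- if (metric %in% c("ZCM", "TAT")) sd_threshold(s)
    compute_activity(s, metric, ep, threshold = thr)
  })
  names(out) <- c("x", "y", "z")
  out
}
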
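#' Pearson correlation between two activity series
#'
#' Standard product-moment coefficient on the epoch grid both series share.
#' A constant input makes the coefficient undefined and raises a classed
#' error instead of returning NA silently.
#'
#' @param a,b [activity_series] on the same epoch grid.
#' @return The correlation coefficient.
#' @export
pearson <- function(a, b) {
  va <- if (inherits(a, "activity_series")) a$values else as.numeric(a)
  vb <- if (inherits(b, "activity_series")) b$values else as.numeric(b)
  if (length(va) != length(vb))
    alignment_error("activity series must share the epoch grid")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    correlation_error("correlation undefined for a constant activity signal")
  stats::cor(va, vb)
}

#' Welch power spectral density estimate
#'
#' Averaged periodogram with Hann window, 50% overlap and per-segment
#' linear detrending; one-sided output. This is the PSD estimate used for
#' frequency-domain comparison of activity signals.
#'
#' @param x Numeric series (epoch-sampled activity values).
#' @param fs Sampling frequency (per epoch units; default 1, i.e.
#'   frequencies in cycles per epoch).
#' @param segment Segment length in samples (default 256).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `freq` and `psd` vectors.
#' @export
welch_psd <- function(x, fs = 1, segment = 256, overlap = 0.5) {
  n <- length(x)
  if (n < segment) size_error("series shorter than one PSD segment")
  step <- max(1L, as.integer(round(segment * (1 - overlap))))
  starts <- seq(1L, n - segment + 1L, by = step)
  k <- seq_len(segment)
  w <- 0.5 * (1 - cos(2 * pi * (k - 1) / (segment - 1)))   # Hann
  scale <- 1 / (fs * sum(w^2))
  t0 <- k - mean(k)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + segment - 1L)]
    fit <- stats::lm.fit(cbind(1, t0), seg)                # linear detrend
    seg <- fit$residuals * w
    p <- abs(stats::fft(seg))^2 * scale
    acc <- acc + p
  }
  p <- acc / length(starts)
  half <- seq_len(segment %/% 2 + 1L)
  psd <- p[half]
  # fold the negative frequencies into the one-sided estimate
  interior <- half[-c(1L, length(half))]
  psd[interior] <- 2 * psd[interior]
  list(freq = (half - 1L) / segment * fs, psd = psd)
}

#' Spectral correlation between two activity signals
#'
#' Pearson coefficient between the Welch power spectral density estimates
#' of the two series on their shared frequency grid. Being phase-blind, it
#' measures whether the two activity signals fluctuate with the same
#' rhythmicity regardless of time alignment.
#'
#' @param a,b [activity_series] (or numeric vectors) of equal length.
#' @param psd_params List with `segment` and `overlap`, see [welch_psd()].
#' @return The correlation coefficient between the PSDs.
#' @export
spectral_correlation <- function(a, b,
                                 psd_params = list(segment = 256, overlap = 0.5)) {
  va <- if (inherits(a, "activity_series")) a$values else as.numeric(a)
  vb <- if (inherits(b, "activity_series")) b$values else as.numeric(b)
  if (length(va) != length(vb))
    alignment_error("activity series must share the epoch grid")
  seg <- psd_params$segment
  if (length(va) < 4 * seg)
    size_error("series must be at least 4 PSD segments long")
  pa <- welch_psd(va, segment = seg, overlap = psd_params$overlap)$psd
  pb <- welch_psd(vb, segment = seg, overlap = psd_params$overlap)$psd
  if (stats::sd(pa) == 0 || stats::sd(pb) == 0)
    correlation_error("correlation undefined for a flat power spectrum")
  stats::cor(pa, pb)
}

#' Default catalog of activity-signal definitions
#'
#' Enumerates every (metric, dataset) pair permitted by the applicability
#' matrix, both PIM integration rules, the per-axis signals, and the three
#' axial combination indicators (sum, sum of squares, VM3) for the metrics
#' that can run per axis. The enumeration is deterministic; its size is
#' reported by `nrow()` and the manifest can be written and re-read with
#' [write_catalog()] / [read_catalog()].
#'
#' @param combinations Include the axial combination indicators
#'   (default TRUE).
#' @param sweep_steps Optionally add ZCM/TAT sweep members on UFNM: number
#'   of 0.05 g steps (0 = none).
#' @return A data frame (`signal_catalog`) with columns `id`, `metric`,
#'   `dataset`, `combination`.
#' @export
default_catalog <- function(combinations = TRUE, sweep_steps = 0) {
  rows <- list()
  add <- function(metric, dataset, combination = "none", threshold = NA_real_) {
    id <- if (combination == "none") sprintf("%s(%s)", metric, dataset)
          else sprintf("%s_%s(%s)", metric, combination, dataset)
    if (!is.na(threshold)) id <- sprintf("%s(%s,T=%.2f)", metric, dataset, threshold)
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, metric = metric, dataset = dataset, combination = combination,
      threshold = threshold, stringsAsFactors = FALSE)
  }
  mags <- c("UFM", "UFNM", "FMpre", "FMpost")
  for (m in c("PIMr", "PIMs", "ZCM", "TAT", "MAD")) for (d in mags) add(m, d)
  for (m in c("PIMr", "PIMs", "ZCM", "TAT", "MAD"))
    for (d in c("FX", "FY", "FZ")) add(m, d)
  for (d in c("UFX", "UFY", "UFZ")) add("MAD", d)
  add("ENMO", "UFM")
  add("HFEN", "HFEN_M")
  add("AI", "UFXYZ"); add("AI", "FXYZ")
  if (combinations) {
    for (m in c("PIMr", "ZCM", "TAT", "MAD"))
      for (cb in c("sum", "sum_sq", "vm3")) add(m, "FXYZ", cb)
    for (cb in c("sum", "sum_sq", "vm3")) add("MAD", "UFXYZ", cb)
  }
  if (sweep_steps > 0)
    for (m in c("ZCM", "TAT")) for (k in seq_len(sweep_steps))
      add(m, "UFNM", threshold = k * 0.05)
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$id)) parameter_error("catalog ids must be unique")
  class(out) <- c("signal_catalog", class(out))
  out
}

#' Write / read a catalog manifest
#'
#' Plain CSV manifest of a [default_catalog()]-style catalog so a run's
#' exact signal enumeration can be archived and reproduced.
#'
#' @param catalog A `signal_catalog` data frame.
#' @param path File path.
#' @return `path` invisibly; `read_catalog()` returns the catalog.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("signal_catalog", class(out))
  out
}

#' Compute every catalog entry for one recording
#'
#' Runs the preprocessing once, derives the SD-adaptive threshold per
#' dataset (axis-wise for per-axis signals), estimates the noise model for
#' AI from the recording's stillest epochs, and evaluates each catalog
#' entry.
#'
#' @param rec A [raw_recording()].
#' @param catalog A `signal_catalog` (default [default_catalog()]).
#' @param ep An [epoch_params()].
#' @param spec Band-pass [filter_spec()].
#' @return Named list of [activity_series], keyed by catalog id.
#' @export
compute_catalog_signals <- function(rec, catalog = default_catalog(),
                                    ep = epoch_params(fs = rec$fs),
                                    spec = filter_spec()) {
  ds <- build_datasets(rec, spec)
  noise <- estimate_noise_variance(rec, ep)
  thr_cache <- list()
  thr_for <- function(kind) {
    if (is.null(thr_cache[[kind]]))
      thr_cache[[kind]] <<- sd_threshold(ds[[kind]])
    thr_cache[[kind]]
  }
  axial_sets <- list(UFXYZ = c("UFX", "UFY", "UFZ"), FXYZ = c("FX", "FY", "FZ"))
  out <- vector("list", nrow(catalog))
  names(out) <- catalog$id
  for (i in seq_len(nrow(catalog))) {
    entry <- catalog[i, ]
    if (entry$metric == "AI") {
      out[[i]] <- compute_activity(unname(ds[axial_sets[[entry$dataset]]]),
                                   "AI", ep, noise = noise)
    } else if (entry$combination != "none") {
      axes <- axial_sets[[entry$dataset]]
      parts <- lapply(axes, function(k) {
        thr <- if (entry$metric %in% c("ZCM", "TAT")) thr_for(k)
        compute_activity(ds[[k]], entry$metric, ep, threshold = thr)
      })
      out[[i]] <- combine_axial(parts[[1]], parts[[2]], parts[[3]],
                                entry$combination)
    } else {
      thr <- if (!entry$metric %in% c("ZCM", "TAT")) NULL
             else if (!is.null(entry$threshold) && !is.na(entry$threshold))
               threshold_spec(entry$threshold +
                              if (entry$dataset == "UFM") 1 else 0,
                              "sweep", entry$dataset)
             else thr_for(entry$dataset)
      out[[i]] <- compute_activity(ds[[entry$dataset]], entry$metric, ep,
                                   threshold = thr)
    }
  }
  out
}

#' Mean +/- SD correlation matrix across subjects
#'
#' For each subject the full pairwise correlation matrix between the
#' catalog signals is computed (time domain: Pearson between the activity
#' values; frequency domain: Pearson between their Welch PSDs), then the
#' identically located cells are averaged across subjects into a mean
#' matrix with a companion SD matrix. Cells whose correlation is undefined
#' for a subject (constant signal) are averaged over the remaining
#' subjects and flagged through `n_effective`.
#'
#' @param subject_signals List over subjects; each element a named list of
#'   [activity_series] covering the same catalog ids.
#' @param domain `"time"` or `"frequency"`.
#' @param psd_params PSD parameters for the frequency domain, see
#'   [spectral_correlation()].
#' @return A `correlation_summary` object: list with `ids`, `mean`, `sd`,
#'   `n_subjects`, `n_effective`, `domain`.
#' @export
correlation_matrix <- function(subject_signals, domain = c("time", "frequency"),
                               psd_params = list(segment = 128, overlap = 0.5)) {
  domain <- match.arg(domain)
  ids <- names(subject_signals[[1]])
  for (s in seq_along(subject_signals)) {
    missing_ids <- setdiff(ids, names(subject_signals[[s]]))
    if (length(missing_ids) > 0)
      coverage_error(sprintf("subject %d lacks catalog entries: %s",
                             s, paste(missing_ids, collapse = ", ")))
  }
  per_subject <- lapply(subject_signals, function(sig) {
    m <- vapply(ids, function(id) sig[[id]]$values,
                numeric(length(sig[[ids[1]]]$values)))
    if (domain == "frequency") {
      m <- vapply(seq_len(ncol(m)), function(j)
        welch_psd(m[, j], segment = psd_params$segment,
                  overlap = psd_params$overlap)$psd,
        numeric(psd_params$segment %/% 2 + 1L))
    }
    sds <- apply(m, 2, stats::sd)
    cc <- suppressWarnings(stats::cor(m))
    cc[sds == 0, ] <- NA_real_; cc[, sds == 0] <- NA_real_
    diag(cc) <- ifelse(sds == 0, NA_real_, 1)
    cc
  })
  arr <- simplify2array(per_subject)
  mean_m <- apply(arr, c(1, 2), function(v) mean(v, na.rm = TRUE))
  sd_m <- apply(arr, c(1, 2), function(v)
    if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) else 0)
  n_eff <- apply(arr, c(1, 2), function(v) sum(!is.na(v)))
  mean_m[n_eff == 0] <- NA_real_; sd_m[n_eff == 0] <- NA_real_
  dimnames(mean_m) <- dimnames(sd_m) <- dimnames(n_eff) <- list(ids, ids)
  structure(list(ids = ids, mean = mean_m, sd = sd_m,
                 n_subjects = length(subject_signals), n_effective = n_eff,
                 domain = domain),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("<correlation_summary> %d x %d signals, %d subjects, %s domain\n",
              length(x$ids), length(x$ids), x$n_subjects, x$domain))
  invisible(x)
}

#' Export a correlation summary
#'
#' Long format: one row per signal pair with mean, SD and effective subject
#' count. Square format: the mean matrix as CSV.
#'
#' @param summary A `correlation_summary` from [correlation_matrix()].
#' @param path Output CSV path.
#' @param layout `"long"` or `"square"`.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(summary, path, layout = c("long", "square")) {
  layout <- match.arg(layout)
  if (layout == "square") {
    utils::write.csv(summary$mean, path, row.names = TRUE)
  } else {
    idx <- which(upper.tri(summary$mean, diag = TRUE), arr.ind = TRUE)
    out <- data.frame(entry_a = summary$ids[idx[, 1]],
                      entry_b = summary$ids[idx[, 2]],
                      domain = summary$domain,
                      mean_r = summary$mean[idx],
                      sd_r = summary$sd[idx],
                      n = summary$n_effective[idx])
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}
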
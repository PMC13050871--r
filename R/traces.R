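# Activity-trace analysis: GCaMP time-lapse ROI masking and dF - F0 peak
# frequency; current-clamp supra-threshold event detection with spike
# integral (AUC).

#' ROI mask from a time-lapse movie
#'
#' Temporal maximum-intensity projection, Kapur maximum-entropy threshold,
#' then noise reduction by removing connected components smaller than
#' `min_size_px` pixels.
#'
#' @param movie 3D numeric array (ny, nx, n_frames), >= 2 frames.
#' @param min_size_px minimum component size kept (pixels).
#' @param n_bins histogram bins for the threshold.
#' @return logical matrix mask.
#' @export
roi_mask_from_movie <- function(movie, min_size_px = 20L, n_bins = 256L) {
  stopifnot(is.array(movie), length(dim(movie)) == 3L, dim(movie)[3] >= 2L)
  mip <- apply(movie, c(1, 2), max)
  if (diff(range(mip)) == 0)
    stop("degenerate input: constant movie")
  thr <- .kapur_threshold(mip, n_bins)
  mask <- mip > thr
  lab <- matrix(.label_3d(as.logical(array(mask, c(dim(mask), 1L))),
                          c(dim(mask), 1L)), nrow(mask), ncol(mask))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size_px)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Extract a fluorescence trace from a movie
#'
#' Per-frame mean intensity over the mask.
#'
#' @param movie 3D numeric array (ny, nx, n_frames).
#' @param mask logical matrix, non-empty.
#' @param dt_s sampling interval (s), default the 0.78 s time-lapse
#'   interval.
#' @return [rq_trace()] of kind "fluorescence".
#' @export
extract_trace <- function(movie, mask, dt_s = 0.78) {
  stopifnot(is.array(movie), length(dim(movie)) == 3L, is.matrix(mask),
            all(dim(mask) == dim(movie)[1:2]))
  if (!any(mask)) stop("empty mask")
  v <- vapply(seq_len(dim(movie)[3]),
              function(k) mean(movie[, , k][mask]), numeric(1))
  rq_trace((seq_along(v) - 1) * dt_s, v, kind = "fluorescence")
}

#' Baseline-correct a fluorescence trace (dF - F0)
#'
#' F0 is the 10th percentile of the trace ("percentile" mode, default) or
#' the mean of the first `k_initial` samples ("initial" mode). The mode and
#' the F0 value used are recorded as attributes.
#'
#' @param trace an [rq_trace()].
#' @param f0_mode "percentile" or "initial".
#' @param percentile percentile used in "percentile" mode (0-100).
#' @param k_initial samples averaged in "initial" mode.
#' @return corrected [rq_trace()] with attributes `f0`, `f0_mode`.
#' @export
baseline_correct <- function(trace, f0_mode = c("percentile", "initial"),
                             percentile = 10, k_initial = 10L) {
  f0_mode <- match.arg(f0_mode)
  stopifnot(nrow(trace) >= 1L)
  f0 <- switch(f0_mode,
               percentile = unname(quantile(trace$value, percentile / 100)),
               initial = mean(trace$value[seq_len(min(k_initial,
                                                      nrow(trace)))]))
  out <- rq_trace(trace$time_s, trace$value - f0,
                  kind = attr(trace, "kind") %||% "generic",
                  duration_s = attr(trace, "duration_s"))
  attr(out, "f0") <- f0
  attr(out, "f0_mode") <- f0_mode
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# topographic prominence of local maxima (scipy-style): on each side, the
# minimum between the peak and the nearest strictly-higher sample (or the
# trace end); prominence = peak height - the larger of the two minima.
.peak_prominence <- function(v, peaks) {
  vapply(peaks, function(p) {
    h <- v[p]
    i <- p - 1L
    lmin <- h
    while (i >= 1L && v[i] <= h) {
      if (v[i] < lmin) lmin <- v[i]
      i <- i - 1L
    }
    j <- p + 1L
    rmin <- h
    while (j <= length(v) && v[j] <= h) {
      if (v[j] < rmin) rmin <- v[j]
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Peak frequency of a baseline-corrected fluorescence trace
#'
#' Noise reduction by a short moving-average filter (matched to the slow
#' calcium-indicator transients), then local maxima with topographic
#' prominence at least `min_prominence`. The default floor is 6 x a robust
#' noise estimate (median absolute deviation of the first differences of
#' the smoothed trace, rescaled for the smoothing autocorrelation), which
#' sits above the ~5-6 sigma prominence that band-limited noise extrema
#' reach over typical inter-event intervals while remaining independent of
#' the signal itself; slow transients at signal-to-noise >= 5 retain far
#' larger prominence after smoothing. Frequency is reported per minute of
#' the nominal trace duration.
#'
#' @param trace baseline-corrected [rq_trace()].
#' @param min_prominence minimum peak prominence; NULL for the MAD default.
#' @param smooth_samples moving-average width in samples (odd; 1 disables
#'   smoothing).
#' @return list of class `rq_peaks`: `peak_times_s`, `peak_count`,
#'   `frequency_per_min`, `min_prominence`.
#' @export
peak_frequency <- function(trace, min_prominence = NULL,
                           smooth_samples = 5L) {
  v <- trace$value
  n <- length(v)
  k <- 1L
  if (smooth_samples > 1L && n > smooth_samples) {
    k <- as.integer(smooth_samples)
    if (k %% 2L == 0L) k <- k + 1L
    r <- (k - 1L) %/% 2L
    idx <- outer(seq_len(n), (-r):r, "+")
    idx[idx < 1L] <- 1L
    idx[idx > n] <- n
    v <- rowMeans(matrix(v[idx], n))
  }
  if (is.null(min_prominence)) {
    # sd of a k-boxcar-smoothed white-noise series, estimated robustly from
    # first differences: sd(diff) = sigma_raw * sqrt(2) / k, so
    # sigma_smoothed = sigma_raw / sqrt(k) = mad(diff) * sqrt(k / 2)
    noise_sm <- if (n > 1) mad(diff(v)) * sqrt(k / 2) else 0
    min_prominence <- 6 * noise_sm
  }
  if (n < 3) {
    peaks <- integer()
  } else {
    core <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
    if (length(core)) {
      prom <- .peak_prominence(v, core)
      peaks <- core[prom >= min_prominence & prom > 0]
    } else {
      peaks <- integer()
    }
  }
  dur_min <- .trace_duration(trace) / 60
  structure(list(peak_times_s = trace$time_s[peaks],
                 peak_count = length(peaks),
                 frequency_per_min = length(peaks) / dur_min,
                 min_prominence = min_prominence),
            class = "rq_peaks")
}

#' Detect supra-threshold events in a voltage trace
#'
#' Events are maximal contiguous runs of samples strictly above the
#' action-potential threshold (default -35 mV), extended outward to the
#' surrounding baseline crossings. The baseline is the median of
#' sub-threshold samples ("rmp" mode). AUC is the trapezoidal integral of
#' (voltage - baseline) over the extended event, in mV s; the rate is
#' events per second of the nominal duration.
#'
#' @param vtrace voltage [rq_trace()] (mV).
#' @param threshold_mV event threshold (mV).
#' @param baseline_mode "rmp" (median of sub-threshold samples) or a numeric
#'   baseline in mV.
#' @return list of class `rq_events`: `events` (data.frame onset_s,
#'   offset_s, peak_mV, auc_mVs), `rate_hz`, `threshold_mV`, `baseline_mV`.
#' @export
detect_events <- function(vtrace, threshold_mV = -35, baseline_mode = "rmp") {
  v <- vtrace$value
  t <- vtrace$time_s
  n <- length(v)
  baseline <- if (identical(baseline_mode, "rmp")) {
    sub <- v[v <= threshold_mV]
    if (length(sub)) median(sub) else min(v)
  } else {
    stopifnot(is.numeric(baseline_mode))
    baseline_mode
  }
  above <- v > threshold_mV
  events <- data.frame(onset_s = numeric(), offset_s = numeric(),
                       peak_mV = numeric(), auc_mVs = numeric())
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    # threshold crossings whose extensions meet without an intervening
    # return to baseline belong to the same depolarization: merge them
    # (events must not overlap)
    if (nrow(runs) > 1) {
      merged <- runs[1, , drop = FALSE]
      for (e in 2:nrow(runs)) {
        gap <- (merged[nrow(merged), 2] + 1L):(runs[e, 1] - 1L)
        if (length(gap) == 0 || all(v[gap] > baseline)) {
          merged[nrow(merged), 2] <- runs[e, 2]
        } else {
          merged <- rbind(merged, runs[e, ])
        }
      }
      runs <- merged
    }
    prev_end <- 0L
    rows <- list()
    for (e in seq_len(nrow(runs))) {
      i0 <- runs[e, 1]
      i1 <- runs[e, 2]
      while (i0 - 1L > prev_end && v[i0 - 1L] > baseline) i0 <- i0 - 1L
      nxt <- if (e < nrow(runs)) runs[e + 1, 1] else n + 1L
      while (i1 + 1L < nxt && v[i1 + 1L] > baseline) i1 <- i1 + 1L
      prev_end <- i1
      seg <- i0:i1
      auc <- if (length(seg) > 1)
        sum(diff(t[seg]) * (head(v[seg] - baseline, -1) +
                              tail(v[seg] - baseline, -1)) / 2)
      else 0
      rows[[e]] <- data.frame(onset_s = t[i0], offset_s = t[i1],
                              peak_mV = max(v[runs[e, 1]:runs[e, 2]]),
                              auc_mVs = auc)
    }
    events <- do.call(rbind, rows)
  }
  structure(list(events = events,
                 rate_hz = nrow(events) / .trace_duration(vtrace),
                 threshold_mV = threshold_mV, baseline_mV = baseline),
            class = "rq_events")
}
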
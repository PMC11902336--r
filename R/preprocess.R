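#' Screen a subject for inclusion
#'
#' A subject is excluded when any of the following holds: the outlier fraction
#' of the 1 Hz signal exceeds 1/5; fewer than three distinct sleep stages
#' appear in the hypnogram; sleep efficiency (total sleep time / time in bed)
#' is below 50%; or total sleep time is below five hours. All thresholds are
#' strict, so a subject sitting exactly on a boundary passes.
#'
#' @param rec An `oxi_recording` with a hypnogram.
#' @return A one-row tibble: `subject_id`, `excluded`, `reasons` (comma-joined
#'   subset of `outlier_fraction`, `stage_count`, `sleep_efficiency`,
#'   `total_sleep_time`), `outlier_fraction`, `n_stages`, `sleep_efficiency`,
#'   `tst_min`.
#' @export
screen_subject <- function(rec) {
  if (is.null(rec$hypnogram) || length(rec$hypnogram) == 0)
    stop("screening requires a hypnogram", call. = FALSE)
  sig <- resample_1hz(rec$spo2, rec$fs)
  outlier_fraction <- mean(flag_outliers(sig))
  n_stages <- length(unique(rec$hypnogram))
  tst_min <- sum(rec$hypnogram != "W") * 0.5
  tib_min <- length(rec$hypnogram) * 0.5
  sleep_eff <- tst_min / tib_min
  reasons <- c(
    if (outlier_fraction > 1 / 5) "outlier_fraction",
    if (n_stages < 3) "stage_count",
    if (sleep_eff < 0.5) "sleep_efficiency",
    if (tst_min < 300) "total_sleep_time"
  )
  tibble::tibble(
    subject_id = rec$subject_id %||% NA_character_,
    excluded = length(reasons) > 0,
    reasons = paste(reasons, collapse = ","),
    outlier_fraction = outlier_fraction, n_stages = n_stages,
    sleep_efficiency = sleep_eff, tst_min = tst_min
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove leading and trailing wake from a recording
#'
#' Drops the maximal runs of wake ("W") epochs at both ends of the hypnogram
#' together with the corresponding signal span; interior wake is retained.
#' Event times are shifted to the new origin and events straddling a clip
#' boundary are truncated to the retained span.
#'
#' @param rec An `oxi_recording`.
#' @return The clipped `oxi_recording`.
#' @export
clip_wake_edges <- function(rec) {
  hyp <- rec$hypnogram
  sleep <- which(hyp != "W")
  if (length(sleep) == 0) stop("recording is entirely wake", call. = FALSE)
  first_ep <- sleep[1]
  last_ep <- sleep[length(sleep)]
  keep_start_s <- (first_ep - 1) * 30
  keep_end_s <- last_ep * 30 # half-open [start, end)
  i0 <- floor(keep_start_s * rec$fs) + 1
  i1 <- floor(keep_end_s * rec$fs)
  rec$spo2 <- rec$spo2[i0:i1]
  rec$hypnogram <- hyp[first_ep:last_ep]
  if (nrow(rec$events) > 0) {
    ev <- rec$events
    end_s <- ev$start_s + ev$duration_s
    new_start <- pmax(ev$start_s, keep_start_s)
    new_end <- pmin(end_s, keep_end_s)
    keep <- new_end > new_start
    rec$events <- tibble::tibble(
      start_s = new_start[keep] - keep_start_s,
      duration_s = (new_end - new_start)[keep],
      type = ev$type[keep]
    )
  }
  rec
}

#' Resample a signal to 1 Hz by per-second bin means
#'
#' @param signal Numeric signal at `fs` Hz.
#' @param fs Sampling rate in Hz, at least 1.
#' @return Numeric vector of length `floor(length(signal) / fs)`.
#' @export
resample_1hz <- function(signal, fs) {
  if (fs < 1) stop("sampling rates below 1 Hz are not supported", call. = FALSE)
  if (fs == 1) return(as.numeric(signal))
  n_out <- floor(length(signal) / fs)
  if (n_out == 0) return(numeric(0))
  bin <- floor((seq_along(signal) - 1) / fs)
  keep <- bin < n_out
  as.numeric(tapply(signal[keep], bin[keep], mean))
}

#' Flag physiologically implausible oximetry samples
#'
#' A 1 Hz sample is an outlier when its value is below 60% or above 100%, or
#' when it cannot be reached from the last credible sample at a physiologic
#' slew rate of 4 %/s (a forward walk over in-range samples; an isolated
#' spike is flagged while the level on either side of it is kept).
#'
#' @param signal 1 Hz SpO2 signal.
#' @return Logical mask, `TRUE` at outliers.
#' @export
flag_outliers <- function(signal) {
  mask <- signal < 60 | signal > 100
  good <- which(!mask)
  if (length(good) >= 2) {
    last <- good[1]
    for (i in good[-1]) {
      if (abs(signal[i] - signal[last]) > 4 * (i - last)) mask[i] <- TRUE
      else last <- i
    }
  }
  mask
}

# maximal runs of TRUE in a logical vector -> data.frame(start, length)
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], length = r$lengths[r$values])
}

#' Interpolate short outlier runs (delta filter)
#'
#' Outlier runs shorter than 3 s whose enclosing `window_s` window is at most
#' 10% flagged are replaced by linear interpolation between the nearest valid
#' neighbours; all other runs stay flagged for sample-wise exclusion.
#'
#' @param signal 1 Hz signal.
#' @param mask Outlier mask from [flag_outliers()].
#' @param window_s Window length used to judge the 10% rule (default 30).
#' @return List with the corrected `signal` and the `residual` mask of
#'   uncorrected outliers.
#' @export
delta_filter <- function(signal, mask = flag_outliers(signal), window_s = 30) {
  if (all(mask)) stop("signal entirely flagged; uncorrectable", call. = FALSE)
  n <- length(signal)
  win <- pmin(floor((seq_len(n) - 1) / window_s), max(floor((n - 1) / window_s), 0))
  # flagged fraction of the nominal window length
  frac_by_win <- tapply(mask, win, sum) / window_s
  residual <- mask
  rr <- runs_of(mask)
  valid_idx <- which(!mask)
  for (k in seq_len(nrow(rr))) {
    s <- rr$start[k]; l <- rr$length[k]
    if (l >= 3) next
    wins <- unique(win[s:(s + l - 1)])
    if (any(frac_by_win[as.character(wins)] > 0.10)) next
    left <- max(valid_idx[valid_idx < s], -Inf)
    right <- min(valid_idx[valid_idx > s + l - 1], Inf)
    idx <- s:(s + l - 1)
    signal[idx] <- if (is.finite(left) && is.finite(right)) {
      signal[left] + (signal[right] - signal[left]) * (idx - left) / (right - left)
    } else if (is.finite(left)) signal[left] else signal[right]
    residual[idx] <- FALSE
  }
  list(signal = signal, residual = residual)
}

#' Segment a cleaned recording into labelled fixed-length windows
#'
#' Consecutive non-overlapping `window_s`-second windows (0-based half-open
#' intervals); the trailing partial window is dropped. A window is labelled
#' positive when the annotated-event time inside it strictly exceeds
#' `min_overlap_s` seconds.
#'
#' @param rec A clipped, 1 Hz `oxi_recording`.
#' @param window_s Window length in whole seconds (default 30).
#' @param min_overlap_s Label threshold in seconds (default 5; strict).
#' @return An `oxi_samples` object: list with `segments` (n x window_s matrix),
#'   `labels` (0/1), `index` (original window positions), `n_total`,
#'   `overnight_mean`, `window_s`, `subject_id`.
#' @export
segment_and_label <- function(rec, window_s = 30, min_overlap_s = 5) {
  sig <- rec$spo2
  n_seg <- floor(length(sig) / window_s)
  if (n_seg < 1) stop("signal shorter than one window", call. = FALSE)
  segs <- matrix(sig[seq_len(n_seg * window_s)], nrow = n_seg,
                 ncol = window_s, byrow = TRUE)
  labels <- integer(n_seg)
  if (nrow(rec$events) > 0) {
    ev0 <- rec$events$start_s
    ev1 <- ev0 + rec$events$duration_s
    w0 <- (seq_len(n_seg) - 1) * window_s
    overlap <- vapply(seq_len(n_seg), function(i) {
      sum(pmax(0, pmin(ev1, w0[i] + window_s) - pmax(ev0, w0[i])))
    }, numeric(1))
    labels <- as.integer(overlap > min_overlap_s)
  }
  structure(list(
    segments = segs, labels = labels, index = seq_len(n_seg), n_total = n_seg,
    overnight_mean = mean(sig), window_s = window_s,
    subject_id = rec$subject_id %||% NA_character_
  ), class = "oxi_samples")
}

#' Drop windows invalidated by residual outliers
#'
#' Windows still containing uncorrected (residual) outlier seconds after the
#' delta filter are removed; the original position index `i` within the
#' original count `N` is retained for the survivors so context features keep
#' their temporal meaning.
#'
#' @param samples An `oxi_samples` object.
#' @param residual Residual outlier mask over the cleaned 1 Hz signal.
#' @return The filtered `oxi_samples`.
#' @export
sample_exclude <- function(samples, residual) {
  n_seg <- nrow(samples$segments)
  w <- samples$window_s
  has_res <- vapply(seq_len(n_seg), function(i) {
    any(residual[((i - 1) * w + 1):(i * w)])
  }, logical(1))
  keep <- !has_res
  samples$segments <- samples$segments[keep, , drop = FALSE]
  samples$labels <- samples$labels[keep]
  samples$index <- samples$index[keep]
  samples
}

# linear interpolation across all masked runs (edge runs take the nearest
# valid value); used to bridge residual artifacts for whole-night features
interp_runs <- function(signal, mask) {
  if (!any(mask)) return(signal)
  if (all(mask)) stop("signal entirely flagged; uncorrectable", call. = FALSE)
  idx <- seq_along(signal)
  signal[mask] <- stats::approx(idx[!mask], signal[!mask], xout = idx[mask],
                                rule = 2)$y
  signal
}

#' Full preprocessing for one recording
#'
#' Runs edge clipping, 1 Hz resampling, outlier flagging, the delta filter,
#' segmentation/labelling and sample exclusion, returning both the cleaned
#' recording and its labelled window set.
#'
#' @inheritParams segment_and_label
#' @return List with `recording` (cleaned 1 Hz recording for whole-night
#'   features, residual artifact runs bridged by interpolation), `samples`
#'   (`oxi_samples`; windows still holding residual artifacts are excluded
#'   instead of bridged), `screening` (from [screen_subject()]), `residual`
#'   (the uncorrected outlier mask) and `sleep_s` (retained signal seconds).
#' @export
preprocess_recording <- function(rec, window_s = 30, min_overlap_s = 5) {
  screening <- screen_subject(rec)
  rec <- clip_wake_edges(rec)
  rec$spo2 <- resample_1hz(rec$spo2, rec$fs)
  rec$fs <- 1
  filt <- delta_filter(rec$spo2, flag_outliers(rec$spo2), window_s)
  rec$spo2 <- filt$signal
  samples <- segment_and_label(rec, window_s, min_overlap_s)
  samples <- sample_exclude(samples, filt$residual)
  # whole-night features must not see dropout spikes the sample-wise rule
  # already discarded: bridge residual runs for the global signal only
  grec <- rec
  grec$spo2 <- interp_runs(rec$spo2, filt$residual)
  samples$overnight_mean <- mean(grec$spo2)
  list(recording = grec, samples = samples, screening = screening,
       residual = filt$residual, sleep_s = length(rec$spo2))
}

#' @export
print.oxi_samples <- function(x, ...) {
  cat(sprintf("<oxi_samples> %s: %d/%d windows of %d s, %.1f%% positive\n",
              x$subject_id, nrow(x$segments), x$n_total, x$window_s,
              100 * mean(x$labels)))
  invisible(x)
}
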
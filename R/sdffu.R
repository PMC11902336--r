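#' AHI log transform and its inverse
#'
#' AHI distributions are heavily right-skewed, so regression targets are
#' `log(Y + 1)`; predictions are mapped back with `exp(Y') - 1`. The
#' round-trip is exact to machine precision.
#'
#' @param y AHI values, events/h (>= 0).
#' @return Transformed values.
#' @export
ahi_transform <- function(y) {
  if (any(y < 0)) stop("AHI values must be >= 0", call. = FALSE)
  log1p(y)
}

#' @param yp Transformed values.
#' @rdname ahi_transform
#' @export
ahi_inverse <- function(yp) expm1(yp)

# inverse transform for regressor outputs: the log-scale prediction is first
# clamped to the regressor's training-target range (a ridge solve is linear
# off the training manifold, and extrapolating a bounded clinical index is
# meaningless), then floored at 0 and capped at 200 events/h — an AHI beyond
# 200 is physically impossible at 10 s per event
ahi_from_log <- function(pred, y_range = NULL) {
  if (!is.null(y_range)) pred <- pmin(pmax(pred, y_range[1]), y_range[2])
  pmin(pmax(ahi_inverse(pred), 0), 200)
}

#' Event statistics of a predicted probability/label sequence
#'
#' Summarizes one subject's window predictions for the detection-based AHI
#' regressor: runs of consecutive positive labels are the predicted events.
#'
#' @param p0 Window probabilities in temporal order.
#' @param y0 Binary window labels (default `p0 > 0.5`).
#' @param window_s Window length, seconds.
#' @param sleep_s Subject sleep time, seconds.
#' @return One-row tibble: `event_time_fraction`, `event_len_mean`,
#'   `event_len_sd` (seconds), `frac_p_gt_05`, `frac_p_lt_03`,
#'   `mean_p_on_events`, `mean_p_on_runs` (runs spanning >= 2 windows).
#'   Subjects with no predicted events get zeros.
#' @export
event_stat_features <- function(p0, y0 = as.integer(p0 > 0.5), window_s,
                                sleep_s) {
  r <- rle(as.logical(y0))
  lens <- r$lengths[r$values] * window_s
  run_id <- rep(seq_along(r$lengths), r$lengths)
  long_run <- rep(r$values & r$lengths >= 2, r$lengths)
  on_ev <- y0 == 1
  tibble::tibble(
    event_time_fraction = sum(y0) * window_s / sleep_s,
    event_len_mean = mean0(lens),
    event_len_sd = sd0(lens),
    frac_p_gt_05 = mean(p0 > 0.5),
    frac_p_lt_03 = mean(p0 < 0.3),
    mean_p_on_events = mean0(p0[on_ev]),
    mean_p_on_runs = mean0(p0[long_run])
  )
}

#' Detection-based AHI estimate
#'
#' Applies the fitted event-statistics regressor (trained on log-transformed
#' AHI labels) and inverse-transforms. Log-scale predictions are clamped to
#' the regressor's training-target range (ridge solves extrapolate linearly
#' off the training manifold), and the result is floored at zero.
#'
#' @param features Tibble of [event_stat_features()] rows (plus optional id
#'   columns, which are ignored).
#' @param regressor A fitted `bls` regressor.
#' @return Numeric vector of AHI estimates, events/h.
#' @export
predict_ahis <- function(features, regressor) {
  stopifnot(inherits(regressor, "bls"))
  if (is.null(regressor$w)) stop("regressor is not fitted", call. = FALSE)
  x <- as.matrix(dplyr::select(features, -dplyr::any_of("subject_id")))
  ahi_from_log(predict(regressor, x), regressor$y_range)
}

#' Correct a probability sequence from the global-local AHI difference
#'
#' When the global-feature AHI estimate and the detection-based estimate for
#' a subject differ by more than `trigger` events/h, the unit rescales part of
#' the probability sequence toward the global estimate. The implied
#' respiratory-event difference is `Evend = round(|dAHI| * 60)` (the printed
#' form; `evend_mode = "hours"` uses the dimensionally coherent
#' `|dAHI| * T / 60`). Samples are ranked by probability in descending order;
#' the top `ceiling(top_frac * N)` most confident are skipped and the next
#' `Evend` are multiplied by `(1 + v)` when the global estimate is higher,
#' `(1 - v)` when lower, with `v = 0.5 * Evend * 60 / T * i / N` (`i` the
#' temporal position). Results are clipped to `[0, 1]`.
#'
#' @param p0 Probability sequence for one subject, temporal order.
#' @param ahig Global-feature AHI estimate, events/h.
#' @param ahis Detection-based AHI estimate, events/h.
#' @param t_min Subject sleep duration, minutes.
#' @param trigger Trigger threshold on `|ahig - ahis|` (strict; default 10).
#' @param top_frac Fraction of most-confident samples to skip (default 0.1).
#' @param evend_mode `"verbatim"` or `"hours"` (see above).
#' @return List: `p` (corrected probabilities) and `record`, a one-row tibble
#'   with `ahig`, `ahis`, `triggered`, `evend`, `n_corrected`, `truncated`.
#' @export
correct_probabilities <- function(p0, ahig, ahis, t_min, trigger = 10,
                                  top_frac = 0.1,
                                  evend_mode = c("verbatim", "hours")) {
  evend_mode <- match.arg(evend_mode)
  stopifnot(t_min > 0, length(p0) >= 1)
  n <- length(p0)
  delta <- ahig - ahis
  rec <- tibble::tibble(ahig = ahig, ahis = ahis,
                        triggered = abs(delta) > trigger,
                        evend = 0, n_corrected = 0L, truncated = FALSE)
  if (!rec$triggered) return(list(p = p0, record = rec))
  evend <- if (evend_mode == "verbatim") floor(abs(delta) * 60 + 0.5)
           else floor(abs(delta) * t_min / 60 + 0.5)
  ord <- order(p0, decreasing = TRUE)
  skip <- ceiling(top_frac * n)
  avail <- max(n - skip, 0)
  take <- min(evend, avail)
  rec$evend <- evend
  rec$truncated <- evend > avail
  if (take == 0) return(list(p = p0, record = rec))
  sel <- ord[(skip + 1):(skip + take)] # temporal indices of corrected samples
  v <- 0.5 * evend * 60 / t_min * sel / n
  fac <- if (delta > 0) 1 + v else 1 - v
  p0[sel] <- pmin(pmax(p0[sel] * fac, 0), 1)
  rec$n_corrected <- length(sel)
  list(p = p0, record = rec)
}
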
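#' Detect oxygen desaturation events
#'
#' A desaturation is a maximal run where the signal sits at least `drop_pct`
#' below its local baseline for at least `min_dur_s` seconds. The baseline at
#' each sample is the running maximum of the preceding 120 s, the reference
#' level the saturation held before the drop.
#'
#' @param signal 1 Hz SpO2 signal, percent.
#' @param drop_pct Required drop below baseline, percent (default 3).
#' @param min_dur_s Minimum sustained duration, seconds (default 10).
#' @param baseline_win_s Trailing baseline window, seconds (default 120).
#' @return Tibble with one row per event: `start_s`, `length_s`, `depth`
#'   (baseline minus nadir), `slope` (depth / time from onset to nadir),
#'   `area` (summed baseline-minus-signal over the event).
#' @export
detect_desaturations <- function(signal, drop_pct = 3, min_dur_s = 10,
                                 baseline_win_s = 120) {
  n <- length(signal)
  empty <- tibble::tibble(start_s = numeric(), length_s = numeric(),
                          depth = numeric(), slope = numeric(),
                          area = numeric())
  if (n < min_dur_s) return(empty)
  base <- runmax_prev_cpp(as.numeric(signal), as.integer(baseline_win_s))
  deficit <- base - signal
  rr <- runs_of(deficit >= drop_pct)
  rr <- rr[rr$length >= min_dur_s, , drop = FALSE]
  if (nrow(rr) == 0) return(empty)
  purrr::map_dfr(seq_len(nrow(rr)), function(k) {
    idx <- rr$start[k]:(rr$start[k] + rr$length[k] - 1)
    d <- deficit[idx]
    nadir <- which.max(d)
    tibble::tibble(start_s = rr$start[k] - 1, length_s = rr$length[k],
                   depth = max(d), slope = max(d) / nadir, area = sum(d))
  })
}

# per-window desaturation rule used by the sample features: >= min_dur_s
# consecutive seconds more than 3% below the overnight mean
in_sample_desat_time <- function(x, overnight_mean, min_dur_s = 10) {
  rr <- runs_of(x < overnight_mean - 3)
  sum(rr$length[rr$length >= min_dur_s])
}

# feature vector for one window
segment_features_one <- function(x, overnight_mean) {
  if (any(!is.finite(x))) stop("non-finite values in segment", call. = FALSE)
  s <- sd(x)
  d <- if (length(x) > 1) abs(diff(x)) else 0
  c(
    spo2_min = min(x), spo2_mean = mean(x), spo2_std = s,
    spo2_range = max(x) - min(x),
    min_minus_overnight_mean = min(x) - overnight_mean,
    p_lt95 = mean(x < 95), p_lt90 = mean(x < 90), p_lt80 = mean(x < 80),
    sampen = if (s > 0) sample_entropy(x, m = 1, r = 0.25 * s) else 0,
    permen = perm_entropy(x, m = 3),
    d1_max = max(d), d1_mean = mean(d),
    d1_gt3_frac = sum(d > 3) / length(x),
    desat_frac = in_sample_desat_time(x, overnight_mean) / length(x)
  )
}

#' Per-window (sample) feature matrix
#'
#' Time-domain and nonlinear descriptors of each 30 s window: minimum, mean,
#' SD, range, minimum minus the overnight mean, fractions below 95/90/80%,
#' sample and permutation entropy, first-difference statistics, and the
#' fraction of the window covered by in-window desaturation (>= 10 s more than
#' 3% below the overnight mean).
#'
#' @param samples An `oxi_samples` object from [segment_and_label()] /
#'   [preprocess_recording()].
#' @return Tibble with `subject_id`, `index`, `label` and one column per
#'   feature; one row per retained window.
#' @export
sample_features <- function(samples) {
  stopifnot(inherits(samples, "oxi_samples"))
  n <- nrow(samples$segments)
  feats <- t(vapply(seq_len(n), function(i) {
    segment_features_one(samples$segments[i, ], samples$overnight_mean)
  }, segment_features_one(rep(samples$overnight_mean, samples$window_s),
                          samples$overnight_mean)))
  dplyr::bind_cols(
    tibble::tibble(subject_id = samples$subject_id, index = samples$index,
                   label = samples$labels),
    tibble::as_tibble(feats)
  )
}

#' Names of the whole-night (global) feature registry
#'
#' 39 signal features in five categories — time domain (13), frequency (4),
#' nonlinear (6), morphological/PRSA (5), desaturation (11) — plus four
#' hypoxic-burden summaries and four demographic covariates, in a fixed
#' column order.
#'
#' @return Character vector of feature names.
#' @export
global_feature_names <- function() {
  c(
    # time domain
    "spo2_mean", "spo2_median", "spo2_min", "spo2_std", "spo2_range",
    "p95", "p90", "p85", "m95", "m90", "m85", "zc", "delta_index",
    # frequency
    "psd_total", "psd_band", "psd_ratio", "psd_peak",
    # nonlinear
    "apen", "sampen", "permen", "lz", "dfa_alpha", "ctm",
    # morphological (PRSA)
    "prsa_c", "prsa_ad", "prsa_s", "prsa_sb", "prsa_sa",
    # desaturation
    "odi3", "dl_mean", "dl_sd", "dd_mean", "dd_sd", "ds_mean", "ds_sd",
    "da_mean", "da_sd", "td_mean", "td_sd",
    # hypoxic burden
    "pod", "aod", "ct90", "ca90",
    # demographics
    "age", "bmi", "sex", "smoking"
  )
}

mean0 <- function(x) if (length(x) == 0) 0 else mean(x)
sd0 <- function(x) if (length(x) < 2) 0 else sd(x)

#' Whole-night (global) feature vector
#'
#' Extracts the full overnight oximetry profile of a cleaned 1 Hz recording:
#' time-domain summaries (including below-95/90/85% time and level, zero
#' crossings about the mean, and the delta index over 12 s interval means),
#' Welch spectral power in the 0.03-0.17 Hz band, nonlinear descriptors
#' (approximate/sample/permutation entropy, LZ76 complexity, DFA exponent,
#' central tendency measure), PRSA morphology, desaturation-event statistics
#' (ODI3 and per-event length/depth/slope/area moments plus inter-event
#' times), hypoxic burden (fraction and area of desaturation, CT90, CA90) and
#' demographics.
#'
#' @param rec A cleaned 1 Hz `oxi_recording` (at least 5 minutes of signal).
#' @param demographics Optional tibble/list with `age`, `bmi`, `sex`,
#'   `smoking`; defaults to the recording's own.
#' @return One-row tibble: `subject_id` plus the [global_feature_names()]
#'   columns.
#' @export
global_features <- function(rec, demographics = rec$demographics) {
  x <- rec$spo2
  n <- length(x)
  if (n < 300) stop("signal too short for global features (< 5 min)", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in signal", call. = FALSE)
  hours <- n / 3600
  s <- sd(x)

  # time domain; Mx is the mean of samples below x and degenerates to the
  # threshold itself when no sample lies below (the continuous limit --
  # a zero placeholder would be a wild outlier after standardization)
  mean_or <- function(v, default) if (length(v) == 0) default else mean(v)
  m95 <- mean_or(x[x < 95], 95)
  m90 <- mean_or(x[x < 90], 90)
  m85 <- mean_or(x[x < 85], 85)
  cen <- x - mean(x)
  nz <- cen[cen != 0]
  zc <- if (length(nz) > 1) sum(diff(sign(nz)) != 0) else 0
  nb <- floor(n / 12)
  iv_means <- if (nb >= 2) colMeans(matrix(x[seq_len(nb * 12)], nrow = 12)) else numeric(0)
  dix <- if (length(iv_means) >= 2) mean(abs(diff(iv_means))) else 0

  # frequency
  spec <- welch_psd(x, fs = 1)
  df <- spec$freq[2] - spec$freq[1]
  band <- spec$freq >= 0.03 & spec$freq <= 0.17
  psd_total <- sum(spec$psd[spec$freq > 0]) * df
  psd_band <- sum(spec$psd[band]) * df
  psd_peak <- if (any(band)) max(spec$psd[band]) else 0

  # desaturation events
  ev <- detect_desaturations(x)
  gaps <- if (nrow(ev) >= 2) diff(ev$start_s) else numeric(0)

  vals <- c(
    spo2_mean = mean(x), spo2_median = median(x), spo2_min = min(x),
    spo2_std = s, spo2_range = max(x) - min(x),
    p95 = mean(x < 95), p90 = mean(x < 90), p85 = mean(x < 85),
    m95 = m95, m90 = m90, m85 = m85, zc = as.numeric(zc), delta_index = dix,
    psd_total = psd_total, psd_band = psd_band,
    psd_ratio = if (psd_total > 0) psd_band / psd_total else 0,
    psd_peak = psd_peak,
    apen = if (s > 0) approx_entropy(x, m = 1, r = 0.25 * s) else 0,
    sampen = if (s > 0) sample_entropy(x, m = 1, r = 0.25 * s) else 0,
    permen = perm_entropy(x, m = 3),
    lz = lz_complexity(x),
    dfa_alpha = dfa_exponent(x),
    ctm = ctm_measure(x, rho = 1),
    prsa_features(x, t_win = 10),
    odi3 = nrow(ev) / hours,
    dl_mean = mean0(ev$length_s), dl_sd = sd0(ev$length_s),
    dd_mean = mean0(ev$depth), dd_sd = sd0(ev$depth),
    ds_mean = mean0(ev$slope), ds_sd = sd0(ev$slope),
    da_mean = mean0(ev$area), da_sd = sd0(ev$area),
    td_mean = mean0(gaps), td_sd = sd0(gaps),
    pod = sum(ev$length_s) / n,
    aod = sum(ev$area) / hours,
    ct90 = mean(x < 90),
    ca90 = sum(pmax(0, 90 - x)) / hours
  )
  demo <- c(
    age = as.numeric(demographics$age %||% 0),
    bmi = as.numeric(demographics$bmi %||% 0),
    sex = as.numeric(demographics$sex %||% 0),
    smoking = as.numeric(demographics$smoking %||% 0)
  )
  out <- tibble::as_tibble(as.list(c(vals, demo)))
  out <- out[, global_feature_names()]
  dplyr::bind_cols(tibble::tibble(subject_id = rec$subject_id %||% NA_character_), out)
}
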
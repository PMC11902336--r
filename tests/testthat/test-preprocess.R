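test_that("screening keeps clean subjects and applies the strict thresholds", {
  # 420 min of sleep, 4 stages, clean signal
  hyp <- c(rep("W", 6), rep(c("N1", "N2", "N3", "REM"), length.out = 840),
           rep("W", 6))
  rec <- make_rec(rep(96, length(hyp) * 30), hyp)
  rep1 <- screen_subject(rec)
  expect_false(rep1$excluded)
  expect_identical(rep1$reasons, "")

  # 25% artifact samples -> excluded for outlier fraction
  sig <- rep(96, length(hyp) * 30)
  sig[seq_len(round(0.25 * length(sig)))] <- 0
  rep2 <- screen_subject(make_rec(sig, hyp))
  expect_true(rep2$excluded)
  expect_match(rep2$reasons, "outlier_fraction")

  # five-hour rule is strict: 299.5 min fails, 300 min passes
  hyp299 <- c(rep("N2", 299), rep("N3", 300), rep("W", 601))
  rep3 <- screen_subject(make_rec(rep(96, length(hyp299) * 30), hyp299))
  expect_true(rep3$excluded)
  expect_match(rep3$reasons, "total_sleep_time")
  hyp300 <- c(rep("N2", 300), rep("N3", 300), rep("W", 600))
  rep4 <- screen_subject(make_rec(rep(96, length(hyp300) * 30), hyp300))
  expect_false(rep4$excluded)

  # sleep efficiency exactly 50% passes (strict "lower than")
  expect_equal(rep4$sleep_efficiency, 0.5)
  expect_error(screen_subject(make_rec(rep(96, 100), character(0))),
               "hypnogram")
})

test_that("edge clipping removes only leading/trailing wake and shifts events", {
  hyp <- c("W", "W", "N2", "N2", "W")
  ev <- tibble::tibble(start_s = c(50, 70, 110), duration_s = c(15, 20, 30),
                       type = rep("apnea", 3))
  rec <- make_rec(seq_len(150), hyp, ev)
  out <- clip_wake_edges(rec)
  expect_identical(out$hypnogram, c("N2", "N2"))
  expect_equal(out$spo2, 61:120)
  # interval-intersection oracle on the retained span [60, 120)
  raw <- cbind(pmax(ev$start_s, 60), pmin(ev$start_s + ev$duration_s, 120))
  keep <- raw[, 2] > raw[, 1]
  expect_equal(out$events$start_s, raw[keep, 1] - 60)
  expect_equal(out$events$duration_s, (raw[, 2] - raw[, 1])[keep])

  rec2 <- make_rec(seq_len(60), c("N2", "N2"))
  expect_identical(clip_wake_edges(rec2)$spo2, rec2$spo2)
  expect_error(clip_wake_edges(make_rec(seq_len(60), c("W", "W"))), "wake")
})

test_that("resampling takes per-second bin means", {
  expect_equal(resample_1hz(c(96, 96, 95, 97), 2), c(96, 96))
  expect_equal(resample_1hz(c(1, 2, 3), 1), c(1, 2, 3))
  expect_equal(resample_1hz(rep(95, 40), 4), rep(95, 10))
  expect_error(resample_1hz(1:10, 0.5), "not supported")
})

test_that("outlier flagging matches the range and delta rules", {
  expect_false(any(flag_outliers(rep(97, 20))))
  sig <- rep(97, 10)
  sig[5] <- 0
  m <- flag_outliers(sig)
  expect_true(m[5]) # the spike, whose adjacent steps violate the delta rule
  expect_false(any(m[-5])) # the level on either side stays credible
  # an in-range spike unreachable at 4 %/s is also flagged
  sig2 <- rep(97, 10)
  sig2[5] <- 90
  expect_identical(which(flag_outliers(sig2)), 5L)
  ramp <- 97 - cumsum(rep(1, 8)) # physiologic 1 %/s fall
  expect_false(any(flag_outliers(c(rep(97, 5), ramp, rev(ramp), rep(97, 5)))))
})

test_that("delta filter interpolates only short sparse runs", {
  out <- delta_filter(c(97, 0, 97))
  expect_equal(out$signal, c(97, 97, 97))
  expect_false(any(out$residual))

  # run of exactly 3 s is NOT interpolated (rule is strictly under 3 s)
  sig <- c(rep(97, 20), rep(0, 3), rep(97, 20))
  out3 <- delta_filter(sig)
  expect_equal(out3$signal[21:23], c(0, 0, 0))
  expect_true(all(out3$residual[21:23]))

  sig2 <- rep(c(95, 96), 20)
  out2 <- delta_filter(sig2)
  expect_equal(out2$signal, sig2)
  expect_false(any(out2$residual))
  expect_error(delta_filter(rep(0, 10)), "uncorrectable")
})

test_that("segmentation counts and the 5 s label rule are exact", {
  rec <- make_rec(rep(96, 3600), rep("N2", 120))
  ss <- segment_and_label(rec, 30)
  expect_equal(nrow(ss$segments), 120)
  expect_true(all(ss$labels == 0))

  # event overlapping the first window by exactly 5 s -> label 0 (strict)
  ev5 <- tibble::tibble(start_s = 25, duration_s = 15, type = "apnea")
  rec5 <- make_rec(rep(96, 120), rep("N2", 4), ev5)
  expect_equal(segment_and_label(rec5, 30)$labels[1], 0L)
  ev6 <- tibble::tibble(start_s = 24, duration_s = 16, type = "apnea")
  rec6 <- make_rec(rep(96, 120), rep("N2", 4), ev6)
  expect_equal(segment_and_label(rec6, 30)$labels[1], 1L)

  expect_error(segment_and_label(make_rec(rep(96, 20), "N2"), 30), "shorter")
})

test_that("sample exclusion drops only windows with residual artifacts", {
  rec <- make_rec(rep(96, 300), rep("N2", 10))
  ss <- segment_and_label(rec, 30)
  none <- sample_exclude(ss, rep(FALSE, 300))
  expect_identical(none$segments, ss$segments)

  # a label-0 window holding a 5 s residual run is removed
  residual <- rep(FALSE, 300)
  residual[40:44] <- TRUE
  out <- sample_exclude(ss, residual)
  expect_equal(nrow(out$segments), 9)
  expect_false(2 %in% out$index)
  expect_equal(out$n_total, 10)

  # an interpolated (non-residual) run does not remove a labelled window
  ev <- tibble::tibble(start_s = 30, duration_s = 20, type = "apnea")
  rec1 <- make_rec(rep(96, 300), rep("N2", 10), ev)
  ss1 <- segment_and_label(rec1, 30)
  expect_equal(ss1$labels[2], 1L)
  out1 <- sample_exclude(ss1, rep(FALSE, 300))
  expect_true(2 %in% out1$index)
})

test_that("cleaning is idempotent and clean cohorts lose no windows", {
  rec <- simulate_recording(synth_config(duration_min = 60,
                                         event_rate_per_hour = 20,
                                         artifact_rate_per_hour = 2, seed = 13))
  p1 <- preprocess_recording(rec)
  p2 <- preprocess_recording(p1$recording)
  expect_equal(p2$recording$spo2, p1$recording$spo2, tolerance = 1e-12)

  clean <- simulate_recording(synth_config(duration_min = 60,
                                           event_rate_per_hour = 20,
                                           artifact_rate_per_hour = 0,
                                           seed = 13))
  pc <- preprocess_recording(clean)
  expect_equal(nrow(pc$samples$segments), pc$samples$n_total)

  # label conservation: positives bounded by events x windows per event
  ev_n <- nrow(clean$events)
  max_dur <- max(clean$events$duration_s)
  expect_lte(sum(pc$samples$labels), ev_n * (ceiling(max_dur / 30) + 1))
})
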
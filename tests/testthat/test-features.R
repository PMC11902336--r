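seg_set <- function(seg, overnight_mean, label = 0L) {
  structure(list(
    segments = matrix(seg, nrow = 1), labels = label, index = 1L,
    n_total = 1L, overnight_mean = overnight_mean,
    window_s = length(seg), subject_id = "T001"
  ), class = "oxi_samples")
}

test_that("sample features of a constant window take their forced values", {
  f <- sample_features(seg_set(rep(95, 30), 95))
  expect_equal(f$spo2_min, 95)
  expect_equal(f$spo2_mean, 95)
  expect_equal(f$spo2_std, 0)
  expect_equal(f$spo2_range, 0)
  expect_equal(f$min_minus_overnight_mean, 0)
  expect_equal(f$p_lt95 + f$p_lt90 + f$p_lt80, 0)
  expect_equal(f$sampen, 0)
  expect_equal(f$permen, 0)
  expect_equal(f$d1_max + f$d1_mean + f$d1_gt3_frac, 0)
  expect_equal(f$desat_frac, 0)
})

test_that("in-window desaturation fraction follows the 10 s / 3% rule", {
  seg <- rep(96, 30)
  seg[10:21] <- 91 # 12 s more than 3% below an overnight mean of 96
  f <- sample_features(seg_set(seg, 96))
  expect_equal(f$desat_frac, 12 / 30)
  seg9 <- rep(96, 30)
  seg9[10:18] <- 91 # only 9 s: below the duration floor
  expect_equal(sample_features(seg_set(seg9, 96))$desat_frac, 0)
})

test_that("first-difference features see a single step", {
  seg <- c(rep(97, 15), rep(93, 15))
  f <- sample_features(seg_set(seg, 97))
  expect_equal(f$d1_max, 4)
  expect_equal(f$d1_gt3_frac, 1 / 30)
})

test_that("sample features are translation-consistent", {
  withr::local_seed(4)
  seg <- 94 + cumsum(rnorm(30, 0, 0.4))
  f0 <- sample_features(seg_set(seg, 95))
  f1 <- sample_features(seg_set(seg + 7, 95 + 7))
  shift_cols <- c("spo2_min", "spo2_mean")
  for (cl in shift_cols) expect_equal(f1[[cl]], f0[[cl]] + 7, tolerance = 1e-10)
  same_cols <- c("spo2_std", "spo2_range", "min_minus_overnight_mean",
                 "sampen", "permen", "d1_max", "d1_mean", "d1_gt3_frac",
                 "desat_frac")
  for (cl in same_cols) expect_equal(f1[[cl]], f0[[cl]], tolerance = 1e-10)
})

test_that("desaturation detector finds constructed dips and not shallow ones", {
  expect_equal(nrow(detect_desaturations(rep(96, 600))), 0)

  dip <- c(rep(96, 200), 96 - 5 * c(seq(0, 1, length.out = 15),
                                    seq(1, 0, length.out = 15)), rep(96, 200))
  ev <- detect_desaturations(dip)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$depth, 5, tolerance = 1e-9)

  shallow <- c(rep(96, 200), rep(93.5, 30), rep(96, 200))
  expect_equal(nrow(detect_desaturations(shallow)), 0)
})

test_that("desaturation counts are additive over disjoint halves", {
  mk <- function(n_dips, seed) {
    sig <- rep(96, 1800)
    starts <- seq(100, 1600, length.out = n_dips)
    for (s in starts) sig[s:(s + 24)] <- 91
    sig
  }
  a <- mk(4)
  b <- mk(3)
  expect_equal(nrow(detect_desaturations(c(a, b))),
               nrow(detect_desaturations(a)) + nrow(detect_desaturations(b)))
})

test_that("global features of a constant night are degenerate and finite", {
  rec <- make_rec(rep(97, 3600), rep("N2", 120))
  g <- global_features(rec)
  expect_equal(g$spo2_std, 0)
  expect_equal(g$spo2_range, 0)
  expect_equal(g$zc, 0)
  expect_equal(g$odi3, 0)
  expect_equal(g$ct90, 0)
  expect_equal(g$prsa_c, 0)
  expect_true(all(is.finite(as.matrix(g[, -1]))))
  expect_error(global_features(make_rec(rep(97, 100), "N2")), "short")
})

test_that("the registry has 39 signal features in stable order plus extras", {
  nm <- global_feature_names()
  expect_length(nm, 47)
  expect_length(setdiff(nm, c("pod", "aod", "ct90", "ca90",
                              "age", "bmi", "sex", "smoking")), 39)
  rec <- simulate_recording(synth_config(duration_min = 60,
                                         event_rate_per_hour = 20, seed = 4))
  p <- preprocess_recording(rec)
  g <- global_features(p$recording, rec$demographics)
  expect_identical(colnames(g), c("subject_id", nm))
  expect_true(all(is.finite(as.matrix(g[, -1]))))
  expect_gte(g$pod, 0)
  expect_lte(g$pod, 1)
  expect_lte(g$ct90, 1)
})

test_that("ODI3 counts constructed desaturations per hour", {
  sig <- rep(96, 3600)
  starts <- seq(100, 3300, length.out = 8)
  for (s in starts) sig[s:(s + 24)] <- 91.5 # depth 4.5, 25 s
  rec <- make_rec(sig, rep("N2", 120))
  expect_equal(global_features(rec)$odi3, 8)
})

test_that("band and total spectral power are consistent", {
  withr::local_seed(6)
  x <- 96 + stats::filter(rnorm(6000), rep(1, 10), sides = 1)
  x[is.na(x)] <- 96
  rec <- make_rec(as.numeric(x), rep("N2", 200))
  g <- global_features(rec)
  spec <- welch_psd(as.numeric(x))
  df <- spec$freq[2] - spec$freq[1]
  out_band <- sum(spec$psd[spec$freq > 0 &
                             (spec$freq < 0.03 | spec$freq > 0.17)]) * df
  expect_equal(g$psd_total, g$psd_band + out_band, tolerance = 0.01 * g$psd_total)
  expect_gte(g$psd_ratio, 0)
  expect_lte(g$psd_ratio, 1)
})
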
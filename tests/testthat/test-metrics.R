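test_that("perfect agreement saturates the classification metrics", {
  y <- factor(rep(c("a", "b", "c"), 10))
  m <- classification_metrics(y, y)
  expect_equal(m$acc, 1)
  expect_equal(m$mf1, 1)
  expect_equal(m$kappa, 1)
})

test_that("all-positive predictions on balanced truth give chance kappa", {
  y <- rep(0:1, 50)
  m <- classification_metrics(y, rep(1, 100))
  expect_equal(m$acc, 0.5)
  expect_equal(m$kappa, 0)
  expect_equal(m$recall, 1)    # positive-class recall
  expect_equal(m$precision, 0.5)
})

test_that("classes absent from truth and prediction are excluded from MF1", {
  y_true <- factor(c("a", "a", "b"), levels = c("a", "b", "z"))
  y_pred <- factor(c("a", "a", "b"), levels = c("a", "b", "z"))
  expect_equal(classification_metrics(y_true, y_pred)$mf1, 1)
  expect_error(classification_metrics(integer(0), integer(0)), "non-empty")
})

test_that("kappa and macro F1 match independent references on random draws", {
  skip_if_not_installed("e1071")
  withr::local_seed(23)
  for (k in 1:100) {
    n <- sample(20:60, 1)
    n_cls <- sample(2:4, 1)
    yt <- sample(seq_len(n_cls), n, replace = TRUE)
    yp <- ifelse(runif(n) < 0.6, yt, sample(seq_len(n_cls), n, replace = TRUE))
    m <- classification_metrics(yt, yp)
    lev <- sort(unique(c(yt, yp)))
    tab <- table(factor(yt, levels = lev), factor(yp, levels = lev))
    expect_equal(m$kappa, e1071::classAgreement(tab)$kappa, tolerance = 1e-10)
    expect_equal(m$mf1, mf1_bf(yt, yp), tolerance = 1e-10)
  }
})

test_that("ICC(2,1) matches the ANOVA oracle and its known behaviours", {
  expect_equal(icc21(1:10, 1:10), 1)
  withr::local_seed(24)
  for (k in 1:100) {
    n <- sample(10:40, 1)
    yt <- rnorm(n, 20, 8)
    yp <- yt + rnorm(n, 0, 3) + runif(1, -4, 4)
    expect_equal(icc21(yt, yp), icc21_aov(yt, yp), tolerance = 1e-10)
  }
  # absolute agreement penalizes a constant offset
  yt <- c(4, 8, 15, 16, 23, 42)
  expect_lt(icc21(yt, yt + 5), 1)
  expect_equal(icc21(c(1, 2, 3, 4), c(4, 3, 2, 1)),
               icc21_aov(c(1, 2, 3, 4), c(4, 3, 2, 1)), tolerance = 1e-10)
})

test_that("regression metrics report both R2 conventions", {
  yt <- c(2, 9, 14, 28, 33)
  m0 <- regression_metrics(yt, yt)
  expect_equal(m0$mae, 0)
  expect_equal(m0$rmse, 0)
  expect_equal(m0$icc, 1)
  expect_equal(m0$r2, 1)
  expect_equal(m0$r2_paper, 1)

  m1 <- regression_metrics(yt, yt + 3)
  expect_equal(m1$mae, 3)
  expect_equal(m1$rmse, 3)
  expect_lt(m1$icc, 1)
  # printed form measures prediction spread about the LABEL mean
  expect_equal(m1$r2_paper,
               sum((yt + 3 - mean(yt))^2) / sum((yt - mean(yt))^2),
               tolerance = 1e-12)
  expect_lt(m1$r2, 1)

  # overshooting predictions push the printed R2 above 1
  m2 <- regression_metrics(yt, mean(yt) + 2 * (yt - mean(yt)))
  expect_gt(m2$r2_paper, 1)
  expect_gte(m2$rmse, m2$mae)
  expect_error(regression_metrics(rep(3, 5), 1:5), "variance")
})

test_that("Bland-Altman limits bracket the mean difference symmetrically", {
  b0 <- bland_altman_summary(1:5, 1:5)
  expect_equal(c(b0$mean_diff, b0$lower, b0$upper), c(0, 0, 0))
  b1 <- bland_altman_summary(c(5, 7), c(6, 6))
  expect_equal(b1$mean_diff, 0)
  expect_equal(b1$sd_diff, sqrt(2), tolerance = 1e-12)
  expect_equal(b1$upper, 1.96 * sqrt(2), tolerance = 1e-12)
  withr::local_seed(25)
  yt <- rnorm(30)
  yp <- yt + rnorm(30)
  b <- bland_altman_summary(yt, yp)
  expect_equal(b$upper - b$mean_diff, b$mean_diff - b$lower, tolerance = 1e-12)
})

test_that("severity bins are left-closed at 5/15/30 with consistent binaries", {
  s <- severity_from_ahi(c(0, 4.99, 5, 14.99, 15, 29.99, 30, 80))
  expect_equal(as.character(s$severity),
               c("none", "none", "mild", "mild", "moderate", "moderate",
                 "severe", "severe"))
  expect_equal(s$sev5, c(0, 0, 1, 1, 1, 1, 1, 1))
  expect_equal(s$sev15, c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(s$sev30, c(0, 0, 0, 0, 0, 0, 1, 1))
  expect_error(severity_from_ahi(-2), ">= 0")

  # binaries are coarsenings of the four-class grade for arbitrary values
  withr::local_seed(26)
  a <- runif(200, 0, 90)
  s2 <- severity_from_ahi(a)
  expect_identical(s2$sev5 == 1, s2$severity != "none")
  expect_identical(s2$sev15 == 1, s2$severity %in% c("moderate", "severe"))
  expect_identical(s2$sev30 == 1, s2$severity == "severe")
})

test_that("the counting AHI divides predicted runs by sleep hours", {
  expect_equal(ahi_from_labels(c(1, 1, 0, 1, 0, 1), t_min = 60), 3)
  expect_equal(ahi_from_labels(rep(0, 10), t_min = 330), 0)
})
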
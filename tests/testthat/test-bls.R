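rand_problem <- function(n = 60, d = 8, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * d), n, d)
    y <- x %*% rnorm(d) + rnorm(n, 0, 0.1)
    list(x = x, y = as.numeric(y))
  })
}

test_that("identity-map BLS without enhancement is exactly ridge regression", {
  pr <- rand_problem(seed = 2)
  lam <- 0.5
  cfg <- bls_config(n_feature_groups = 1, feature_map = "identity",
                    n_enhancement = 0, ridge_lambda = lam, task = "regress",
                    seed = 1)
  fit <- bls_fit(pr$x, pr$y, cfg)
  xs <- scale(pr$x, center = colMeans(pr$x),
              scale = sqrt(colMeans(scale(pr$x, scale = FALSE)^2)))
  w_oracle <- ridge_oracle(xs, matrix(pr$y), lam)
  expect_equal(as.numeric(fit$w), as.numeric(w_oracle), tolerance = 1e-8)
})

test_that("fitted weights satisfy the ridge normal equations", {
  pr <- rand_problem(n = 100, d = 10, seed = 3)
  cfg <- bls_config(task = "regress", seed = 4)
  fit <- bls_fit(pr$x, pr$y, cfg)
  a <- oxibls:::design_matrix(fit, pr$x)
  resid <- crossprod(a) %*% fit$w + cfg$ridge_lambda * fit$w -
    crossprod(a, matrix(pr$y))
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("fits are bit-identical under the same seed", {
  pr <- rand_problem(seed = 5)
  cfg <- bls_config(task = "regress", seed = 77)
  f1 <- bls_fit(pr$x, pr$y, cfg)
  f2 <- bls_fit(pr$x, pr$y, cfg)
  expect_identical(f1$w, f2$w)
  f3 <- bls_fit(pr$x, pr$y, bls_config(task = "regress", seed = 78))
  expect_false(identical(f3$w, f1$w))
})

test_that("row duplication with doubled ridge leaves the weights unchanged", {
  pr <- rand_problem(seed = 6)
  lam <- 0.3
  cfg1 <- bls_config(task = "regress", ridge_lambda = lam, seed = 9)
  cfg2 <- bls_config(task = "regress", ridge_lambda = 2 * lam, seed = 9)
  f1 <- bls_fit(pr$x, pr$y, cfg1)
  f2 <- bls_fit(rbind(pr$x, pr$x), c(pr$y, pr$y), cfg2)
  expect_equal(f1$w, f2$w, tolerance = 1e-8)
})

test_that("enhancement nodes lift a nonlinear (XOR) problem above linear", {
  withr::local_seed(10)
  x <- matrix(runif(400, -1, 1), 200, 2)
  y <- factor(as.integer(x[, 1] * x[, 2] > 0), levels = 0:1)
  lin <- bls_fit(x, y, bls_config(n_feature_groups = 1,
                                  feature_map = "identity", n_enhancement = 0,
                                  ridge_lambda = 1e-6, seed = 2))
  enh <- bls_fit(x, y, bls_config(n_enhancement = 100, ridge_lambda = 1e-6,
                                  seed = 2))
  acc <- function(fit) mean(predict(fit, x, type = "class") == y)
  expect_gt(acc(enh), acc(lin))
})

test_that("predictions are row-equivariant and self-consistent", {
  pr <- rand_problem(seed = 11)
  fit <- bls_fit(pr$x, pr$y, bls_config(task = "regress", seed = 3))
  p <- predict(fit, pr$x)
  expect_lt(sqrt(mean((p - pr$y)^2)), sd(pr$y)) # within ridge bias
  perm <- sample(nrow(pr$x))
  expect_equal(predict(fit, pr$x[perm, ]), p[perm], tolerance = 1e-12)
})

test_that("affine rescaling of an input column leaves predictions unchanged", {
  pr <- rand_problem(seed = 12)
  cfg <- bls_config(task = "regress", seed = 5)
  f1 <- bls_fit(pr$x, pr$y, cfg)
  x2 <- pr$x
  x2[, 3] <- 100 * x2[, 3] - 40
  f2 <- bls_fit(x2, pr$y, cfg)
  xt <- matrix(rnorm(40), 5, 8)
  xt2 <- xt
  xt2[, 3] <- 100 * xt2[, 3] - 40
  expect_equal(predict(f2, xt2), predict(f1, xt), tolerance = 1e-8)
})

test_that("a zero increment reproduces the base model exactly", {
  pr <- rand_problem(seed = 13)
  cfg <- bls_config(task = "regress", seed = 6)
  base <- bls_fit(pr$x, pr$y, cfg)
  inc <- bls_fit_incremental(base, pr$x, matrix(0, nrow(pr$x), 2), pr$y)
  expect_equal(predict(inc, pr$x, x_inc = matrix(0, nrow(pr$x), 2)),
               predict(base, pr$x), tolerance = 1e-8)
})

test_that("incremental refit equals the direct solve on the augmented design", {
  for (s in 1:5) {
    pr <- rand_problem(n = 50, d = 6, seed = 20 + s)
    x_inc <- withr::with_seed(40 + s, matrix(rnorm(50 * 3), 50, 3))
    cfg <- bls_config(task = "regress", seed = 7)
    base <- bls_fit(pr$x, pr$y, cfg)
    inc <- bls_fit_incremental(base, pr$x, x_inc, pr$y)
    a_aug <- oxibls:::design_matrix(inc, pr$x, x_inc)
    w_oracle <- ridge_oracle(a_aug, matrix(pr$y), cfg$ridge_lambda)
    expect_equal(as.numeric(inc$w), as.numeric(w_oracle), tolerance = 1e-8)
  }
})

test_that("a leaky increment drives training error to zero as ridge vanishes", {
  pr <- rand_problem(seed = 30)
  errs <- vapply(c(1, 1e-4, 1e-8), function(lam) {
    cfg <- bls_config(task = "regress", ridge_lambda = lam, seed = 8)
    base <- bls_fit(pr$x, pr$y, cfg)
    inc <- bls_fit_incremental(base, pr$x, matrix(pr$y), pr$y)
    sqrt(mean((predict(inc, pr$x, x_inc = matrix(pr$y)) - pr$y)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
})

test_that("models survive a save/load round trip bit-exactly", {
  pr <- rand_problem(seed = 31)
  fit <- bls_fit(pr$x, pr$y, bls_config(task = "regress", seed = 2))
  path <- withr::local_tempfile(fileext = ".rds")
  bls_save(fit, path)
  back <- bls_load(path)
  expect_identical(predict(back, pr$x), predict(fit, pr$x))
})

test_that("invalid inputs are refused", {
  pr <- rand_problem(seed = 32)
  expect_error(bls_config(ridge_lambda = 0), "ridge_lambda")
  bad <- pr$x
  bad[1, 1] <- NA
  expect_error(bls_fit(bad, pr$y, bls_config(task = "regress")), "missing")
  base <- bls_fit(pr$x, pr$y, bls_config(task = "regress"))
  expect_error(bls_fit_incremental(base, pr$x, matrix(0, 3, 1), pr$y),
               "same number of rows")
  expect_error(bls_fit(pr$x, rep(1, nrow(pr$x)),
                       bls_config(task = "classify")), "two classes")
})

test_that("tidy and glance summarize fitted models", {
  pr <- rand_problem(seed = 33)
  fit <- bls_fit(pr$x, pr$y, bls_config(task = "regress", seed = 2))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(fit$w))
  gl <- glance(fit)
  expect_identical(gl$task, "regress")
  expect_equal(gl$n_train, nrow(pr$x))
})
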
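#' Classification metrics
#'
#' Accuracy, macro F1 (unweighted mean of per-class F1 over classes present
#' in truth or prediction), Cohen's kappa (marginal-product chance
#' agreement), recall, precision and specificity. For binary tasks
#' recall/precision/specificity refer to the positive class (the highest
#' level); for more classes they are macro-averaged. Classes absent from both
#' vectors are excluded from macro averages.
#'
#' @param y_true,y_pred Equal-length label vectors (coerced to a common
#'   factor).
#' @return One-row tibble: `acc`, `mf1`, `kappa`, `recall`, `precision`,
#'   `specificity`, `n`.
#' @export
classification_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred))
    stop("label vectors must be non-empty and equal length", call. = FALSE)
  lev <- if (is.factor(y_true)) union(levels(y_true), levels(factor(y_pred)))
         else sort(unique(c(as.character(y_true), as.character(y_pred))))
  yt <- factor(y_true, levels = lev)
  yp <- factor(y_pred, levels = lev)
  cm <- table(yt, yp)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  p_o <- acc
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)

  present <- rowSums(cm) + colSums(cm) > 0
  per_class <- purrr::map_dfr(which(present), function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    tn <- n - tp - fp - fn
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    pre <- if (tp + fp > 0) tp / (tp + fp) else 0
    tibble::tibble(
      recall = rec, precision = pre,
      specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
      f1 = if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
    )
  })
  binary <- sum(present) == 2
  pick <- if (binary) nrow(per_class) else seq_len(nrow(per_class))
  tibble::tibble(
    acc = acc, mf1 = mean(per_class$f1), kappa = kappa,
    recall = mean(per_class$recall[pick]),
    precision = mean(per_class$precision[pick]),
    specificity = mean(per_class$specificity[pick]),
    n = n
  )
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, single-rater, absolute-agreement ICC between two
#' sequences, from the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with `k = 2` raters.
#'
#' @param y_true,y_pred Equal-length numeric vectors (n >= 2).
#' @return ICC(2,1) value.
#' @export
icc21 <- function(y_true, y_pred) {
  n <- length(y_true)
  stopifnot(n >= 2, length(y_pred) == n)
  dat <- cbind(y_true, y_pred)
  k <- 2
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  grand <- mean(dat)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((dat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Regression metrics for AHI prediction
#'
#' MAE, RMSE, the printed variance-ratio R2 (`sum((yhat - ybar)^2) /
#' sum((y - ybar)^2)`, reported as `r2_paper`; it can exceed 1 when
#' predictions overshoot), the conventional `1 - SSres/SStot` R2, and
#' ICC(2,1).
#'
#' @param y_true,y_pred Equal-length numeric vectors (n >= 2).
#' @return One-row tibble: `mae`, `rmse`, `r2_paper`, `r2`, `icc`, `n`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  n <- length(y_true)
  if (n < 2 || length(y_pred) != n)
    stop("need n >= 2 paired values", call. = FALSE)
  if (var(y_true) == 0)
    stop("zero variance in `y_true`: R2 and ICC undefined", call. = FALSE)
  err <- y_true - y_pred
  ybar <- mean(y_true)
  tibble::tibble(
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    r2_paper = sum((y_pred - ybar)^2) / sum((y_true - ybar)^2),
    r2 = 1 - sum(err^2) / sum((y_true - ybar)^2),
    icc = icc21(y_true, y_pred),
    n = n
  )
}

#' Bland-Altman summary of two sequences
#'
#' Mean difference and the limits of agreement at +/- 1.96 sample SDs of the
#' differences.
#'
#' @param y_true,y_pred Equal-length numeric vectors (n >= 2).
#' @return One-row tibble: `mean_diff`, `lower`, `upper`, `sd_diff`, `n`.
#' @export
bland_altman_summary <- function(y_true, y_pred) {
  n <- length(y_true)
  stopifnot(n >= 2, length(y_pred) == n)
  d <- y_pred - y_true
  m <- mean(d)
  s <- if (all(d == d[1])) 0 else sd(d)
  tibble::tibble(mean_diff = m, lower = m - 1.96 * s, upper = m + 1.96 * s,
                 sd_diff = s, n = n)
}
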
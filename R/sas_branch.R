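#' Initial per-window SAS detection
#'
#' Applies a fitted BLS classifier to the per-window features and returns the
#' positive-class softmax probability `p0` and its 0.5-thresholded label `y0`.
#'
#' @param features Tibble from [sample_features()] (feature columns are
#'   everything except `subject_id`, `index`, `label`).
#' @param model A fitted `bls` classifier (positive class `"1"`).
#' @return The input tibble with `p0` and `y0` columns appended.
#' @export
initial_detect <- function(features, model) {
  stopifnot(inherits(model, "bls"))
  if (is.null(model$w)) stop("model is not fitted", call. = FALSE)
  x <- feature_cols(features)
  p <- predict(model, x, type = "prob")[, "1"]
  dplyr::mutate(features, p0 = as.numeric(p), y0 = as.integer(p > 0.5))
}

feature_cols <- function(tb) {
  as.matrix(dplyr::select(tb, -dplyr::any_of(c("subject_id", "index", "label",
                                               "p0", "y0", "p0c", "ctx_p",
                                               "final_p", "final_label"))))
}

#' Context expansion of a probability sequence
#'
#' For one subject's window-ordered probabilities, builds the five-column
#' context matrix (probabilities at positions i-2 ... i+2, out-of-range
#' positions padded), per-window context statistics of the 0.5-thresholded
#' context (event count, total, average and maximum run length inside the
#' five-window), and the run-length indicator `llen` that marks windows lying
#' in a thresholded run of length >= 3 over the full sequence.
#'
#' @param p Probability vector in temporal order for one subject.
#' @param pad `"zero"` (no evidence beyond the record) or `"edge"`
#'   replication for the boundary rows.
#' @return Matrix with 10 named columns: `pcon_m2 ... pcon_p2`,
#'   `ctx_n_events`, `ctx_total_len`, `ctx_avg_len`, `ctx_max_len`, `llen`.
#' @export
build_context <- function(p, pad = c("zero", "edge")) {
  pad <- match.arg(pad)
  n <- length(p)
  if (n < 1) stop("empty probability sequence", call. = FALSE)
  offs <- -2:2
  pcon <- vapply(offs, function(o) {
    idx <- seq_len(n) + o
    if (pad == "zero") {
      out <- numeric(n)
      ok <- idx >= 1 & idx <= n
      out[ok] <- p[idx[ok]]
      out
    } else p[pmin(pmax(idx, 1), n)]
  }, numeric(n))
  colnames(pcon) <- c("pcon_m2", "pcon_m1", "pcon_0", "pcon_p1", "pcon_p2")

  bin <- pcon > 0.5
  stats <- t(apply(bin, 1, function(b) {
    r <- rle(as.logical(b))
    lens <- r$lengths[r$values]
    c(length(lens), sum(lens), if (length(lens)) mean(lens) else 0,
      if (length(lens)) max(lens) else 0)
  }))
  colnames(stats) <- c("ctx_n_events", "ctx_total_len", "ctx_avg_len",
                       "ctx_max_len")

  # run membership over the full subject sequence
  seq_bin <- p > 0.5
  r <- rle(as.logical(seq_bin))
  run_len <- rep(r$lengths, r$lengths)
  llen <- as.integer(seq_bin & run_len >= 3)

  cbind(pcon, stats, llen = llen)
}

#' Split windows into confidence groups
#'
#' The confidence of each window is the positive-class softmax probability;
#' windows above 0.5 form the high-confidence group, the rest (ties included)
#' the low-confidence group. Original indices are retained so downstream
#' predictions can be re-interleaved in order.
#'
#' @param p0 Positive-class probabilities.
#' @return List with integer index vectors `hi` and `lo`.
#' @export
confidence_split <- function(p0) {
  list(hi = which(p0 > 0.5), lo = which(p0 <= 0.5))
}

#' Context-feature SAS detection with confidence-gated models
#'
#' Trains one BLS classifier per confidence group on the training-fold
#' windows of that group and applies it to the same group's target windows;
#' predictions are re-interleaved into the original window order. When a
#' group has no usable training members (empty, or single-class), the other
#' group's model is used as a fallback; if both are degenerate the majority
#' label is emitted.
#'
#' @param xcon Context-feature matrix (rows in original window order).
#' @param labels Binary labels (used for training rows only).
#' @param groups List from [confidence_split()] over all rows.
#' @param train Logical/integer selector of training rows.
#' @param config A [bls_config()] for the group models.
#' @return Numeric vector of context probabilities for every row.
#' @export
context_detect <- function(xcon, labels, groups, train, config = bls_config()) {
  n <- nrow(xcon)
  train_idx <- if (is.logical(train)) which(train) else as.integer(train)
  out <- rep(NA_real_, n)
  fits <- purrr::map(groups, function(g) {
    tr <- intersect(g, train_idx)
    if (length(tr) < 2 || length(unique(labels[tr])) < 2) return(NULL)
    bls_fit(xcon[tr, , drop = FALSE], factor(labels[tr], levels = 0:1), config)
  })
  fallback <- fits[[1]] %||% fits[[2]]
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    if (length(g) == 0) next
    fit <- fits[[k]] %||% fallback
    out[g] <- if (is.null(fit)) {
      rep(as.numeric(mean(labels[train_idx]) > 0.5), length(g))
    } else predict(fit, xcon[g, , drop = FALSE], type = "prob")[, "1"]
  }
  out
}

#' Final SAS detection by incremental BLS
#'
#' Appends the context-stage probability to the per-window features as an
#' incremental feature group of the initial classifier and re-solves the
#' output weights; the thresholded output is the branch's final label.
#'
#' @param model The initial `bls` classifier.
#' @param x Per-window feature matrix (training rows).
#' @param ctx_p Context probabilities aligned with `x`.
#' @param labels Binary training labels.
#' @return A fitted incremental `bls`; predict with
#'   `predict(fit, x, x_inc = ctx_p)`.
#' @export
final_detect_fit <- function(model, x, ctx_p, labels) {
  bls_fit_incremental(model, x, matrix(as.numeric(ctx_p), ncol = 1),
                      factor(labels, levels = 0:1))
}
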
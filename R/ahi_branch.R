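#' Global-feature AHI estimate
#'
#' Applies the first global-feature regressor (trained on log-transformed
#' AHI) and inverse-transforms, with log-scale predictions clamped to the
#' training-target range and the result floored at zero. This estimate feeds
#' the probability-correction unit.
#'
#' @param global Tibble from [global_features()] (id column ignored).
#' @param regressor A fitted `bls` regressor.
#' @return Numeric AHI estimates, events/h.
#' @export
predict_ahig <- function(global, regressor) {
  stopifnot(inherits(regressor, "bls"))
  if (is.null(regressor$w)) stop("regressor is not fitted", call. = FALSE)
  x <- as.matrix(dplyr::select(global, -dplyr::any_of("subject_id")))
  ahi_from_log(predict(regressor, x), regressor$y_range)
}

#' AHI implied by a final label sequence
#'
#' The number of predicted event runs divided by sleep hours — the counting
#' estimate used as the incremental feature of the final AHI regressor.
#'
#' @param labels Binary window labels in temporal order.
#' @param t_min Sleep duration, minutes.
#' @return AHI, events/h.
#' @export
ahi_from_labels <- function(labels, t_min) {
  r <- rle(as.logical(labels))
  sum(r$values) / (t_min / 60)
}

#' Final fused AHI prediction
#'
#' Refits the global regressor with the detection-implied AHI as an
#' incremental feature ([bls_fit_incremental()]) and predicts, with inverse
#' transform and zero floor.
#'
#' @param global Global features (training rows for `fit`, target rows for
#'   `predict`).
#' @param ahi_inc Detection-implied AHI per subject ([ahi_from_labels()]).
#' @param model For `predict_final_ahi()`: the incremental regressor from
#'   `fit_final_ahi()`.
#' @param y True AHI labels (events/h) for fitting.
#' @param base The fitted global-only regressor to extend.
#' @return `fit_final_ahi()` a fitted `bls`; `predict_final_ahi()` numeric
#'   AHI estimates.
#' @export
fit_final_ahi <- function(base, global, ahi_inc, y) {
  x <- as.matrix(dplyr::select(global, -dplyr::any_of("subject_id")))
  bls_fit_incremental(base, x, matrix(ahi_transform(ahi_inc), ncol = 1),
                      ahi_transform(y))
}

#' @rdname fit_final_ahi
#' @export
predict_final_ahi <- function(model, global, ahi_inc) {
  x <- as.matrix(dplyr::select(global, -dplyr::any_of("subject_id")))
  ahi_from_log(predict(model, x,
                       x_inc = matrix(ahi_transform(ahi_inc), ncol = 1)),
               model$y_range)
}

#' Severity grading from AHI
#'
#' Clinical four-class grading with left-closed bins — none `[0, 5)`, mild
#' `[5, 15)`, moderate `[15, 30)`, severe `[30, Inf)` — plus the three binary
#' tasks at cut-offs 5, 15 and 30 (`AHI >= cutoff`).
#'
#' @param ahi Numeric AHI values (>= 0).
#' @return Tibble: `ahi`, `severity` (ordered factor), `sev5`, `sev15`,
#'   `sev30` (integer 0/1).
#' @export
severity_from_ahi <- function(ahi) {
  if (any(ahi < 0)) stop("AHI must be >= 0", call. = FALSE)
  cls <- cut(ahi, breaks = c(-Inf, 5, 15, 30, Inf),
             labels = c("none", "mild", "moderate", "severe"), right = FALSE)
  tibble::tibble(
    ahi = ahi,
    severity = factor(cls, levels = c("none", "mild", "moderate", "severe"),
                      ordered = TRUE),
    sev5 = as.integer(ahi >= 5),
    sev15 = as.integer(ahi >= 15),
    sev30 = as.integer(ahi >= 30)
  )
}
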
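#' Plot a cross-validation run
#'
#' `type = "agreement"` draws held-out predicted AHI against the label with
#' the identity line; `type = "bland_altman"` draws the difference plot with
#' the mean difference and the +/- 1.96 SD limits of agreement;
#' `type = "probabilities"` shows one subject's window probabilities before
#' and after correction with the true labels underneath.
#'
#' @param object An `oxi_run` from [run_pipeline()].
#' @param type Plot type.
#' @param subject_id Subject to show for `type = "probabilities"` (default:
#'   the first with a triggered correction, else the first subject).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oxi_run <- function(object, type = c("agreement", "bland_altman",
                                              "probabilities"),
                             subject_id = NULL, ...) {
  type <- match.arg(type)
  subj <- object$subjects
  if (type == "agreement") {
    return(
      ggplot2::ggplot(subj, ggplot2::aes(x = .data$ahi_label, y = .data$ahi_hat)) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                             colour = "grey50") +
        ggplot2::geom_point(ggplot2::aes(colour = .data$true_severity)) +
        ggplot2::labs(x = "AHI label (events/h)", y = "Predicted AHI (events/h)",
                      colour = "Severity") +
        ggplot2::theme_minimal()
    )
  }
  if (type == "bland_altman") {
    ba <- object$metrics$bland_altman
    d <- dplyr::mutate(subj, avg = (.data$ahi_label + .data$ahi_hat) / 2,
                       diff = .data$ahi_hat - .data$ahi_label)
    return(
      ggplot2::ggplot(d, ggplot2::aes(x = .data$avg, y = .data$diff)) +
        ggplot2::geom_hline(yintercept = c(ba$mean_diff, ba$lower, ba$upper),
                            linetype = c("solid", "dashed", "dashed"),
                            colour = c("black", "grey40", "grey40")) +
        ggplot2::geom_point(alpha = 0.7) +
        ggplot2::labs(x = "Mean of label and prediction (events/h)",
                      y = "Prediction - label (events/h)") +
        ggplot2::theme_minimal()
    )
  }
  if (is.null(subject_id)) {
    trig <- object$corrections$subject_id[object$corrections$triggered]
    subject_id <- if (length(trig)) trig[1] else subj$subject_id[1]
  }
  d <- dplyr::filter(object$samples, .data$subject_id == !!subject_id) |>
    dplyr::select("index", "label", "p0", "p0_corrected") |>
    tidyr::pivot_longer(c("p0", "p0_corrected"), names_to = "stage",
                        values_to = "p")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$p,
                                  colour = .data$stage)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = -0.05, alpha = factor(.data$label)),
                        colour = "red", shape = 15, show.legend = FALSE) +
    ggplot2::scale_alpha_manual(values = c(`0` = 0, `1` = 1)) +
    ggplot2::labs(x = "Window index", y = "Event probability",
                  colour = NULL, title = subject_id) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic recording
#'
#' SpO2 trace with annotated events shaded.
#'
#' @param object An `oxi_recording`.
#' @param from_s,to_s Optional time range, seconds.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oxi_recording <- function(object, from_s = 0,
                                   to_s = length(object$spo2) / object$fs, ...) {
  t <- (seq_along(object$spo2) - 1) / object$fs
  keep <- t >= from_s & t <= to_s
  d <- tibble::tibble(t = t[keep] / 60, spo2 = object$spo2[keep])
  ev <- dplyr::filter(object$events, .data$start_s + .data$duration_s >= from_s,
                      .data$start_s <= to_s)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$spo2))
  if (nrow(ev) > 0) {
    p <- p + ggplot2::geom_rect(
      data = ev, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_s / 60,
                   xmax = (.data$start_s + .data$duration_s) / 60),
      ymin = -Inf, ymax = Inf, fill = "salmon", alpha = 0.3)
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (min)", y = "SpO2 (%)",
                  title = object$subject_id) +
    ggplot2::theme_minimal()
}
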
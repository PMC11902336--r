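#' Prepare a cohort: screen, preprocess, extract features
#'
#' Runs subject screening, the cleaning pipeline and both feature extractors
#' over a list of recordings, so that model runs (and ablation pairs) can
#' share one feature pass.
#'
#' @param recordings List of `oxi_recording` objects.
#' @param window_s Window length, seconds (default 30).
#' @param min_overlap_s Label threshold, seconds (default 5).
#' @return An `oxi_cohort`: list with `screening` (tibble), `samples`
#'   (per-window feature tibble over included subjects), `global` (per-subject
#'   global feature tibble), `subjects` (tibble with `subject_id`, `ahi_label`,
#'   `t_min`, `n_windows`), and `window_s`.
#' @export
prepare_cohort <- function(recordings, window_s = 30, min_overlap_s = 5) {
  screening <- purrr::map_dfr(recordings, screen_subject)
  included <- recordings[!screening$excluded]
  if (length(included) == 0) stop("all subjects excluded by screening", call. = FALSE)
  prep <- purrr::map(included, preprocess_recording,
                     window_s = window_s, min_overlap_s = min_overlap_s)
  samples <- purrr::map_dfr(prep, function(p) sample_features(p$samples))
  global <- purrr::map2_dfr(included, prep, function(rec, p) {
    global_features(p$recording, rec$demographics)
  })
  subjects <- purrr::map2_dfr(included, prep, function(rec, p) {
    tibble::tibble(subject_id = rec$subject_id, ahi_label = rec$ahi_label,
                   t_min = p$sleep_s / 60, n_windows = nrow(p$samples$segments),
                   n_total = p$samples$n_total)
  })
  structure(list(screening = screening, samples = samples, global = global,
                 subjects = subjects, window_s = window_s),
            class = "oxi_cohort")
}

#' @export
print.oxi_cohort <- function(x, ...) {
  cat(sprintf("<oxi_cohort> %d subjects (%d screened out), %d windows of %d s\n",
              nrow(x$subjects), sum(x$screening$excluded), nrow(x$samples),
              x$window_s))
  invisible(x)
}

# round-robin fold assignment after a seeded subject shuffle
assign_folds <- function(subject_ids, n_folds, seed) {
  ord <- withr::with_seed(seed, sample(seq_along(subject_ids)))
  folds <- integer(length(subject_ids))
  folds[ord] <- rep_len(seq_len(n_folds), length(subject_ids))
  setNames(folds, subject_ids)
}

# run all model stages for one fold; returns sample- and subject-level
# predictions for the test subjects
run_fold <- function(cohort, fold_test, configs, use_global, trigger,
                     top_frac, evend_mode) {
  samples <- cohort$samples
  subjects <- cohort$subjects
  is_test_subj <- subjects$subject_id %in% fold_test
  train_subj <- subjects$subject_id[!is_test_subj]
  s_train <- !(samples$subject_id %in% fold_test)

  x_all <- feature_cols(samples)
  lab_all <- samples$label

  # stage 1: initial classifier on per-window features
  init <- bls_fit(x_all[s_train, , drop = FALSE],
                  factor(lab_all[s_train], levels = 0:1), configs$detect)
  p0 <- predict(init, x_all, type = "prob")[, "1"]
  y0 <- as.integer(p0 > 0.5)

  by_subj <- split(seq_len(nrow(samples)), samples$subject_id)
  t_min <- setNames(subjects$t_min, subjects$subject_id)
  ahi_lab <- setNames(subjects$ahi_label, subjects$subject_id)

  correction_log <- NULL
  p0c <- p0
  ahig <- NULL
  if (use_global) {
    # detection-based AHI regressor (event statistics of stage-1 output)
    stats_tb <- purrr::map_dfr(names(by_subj), function(sid) {
      idx <- by_subj[[sid]]
      dplyr::bind_cols(tibble::tibble(subject_id = sid),
                       event_stat_features(p0[idx], y0[idx], cohort$window_s,
                                           t_min[sid] * 60))
    })
    reg_s <- bls_fit(as.matrix(dplyr::select(stats_tb, -"subject_id"))[
                       stats_tb$subject_id %in% train_subj, , drop = FALSE],
                     ahi_transform(ahi_lab[stats_tb$subject_id[
                       stats_tb$subject_id %in% train_subj]]),
                     configs$regress)
    ahis_all <- setNames(predict_ahis(stats_tb, reg_s), stats_tb$subject_id)

    # global-feature AHI regressor
    g_x <- as.matrix(dplyr::select(cohort$global, -"subject_id"))
    g_train <- cohort$global$subject_id %in% train_subj
    reg_g <- bls_fit(g_x[g_train, , drop = FALSE],
                     ahi_transform(ahi_lab[cohort$global$subject_id[g_train]]),
                     configs$regress)
    ahig <- setNames(ahi_from_log(predict(reg_g, g_x), reg_g$y_range),
                     cohort$global$subject_id)

    # probability correction per subject
    for (sid in names(by_subj)) {
      idx <- by_subj[[sid]]
      cr <- correct_probabilities(p0[idx], ahig[sid], ahis_all[sid],
                                  t_min[sid], trigger, top_frac, evend_mode)
      p0c[idx] <- cr$p
      correction_log <- dplyr::bind_rows(
        correction_log,
        dplyr::bind_cols(tibble::tibble(subject_id = sid), cr$record))
    }
  }

  # stage 2: context models gated by confidence
  xcon <- do.call(rbind, purrr::map(names(by_subj), function(sid) {
    build_context(p0c[by_subj[[sid]]])
  }))
  xcon <- xcon[order(unlist(by_subj, use.names = FALSE)), , drop = FALSE]
  groups <- confidence_split(p0)
  ctx_p <- context_detect(xcon, lab_all, groups, which(s_train), configs$context)

  # stage 3: final incremental classifier
  fin <- final_detect_fit(init, x_all[s_train, , drop = FALSE],
                          ctx_p[s_train], lab_all[s_train])
  final_p <- predict(fin, x_all, x_inc = matrix(ctx_p, ncol = 1),
                     type = "prob")[, "1"]
  final_label <- as.integer(final_p > 0.5)

  # AHI output
  ahi_cnt <- vapply(names(by_subj), function(sid) {
    ahi_from_labels(final_label[by_subj[[sid]]], t_min[sid])
  }, numeric(1))
  if (use_global) {
    g_x_tb <- cohort$global
    fin_reg <- fit_final_ahi(reg_g, g_x_tb[g_train, , drop = FALSE],
                             ahi_cnt[g_x_tb$subject_id[g_train]],
                             ahi_lab[g_x_tb$subject_id[g_train]])
    ahi_hat <- setNames(
      predict_final_ahi(fin_reg, g_x_tb, ahi_cnt[g_x_tb$subject_id]),
      g_x_tb$subject_id)
  } else {
    # ablated arm: regression on event statistics of the final detections only
    stats_fin <- purrr::map_dfr(names(by_subj), function(sid) {
      idx <- by_subj[[sid]]
      dplyr::bind_cols(tibble::tibble(subject_id = sid),
                       event_stat_features(final_p[idx], final_label[idx],
                                           cohort$window_s, t_min[sid] * 60))
    })
    reg_a <- bls_fit(as.matrix(dplyr::select(stats_fin, -"subject_id"))[
                       stats_fin$subject_id %in% train_subj, , drop = FALSE],
                     ahi_transform(ahi_lab[stats_fin$subject_id[
                       stats_fin$subject_id %in% train_subj]]),
                     configs$regress)
    ahi_hat <- setNames(predict_ahis(stats_fin, reg_a), stats_fin$subject_id)
  }

  test_rows <- which(samples$subject_id %in% fold_test)
  list(
    samples = tibble::tibble(
      subject_id = samples$subject_id[test_rows],
      index = samples$index[test_rows],
      label = lab_all[test_rows],
      p0 = p0[test_rows], p0_corrected = p0c[test_rows],
      ctx_p = ctx_p[test_rows],
      final_p = final_p[test_rows], final_label = final_label[test_rows]
    ),
    subjects = tibble::tibble(
      subject_id = fold_test,
      ahi_label = ahi_lab[fold_test],
      ahi_hat = ahi_hat[fold_test],
      ahi_g = if (use_global) ahig[fold_test] else NA_real_,
      ahi_count = ahi_cnt[fold_test]
    ),
    corrections = correction_log
  )
}

#' Run the full detection + AHI pipeline with subject-wise cross-validation
#'
#' Simulated or real recordings are screened, cleaned and featurized; subjects
#' are shuffled into `n_folds` folds (never splitting a subject's windows);
#' and per fold the initial classifier, the global/detection AHI regressors
#' with probability correction, the confidence-gated context models and the
#' final incremental units are trained on the training subjects and applied
#' to the held-out subjects. Fully deterministic given `seed`.
#'
#' @param x List of `oxi_recording`s or a prepared `oxi_cohort`.
#' @param window_s,min_overlap_s Segmentation parameters (ignored when `x` is
#'   already a cohort).
#' @param n_folds Number of cross-validation folds (>= 2).
#' @param seed Seed controlling fold assignment and model initialisation.
#' @param use_global `FALSE` disables the global-feature branch and the
#'   correction unit (the ablation arm): detection uses sample features only
#'   and AHI comes from a regressor on the detection statistics.
#' @param trigger,top_frac,evend_mode Correction-unit parameters
#'   ([correct_probabilities()]).
#' @param detect_config,context_config,regress_config [bls_config()]s for the
#'   three unit types (seeds are derived from `seed`).
#' @return An `oxi_run`: list with `samples` (held-out window predictions),
#'   `subjects` (held-out AHI predictions with severity), `metrics` (list of
#'   tibbles: `detection`, `ahi`, `severity`, `binary`, `bland_altman`),
#'   `corrections`, `folds`, and the call parameters.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(10, seed = 42, duration_min = 330)
#' run <- run_pipeline(cohort, n_folds = 2, seed = 1)
#' run$metrics$detection
#' }
#' @export
run_pipeline <- function(x, window_s = 30, min_overlap_s = 5, n_folds = 5,
                         seed = 1L, use_global = TRUE, trigger = 10,
                         top_frac = 0.1,
                         evend_mode = c("verbatim", "hours"),
                         detect_config = NULL, context_config = NULL,
                         regress_config = NULL) {
  evend_mode <- match.arg(evend_mode)
  cohort <- if (inherits(x, "oxi_cohort")) x
            else prepare_cohort(x, window_s, min_overlap_s)
  n_subj <- nrow(cohort$subjects)
  if (n_subj < n_folds)
    stop(sprintf("fewer subjects (%d) than folds (%d)", n_subj, n_folds),
         call. = FALSE)
  configs <- list(
    detect = detect_config %||% bls_config(seed = seed + 101L),
    context = context_config %||% bls_config(seed = seed + 202L),
    # subject-level regressions see tens of rows, not thousands: keep the
    # mapped layer at least as wide as the input so no direction is lost,
    # but use a firmer ridge than the classifiers
    regress = regress_config %||%
      bls_config(task = "regress", n_enhancement = 20, ridge_lambda = 0.01,
                 seed = seed + 303L)
  )
  folds <- assign_folds(cohort$subjects$subject_id, n_folds, seed)
  fold_out <- purrr::map(seq_len(n_folds), function(k) {
    run_fold(cohort, names(folds)[folds == k], configs, use_global, trigger,
             top_frac, evend_mode)
  })
  samples <- purrr::map_dfr(fold_out, "samples")
  subjects <- purrr::map_dfr(fold_out, "subjects")
  subjects <- dplyr::bind_cols(
    subjects,
    dplyr::select(severity_from_ahi(subjects$ahi_hat), -"ahi") |>
      dplyr::rename_with(~ paste0("pred_", .x)),
    dplyr::select(severity_from_ahi(subjects$ahi_label), -"ahi") |>
      dplyr::rename_with(~ paste0("true_", .x))
  )
  corrections <- purrr::map_dfr(fold_out, "corrections")

  metrics <- list(
    detection = classification_metrics(samples$label, samples$final_label),
    ahi = regression_metrics(subjects$ahi_label, subjects$ahi_hat),
    severity = classification_metrics(subjects$true_severity,
                                      subjects$pred_severity),
    binary = purrr::map_dfr(c(5, 15, 30), function(th) {
      col <- paste0("sev", th)
      dplyr::bind_cols(
        tibble::tibble(cutoff = th),
        classification_metrics(subjects[[paste0("true_", col)]],
                               subjects[[paste0("pred_", col)]]))
    }),
    bland_altman = bland_altman_summary(subjects$ahi_label, subjects$ahi_hat)
  )
  structure(list(
    samples = samples, subjects = subjects, metrics = metrics,
    corrections = corrections, folds = folds,
    params = list(window_s = cohort$window_s, n_folds = n_folds, seed = seed,
                  use_global = use_global, trigger = trigger,
                  top_frac = top_frac, evend_mode = evend_mode)
  ), class = "oxi_run")
}

#' @export
print.oxi_run <- function(x, ...) {
  d <- x$metrics$detection
  a <- x$metrics$ahi
  cat(sprintf(paste0(
    "<oxi_run> %d subjects, %d windows, %d folds%s\n",
    "  detection: ACC %.3f  MF1 %.3f  kappa %.3f  recall %.3f\n",
    "  AHI:       MAE %.2f  RMSE %.2f  ICC %.3f\n"),
    nrow(x$subjects), nrow(x$samples), x$params$n_folds,
    if (x$params$use_global) "" else " (ablated: no global branch)",
    d$acc, d$mf1, d$kappa, d$recall, a$mae, a$rmse, a$icc))
  invisible(x)
}

#' Paired full-vs-ablated comparison on one cohort
#'
#' Runs the pipeline twice on the same prepared cohort — with and without the
#' global-feature branch and the correction unit — and reports the deltas
#' (full minus ablated) for the headline metrics.
#'
#' @inheritParams run_pipeline
#' @return List with `full` and `ablated` (`oxi_run`s) and `deltas`, a one-row
#'   tibble of metric differences.
#' @export
ablation_mode <- function(x, window_s = 30, min_overlap_s = 5, n_folds = 5,
                          seed = 1L, ...) {
  cohort <- if (inherits(x, "oxi_cohort")) x
            else prepare_cohort(x, window_s, min_overlap_s)
  full <- run_pipeline(cohort, n_folds = n_folds, seed = seed,
                       use_global = TRUE, ...)
  ablated <- run_pipeline(cohort, n_folds = n_folds, seed = seed,
                          use_global = FALSE, ...)
  deltas <- tibble::tibble(
    d_acc = full$metrics$detection$acc - ablated$metrics$detection$acc,
    d_mf1 = full$metrics$detection$mf1 - ablated$metrics$detection$mf1,
    d_recall = full$metrics$detection$recall - ablated$metrics$detection$recall,
    d_kappa = full$metrics$detection$kappa - ablated$metrics$detection$kappa,
    d_icc = full$metrics$ahi$icc - ablated$metrics$ahi$icc,
    d_rmse = full$metrics$ahi$rmse - ablated$metrics$ahi$rmse
  )
  list(full = full, ablated = ablated, deltas = deltas)
}
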
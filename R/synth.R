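#' Configuration for the synthetic overnight-SpO2 generator
#'
#' Defines one simulated subject: sleep duration, baseline saturation, the
#' apnea/hypopnea event process, the desaturation morphology each event
#' imprints on the SpO2 trace, sensor artifacts and slow baseline wander.
#'
#' Event durations are lognormal with mean 21.6 s and SD 11.81 s by default,
#' the event-length statistics of large home-polysomnography cohorts; depths
#' are drawn uniformly from `desat_depth_range` (hypopneas from the shallow
#' 60%, apneas from the deep 60% of the range). Each event produces a
#' piecewise-linear desaturation starting `desat_lag_s` after event onset:
#' a 10 s fall to the nadir, a 5 s hold, and a 15 s recovery.
#'
#' @param duration_min Minutes of sleep (wake padding is added around it).
#' @param baseline_spo2 Baseline saturation, percent.
#' @param event_rate_per_hour Target apnea/hypopnea rate (the intended AHI).
#' @param event_duration_mean_s,event_duration_sd_s Lognormal event-duration
#'   moments, seconds.
#' @param desat_depth_range Two-element range of desaturation depths, percent.
#' @param desat_lag_s Seconds from event onset to the start of the fall.
#' @param artifact_rate_per_hour Rate of sensor dropout bursts (value 0),
#'   duration geometric with mean 2 s.
#' @param drift_amplitude Amplitude of slow sinusoidal baseline wander, percent.
#' @param noise_sd SD of additive measurement noise, percent; noise is clamped
#'   at three SDs so signal excursions stay bounded.
#' @param seed RNG seed; generation is fully deterministic given the config.
#' @return An object of class `synth_config` (a named list).
#' @examples
#' cfg <- synth_config(duration_min = 360, event_rate_per_hour = 20, seed = 1)
#' rec <- simulate_recording(cfg)
#' rec$ahi_label
#' @export
synth_config <- function(duration_min = 480, baseline_spo2 = 97,
                         event_rate_per_hour = 15,
                         event_duration_mean_s = 21.6,
                         event_duration_sd_s = 11.81,
                         desat_depth_range = c(3, 10),
                         desat_lag_s = 10,
                         artifact_rate_per_hour = 1,
                         drift_amplitude = 1,
                         noise_sd = 0.4,
                         seed = 1L) {
  if (!is.numeric(duration_min) || length(duration_min) != 1 || duration_min <= 0)
    stop("`duration_min` must be a single positive number", call. = FALSE)
  if (event_rate_per_hour < 0)
    stop("`event_rate_per_hour` must be >= 0", call. = FALSE)
  if (length(desat_depth_range) != 2 || any(desat_depth_range <= 0) ||
      any(desat_depth_range > 30) || diff(desat_depth_range) < 0)
    stop("`desat_depth_range` must be an increasing pair within (0, 30]", call. = FALSE)
  if (noise_sd < 0 || drift_amplitude < 0 || artifact_rate_per_hour < 0)
    stop("noise, drift and artifact parameters must be >= 0", call. = FALSE)
  structure(list(
    duration_min = duration_min, baseline_spo2 = baseline_spo2,
    event_rate_per_hour = event_rate_per_hour,
    event_duration_mean_s = event_duration_mean_s,
    event_duration_sd_s = event_duration_sd_s,
    desat_depth_range = desat_depth_range, desat_lag_s = desat_lag_s,
    artifact_rate_per_hour = artifact_rate_per_hour,
    drift_amplitude = drift_amplitude, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# lognormal (meanlog, sdlog) from arithmetic mean m and sd s
lnorm_pars <- function(m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# simple sleep architecture: W lead-in, repeating N1/N2/N3/N2/REM cycles with
# occasional interior wake epochs, W tail. One epoch = 30 s.
make_hypnogram <- function(n_sleep_epochs, lead_w, trail_w) {
  cycle <- c(rep("N1", 4), rep("N2", 30), rep("N3", 20), rep("N2", 20), rep("REM", 16))
  stages <- rep(cycle, length.out = n_sleep_epochs)
  c(rep("W", lead_w), stages, rep("W", trail_w))
}

#' Simulate one overnight SpO2 recording
#'
#' Draws apnea/hypopnea events as a Poisson process at the configured rate,
#' enforces non-overlap (a 30 s refractory gap after each event so successive
#' desaturations stay resolvable), imprints one desaturation per event on a
#' drifting baseline, then adds bounded noise and optional sensor-dropout
#' artifacts. The stored `ahi_label` is 60 * n_events / duration_min, i.e. the
#' rate actually realized, not the target.
#'
#' @param config A [synth_config()].
#' @return An `oxi_recording`: list with `spo2` (percent, at `fs` Hz), `fs`,
#'   `hypnogram` (one stage code per 30 s epoch), `events` (tibble with
#'   `start_s`, `duration_s`, `type`; times relative to recording start),
#'   `demographics` (age, bmi, sex, smoking), `ahi_label`, `subject_id`.
#' @export
simulate_recording <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  withr::with_seed(config$seed, simulate_recording_impl(config))
}

simulate_recording_impl <- function(cfg) {
  sleep_s <- round(cfg$duration_min * 60)
  lead_w <- sample(4:10, 1)
  trail_w <- sample(4:10, 1)
  n_sleep_ep <- floor(sleep_s / 30)
  sleep_s <- n_sleep_ep * 30
  hyp <- make_hypnogram(n_sleep_ep, lead_w, trail_w)
  total_s <- length(hyp) * 30
  sleep_start <- lead_w * 30

  # --- events: Poisson count, uniform starts within sleep, lognormal lengths
  lp <- lnorm_pars(cfg$event_duration_mean_s, cfg$event_duration_sd_s)
  n_raw <- rpois(1, cfg$event_rate_per_hour * sleep_s / 3600)
  events <- tibble::tibble(start_s = numeric(), duration_s = numeric(),
                           type = character())
  if (n_raw > 0) {
    dur <- pmin(pmax(rlnorm(n_raw, lp["meanlog"], lp["sdlog"]), 10), 90)
    start <- sleep_start + sort(runif(n_raw, 0, sleep_s - 100))
    type <- sample(c("apnea", "hypopnea"), n_raw, replace = TRUE, prob = c(1, 2))
    keep <- rep(TRUE, n_raw)
    last_end <- -Inf
    for (i in seq_len(n_raw)) {
      if (start[i] < last_end + 10) keep[i] <- FALSE
      else last_end <- start[i] + dur[i]
    }
    events <- tibble::tibble(start_s = start[keep], duration_s = dur[keep],
                             type = type[keep])
  }

  # --- desaturation depths: hypopneas shallow, apneas deep
  rng <- cfg$desat_depth_range
  span <- diff(rng)
  depth <- ifelse(events$type == "apnea",
                  runif(nrow(events), rng[1] + 0.4 * span, rng[2]),
                  runif(nrow(events), rng[1], rng[1] + 0.6 * span))

  # --- signal
  t <- seq_len(total_s) - 1
  phase <- runif(1, 0, 2 * pi)
  x <- cfg$baseline_spo2 + cfg$drift_amplitude * sin(2 * pi * t / 1200 + phase)
  if (nrow(events) > 0) {
    # overlapping desaturations combine by pointwise maximum deficit, so the
    # floor baseline - max depth - drift is exact whatever the event spacing
    deficit <- numeric(total_s)
    for (i in seq_len(nrow(events))) {
      d0 <- events$start_s[i] + cfg$desat_lag_s # fall onset
      shape_t <- c(d0, d0 + 10, d0 + 15, d0 + 30) # fall, hold, recover
      idx <- which(t >= shape_t[1] & t <= shape_t[4])
      if (length(idx)) {
        tt <- t[idx]
        dep <- depth[i]
        dip <- ifelse(tt <= shape_t[2], dep * (tt - shape_t[1]) / 10,
               ifelse(tt <= shape_t[3], dep,
                      dep * (shape_t[4] - tt) / 15))
        deficit[idx] <- pmax(deficit[idx], dip)
      }
    }
    x <- x - deficit
  }
  if (cfg$noise_sd > 0) {
    eps <- rnorm(total_s, 0, cfg$noise_sd)
    bound <- 3 * cfg$noise_sd
    x <- x + pmin(pmax(eps, -bound), bound)
  }
  # sensor dropout bursts
  if (cfg$artifact_rate_per_hour > 0) {
    n_art <- rpois(1, cfg$artifact_rate_per_hour * total_s / 3600)
    if (n_art > 0) {
      a_start <- floor(runif(n_art, 0, total_s - 10))
      a_len <- rgeom(n_art, 0.5) + 1L # mean 2 s
      for (i in seq_len(n_art)) x[a_start[i] + seq_len(a_len[i])] <- 0
    }
  }
  x <- pmin(pmax(x, 0), 100)

  structure(list(
    spo2 = x, fs = 1,
    hypnogram = hyp,
    events = events,
    demographics = tibble::tibble(
      age = round(runif(1, 35, 80)), bmi = round(runif(1, 20, 40), 1),
      sex = sample(0:1, 1), smoking = sample(0:1, 1)
    ),
    ahi_label = 60 * nrow(events) / (sleep_s / 60),
    subject_id = sprintf("synth-%08d", cfg$seed %% 99999999L)
  ), class = "oxi_recording")
}

#' Simulate a cohort of overnight recordings
#'
#' Per-subject seeds are derived deterministically from `seed`; target event
#' rates are drawn uniformly over `ahi_range` unless a `config_fn` supplies a
#' full config per subject.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Master seed.
#' @param ahi_range Range of target AHI values, events/h.
#' @param duration_min Minutes of sleep per subject.
#' @param config_fn Optional `function(i, seed_i)` returning a [synth_config()];
#'   overrides `ahi_range`/`duration_min`/`...`.
#' @param ... Further arguments passed to [synth_config()].
#' @return List of `oxi_recording` objects with unique `subject_id`s.
#' @export
simulate_cohort <- function(n_subjects, seed = 1L, ahi_range = c(0, 60),
                            duration_min = 330, config_fn = NULL, ...) {
  stopifnot(n_subjects >= 1)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n_subjects))
  targets <- withr::with_seed(seed + 1L,
                              runif(n_subjects, ahi_range[1], ahi_range[2]))
  purrr::map(seq_len(n_subjects), function(i) {
    cfg <- if (is.null(config_fn)) {
      synth_config(duration_min = duration_min,
                   event_rate_per_hour = targets[i], seed = seeds[i], ...)
    } else config_fn(i, seeds[i])
    rec <- simulate_recording(cfg)
    rec$subject_id <- sprintf("S%03d", i)
    rec$ahi_target <- if (is.null(config_fn)) targets[i] else cfg$event_rate_per_hour
    rec
  })
}

#' @export
print.oxi_recording <- function(x, ...) {
  cat(sprintf("<oxi_recording> %s: %.1f h at %g Hz, %d events, AHI %.1f\n",
              x$subject_id, length(x$spo2) / x$fs / 3600, x$fs,
              nrow(x$events), x$ahi_label))
  invisible(x)
}

#' Write / read a recording as plain-text fixtures
#'
#' The on-disk form is a `<id>_spo2.csv` (`time_s,spo2`), a `<id>_events.tsv`
#' (`start_s`, `duration_s`, `type`), and a `<id>_meta.json` sidecar with
#' sampling rate, hypnogram, demographics and the AHI label.
#'
#' @param rec An `oxi_recording`.
#' @param dir Directory to write into (created if missing).
#' @return `write_recording()` returns the three paths invisibly;
#'   `read_recording()` returns the reconstructed `oxi_recording`.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- rec$subject_id
  p1 <- file.path(dir, paste0(id, "_spo2.csv"))
  p2 <- file.path(dir, paste0(id, "_events.tsv"))
  p3 <- file.path(dir, paste0(id, "_meta.json"))
  utils::write.csv(
    data.frame(time_s = (seq_along(rec$spo2) - 1) / rec$fs, spo2 = rec$spo2),
    p1, row.names = FALSE)
  utils::write.table(rec$events, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    subject_id = id, fs = rec$fs, hypnogram = rec$hypnogram,
    demographics = as.list(rec$demographics), ahi_label = rec$ahi_label
  ), p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}

#' @param id Subject identifier (file prefix).
#' @rdname write_recording
#' @export
read_recording <- function(dir, id) {
  sig <- utils::read.csv(file.path(dir, paste0(id, "_spo2.csv")))
  ev <- utils::read.table(file.path(dir, paste0(id, "_events.tsv")),
                          header = TRUE, sep = "\t",
                          colClasses = c("numeric", "numeric", "character"))
  meta <- jsonlite::read_json(file.path(dir, paste0(id, "_meta.json")),
                              simplifyVector = TRUE)
  structure(list(
    spo2 = sig$spo2, fs = meta$fs, hypnogram = meta$hypnogram,
    events = tibble::as_tibble(ev),
    demographics = tibble::as_tibble(meta$demographics),
    ahi_label = meta$ahi_label, subject_id = meta$subject_id
  ), class = "oxi_recording")
}
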
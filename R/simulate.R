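# Synthetic multichannel trial generator.
#
# Emulates the statistical structure the decoder assumes: a P300-like
# evoked response (Gaussian-windowed positive deflection, peaking around
# 400 ms in the EEG-like preset and around 340 ms in the MEG-like preset)
# appears after every *attended* flash on a subject-specific focal
# topography; every flash — attended or not — additionally evokes a short
# common response on a broad topography, whose superposition at the 6 Hz
# stimulation rate produces the stimulus-locked oscillation seen in single
# condition averages; noise is a mix of white sensor noise and spatially
# correlated pink (AR(1)) background sources.  No biophysical forward
# model is involved: channels are abstract sensors.

#' Simulation configuration
#'
#' Collects every parameter of the synthetic cohort.  The defaults mirror
#' the nominal 12-object, 5-repetition oddball design: SOA 1/6 s, minimum
#' same-object gap 0.5 s, raw sampling rate 508.63 Hz decimated by 10,
#' 0.8 s analysis window (d = 41 samples), 12 trials per run with each
#' object targeted exactly once per run.
#'
#' @param preset `"eeg"` (29 channels, template peak 0.40 s) or `"meg"`
#'   (245 channels, template peak 0.34 s, different unit scale).
#' @param ... Overrides for any configuration field: `n_channels`,
#'   `fs_raw`, `n_objects`, `n_reps`, `soa`, `min_gap`, `post_window`,
#'   `buffer`, `decim_factor`, `d`, `template_latency` (s),
#'   `template_width` (Gaussian SD, s), `template_amp`, `ssvep_latency`,
#'   `ssvep_width`, `ssvep_amp`, `noise_white`, `noise_pink`,
#'   `n_noise_sources`, `snr` (scales the evoked amplitude against the
#'   noise), `topography_mode` (`"shared"`: common focal pattern perturbed
#'   per subject; `"independent"`: a fresh random pattern per subject,
#'   breaking cross-subject transfer), `subject_variability` (dispersion of
#'   the per-subject topography/latency perturbations), `latency_jitter`
#'   (latency SD per unit variability, s), `unit_scale`, `n_subjects`,
#'   `n_runs`, `trials_per_run`, `seed`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(preset = c("eeg", "meg"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    n_channels = if (preset == "eeg") 29L else 245L,
    fs_raw = 508.63,
    n_objects = 12L, n_reps = 5L, soa = 1 / 6, min_gap = 0.5,
    post_window = 0.8, buffer = 0.1, decim_factor = 10L, d = 41L,
    template_latency = if (preset == "eeg") 0.40 else 0.34,
    template_width = 0.06, template_amp = 1,
    ssvep_latency = 0.10, ssvep_width = 0.025, ssvep_amp = 0.4,
    noise_white = 1, noise_pink = 1, n_noise_sources = 6L,
    snr = 1.5,
    topography_mode = "shared",
    subject_variability = 0.2, latency_jitter = 0.03,
    unit_scale = if (preset == "eeg") 1 else 1e-2,
    n_subjects = 1L, n_runs = 2L, trials_per_run = 12L,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop_ccabci("unknown sim_config fields: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  amps <- c(cfg$template_amp, cfg$ssvep_amp, cfg$noise_white, cfg$noise_pink,
            cfg$snr, cfg$subject_variability)
  if (any(amps < 0)) stop_ccabci("amplitudes and dispersions must be >= 0")
  if (cfg$fs_raw <= 0) stop_ccabci("fs_raw must be positive")
  structure(cfg, class = "sim_config")
}

# smooth focal pattern over the (abstract) channel axis, unit norm;
# drawn from the cohort seed so "shared" cohorts share it
.base_topography <- function(config) {
  c <- config$n_channels
  with_seed(config$seed + 104729L, {
    center <- runif(1, 0.2, 0.8) * c
    width <- runif(1, 0.08, 0.2) * c
    topo <- exp(-((seq_len(c) - center)^2) / (2 * width^2))
    topo / sqrt(sum(topo^2))
  })
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Draw per-subject simulation parameters
#'
#' Gives each subject an evoked-response topography and template latency.
#' In `"shared"` mode the cohort's focal base pattern is perturbed by
#' Gaussian noise scaled by `subject_variability`; in `"independent"` mode
#' every subject receives a fresh random unit-norm pattern, which removes
#' the cross-subject structure transfer learning relies on.  The template
#' latency is jittered by `subject_variability * latency_jitter` seconds
#' (SD).  `subject_variability = 0` makes all subjects identical.
#'
#' @param config A `sim_config`.
#' @param subject_seed Integer seed of this subject's draws.
#' @return List with `topography` (unit norm), `latency` (s),
#'   `ssvep_topography` and `seed`.
#' @export
make_subject <- function(config, subject_seed) {
  c <- config$n_channels
  base <- .base_topography(config)
  with_seed(subject_seed, {
    topo <- if (config$topography_mode == "independent") {
      .unit(rnorm(c))
    } else {
      # perturbation vector has expected norm ~ subject_variability
      # relative to the unit-norm base pattern
      .unit(base + config$subject_variability * rnorm(c) / sqrt(c))
    }
    latency <- config$template_latency +
      rnorm(1, 0, config$subject_variability * config$latency_jitter)
    latency <- min(max(latency, 0.1), config$post_window - 2 * config$template_width)
    list(
      topography = topo,
      latency = latency,
      ssvep_topography = .unit(rep(1, c)),
      seed = subject_seed
    )
  })
}

# gaussian waveform sampled on the raw grid over [0, post_window)
.gauss_waveform <- function(fs, post_window, latency, width, amp) {
  t <- seq(0, post_window - 1 / fs, by = 1 / fs)
  amp * exp(-((t - latency)^2) / (2 * width^2))
}

# overlap-add `wave` at 0-based onsets into a length-n vector
.place_waveform <- function(n, onsets, wave) {
  z <- numeric(n)
  L <- length(wave)
  for (t in onsets) {
    j_max <- min(L, n - t)
    if (j_max >= 1L) {
      idx <- t + seq_len(j_max)
      z[idx] <- z[idx] + wave[seq_len(j_max)]
    }
  }
  z
}

#' Simulate one raw multichannel trial
#'
#' Forward model: the subject's evoked template is overlap-added at the
#' target object's flash onsets and spread over the focal topography
#' (scaled by `snr * template_amp`); a short common response is added after
#' *every* flash on a broad topography (`ssvep_amp`), producing the
#' stimulus-locked ~6 Hz component; white sensor noise and spatially
#' correlated AR(1) pink noise complete the mixture.  The returned trial is
#' at the raw sampling rate and still carries the filtering buffers — run
#' [lowpass_decimate()] to obtain the analysis-ready trial.
#'
#' @param subject Parameters from [make_subject()].
#' @param schedule The trial's `stim_schedule`.
#' @param target Attended object index.
#' @param config A `sim_config`.
#' @param seed Trial seed (noise draws).
#' @param run_id,subject_id Metadata stored in the trial.
#' @return A raw-rate `trial_data` with `buffer = config$buffer`.
#' @export
simulate_trial <- function(subject, schedule, target, config, seed = NULL,
                           run_id = NA_integer_, subject_id = NA_integer_) {
  if (target < 1 || target > schedule$n_objects) {
    stop_ccabci("target must be an object index")
  }
  fs <- config$fs_raw
  c <- config$n_channels
  dur <- segment_duration(schedule, config$post_window)
  b <- as.integer(round_half_away(config$buffer * fs))
  n <- as.integer(round_half_away(dur * fs)) + 2L * b
  on_raw <- lapply(onsets_to_samples(schedule, fs), function(x) x + b)

  with_seed(seed, {
    tmpl <- .gauss_waveform(fs, config$post_window, subject$latency,
                            config$template_width,
                            config$snr * config$template_amp)
    z_target <- .place_waveform(n, on_raw[[target]], tmpl)
    X <- tcrossprod(z_target, subject$topography)

    if (config$ssvep_amp > 0) {
      common <- .gauss_waveform(fs, config$post_window, config$ssvep_latency,
                                config$ssvep_width, config$ssvep_amp)
      z_all <- .place_waveform(n, sort(unlist(on_raw)), common)
      X <- X + tcrossprod(z_all, subject$ssvep_topography)
    }
    if (config$noise_white > 0) {
      X <- X + config$noise_white * matrix(rnorm(n * c), n, c)
    }
    if (config$noise_pink > 0 && config$n_noise_sources > 0) {
      scale <- config$noise_pink * sqrt(c / config$n_noise_sources)
      for (s in seq_len(config$n_noise_sources)) {
        src <- as.numeric(stats::filter(rnorm(n), 0.98, method = "recursive"))
        src <- src / sd(src)
        X <- X + scale * tcrossprod(src, .unit(rnorm(c)))
      }
    }
    new_trial_data(config$unit_scale * X, fs, schedule,
                   modality = config$preset, target = target,
                   run_id = run_id, subject_id = subject_id,
                   buffer = config$buffer)
  })
}

#' Simulate a labeled cohort of trials
#'
#' Generates `n_subjects x n_runs x trials_per_run` trials.  Every trial
#' gets a fresh constrained pseudo-random schedule; targets are balanced
#' within runs (each object selected equally often per run, so
#' `trials_per_run` must be a multiple of `n_objects`).  All randomness is
#' derived from `config$seed`, so the same configuration reproduces the
#' dataset bit for bit.
#'
#' @param config A `sim_config`.
#' @param preprocess Apply [lowpass_decimate()] with the configured factor
#'   (default `TRUE`); `FALSE` returns raw-rate trials with buffers.
#' @return An object of class `trial_dataset`: list with `trials` (flat
#'   list of `trial_data`), `subjects` (per-subject parameters) and
#'   `config`.
#' @export
simulate_dataset <- function(config, preprocess = TRUE) {
  m <- config$n_objects
  if (config$trials_per_run %% m != 0L) {
    stop_ccabci("trials_per_run must be a multiple of n_objects for ",
                "balanced target selection")
  }
  with_seed(config$seed, {
    subject_seeds <- draw_seeds(config$n_subjects)
    subjects <- lapply(subject_seeds, make_subject, config = config)
    trials <- list()
    for (s in seq_len(config$n_subjects)) {
      for (r in seq_len(config$n_runs)) {
        targets <- sample(rep(seq_len(m), config$trials_per_run / m))
        for (i in seq_along(targets)) {
          seeds <- draw_seeds(2L)
          sched <- generate_schedule(m, config$n_reps, config$soa,
                                     config$min_gap, seed = seeds[1])
          tr <- simulate_trial(subjects[[s]], sched, targets[i], config,
                               seed = seeds[2], run_id = r, subject_id = s)
          if (preprocess) tr <- lowpass_decimate(tr, config$decim_factor)
          trials[[length(trials) + 1L]] <- tr
        }
      }
    }
    structure(list(trials = trials, subjects = subjects, config = config),
              class = "trial_dataset")
  })
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("<trial_dataset> ", length(x$trials), " trials, ",
      x$config$n_subjects, " subject(s) x ", x$config$n_runs, " run(s), ",
      x$config$n_channels, " channels (", x$config$preset, " preset)\n",
      sep = "")
  invisible(x)
}

#' Subject's evoked template on the decimated sample grid
#'
#' The planted ground-truth waveform sampled at the analysis rate, e.g. for
#' comparison with a recovered matched filter.
#'
#' @param subject Parameters from [make_subject()].
#' @param config The `sim_config`.
#' @return Numeric vector of `d` samples.
#' @export
subject_template <- function(subject, config) {
  fs_dec <- config$fs_raw / config$decim_factor
  t <- (seq_len(config$d) - 1) / fs_dec
  exp(-((t - subject$latency)^2) / (2 * config$template_width^2))
}
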
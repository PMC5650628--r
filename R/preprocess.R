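# Trial container and preprocessing: segmentation, anti-alias low-pass +
# decimation, least-squares reference-noise cancellation, modality merging.

#' Construct a trial container
#'
#' Holds one trial's multichannel segment together with its stimulus
#' schedule and metadata.  `buffer` marks symmetric filtering margins (in
#' seconds) still present at both ends of `X`; [lowpass_decimate()] removes
#' them after filtering.
#'
#' @param X Numeric matrix, samples x channels.
#' @param fs Sampling frequency in Hz.
#' @param schedule The trial's `stim_schedule`.
#' @param channel_labels Character vector of channel names (default
#'   `CH1..CHc`).
#' @param modality Per-channel modality tag ("eeg", "meg", ...); recycled.
#' @param target Attended object index, or `NA` when unknown.
#' @param run_id,subject_id Identifiers carried through the evaluation
#'   schemes.
#' @param buffer Filtering buffer still attached on each side, seconds.
#' @return An object of class `trial_data`.
#' @export
new_trial_data <- function(X, fs, schedule, channel_labels = NULL,
                           modality = "synthetic", target = NA_integer_,
                           run_id = NA_integer_, subject_id = NA_integer_,
                           buffer = 0) {
  X <- as.matrix(X)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("CH", seq_len(ncol(X)))
  }
  if (length(channel_labels) != ncol(X)) {
    stop_ccabci("channel_labels length must equal the channel count")
  }
  modality <- rep_len(modality, ncol(X))
  structure(
    list(
      X = X, fs = fs, schedule = schedule,
      channel_labels = channel_labels, modality = modality,
      target = if (is.na(target)) NA_integer_ else as.integer(target),
      run_id = run_id, subject_id = subject_id, buffer = buffer
    ),
    class = "trial_data"
  )
}

#' @export
print.trial_data <- function(x, ...) {
  cat("<trial_data> ", nrow(x$X), " samples x ", ncol(x$X), " channels @ ",
      signif(x$fs, 6), " Hz; target = ", x$target,
      ", subject = ", x$subject_id, ", run = ", x$run_id, "\n", sep = "")
  invisible(x)
}

# keep a subset of channels (used by the channel-subset analysis)
subset_channels <- function(trial, idx) {
  trial$X <- trial$X[, idx, drop = FALSE]
  trial$channel_labels <- trial$channel_labels[idx]
  trial$modality <- trial$modality[idx]
  trial
}

#' Extract one trial segment from a continuous recording
#'
#' Cuts the span `[first_onset - buffer, last_onset + post_window + buffer]`
#' out of a continuous multichannel recording.  The buffers are kept
#' attached (recorded in the `buffer` field) so that the low-pass filter can
#' run over them; [lowpass_decimate()] trims them afterwards.  Onset times
#' in the attached schedule are relative to `first_onset`, i.e. to the
#' segment start after trimming.
#'
#' @param X Continuous recording, samples x channels.
#' @param fs Sampling frequency in Hz.
#' @param schedule `stim_schedule` of the trial.
#' @param first_onset Time of the trial's first flash in the recording,
#'   seconds.
#' @param post_window Seconds retained after the last flash onset.
#' @param buffer Filtering margin on each side, seconds.
#' @param ... Metadata passed to [new_trial_data()].
#' @return A `trial_data` whose `X` still carries the buffers.
#' @export
extract_segment <- function(X, fs, schedule, first_onset, post_window = 0.8,
                            buffer = 0.1, ...) {
  X <- as.matrix(X)
  dur <- segment_duration(schedule, post_window)
  i0 <- round_half_away((first_onset - buffer) * fs)
  n <- as.integer(round_half_away((dur + 2 * buffer) * fs))
  if (i0 < 0 || i0 + n > nrow(X)) {
    stop_ccabci("requested segment lies outside the recording")
  }
  new_trial_data(X[i0 + seq_len(n), , drop = FALSE], fs, schedule,
                 buffer = buffer, ...)
}

# symmetric zero-phase FIR applied as centred convolution on
# edge-reflected padding; h must have odd length
.fir_zero_phase <- function(X, h) {
  n <- nrow(X)
  pad <- (length(h) - 1L) / 2L
  if (pad >= n) {
    stop_ccabci("segment shorter than the filter length (", length(h),
                " taps)")
  }
  idx <- c(seq(pad + 1L, 2L, by = -1L), seq_len(n),
           seq(n - 1L, n - pad, by = -1L))
  Xp <- X[idx, , drop = FALSE]
  Yp <- stats::filter(Xp, h, method = "convolution", sides = 2)
  matrix(as.numeric(Yp[pad + seq_len(n), ]), n, ncol(X))
}

#' Anti-alias low-pass filter, buffer removal and decimation
#'
#' Applies a Hamming-windowed-sinc FIR low-pass at the output Nyquist
#' frequency (`fs / (2 * factor)`), trims the filtering buffers recorded in
#' the trial, and keeps every `factor`-th sample.  The symmetric FIR is
#' applied as a centred convolution over edge-reflected padding, so the
#' overall filter is strictly zero-phase: matched-filter latencies are not
#' shifted.  The filter order is chosen so the transition band is at most
#' 20% of the output Nyquist frequency.  With `factor = 1` the signal is
#' passed through unfiltered (only the buffers are trimmed).
#'
#' @param trial A `trial_data`.
#' @param factor Integer decimation factor (nominal design: 10,
#'   508.63 Hz -> 50.863 Hz).
#' @return The decimated `trial_data` (`fs` divided by `factor`,
#'   `buffer = 0`).
#' @export
lowpass_decimate <- function(trial, factor = 10) {
  if (factor < 1 || factor != round(factor)) {
    stop_ccabci("factor must be a positive integer")
  }
  X <- trial$X
  fs <- trial$fs
  if (factor > 1) {
    cutoff <- fs / (2 * factor)
    transition <- 0.2 * cutoff
    order <- ceiling(3.3 * fs / transition)
    if (order %% 2 == 1) order <- order + 1 # even order -> odd symmetric taps
    h <- signal::fir1(order, 1 / factor, type = "low")
    X <- .fir_zero_phase(X, h)
  }
  b <- as.integer(round_half_away(trial$buffer * fs))
  if (b > 0) {
    if (2 * b >= nrow(X)) stop_ccabci("buffers longer than the segment")
    X <- X[(b + 1):(nrow(X) - b), , drop = FALSE]
  }
  X <- X[seq(1, nrow(X), by = factor), , drop = FALSE]
  trial$X <- X
  trial$fs <- fs / factor
  trial$buffer <- 0
  trial
}

#' Cancel environmental noise with reference sensors
#'
#' Replaces every data channel by its residual after least-squares
#' projection onto the reference-sensor channels (per trial).  An empty
#' reference set is a no-op.  Rank-deficient reference sets are handled by
#' a pseudo-inverse solve, with a warning.
#'
#' @param trial A `trial_data`.
#' @param reference_channels Matrix of reference signals, time-aligned with
#'   `trial$X` (same number of rows); `NULL` or zero columns for none.
#' @return The cleaned `trial_data`.
#' @export
regress_out_references <- function(trial, reference_channels) {
  R <- reference_channels
  if (is.null(R) || NCOL(R) == 0L) {
    return(trial)
  }
  R <- as.matrix(R)
  if (nrow(R) != nrow(trial$X)) {
    stop_ccabci("reference channels are not time-aligned with the data")
  }
  qrR <- qr(R)
  if (qrR$rank < ncol(R)) {
    warning("rank-deficient reference set; using pseudo-inverse projection")
    beta <- MASS::ginv(R) %*% trial$X
  } else {
    beta <- qr.coef(qrR, trial$X)
  }
  trial$X <- trial$X - R %*% beta
  trial
}

#' Merge two simultaneously recorded modalities into one trial
#'
#' Channel-wise concatenation of two trials sharing the same sampling rate,
#' sample count and stimulus schedule (e.g. 29 EEG + 245 MEG channels into
#' one 274-channel trial).  Modality tags are preserved.  No unit
#' harmonization is applied: the downstream CCA is invariant to per-channel
#' scaling, so volts and tesla can sit side by side.
#'
#' @param trial_a,trial_b `trial_data` objects; `trial_b` may be `NULL`.
#' @return The merged `trial_data`.
#' @export
merge_modalities <- function(trial_a, trial_b) {
  if (is.null(trial_b) || ncol(trial_b$X) == 0L) {
    return(trial_a)
  }
  if (abs(trial_a$fs - trial_b$fs) > 1e-9 ||
      nrow(trial_a$X) != nrow(trial_b$X) ||
      !identical(trial_a$schedule$global_order, trial_b$schedule$global_order) ||
      abs(trial_a$schedule$soa - trial_b$schedule$soa) > 1e-12) {
    stop_ccabci("trials are not time-aligned (fs, length or schedule differ)")
  }
  if (!is.na(trial_a$target) && !is.na(trial_b$target) &&
      trial_a$target != trial_b$target) {
    stop_ccabci("trials have conflicting target labels")
  }
  trial_a$X <- cbind(trial_a$X, trial_b$X)
  trial_a$channel_labels <- make.unique(
    c(trial_a$channel_labels, trial_b$channel_labels)
  )
  trial_a$modality <- c(trial_a$modality, trial_b$modality)
  if (is.na(trial_a$target)) trial_a$target <- trial_b$target
  trial_a
}
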
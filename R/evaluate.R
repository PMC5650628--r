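# Validation machinery: accuracy and ITR metrics, cross-validation schemes,
# online simulation, transfer learning, permutation chance level,
# truncated-stimulation analysis and component-similarity statistics.

.trial_field <- function(trials, field) {
  vapply(trials, function(tr) {
    v <- tr[[field]]
    if (is.null(v) || length(v) == 0L) NA_integer_ else as.integer(v)
  }, integer(1))
}

.results_frame <- function(trials, results) {
  data.frame(
    subject = .trial_field(trials, "subject_id"),
    run = .trial_field(trials, "run_id"),
    true = vapply(results, function(r) r$true_target, integer(1)),
    predicted = vapply(results, function(r) r$predicted, integer(1)),
    rank_of_true = vapply(results, function(r) {
      if (is.na(r$true_target)) NA_integer_
      else which(r$ranking == r$true_target)
    }, integer(1))
  )
}

new_evaluation_report <- function(scheme, results_frame, ...) {
  structure(
    c(list(scheme = scheme, results = results_frame,
           da = mean(results_frame$predicted == results_frame$true)),
      list(...)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> scheme = ", x$scheme, ", ",
      nrow(x$results), " trials, DA = ", signif(x$da, 4), "\n", sep = "")
  invisible(x)
}

#' Decoding accuracy
#'
#' Ratio of correctly decoded target objects to the total number of trials.
#'
#' @param results A list of `decoding_result`s (all labeled), a
#'   `decoding_result`, or an `evaluation_report`.
#' @return Proportion in `[0, 1]`.
#' @export
decoding_accuracy <- function(results) {
  if (inherits(results, "evaluation_report")) {
    return(results$da)
  }
  if (inherits(results, "decoding_result")) results <- list(results)
  if (length(results) == 0L) stop_ccabci("no decoding results")
  truth <- vapply(results, function(r) r$true_target, integer(1))
  if (anyNA(truth)) stop_ccabci("all results must carry the true target")
  pred <- vapply(results, function(r) r$predicted, integer(1))
  mean(pred == truth)
}

#' Wolpaw information transfer rate
#'
#' Bits per selection
#' `B = log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))`
#' (with `0 log 0 = 0`), converted to bit/min using the trial duration plus
#' an inter-trial overhead.  The "practical" ITR of a 10 s selection with
#' 2.5 s of feedback/preparation uses `trial_seconds = 10`,
#' `overhead_seconds = 2.5`.
#'
#' @param P Decoding accuracy in `[0, 1]`.
#' @param N Number of selectable items (>= 2).
#' @param trial_seconds Stimulation duration per trial, seconds.
#' @param overhead_seconds Added feedback/preparation interval, seconds.
#' @return Information transfer rate in bit/min.
#' @export
wolpaw_itr <- function(P, N, trial_seconds, overhead_seconds = 2.5) {
  if (N < 2) stop_ccabci("N must be at least 2")
  if (P < 0 || P > 1) stop_ccabci("P must lie in [0, 1]")
  if (trial_seconds + overhead_seconds <= 0) {
    stop_ccabci("total trial time must be positive")
  }
  xlog2 <- function(p) if (p <= 0) 0 else p * log2(p)
  bits <- log2(N) + xlog2(P) + if (P >= 1) 0 else {
    (1 - P) * log2((1 - P) / (N - 1))
  }
  bits * 60 / (trial_seconds + overhead_seconds)
}

#' Leave-one-run-out cross-validation
#'
#' For every run, trains a filter model on all remaining runs and decodes
#' the held-out run; reports the pooled decoding accuracy.
#'
#' @param trials List of labeled `trial_data` carrying `run_id`s (>= 2
#'   distinct runs, none empty).
#' @param d,rho_min,alpha,ridge Model parameters, see
#'   [train_filter_model()].
#' @return An `evaluation_report` with fields `da`, `results` (per-trial
#'   frame) and `per_run` (per-run accuracies).
#' @export
leave_one_run_out_cv <- function(trials, d = 41, rho_min = 0.1, alpha = 0.05,
                                 ridge = 1e-8) {
  runs <- .trial_field(trials, "run_id")
  if (anyNA(runs)) stop_ccabci("all trials must carry a run_id")
  uruns <- unique(runs)
  if (length(uruns) < 2L) stop_ccabci("need at least two runs")
  results <- vector("list", length(trials))
  for (r in uruns) {
    held <- which(runs == r)
    if (length(held) == length(trials)) stop_ccabci("a run spans all trials")
    model <- train_filter_model(trials[-held], d = d, rho_min = rho_min,
                                alpha = alpha, ridge = ridge)
    results[held] <- lapply(trials[held], decode_trial, model = model)
  }
  rf <- .results_frame(trials, results)
  per_run <- tapply(rf$predicted == rf$true, rf$run, mean)
  new_evaluation_report("leave-one-run-out", rf,
                        per_run = per_run, d = d)
}

#' Online decoding simulation with incremental filter updates
#'
#' Replays the trials chronologically: the very first trial is decoded with
#' the untrained initial model (all-ones spatial filter, triangular
#' template); afterwards the model is refitted from all past trials — after
#' every trial during the first `per_trial_runs` runs, and at run
#' boundaries thereafter.
#'
#' @param trials Chronologically ordered labeled `trial_data` with
#'   `run_id`s.
#' @param per_trial_runs Number of initial runs with per-trial refits
#'   (default 2).
#' @param d,rho_min,alpha,ridge Model parameters.
#' @return An `evaluation_report` with the per-trial `results`, the
#'   cumulative-accuracy `curve` (`n_train`, `correct`, `cum_da`) and the
#'   final `model`.
#' @export
online_simulation <- function(trials, per_trial_runs = 2, d = 41,
                              rho_min = 0.1, alpha = 0.05, ridge = 1e-8) {
  runs <- .trial_field(trials, "run_id")
  if (anyNA(runs)) stop_ccabci("all trials must carry a run_id")
  run_index <- match(runs, unique(runs))
  n <- length(trials)
  model <- initial_filter_model(ncol(trials[[1]]$X), d,
                                trials[[1]]$channel_labels)
  results <- vector("list", n)
  n_train <- integer(n)
  for (i in seq_len(n)) {
    results[[i]] <- decode_trial(trials[[i]], model)
    n_train[i] <- model$n_train_trials
    last_of_run <- i == n || run_index[i + 1L] != run_index[i]
    refit <- run_index[i] <= per_trial_runs || last_of_run
    if (refit) {
      model <- train_filter_model(trials[seq_len(i)], d = d,
                                  rho_min = rho_min, alpha = alpha,
                                  ridge = ridge)
    }
  }
  rf <- .results_frame(trials, results)
  correct <- rf$predicted == rf$true
  curve <- data.frame(trial = seq_len(n), n_train = n_train,
                      correct = correct,
                      cum_da = cumsum(correct) / seq_len(n))
  new_evaluation_report("online-simulation", rf, curve = curve,
                        model = model, d = d)
}

#' Leave-one-subject-out transfer learning
#'
#' Decodes every subject's trials with a model trained on the pooled trials
#' of all other subjects — the no-calibration transfer scenario.
#'
#' @param trials List of labeled `trial_data` with `subject_id`s (>= 2
#'   subjects, identical channel layouts).
#' @param d,rho_min,alpha,ridge Model parameters.
#' @return An `evaluation_report` with pooled `da` and `per_subject`
#'   accuracies.
#' @export
leave_one_subject_out <- function(trials, d = 41, rho_min = 0.1,
                                  alpha = 0.05, ridge = 1e-8) {
  subj <- .trial_field(trials, "subject_id")
  if (anyNA(subj)) stop_ccabci("all trials must carry a subject_id")
  usub <- unique(subj)
  if (length(usub) < 2L) stop_ccabci("need at least two subjects")
  layouts <- vapply(trials, function(tr) ncol(tr$X), integer(1))
  if (length(unique(layouts)) != 1L) {
    stop_ccabci("subjects have inconsistent channel layouts")
  }
  results <- vector("list", length(trials))
  for (s in usub) {
    held <- which(subj == s)
    model <- train_filter_model(trials[-held], d = d, rho_min = rho_min,
                                alpha = alpha, ridge = ridge)
    results[held] <- lapply(trials[held], decode_trial, model = model)
  }
  rf <- .results_frame(trials, results)
  per_subject <- tapply(rf$predicted == rf$true, rf$subject, mean)
  new_evaluation_report("leave-one-subject-out", rf,
                        per_subject = per_subject, d = d)
}

#' Select a transfer pool of foreign trials
#'
#' Scores every candidate trial by the atanh-correlation of its own target
#' sequence under a donor-group model and returns the `n` highest-scoring
#' trials — the "most reliable trials for generalization".
#'
#' @param candidates List of labeled `trial_data` from other subjects.
#' @param model Donor-group `filter_model` (typically trained on all
#'   candidates).
#' @param n Pool size.
#' @return The selected trials, ordered by descending score.
#' @export
select_transfer_pool <- function(candidates, model, n) {
  if (n < 1 || n > length(candidates)) {
    stop_ccabci("pool size must lie in [1, number of candidates]")
  }
  score <- vapply(candidates, function(tr) {
    decode_trial(tr, model)$scores[tr$target]
  }, numeric(1))
  candidates[order(score, decreasing = TRUE)[seq_len(n)]]
}

#' Accuracy curve under incremental substitution of a foreign pool
#'
#' Starts from a model trained on a pool of foreign (cross-subject) trials;
#' at step `t` the `t` lowest-ranked pool trials have been replaced by the
#' individual's first `t` trials, the model is refitted, and the
#' individual's trial `t + 1` is decoded.  At full substitution the
#' training set equals the individual's first `length(pool)` trials.
#'
#' @param individual Chronologically ordered labeled `trial_data` of the
#'   current subject.
#' @param pool Foreign trials, ordered by decreasing reliability (e.g. from
#'   [select_transfer_pool()]); substitution removes from the tail.
#' @param d,rho_min,alpha,ridge Model parameters.
#' @return An `evaluation_report` whose `curve` has one row per step
#'   (`n_individual`, `correct`, `cum_da`).
#' @export
pooled_transfer_curve <- function(individual, pool, d = 41, rho_min = 0.1,
                                  alpha = 0.05, ridge = 1e-8) {
  if (length(pool) < 1L) stop_ccabci("pool must contain at least one trial")
  n_pool <- length(pool)
  steps <- 0:min(n_pool, length(individual) - 1L)
  results <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    t <- steps[i]
    training <- c(pool[seq_len(n_pool - t)],
                  if (t > 0) individual[seq_len(t)])
    model <- train_filter_model(training, d = d, rho_min = rho_min,
                                alpha = alpha, ridge = ridge)
    results[[i]] <- decode_trial(individual[[t + 1L]], model)
  }
  rf <- .results_frame(individual[steps + 1L], results)
  correct <- rf$predicted == rf$true
  curve <- data.frame(n_individual = steps, correct = correct,
                      cum_da = cumsum(correct) / seq_along(steps))
  new_evaluation_report("pooled-transfer", rf, curve = curve, d = d)
}

#' Permutation estimate of the guessing level
#'
#' Repeatedly permutes the assignment between labels and object-specific
#' stimulus sequences (every trial's label is reassigned to a uniformly
#' drawn object's sequence) and reruns the leave-one-run-out
#' cross-validation.  The mean of the resulting accuracy distribution
#' estimates the chance ("guessing") level; the 2.5%/97.5% quantiles give
#' its 95% interval.
#'
#' The uniform draw deliberately includes the originally attended object:
#' under a uniform assignment the probability that the winning sequence
#' carries the reassigned label is exactly `1/m` whatever the classifier
#' does, which is the calibration a guessing level must have.  Excluding
#' the true object would bias the estimate below `1/m` whenever residual
#' evoked structure lets predictions track the truly attended object
#' through overlapping analysis windows.
#'
#' @param trials Labeled `trial_data` with `run_id`s.
#' @param n_perm Number of permutations (500 in the full design).
#' @param seed Seed for the label reassignment.
#' @param d,rho_min,alpha,ridge Model parameters.
#' @return List with `das` (per-permutation accuracies), `mean`, `ci95`
#'   and `n_perm`.
#' @export
permutation_chance <- function(trials, n_perm = 500, seed = NULL, d = 41,
                               rho_min = 0.1, alpha = 0.05, ridge = 1e-8) {
  if (n_perm < 1) stop_ccabci("n_perm must be at least 1")
  m <- trials[[1]]$schedule$n_objects
  das <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      perm <- lapply(trials, function(tr) {
        tr$target <- sample.int(m, 1L)
        tr
      })
      leave_one_run_out_cv(perm, d = d, rho_min = rho_min, alpha = alpha,
                           ridge = ridge)$da
    }, numeric(1))
  })
  list(das = das, mean = mean(das),
       ci95 = unname(quantile(das, c(0.025, 0.975))), n_perm = n_perm)
}

#' Truncate the stimulation interval of a trial or dataset
#'
#' Keeps only the first `reps_kept * n_objects` flash slots and shortens
#' the data segment to `post_window` seconds after the last kept onset —
#' the faster-selection analysis (1 repetition per object corresponds to
#' about 2 s of stimulation in the 12-object design).  Truncated schedules
#' are flagged and exempt from the exact per-object flash-count invariant.
#'
#' @param x A `trial_data` or a list of them.
#' @param reps_kept Number of repetitions per object to keep (1 to the
#'   design's `n_reps`).
#' @param post_window Seconds retained after the last kept onset.
#' @return The truncated object, same shape as `x`.
#' @export
truncate_stimuli <- function(x, reps_kept, post_window = 0.8) {
  if (is.list(x) && !inherits(x, "trial_data")) {
    return(lapply(x, truncate_stimuli, reps_kept = reps_kept,
                  post_window = post_window))
  }
  trial <- x
  sched <- trial$schedule
  if (reps_kept < 1 || reps_kept > sched$n_reps) {
    stop_ccabci("reps_kept must lie in [1, n_reps]")
  }
  if (reps_kept == sched$n_reps) {
    return(trial)
  }
  n_slots <- reps_kept * sched$n_objects
  new_sched <- new_stim_schedule(
    sched$n_objects, reps_kept, sched$soa, sched$min_gap,
    sched$global_order[seq_len(n_slots)], truncated = TRUE
  )
  n_new <- as.integer(round_half_away(
    ((n_slots - 1) * sched$soa + post_window) * trial$fs
  ))
  n_new <- min(n_new, nrow(trial$X))
  trial$X <- trial$X[seq_len(n_new), , drop = FALSE]
  trial$schedule <- new_sched
  trial
}

#' Similarity of two matched filters
#'
#' Pearson correlation between two temporal templates.
#'
#' @param s_a,s_b Matched filters of equal length.
#' @return Correlation coefficient.
#' @export
component_similarity <- function(s_a, s_b) {
  if (length(s_a) != length(s_b)) {
    stop_ccabci("matched filters must have equal length")
  }
  if (sd(s_a) == 0 || sd(s_b) == 0) {
    stop_ccabci("zero-variance matched filter")
  }
  cor(s_a, s_b)
}

#' Average correlations on the atanh scale
#'
#' Group averages of correlation coefficients are computed on
#' atanh-transformed values and back-transformed, since r values are not
#' metric.
#'
#' @param r Vector of correlation coefficients.
#' @return The back-transformed mean correlation.
#' @export
average_similarity <- function(r) {
  tanh(mean(atanh_clamped(r)))
}

#' Attended-minus-ignored difference wave
#'
#' Epochs `window` seconds after every flash onset, averages separately
#' over attended (the trial's target object) and ignored events, and
#' subtracts.  Stimulus-locked activity common to all flashes — such as the
#' ~6 Hz oscillation driven by the stimulation rate — cancels in the
#' difference wave; the attention-specific evoked response remains.
#'
#' @param trials List of labeled `trial_data`.
#' @param W Optional spatial filters; when given, epochs are extracted from
#'   the surrogate channels `X W` instead of the sensor channels.
#' @param window Epoch length in seconds (default 0.8).
#' @return List with matrices `attended`, `ignored`, `difference` (epoch
#'   samples x channels), the epoch `times` in seconds and the event counts.
#' @export
difference_wave <- function(trials, W = NULL, window = 0.8) {
  if (length(trials) == 0L) stop_ccabci("no trials")
  fs <- trials[[1]]$fs
  d <- as.integer(round_half_away(window * fs))
  acc_a <- acc_i <- NULL
  n_a <- n_i <- 0L
  for (tr in trials) {
    if (is.na(tr$target)) stop_ccabci("all trials must be labeled")
    X <- if (is.null(W)) tr$X else tr$X %*% W
    on <- onsets_to_samples(tr$schedule, tr$fs)
    if (is.null(acc_a)) {
      acc_a <- acc_i <- matrix(0, d, ncol(X))
    }
    for (e in seq_along(on)) {
      for (t in on[[e]]) {
        if (t + d > nrow(X)) next
        ep <- X[t + seq_len(d), , drop = FALSE]
        if (e == tr$target) {
          acc_a <- acc_a + ep
          n_a <- n_a + 1L
        } else {
          acc_i <- acc_i + ep
          n_i <- n_i + 1L
        }
      }
    }
  }
  if (n_a == 0L || n_i == 0L) stop_ccabci("no usable events")
  attended <- acc_a / n_a
  ignored <- acc_i / n_i
  list(attended = attended, ignored = ignored,
       difference = attended - ignored,
       times = (seq_len(d) - 1) / fs, n_attended = n_a, n_ignored = n_i)
}
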
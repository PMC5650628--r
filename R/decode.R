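# Scoring candidate stimulus sequences against a filter model.
#
# A trial is projected onto the spatial filters (u_k = X w_k); for every
# candidate object e the matched filters are expanded along that object's
# sequence (v_{k,e} = Y_e s_k) and correlated with u_k.  Correlations are
# atanh-transformed, averaged over components, and the object with the
# highest average is predicted.

#' Project a trial onto the spatial filters
#'
#' `U = X W`: one surrogate channel per retained component.
#'
#' @param X Trial matrix (samples x channels) or a `trial_data`.
#' @param W Spatial filter matrix (channels x K).
#' @return Matrix of surrogate channels, samples x K.
#' @export
project_trial <- function(X, W) {
  if (inherits(X, "trial_data")) X <- X$X
  if (ncol(X) != nrow(W)) {
    stop_ccabci("channel count mismatch between trial (", ncol(X),
                ") and filters (", nrow(W), ")")
  }
  X %*% W
}

#' Score every candidate object of a trial
#'
#' For each object `e` and component `k` computes
#' `rho_{k,e} = cor(u_k, Y_e s_k)` and the per-object score
#' `mean_k atanh(rho_{k,e})`.  Correlations are clamped at `1 - 1e-12`
#' before the transform; a zero-variance surrogate time course (e.g. an
#' empty sequence after truncation) contributes a correlation of 0.
#'
#' @param U Surrogate channels (samples x K), from [project_trial()].
#' @param references A `reference_set` with one `Y_e` per candidate object.
#' @param S Matched filters (d x K).
#' @param true_target Optional known attended object, stored in the result.
#' @return An object of class `decoding_result`: `scores` (length m),
#'   `ranking` (objects by descending score, ties broken by lowest index),
#'   `predicted`, `true_target` and `per_component_corr` (K x m).
#' @export
score_objects <- function(U, references, S, true_target = NA_integer_) {
  S <- as.matrix(S)
  if (references$d != nrow(S)) {
    stop_ccabci("window length mismatch between references (", references$d,
                ") and matched filters (", nrow(S), ")")
  }
  m <- length(references$Y)
  K <- ncol(S)
  corr <- matrix(0, K, m)
  for (e in seq_len(m)) {
    V <- references$Y[[e]] %*% S
    for (k in seq_len(K)) {
      corr[k, e] <- safe_cor(U[, k], V[, k])
    }
  }
  scores <- colMeans(matrix(atanh_clamped(corr), K, m))
  ranking <- order(scores, decreasing = TRUE) # stable: ties -> lowest index
  structure(
    list(
      scores = scores, ranking = ranking, predicted = ranking[1L],
      true_target = if (is.na(true_target)) NA_integer_
                    else as.integer(true_target),
      per_component_corr = corr
    ),
    class = "decoding_result"
  )
}

#' Decode the attended object of one trial
#'
#' Builds the trial's reference set from its schedule, projects the data
#' onto the model's spatial filters, scores all candidate objects and
#' returns the ranking.  A degenerate model (no significant component) is
#' replaced by the untrained initial model of matching dimensions.
#'
#' @param trial A `trial_data`.
#' @param model A `filter_model` (trained or initial).
#' @return A `decoding_result`.
#' @seealso [score_objects()], [train_filter_model()]
#' @export
decode_trial <- function(trial, model) {
  if (model$degenerate) {
    model <- initial_filter_model(ncol(trial$X), model$d,
                                  trial$channel_labels)
  }
  on <- onsets_to_samples(trial$schedule, trial$fs)
  refs <- build_reference_set(on, nrow(trial$X), model$d)
  U <- project_trial(trial$X, model$W)
  score_objects(U, refs, model$S, true_target = trial$target)
}

#' @rdname decode_trial
#' @param object A `filter_model`.
#' @param ... Unused.
#' @export
predict.filter_model <- function(object, trial, ...) {
  decode_trial(trial, object)
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result> predicted = ", x$predicted,
      if (!is.na(x$true_target)) paste0(" (true = ", x$true_target, ")"),
      "\n  scores: ", paste(signif(x$scores, 3), collapse = " "), "\n",
      sep = "")
  invisible(x)
}
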
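# Joint estimation of spatial filters and matched filters by canonical
# correlation analysis (CCA) between concatenated brain signals X and the
# impulse reference functions Y of the attended objects.
#
# Implementation: columns are centred and scaled once, the covariance
# blocks Cxx, Cyy, Cxy are formed (with optional ridge ~ eps * trace / p on
# the diagonals for the rank-deficient many-channel / few-trials regime),
# both blocks are whitened through their symmetric eigen-decompositions and
# the canonical structure is read off the SVD of the whitened cross block.
# Filters are returned on the raw data scale, so u_k = X w_k applies
# directly to unstandardized trials.

#' Canonical correlation analysis of two variable sets
#'
#' Returns all `min(c, d)` canonical pairs between the columns of `X`
#' (brain channels) and `Y` (reference functions), correlations in
#' descending order.  Each returned weight pair satisfies
#' `cor(X %*% W[, k], Y %*% S[, k]) = rho[k]`, and canonical variates are
#' mutually uncorrelated within each set.  The component sign is fixed so
#' that the largest-magnitude coefficient of each matched filter `S[, k]`
#' is positive, making templates comparable across fits and subjects.
#'
#' @param X Numeric matrix N x c; columns are centred (and scaled)
#'   internally.
#' @param Y Numeric matrix N x d.
#' @param ridge Diagonal regularization added to each covariance block as
#'   `ridge * mean(diag(C))`; stabilizes the solve when the block is (near)
#'   rank deficient, e.g. 245 channels estimated from a handful of trials.
#'   Use 0 for an exact unregularized solve.
#' @return An object of class `cca_fit`: list with `W` (c x K weight matrix
#'   on the raw `X` scale), `S` (d x K), `rho` (descending canonical
#'   correlations), `n` (sample count), `scale_x`, `scale_y` (per-column
#'   standard deviations used internally).
#' @export
fit_cca <- function(X, Y, ridge = 1e-8) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop_ccabci("X and Y must have the same number of rows")
  if (n < 2L) stop_ccabci("need at least two samples")

  std <- function(M) {
    mu <- colMeans(M)
    M <- sweep(M, 2, mu, "-")
    s <- sqrt(colSums(M^2) / (n - 1))
    s[s == 0] <- 1
    list(M = sweep(M, 2, s, "/"), s = s)
  }
  sx <- std(X)
  sy <- std(Y)

  Cxx <- crossprod(sx$M) / (n - 1)
  Cyy <- crossprod(sy$M) / (n - 1)
  Cxy <- crossprod(sx$M, sy$M) / (n - 1)
  if (ridge > 0) {
    diag(Cxx) <- diag(Cxx) + ridge * mean(diag(Cxx))
    diag(Cyy) <- diag(Cyy) + ridge * mean(diag(Cyy))
  }

  isqrt <- function(C) {
    e <- eigen(C, symmetric = TRUE)
    tol <- max(e$values) * 1e-12
    v <- pmax(e$values, tol)
    e$vectors %*% (t(e$vectors) / sqrt(v))
  }
  Wx <- isqrt(Cxx)
  Wy <- isqrt(Cyy)
  sv <- svd(Wx %*% Cxy %*% Wy)

  K <- min(ncol(X), ncol(Y))
  rho <- pmin(sv$d[seq_len(K)], 1)
  W <- (Wx %*% sv$u[, seq_len(K), drop = FALSE]) / sx$s
  S <- (Wy %*% sv$v[, seq_len(K), drop = FALSE]) / sy$s

  for (k in seq_len(K)) { # peak of the matched filter positive
    if (S[which.max(abs(S[, k])), k] < 0) {
      S[, k] <- -S[, k]
      W[, k] <- -W[, k]
    }
  }
  structure(
    list(W = W, S = S, rho = rho, n = n, scale_x = sx$s, scale_y = sy$s),
    class = "cca_fit"
  )
}

#' Select significant canonical components
#'
#' Retains the leading components whose canonical correlation is at least
#' `rho_min` and whose sequential chi-squared test rejects the null
#' hypothesis that all remaining correlations are zero at level `alpha`.
#' The test statistic for position `i` is Bartlett's
#' `-(N - 1 - (c + d + 1)/2) * sum_{j >= i} log(1 - rho_j^2)` with
#' `(c - i + 1) * (d - i + 1)` degrees of freedom.  `K = 0` is a valid
#' outcome; the decoder then falls back to the untrained initial model.
#'
#' @param rho Canonical correlations, descending.
#' @param N Number of (concatenated) samples the CCA was fitted on.
#' @param c,d Dimensions of the two variable sets.
#' @param rho_min Minimum canonical correlation (default 0.1).
#' @param alpha Significance level of the sequential test (default 0.05).
#' @return Integer `K`, the number of retained leading components.
#' @export
select_components <- function(rho, N, c, d, rho_min = 0.1, alpha = 0.05) {
  if (length(rho) == 0L) return(0L)
  r2 <- pmin(rho, 1 - 1e-12)^2
  tails <- rev(cumsum(rev(log(1 - r2))))
  ks <- seq_along(rho)
  stat <- -(N - 1 - (c + d + 1) / 2) * tails
  df <- (c - ks + 1) * (d - ks + 1)
  p <- pchisq(stat, df, lower.tail = FALSE)
  ok <- (rho >= rho_min) & (p < alpha)
  keep <- which(!ok)
  if (length(keep) == 0L) length(rho) else keep[1L] - 1L
}

#' Train a filter model from labeled trials
#'
#' Concatenates each training trial's channel data `X` and the impulse
#' reference matrix `Y_e` of its attended object along the time axis, fits
#' the CCA, and retains the significant components.  The resulting model
#' holds spatial filters `W` (channel weights), matched filters `S`
#' (post-stimulus templates of `d` samples) and their canonical
#' correlations.
#'
#' @param trials List of labeled `trial_data` (identical channel layout and
#'   sampling rate; `target` set).
#' @param d Matched-filter window length in samples (default 41 = 0.8 s at
#'   50.863 Hz).
#' @param rho_min,alpha Component-retention parameters, see
#'   [select_components()].
#' @param ridge Covariance regularization, see [fit_cca()].
#' @return An object of class `filter_model` with fields `W` (c x K), `S`
#'   (d x K), `rho`, `K`, `d`, `channel_labels`, `scale_x` (per-channel SD
#'   on the training data), `degenerate` (`TRUE` when no component
#'   survived), `n_train_samples` and `n_train_trials`.
#' @export
train_filter_model <- function(trials, d = 41, rho_min = 0.1, alpha = 0.05,
                               ridge = 1e-8) {
  if (length(trials) == 0L) stop_ccabci("no training trials")
  targets <- vapply(trials, function(tr) tr$target, integer(1))
  if (anyNA(targets)) stop_ccabci("all training trials must be labeled")

  Xs <- vector("list", length(trials))
  Ys <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    on <- onsets_to_samples(tr$schedule, tr$fs)
    Xs[[i]] <- tr$X
    Ys[[i]] <- .impulse_matrix(on[[tr$target]], nrow(tr$X), d)
  }
  X_cat <- do.call(rbind, Xs)
  Y_cat <- do.call(rbind, Ys)

  fit <- fit_cca(X_cat, Y_cat, ridge = ridge)
  K <- select_components(fit$rho, N = nrow(X_cat), c = ncol(X_cat), d = d,
                         rho_min = rho_min, alpha = alpha)
  keep <- seq_len(max(K, 1L)) # keep the leading pair even when degenerate
  structure(
    list(
      W = fit$W[, keep, drop = FALSE],
      S = fit$S[, keep, drop = FALSE],
      rho = fit$rho[keep],
      K = as.integer(max(K, 1L)),
      degenerate = K == 0L,
      initial = FALSE,
      d = as.integer(d),
      channel_labels = trials[[1]]$channel_labels,
      scale_x = fit$scale_x,
      n_train_samples = nrow(X_cat),
      n_train_trials = length(trials)
    ),
    class = "filter_model"
  )
}

#' Untrained initial filter model
#'
#' The bootstrap model used before any training data exist: the spatial
#' filter averages all channels (`w_i = 1`) and the matched filter is a
#' symmetric triangular ("hat") template over the `d`-sample window — a
#' simplified ERP shape.  It allows a prediction already in the very first
#' trial of an online session.
#'
#' @param c Number of channels.
#' @param d Window length in samples.
#' @param channel_labels Optional channel names.
#' @return A `filter_model` with a single component and `rho = 1` by
#'   convention.
#' @export
initial_filter_model <- function(c, d = 41, channel_labels = NULL) {
  mid <- (d + 1) / 2
  s <- 1 - abs(seq_len(d) - mid) / mid
  structure(
    list(
      W = matrix(1, c, 1), S = matrix(s, d, 1), rho = 1,
      K = 1L, degenerate = FALSE, initial = TRUE,
      d = as.integer(d),
      channel_labels = if (is.null(channel_labels)) paste0("CH", seq_len(c))
                       else channel_labels,
      scale_x = rep(1, c),
      n_train_samples = 0L, n_train_trials = 0L
    ),
    class = "filter_model"
  )
}

#' Rank channels by spatial-filter weight and refit on a subset
#'
#' Ranks channels by the maximum absolute standardized spatial-filter
#' weight over the retained components (weights are compared on the
#' per-channel standardized scale so that signal units do not bias the
#' ranking), keeps the `n_keep` best, and refits the CCA on the reduced
#' channel set.
#'
#' @param model A trained `filter_model`.
#' @param trials The training trials (full channel set).
#' @param n_keep Number of channels to retain.
#' @param ... Passed to [train_filter_model()] for the refit.
#' @return List with `channels` (sorted indices of the kept channels) and
#'   `model` (the refitted `filter_model`).
#' @export
channel_subset <- function(model, trials, n_keep, ...) {
  c <- nrow(model$W)
  if (n_keep < 1) stop_ccabci("n_keep must be at least 1")
  if (n_keep > c) stop_ccabci("n_keep exceeds the channel count")
  w_std <- abs(model$W * model$scale_x)
  importance <- apply(w_std, 1, max)
  idx <- sort(order(importance, decreasing = TRUE)[seq_len(n_keep)])
  sub <- lapply(trials, subset_channels, idx = idx)
  list(channels = idx, model = train_filter_model(sub, d = model$d, ...))
}

#' @export
print.filter_model <- function(x, ...) {
  cat("<filter_model> ", nrow(x$W), " channels, d = ", x$d, ", K = ", x$K,
      if (x$initial) " (initial)", if (x$degenerate) " (degenerate)",
      "\n  rho:", paste(signif(x$rho, 3), collapse = " "), "\n", sep = "")
  invisible(x)
}
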
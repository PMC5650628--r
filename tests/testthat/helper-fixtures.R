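# Shared fixtures and independent oracles.  Expensive simulated cohorts are
# built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# one EEG-like subject at the calibrated default SNR, 4 runs x 12 trials
fx_default_subject <- function() {
  fixture("default_subject", function() {
    simulate_dataset(sim_config("eeg", n_subjects = 1, n_runs = 4, seed = 11))
  })
}

# high-SNR subject for parameter-recovery checks, 5 runs x 12 trials
fx_highsnr_subject <- function() {
  fixture("highsnr_subject", function() {
    simulate_dataset(sim_config("eeg", n_subjects = 1, n_runs = 5, snr = 3,
                                seed = 7))
  })
}

# small cohort sharing one focal topography (transfer learning works)
fx_shared_cohort <- function() {
  fixture("shared_cohort", function() {
    simulate_dataset(sim_config("eeg", n_subjects = 4, n_runs = 2,
                                topography_mode = "shared", seed = 21))
  })
}

# same size, but every subject gets an independent random topography
fx_rotated_cohort <- function() {
  fixture("rotated_cohort", function() {
    simulate_dataset(sim_config("eeg", n_subjects = 4, n_runs = 2,
                                topography_mode = "independent", seed = 22))
  })
}

# scaled-down design for cheap structural tests: 4 objects x 3 reps,
# same decimated rate (50.863 Hz) and d = 41 as the nominal design
mini_cfg <- function(...) {
  sim_config("eeg", n_objects = 4L, n_reps = 3L, trials_per_run = 4L,
             fs_raw = 203.452, decim_factor = 4L, n_channels = 8L,
             n_noise_sources = 3L, ...)
}

# reproducible shuffle of 1..n
with_seed_order <- function(n, seed) {
  set.seed(seed)
  sample.int(n)
}

# ---- independent oracles ------------------------------------------------

# brute-force CCA through the generalized eigenproblem of the covariance
# blocks (no whitening/SVD); returns descending canonical correlations and
# the X-side weights
oracle_cca <- function(X, Y) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  n <- nrow(X)
  Cxx <- crossprod(X) / (n - 1)
  Cyy <- crossprod(Y) / (n - 1)
  Cxy <- crossprod(X, Y) / (n - 1)
  M <- solve(Cxx, Cxy) %*% solve(Cyy, t(Cxy))
  e <- eigen(M)
  ord <- order(Re(e$values), decreasing = TRUE)
  k <- min(ncol(X), ncol(Y))
  list(
    rho = sqrt(pmax(Re(e$values[ord]), 0))[seq_len(k)],
    W = Re(e$vectors[, ord, drop = FALSE])[, seq_len(k), drop = FALSE]
  )
}

# overlap-add of shifted template copies, written as an explicit loop
oracle_expand <- function(onsets, n, s) {
  v <- numeric(n)
  for (t in onsets) {
    for (j in seq_along(s)) {
      i <- t + j
      if (i <= n) v[i] <- v[i] + s[j]
    }
  }
  v
}

# element-by-element construction of an impulse reference matrix
oracle_impulse_matrix <- function(onsets, n, d) {
  Y <- matrix(0, n, d)
  for (i in seq_len(n)) {
    for (j in seq_len(d)) {
      if (any(i == j + onsets)) Y[i, j] <- 1
    }
  }
  Y
}
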
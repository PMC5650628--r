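test_that("self-correlation gives unit canonical correlations", {
  set.seed(1)
  X <- matrix(rnorm(200 * 4), 200, 4)
  fit <- fit_cca(X, X, ridge = 0)
  expect_equal(fit$rho, rep(1, 4), tolerance = 1e-8)
})

test_that("fit_cca matches the covariance-eigenproblem oracle and cancor", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(80:300, 1)
    c <- sample(2:6, 1)
    d <- sample(2:6, 1)
    X <- matrix(rnorm(n * c), n, c)
    Y <- matrix(rnorm(n * d), n, d)
    fit <- fit_cca(X, Y, ridge = 0)
    ora <- oracle_cca(X, Y)
    expect_equal(fit$rho, ora$rho, tolerance = 1e-8)
    expect_equal(fit$rho, stats::cancor(X, Y)$cor, tolerance = 1e-8)
    # weights agree up to sign/scale: canonical variates collinear
    for (k in seq_len(min(c, d))) {
      u_mine <- X %*% fit$W[, k]
      u_ora <- X %*% ora$W[, k]
      expect_gt(abs(cor(u_mine, u_ora)), 1 - 1e-6)
    }
    # the returned pair reproduces its correlation on the raw data
    for (k in seq_len(min(c, d))) {
      expect_equal(abs(cor(drop(X %*% fit$W[, k]), drop(Y %*% fit$S[, k]))),
                   fit$rho[k], tolerance = 1e-8)
    }
  }
})

test_that("an embedded common latent is recovered at its true correlation", {
  set.seed(3)
  n <- 10000
  z <- rnorm(n)
  X <- cbind(z + rnorm(n) * 0, rnorm(n), rnorm(n), rnorm(n))
  Y <- cbind(0.7 * scale(z) + sqrt(1 - 0.49) * rnorm(n), rnorm(n), rnorm(n))
  fit <- fit_cca(X, Y, ridge = 0)
  expect_equal(fit$rho[1], 0.7, tolerance = 0.03)
})

test_that("canonical correlations are invariant to invertible channel mixing", {
  set.seed(4)
  n <- 300
  X <- matrix(rnorm(n * 5), n, 5)
  Y <- matrix(rnorm(n * 4), n, 4)
  A <- matrix(rnorm(25), 5, 5) + diag(5)
  f1 <- fit_cca(X, Y, ridge = 0)
  f2 <- fit_cca(X %*% A, Y, ridge = 0)
  expect_equal(f1$rho, f2$rho, tolerance = 1e-8)
  for (k in 1:4) {
    expect_gt(abs(cor(X %*% f1$W[, k], (X %*% A) %*% f2$W[, k])), 1 - 1e-6)
  }
  # per-channel rescaling (diagonal A) leaves everything unchanged too
  D <- diag(c(1, 10, 0.01, 5, 100))
  f3 <- fit_cca(X %*% D, Y, ridge = 0)
  expect_equal(f1$rho, f3$rho, tolerance = 1e-10)
})

test_that("component retention applies the rho floor and the sequential test", {
  expect_equal(select_components(rep(0, 5), 1000, 29, 41), 0L)
  expect_equal(select_components(c(0.9, 0.05, 0.01), 5000, 29, 41), 1L)
  # recompute the sequential Bartlett test independently
  rho <- c(0.3, 0.25, 0.12)
  N <- 5000; c <- 29; d <- 41
  ok <- logical(3)
  for (i in 1:3) {
    stat <- -(N - 1 - (c + d + 1) / 2) * sum(log(1 - rho[i:3]^2))
    df <- (c - i + 1) * (d - i + 1)
    ok[i] <- (rho[i] >= 0.1) && (pchisq(stat, df, lower.tail = FALSE) < 0.05)
  }
  K_expected <- if (!ok[1]) 0L else max(which(cumsum(!ok) == 0))
  expect_equal(select_components(rho, N, c, d), K_expected)
  # tiny N: nothing is significant
  expect_equal(select_components(c(0.3, 0.2), 10, 29, 41), 0L)
})

test_that("training on labeled trials recovers the planted component", {
  ds <- fx_highsnr_subject()
  model <- train_filter_model(ds$trials)
  expect_false(model$degenerate)
  tmpl <- subject_template(ds$subjects[[1]], ds$config)
  expect_gt(abs(cor(model$S[, 1], tmpl)), 0.95)
  # spatial pattern ranks the planted channels highest
  topo <- ds$subjects[[1]]$topography
  w_imp <- abs(model$W[, 1] * model$scale_x)
  top4 <- order(w_imp, decreasing = TRUE)[1:4]
  expect_true(all(top4 %in% order(abs(topo), decreasing = TRUE)[1:8]))
})

test_that("single-trial fits work and duplicated trials change nothing", {
  ds <- fx_default_subject()
  one <- train_filter_model(ds$trials[1])
  expect_s3_class(one, "filter_model")
  sub <- ds$trials[1:12]
  m1 <- train_filter_model(sub)
  m2 <- train_filter_model(c(sub, sub))
  # the CCA solution is unchanged by duplication (correlations are
  # scale-free); only the sample count entering the significance test
  # doubles, so compare the leading components common to both fits
  k <- seq_len(min(m1$K, m2$K))
  expect_equal(m1$rho[k], m2$rho[k], tolerance = 1e-6)
  expect_equal(m1$W[, k, drop = FALSE], m2$W[, k, drop = FALSE],
               tolerance = 1e-3)
  expect_equal(m1$S[, k, drop = FALSE], m2$S[, k, drop = FALSE],
               tolerance = 1e-3)
  expect_error(train_filter_model(list()), "no training trials")
})

test_that("the initial model averages channels and uses a hat template", {
  m <- initial_filter_model(29, 41)
  expect_equal(m$W, matrix(1, 29, 1))
  expect_equal(which.max(m$S[, 1]), 21) # 0-based index 20
  expect_equal(m$S[, 1], rev(m$S[, 1])) # symmetric triangle
  expect_equal(initial_filter_model(3, 1)$S[, 1], 1)
  # projection with the initial model is the plain channel sum
  X <- matrix(rnorm(60), 20, 3)
  expect_equal(drop(project_trial(X, initial_filter_model(3, 5)$W)),
               rowSums(X))
})

test_that("channel ranking recovers planted support and keeps full sets intact", {
  # signal confined to 4 known channels out of 12
  cfg <- mini_cfg(n_channels = 12L, snr = 6, n_runs = 3L,
                  trials_per_run = 8L, seed = 33)
  ds <- simulate_dataset(cfg)
  support <- c(2L, 5L, 7L, 9L)
  topo <- numeric(12); topo[support] <- c(0.6, 0.55, 0.5, 0.58)
  subj <- ds$subjects[[1]]
  subj$topography <- topo / sqrt(sum(topo^2))
  trials <- with_seed_trials <- lapply(seq_along(ds$trials), function(i) {
    tr <- ds$trials[[i]]
    sim <- simulate_trial(subj, tr$schedule, tr$target, cfg, seed = 1000 + i,
                          run_id = tr$run_id, subject_id = 1)
    lowpass_decimate(sim, cfg$decim_factor)
  })
  model <- train_filter_model(trials)
  sel <- channel_subset(model, trials, 4)
  expect_equal(sel$channels, support)
  expect_s3_class(sel$model, "filter_model")
  # keeping every channel reproduces the model
  all_ch <- channel_subset(model, trials, 12)
  expect_equal(all_ch$channels, 1:12)
  expect_equal(all_ch$model$rho, model$rho, tolerance = 1e-8)
  expect_error(channel_subset(model, trials, 0), "n_keep")
})
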
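test_that("decoding accuracy is the fraction of correct predictions", {
  mk <- function(pred, true) {
    structure(list(predicted = as.integer(pred), ranking = 1:12,
                   true_target = as.integer(true)),
              class = "decoding_result")
  }
  all_right <- lapply(1:12, function(i) mk(i, i))
  expect_equal(decoding_accuracy(all_right), 1)
  one_wrong <- c(all_right[1:11], list(mk(1, 2)))
  expect_equal(decoding_accuracy(one_wrong), 11 / 12)
  expect_error(decoding_accuracy(list()), "no decoding results")
  set.seed(20)
  rand <- lapply(1:10000, function(i) mk(sample(12, 1), sample(12, 1)))
  expect_equal(decoding_accuracy(rand), 1 / 12, tolerance = 0.15)
})

test_that("the Wolpaw ITR matches closed forms and is monotone in accuracy", {
  expect_equal(wolpaw_itr(1, 12, 10, 2.5), log2(12) * 60 / 12.5,
               tolerance = 1e-12)
  expect_equal(wolpaw_itr(1 / 12, 12, 10, 2.5), 0, tolerance = 1e-9)
  expect_equal(wolpaw_itr(0.911, 12, 10, 2.5),
               (log2(12) + 0.911 * log2(0.911) +
                  0.089 * log2(0.089 / 11)) * 60 / 12.5,
               tolerance = 1e-12)
  # strictly increasing on (1/N, 1]
  p <- seq(1 / 12 + 0.01, 1, length.out = 50)
  b <- vapply(p, wolpaw_itr, numeric(1), N = 12, trial_seconds = 10)
  expect_true(all(diff(b) > 0))
  expect_error(wolpaw_itr(0.5, 1, 10), "N must be")
  expect_error(wolpaw_itr(1.2, 12, 10), "P must")
})

test_that("leave-one-run-out CV is deterministic and order-invariant", {
  ds <- fx_default_subject()
  rep1 <- leave_one_run_out_cv(ds$trials)
  rep2 <- leave_one_run_out_cv(ds$trials)
  expect_equal(rep1$da, rep2$da)
  shuffled <- ds$trials[with_seed_order(length(ds$trials), 99)]
  rep3 <- leave_one_run_out_cv(shuffled)
  expect_equal(rep3$da, rep1$da)
  expect_equal(sort(names(rep1$per_run)), sort(names(rep3$per_run)))
  expect_true(rep1$da >= 0 && rep1$da <= 1)
  expect_error(leave_one_run_out_cv(ds$trials[1:12]), "two runs")
})

test_that("high-SNR subjects decode almost perfectly, null subjects at chance", {
  expect_gt(leave_one_run_out_cv(fx_highsnr_subject()$trials)$da, 0.95)
  cfg <- sim_config("eeg", snr = 0, n_subjects = 1, n_runs = 2, seed = 44)
  null_da <- leave_one_run_out_cv(simulate_dataset(cfg)$trials)$da
  k <- round(null_da * 24)
  expect_gt(stats::binom.test(k, 24, 1 / 12)$p.value, 0.01)
})

test_that("online simulation bootstraps from the initial model and improves", {
  ds <- fx_default_subject()
  rep <- online_simulation(ds$trials)
  expect_equal(rep$curve$n_train[1], 0L) # first trial: untrained model
  # accuracy is high within the first 20 trials and stays there
  expect_gt(rep$curve$cum_da[20], 0.7)
  expect_gt(mean(rep$curve$correct[2:48]), 0.8)
  # per-trial vs per-run refitting converge to the same final model
  rep_all <- online_simulation(ds$trials[1:24], per_trial_runs = 99)
  rep_run <- online_simulation(ds$trials[1:24], per_trial_runs = 0)
  expect_equal(rep_all$model$W, rep_run$model$W, tolerance = 1e-10)
  expect_equal(rep_all$model$S, rep_run$model$S, tolerance = 1e-10)
})

test_that("permutation relabeling estimates the guessing level near 1/m", {
  ds <- fixture("perm_ds", function() {
    simulate_dataset(sim_config("eeg", n_subjects = 1, n_runs = 2, seed = 31))
  })
  pc <- permutation_chance(ds$trials, n_perm = 60, seed = 17)
  mc_half_width <- 1.96 * sd(pc$das) / sqrt(pc$n_perm)
  expect_lt(abs(pc$mean - 1 / 12), mc_half_width + 1e-9)
  expect_true(pc$mean >= pc$ci95[1] && pc$mean <= pc$ci95[2])
  # the unpermuted accuracy separates from the permutation interval
  expect_gt(leave_one_run_out_cv(ds$trials)$da, pc$ci95[2])
  one <- permutation_chance(ds$trials, n_perm = 1, seed = 3)
  expect_length(one$das, 1)
})

test_that("truncating stimulation shortens schedules and data consistently", {
  ds <- fx_highsnr_subject()
  tr <- ds$trials[[1]]
  expect_identical(truncate_stimuli(tr, 5), tr) # identity at full length
  short <- truncate_stimuli(tr, 1)
  expect_length(short$schedule$global_order, 12)
  expect_equal(nrow(short$X),
               round((11 * (1 / 6) + 0.8) * tr$fs)) # ~2.6 s segment
  expect_silent(validate_schedule(short$schedule))
  expect_error(truncate_stimuli(tr, 0), "reps_kept")
  # accuracy grows with the number of stimuli per object
  das <- vapply(c(1, 3, 5), function(k) {
    leave_one_run_out_cv(truncate_stimuli(ds$trials, k))$da
  }, numeric(1))
  expect_gte(das[2], das[1] - 0.05)
  expect_gte(das[3], das[2] - 0.05)
  expect_gt(das[3], das[1] - 0.05)
})

test_that("matched-filter similarity behaves like a correlation", {
  s <- exp(-((0:40) - 20)^2 / 60)
  expect_equal(component_similarity(s, s), 1)
  expect_equal(component_similarity(s, -s), -1)
  expect_error(component_similarity(s, s[1:10]), "equal length")
  expect_error(component_similarity(rep(1, 41), s), "zero-variance")
  expect_equal(average_similarity(c(0.8, 0.8)), 0.8, tolerance = 1e-12)
  # atanh-scale averaging weighs strong correlations more than the raw mean
  expect_gt(average_similarity(c(0.99, 0.5)), mean(c(0.99, 0.5)))
})

test_that("templates recovered across subjects agree with the planted one", {
  ds <- fx_shared_cohort()
  subj_ids <- vapply(ds$trials, function(tr) tr$subject_id, integer(1))
  rs <- vapply(1:4, function(s) {
    model <- train_filter_model(ds$trials[subj_ids == s])
    tmpl <- subject_template(ds$subjects[[s]], ds$config)
    abs(cor(model$S[, 1], tmpl))
  }, numeric(1))
  expect_gt(mean(rs), 0.9)
})

test_that("the difference wave isolates the attended evoked response", {
  ds <- fx_highsnr_subject()
  dw <- difference_wave(ds$trials)
  # peak channel and latency of the difference wave match the plant
  topo <- ds$subjects[[1]]$topography
  best_ch <- which.max(abs(topo))
  peak_idx <- which.max(dw$difference[, best_ch])
  lat_samples <- ds$subjects[[1]]$latency * ds$trials[[1]]$fs
  expect_lt(abs(peak_idx - 1 - lat_samples), 2.5) # within +-2 samples
  # zero-amplitude evoked response: difference wave ~ 0, but the 6 Hz
  # stimulus-locked component persists in single-condition averages
  cfg0 <- sim_config("eeg", snr = 0, noise_white = 0.02, noise_pink = 0,
                     n_subjects = 1, n_runs = 1, seed = 61)
  ds0 <- simulate_dataset(cfg0)
  dw0 <- difference_wave(ds0$trials)
  expect_lt(max(abs(dw0$difference)), 0.1 * max(abs(dw0$attended)))
  amp6 <- function(x) { # 6 Hz amplitude in an epoch-average trace
    t <- dw0$times
    B <- cbind(sin(2 * pi * 6 * t), cos(2 * pi * 6 * t))
    sqrt(sum(qr.coef(qr(B), x - mean(x))^2))
  }
  strongest <- which.max(colSums(dw0$attended^2))
  expect_gt(amp6(dw0$attended[, strongest]),
            10 * amp6(dw0$difference[, strongest]))
  expect_error(difference_wave(list()), "no trials")
})
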
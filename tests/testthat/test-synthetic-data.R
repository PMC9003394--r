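test_that("trial generation is bit-reproducible and respects the degenerate cases", {
  cfg <- quick_config()
  t1 <- simulate_trial(cfg, c(6, 9.5), seed = 123)
  t2 <- simulate_trial(cfg, c(6, 9.5), seed = 123)
  expect_identical(t1$data, t2$data)
  t3 <- simulate_trial(cfg, c(6, 9.5), seed = 124)
  expect_false(identical(t1$data, t3$data))

  # the local seed must not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(simulate_trial(cfg, c(6, 9.5), seed = 5)); b <- runif(1)
  expect_identical(a, b)

  # evoked amplitude zero: identical config/seed with and without the
  # evoked term gives the same pure-noise output
  cfg_off <- quick_config(snr_db = -Inf)
  off <- simulate_trial(cfg_off, c(6, 9.5), seed = 9)
  expect_equal(dim(off$data), c(6, 1750))
  expect_true(all(is.finite(off$data)))

  expect_error(simulate_trial(quick_config(nh_signal = 30L), c(6, 9.5)),
               "Nyquist")
})

test_that("averaged high-SNR spectra peak at the pair frequencies and harmonics only", {
  cfg <- quick_config(snr_db = 20)
  fs <- cfg$fs
  acc <- NULL
  for (i in 1:50) {
    tr <- simulate_trial(cfg, c(6, 9.5), seed = 9000 + i)
    p <- welch_psd(tr$data["Oz", ], fs, L = 1000)
    acc <- if (is.null(acc)) p$power else acc + p$power
  }
  p$power <- acc / 50
  peaks <- dfssmvep:::psd_peaks(p, fmax = 25)
  expected <- c(6, 9.5, 12, 19)  # fundamentals and 2nd harmonics
  top <- sort(p$frequency[peaks[1:4]])
  expect_equal(top, sort(expected), tolerance = 1e-9)
  # no non-plan frequency among the strong local maxima
  strong <- p$frequency[peaks[p$power[peaks] > 0.2 * max(p$power[peaks])]]
  expect_true(all(vapply(strong, function(f)
    min(abs(f - expected)) < 0.5, logical(1))))
})

test_that("dataset emulation yields the protocol shape with uniform labels", {
  plan <- five_target_plan()
  cfg <- quick_config()
  ds <- simulate_dataset(cfg, plan, n_subjects = 2, n_sessions = 2,
                         n_trials_per_target = 4)
  expect_equal(nrow(ds$manifest), 2 * 2 * 5 * 4)
  expect_equal(unname(table(ds$manifest$target)), rep(16L, 5),
               ignore_attr = TRUE)
  per_subject <- table(ds$manifest$subject)
  expect_true(all(per_subject == 40))  # 2 sessions x 5 targets x 4 trials
  per_cell <- table(ds$manifest$subject, ds$manifest$target)
  expect_true(all(per_cell == 8))

  mini <- simulate_dataset(cfg, plan, 1, 1, 1)
  expect_equal(nrow(mini$manifest), 5)
  expect_equal(sort(mini$manifest$target), 1:5)

  expect_error(simulate_dataset(cfg, plan, 0, 1, 1), "n_subjects")
})

test_that("end-to-end recovery is near-perfect at high SNR and at chance deep in noise", {
  plan <- five_target_plan()
  cfg_hi <- quick_config(snr_db = 10)
  ds_hi <- simulate_dataset(cfg_hi, plan, n_subjects = 2, n_sessions = 1,
                            n_trials_per_target = 4)
  expect_gte(decode_accuracy(ds_hi$trials, plan), 0.95)

  # far below the detection threshold the decoder is at chance
  cfg_lo <- quick_config(snr_db = -30)
  ds_lo <- simulate_dataset(cfg_lo, plan, n_subjects = 5, n_sessions = 2,
                            n_trials_per_target = 2)
  acc_lo <- decode_accuracy(ds_lo$trials, plan)
  expect_lt(abs(acc_lo - 0.2), 3 * sqrt(0.2 * 0.8 / 100))
})

test_that("attenuating one pair frequency suppresses its single-frequency score but not BCCA's rho1", {
  plan <- five_target_plan()
  betas <- c(1, 0.5, 0.25, 0.1)
  mean_rho2 <- mean_rho1 <- numeric(length(betas))
  for (k in seq_along(betas)) {
    cfg <- quick_config(snr_db = 0, amplitude_imbalance = betas[k])
    r1 <- r2 <- numeric(15)
    for (i in 1:15) {
      tr <- bandpass_filter(simulate_trial(cfg, c(6, 9.5), seed = 40 + i))
      feat <- bcca_classify(tr, plan)$features[[5]]  # target (6, 9.5)
      r1[i] <- feat[["rho1"]]
      r2[i] <- feat[["rho2"]]
    }
    mean_rho1[k] <- mean(r1)
    mean_rho2[k] <- mean(r2)
  }
  # the weak-frequency correlation decays monotonically toward noise level
  expect_true(all(diff(mean_rho2) < 0))
  # while the strong-frequency correlation stays high throughout
  expect_true(all(mean_rho1 > 0.8 * mean_rho1[1]))
})
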
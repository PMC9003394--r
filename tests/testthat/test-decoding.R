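fs <- 500

test_that("harmonic reference sets have the sampled-sinusoid structure", {
  y <- harmonic_references(6, 2, fs, 1750)
  expect_equal(dim(y), c(4, 1750))
  expect_equal(attr(y, "frequencies"), c(6, 6, 12, 12))
  # squared norm of each row ~ m/2 for integer cycle counts
  expect_equal(rowSums(unclass(y)^2), rep(1750 / 2, 4), tolerance = 0.01)

  y7 <- harmonic_references(7, 1, fs, 500)
  expect_lt(abs(sum(y7[1, ] * y7[2, ])), 1e-9)  # cos/sin orthogonal

  expect_error(harmonic_references(7, 40, fs, 1750), "Nyquist")
})

test_that("first canonical correlation matches a brute-force projection search", {
  set.seed(31)
  for (i in 1:20) {
    m <- sample(40:120, 1)
    X <- matrix(rnorm(2 * m), 2)
    Y <- matrix(rnorm(2 * m), 2)
    got <- first_canonical_correlation(X, Y)$rho
    expect_equal(got, brute_force_cca(X, Y), tolerance = 1e-3)
    expect_gte(got, 0)
    expect_lte(got, 1)
  }
})

test_that("canonical correlation is exact on aligned, disjoint, and mixed inputs", {
  set.seed(5)
  Z <- matrix(rnorm(3 * 100), 3)
  expect_equal(first_canonical_correlation(Z, Z)$rho, 1, tolerance = 1e-12)

  # disjoint Fourier frequencies over integer cycles decorrelate completely
  tt <- (1:500) / fs
  X7 <- rbind(sin(2 * pi * 7 * tt), cos(2 * pi * 7 * tt))
  expect_lt(first_canonical_correlation(X7, harmonic_references(11, 2, fs, 500))$rho,
            0.05)

  # invariance under invertible channel mixing
  X <- matrix(rnorm(6 * 500), 6)
  Y <- harmonic_references(7, 2, fs, 500)
  A <- matrix(rnorm(36), 6)
  expect_equal(first_canonical_correlation(A %*% X, Y)$rho,
               first_canonical_correlation(X, Y)$rho, tolerance = 1e-9)

  # returned weights realise the reported correlation
  cc <- first_canonical_correlation(X, Y)
  px <- drop(cc$w_x %*% (X - rowMeans(X)))
  py <- drop(cc$w_y %*% (Y - rowMeans(Y)))
  expect_equal(abs(stats::cor(px, py)), cc$rho, tolerance = 1e-9)
})

test_that("CCA scores are invariant to the reference time origin", {
  set.seed(8)
  X <- matrix(rnorm(6 * 1750), 6)
  tt <- (1:1750) / fs
  for (shift in c(0.123, 1, -0.4)) {
    ts <- tt + shift
    Yshift <- rbind(cos(2 * pi * 7 * ts), sin(2 * pi * 7 * ts),
                    cos(2 * pi * 14 * ts), sin(2 * pi * 14 * ts))
    expect_equal(first_canonical_correlation(X, Yshift)$rho,
                 first_canonical_correlation(X, harmonic_references(7, 2, fs, 1750))$rho,
                 tolerance = 1e-9)
  }
})

test_that("rank-deficient and degenerate inputs are handled, not crashed", {
  set.seed(12)
  base <- matrix(rnorm(2 * 200), 2)
  X <- rbind(base, base[1, ] + base[2, ])  # rank 2 in 3 rows
  Y <- harmonic_references(9, 1, fs, 200)
  rho <- first_canonical_correlation(X, Y)$rho
  expect_true(is.finite(rho) && rho >= 0 && rho <= 1)
  expect_error(first_canonical_correlation(matrix(1, 2, 200), Y),
               "non-constant")
})

test_that("standard CCA recognises the driving frequency and its invariances", {
  tt <- (1:1750) / fs
  X <- rbind(sin(2 * pi * 8 * tt) + 0.5 * sin(2 * pi * 16 * tt),
             cos(2 * pi * 8 * tt) + 0.3 * cos(2 * pi * 16 * tt),
             0.7 * sin(2 * pi * 8 * tt + 0.4))
  res <- cca_classify(X, c(5, 6, 7, 8, 9), Nh = 2, fs = fs)
  expect_equal(res$predicted, 4L)
  expect_equal(res$scores[["8Hz"]], 1, tolerance = 1e-6)

  # invertible mixing leaves the prediction unchanged
  set.seed(3)
  A <- matrix(rnorm(9), 3)
  res_mixed <- cca_classify(A %*% X, c(5, 6, 7, 8, 9), Nh = 2, fs = fs)
  expect_equal(res_mixed$predicted, 4L)
  expect_equal(res_mixed$scores, res$scores, tolerance = 1e-9)

  # pure noise still yields an argmax prediction (no abstention)
  noise <- matrix(rnorm(6 * 1750), 6)
  rn <- cca_classify(noise, c(5, 6, 7, 8, 9), Nh = 2, fs = fs)
  expect_true(rn$predicted %in% 1:5)
  expect_true(all(rn$scores < 0.5))
})

test_that("BCCA reference triplets stack both frequencies plus their sum", {
  refs <- bcca_reference_triplet(c(6, 9.5), 2, fs, 1750)
  expect_equal(nrow(refs$yc), 10)  # 4*Nh + 2
  expect_true(any(abs(attr(refs$yc, "frequencies") - 15.5) < 1e-12))
  expect_equal(dim(refs$y1), c(4, 1750))
  expect_equal(dim(refs$y2), c(4, 1750))

  refs1 <- bcca_reference_triplet(c(5, 8.5), 1, fs, 1750)
  expect_setequal(unique(attr(refs1$yc, "frequencies")), c(5, 8.5, 13.5))

  # degenerate equal pair: duplicated rows dropped, full row rank
  dg <- bcca_reference_triplet(c(6, 6), 2, fs, 1750)
  expect_equal(qr(t(unclass(dg$yc)))$rank, nrow(dg$yc))

  expect_error(bcca_reference_triplet(c(200, 100), 1, fs, 1750), "Nyquist")
})

test_that("BCCA scores average the three correlations and decode dual-frequency trials", {
  plan <- five_target_plan()
  tt <- (1:1750) / fs
  # noiseless trial carrying both frequencies of target (6, 9.5): four
  # channels mixing the sin/cos quadratures with a full-rank matrix, so
  # the decoder can isolate either frequency by channel combination
  comps <- rbind(sin(2 * pi * 6 * tt), cos(2 * pi * 6 * tt),
                 sin(2 * pi * 9.5 * tt), cos(2 * pi * 9.5 * tt))
  set.seed(61)
  X <- matrix(rnorm(16), 4) %*% comps
  res <- bcca_classify(X, plan, Nh = 2, fs = fs)
  tg <- which(plan$pairs$a == 6)
  expect_equal(res$predicted, tg)
  feat <- res$features[[tg]]
  expect_gt(feat[["rho1"]], 0.99)
  expect_gt(feat[["rho2"]], 0.99)
  expect_gt(feat[["rhoc"]], 0.99)
  for (f in res$features) {
    expect_true(all(f[c("rho1", "rho2", "rhoc")] >= 0 &
                      f[c("rho1", "rho2", "rhoc")] <= 1))
    expect_identical(f[["rho_a"]],
                     (f[["rho1"]] + f[["rho2"]] + f[["rhoc"]]) / 3)
  }

  # a trial at a frequency outside the plan, its harmonics, and its sum
  # frequencies still returns an argmax index, with low scores throughout
  Xoff <- rbind(sin(2 * pi * 3.3 * tt), cos(2 * pi * 3.3 * tt))
  roff <- bcca_classify(Xoff, plan, Nh = 2, fs = fs)
  expect_true(roff$predicted %in% seq_len(nrow(plan$pairs)))
  expect_true(all(roff$scores < 0.5))
})

test_that("BCCA rescues imbalanced trials that single-frequency CCA at the weak frequency misses", {
  plan <- five_target_plan()
  cfg <- quick_config(snr_db = 0, amplitude_imbalance = 0.25)
  hits_b <- 0L; hits_bcca <- 0L
  n <- 20L
  for (i in seq_len(n)) {
    tr <- simulate_trial(cfg, c(6, 9.5), seed = 500 + i, true_target = 5L)
    tr <- bandpass_filter(tr)
    # CCA offered only the secondary (attenuated) frequencies
    hits_b <- hits_b + (cca_classify(tr, plan$pairs$b)$predicted == 5L)
    hits_bcca <- hits_bcca + (bcca_classify(tr, plan)$predicted == 5L)
  }
  expect_gte(hits_bcca, hits_b)
  expect_gt(hits_bcca / n, 0.9)
})
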
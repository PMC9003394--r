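# Shared fixtures: the canonical five-target plan, small simulation
# configurations, and an independent brute-force CCA oracle.

five_target_plan <- function() assign_dual_frequencies(c(5, 6, 7, 8, 9))

quick_config <- function(...) simulation_config(seed = 101L, ...)

# Independent oracle for the first canonical correlation on 2 x m inputs:
# exhaustive grid search over unit projection vectors on both sides.
brute_force_cca <- function(X, Y, n_grid = 3142L) {
  th <- seq(0, pi, length.out = n_grid)
  W <- rbind(cos(th), sin(th))
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  Px <- t(W) %*% Xc
  Py <- t(W) %*% Yc
  Px <- Px - rowMeans(Px)
  Py <- Py - rowMeans(Py)
  nx <- sqrt(rowSums(Px^2))
  ny <- sqrt(rowSums(Py^2))
  C <- (Px %*% t(Py)) / (nx %o% ny)
  max(abs(C))
}

# Decode a list of trials (band-pass first) and return accuracy.
decode_accuracy <- function(trials, plan, method = "bcca", Nh = 2L) {
  pred <- vapply(trials, function(tr) {
    tr <- bandpass_filter(tr)
    if (method == "bcca") bcca_classify(tr, plan, Nh)$predicted
    else cca_classify(tr, plan$pairs$a, Nh)$predicted
  }, integer(1))
  truth <- vapply(trials, function(tr) as.integer(tr$true_target), integer(1))
  mean(pred == truth)
}
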
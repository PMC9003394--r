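# Frequency recognition by canonical correlation against sinusoidal
# references: standard CCA scores one reference set per candidate frequency;
# bifold CCA (BCCA) scores each dual-frequency target with three reference
# sets -- one per pair frequency plus a combined set carrying both and their
# sum frequency -- and averages the three first canonical correlations.

#' Sin/cos harmonic reference set for one stimulation frequency
#'
#' Builds the 2*Nh reference rows `cos(2*pi*h*f*t)`, `sin(2*pi*h*f*t)` for
#' harmonics `h = 1..Nh`, evaluated at the 1-based sample times
#' `t = 1/fs, ..., m/fs`. The decoder correlates EEG channels against this
#' matrix; its row space (not the time origin) is what matters.
#'
#' @param f Stimulation frequency in Hz.
#' @param Nh Number of harmonics (>= 1).
#' @param fs Sampling rate in Hz; requires `f * Nh < fs / 2`.
#' @param m Number of samples (>= 2 * Nh).
#' @return A `reference_set`: numeric matrix of `2 * Nh` rows and `m`
#'   columns with attribute `frequencies` giving each row's frequency.
#' @export
harmonic_references <- function(f, Nh, fs, m) {
  stopifnot(f > 0, Nh >= 1, fs > 0, m >= 2 * Nh)
  if (f * Nh >= fs / 2)
    stop(sprintf("harmonic %d of %g Hz is at or above the Nyquist frequency %g Hz",
                 Nh, f, fs / 2))
  t <- seq_len(m) / fs
  rows <- matrix(0, nrow = 2L * Nh, ncol = m)
  freqs <- numeric(2L * Nh)
  for (h in seq_len(Nh)) {
    rows[2L * h - 1L, ] <- cos(2 * pi * h * f * t)
    rows[2L * h, ] <- sin(2 * pi * h * f * t)
    freqs[c(2L * h - 1L, 2L * h)] <- h * f
  }
  structure(rows, frequencies = freqs, class = c("reference_set", "matrix"))
}

# First canonical pair via QR + SVD on row-centered data. Rank deficiency is
# handled by truncating the QR at a relative tolerance, which keeps the
# result exactly invariant under invertible channel mixing (the orthonormal
# basis spans the same subspace).
#' First canonical correlation between two multichannel signals
#'
#' Finds projection vectors `w_x`, `w_y` maximising the correlation between
#' `w_x' X` and `w_y' Y` and returns the maximised (first) canonical
#' correlation. Rows are centered; each side is reduced to an orthonormal
#' basis of its row space by a rank-revealing QR, and the correlations are
#' the singular values of the product of the two bases, so the value is
#' invariant under invertible linear mixing of either side's rows and is
#' well defined for rank-deficient inputs.
#'
#' @param X Numeric matrix, variables x samples (e.g. EEG channels).
#' @param Y Numeric matrix, variables x samples (e.g. a reference set),
#'   same sample count.
#' @return A list with `rho` (in \[0, 1\]), `w_x`, `w_y` (unit-norm
#'   projection vectors, zero in directions removed by rank truncation).
#' @export
first_canonical_correlation <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  m <- ncol(X)
  if (ncol(Y) != m) stop("X and Y must have the same number of samples")
  if (m <= nrow(X) + nrow(Y))
    stop("need more samples than total variables for a meaningful CCA")
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("inputs must be finite")
  orth <- function(A) {
    Ac <- A - rowMeans(A)
    qr_a <- qr(t(Ac), LAPACK = TRUE)
    d <- abs(diag(qr_a$qr))[seq_len(min(dim(A)))]
    rank <- sum(d > max(d[1], 0) * max(dim(Ac)) * .Machine$double.eps)
    if (rank == 0L)
      stop("input has no non-constant row")
    list(Q = qr.Q(qr_a)[, seq_len(rank), drop = FALSE],
         R = qr.R(qr_a)[seq_len(rank), seq_len(rank), drop = FALSE],
         pivot = qr_a$pivot, rank = rank, p = nrow(A))
  }
  ox <- orth(X); oy <- orth(Y)
  sv <- svd(crossprod(ox$Q, oy$Q))
  rho <- min(max(sv$d[1], 0), 1)
  unpivot <- function(o, u) {
    w_r <- backsolve(o$R, u)
    w <- numeric(o$p)
    w[o$pivot[seq_len(o$rank)]] <- w_r
    n <- sqrt(sum(w^2))
    if (n > 0) w / n else w
  }
  list(rho = rho,
       w_x = unpivot(ox, sv$u[, 1]),
       w_y = unpivot(oy, sv$v[, 1]))
}

decoding_result <- function(scores, method, features = NULL) {
  predicted <- unname(which.max(scores))  # ties resolve to the lowest index
  ties <- sum(abs(scores - scores[predicted]) < 1e-12)
  if (ties > 1L)
    message("decoding: ", ties, " tied top scores; lowest target index kept")
  structure(list(scores = scores, predicted = predicted, method = method,
                 features = features),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("%s decoding: predicted target %d\n", toupper(x$method),
              x$predicted))
  print(round(x$scores, 4))
  invisible(x)
}

#' Standard CCA frequency recognition
#'
#' Scores a trial against each candidate frequency's harmonic reference set
#' with the first canonical correlation and predicts the argmax.
#'
#' @param trial An [eeg_trial()], or a channels x samples matrix (then `fs`
#'   is required).
#' @param target_frequencies Candidate stimulation frequencies in Hz.
#' @param Nh Harmonics per reference set (default 2).
#' @param fs Sampling rate, taken from the trial when omitted.
#' @return A `decoding_result` with per-target scores (rho) and the
#'   predicted target index.
#' @export
cca_classify <- function(trial, target_frequencies, Nh = 2L, fs = NULL) {
  X <- if (inherits(trial, "eeg_trial")) trial$data else as.matrix(trial)
  if (is.null(fs)) {
    if (!inherits(trial, "eeg_trial")) stop("'fs' required for a bare matrix")
    fs <- trial$fs
  }
  m <- ncol(X)
  scores <- vapply(target_frequencies, function(f) {
    Y <- harmonic_references(f, Nh, fs, m)
    first_canonical_correlation(X, Y)$rho
  }, numeric(1))
  names(scores) <- paste0(target_frequencies, "Hz")
  decoding_result(scores, "cca")
}

#' BCCA reference triplet for a dual-frequency target
#'
#' For a target carrying frequencies `f1` and `f2`, builds the three
#' reference sets used by bifold CCA: `y1` and `y2` are the harmonic sets of
#' each frequency, and `yc` stacks `y1`, `y2` and the sum-frequency pair
#' `cos/sin(2*pi*(f1+f2)*t)` vertically (`4 * Nh + 2` rows). Rows whose
#' frequencies collide within 1e-9 Hz (degenerate pairs, harmonic overlaps)
#' are de-duplicated so that `yc` has full row rank.
#'
#' @param pair Length-2 numeric vector `(f1, f2)` in Hz.
#' @param Nh Harmonics per frequency.
#' @param fs Sampling rate in Hz; requires `f1 + f2 < fs / 2` and
#'   `Nh * max(pair) < fs / 2`.
#' @param m Number of samples.
#' @return A list with reference sets `y1`, `y2`, `yc`.
#' @export
bcca_reference_triplet <- function(pair, Nh, fs, m) {
  stopifnot(length(pair) == 2L, all(pair > 0))
  f1 <- pair[1]; f2 <- pair[2]
  if (f1 + f2 >= fs / 2)
    stop(sprintf("sum frequency %g Hz is at or above the Nyquist frequency %g Hz",
                 f1 + f2, fs / 2))
  y1 <- harmonic_references(f1, Nh, fs, m)
  y2 <- harmonic_references(f2, Nh, fs, m)
  t <- seq_len(m) / fs
  sum_rows <- rbind(cos(2 * pi * (f1 + f2) * t), sin(2 * pi * (f1 + f2) * t))
  yc <- rbind(unclass(y1), unclass(y2), sum_rows)
  yc_freq <- c(attr(y1, "frequencies"), attr(y2, "frequencies"),
               rep(f1 + f2, 2L))
  yc_phase <- rep(c("cos", "sin"), length.out = nrow(yc))
  keep <- !duplicated(paste(round(yc_freq / 1e-9), yc_phase))
  yc <- yc[keep, , drop = FALSE]
  structure(list(y1 = y1, y2 = y2,
                 yc = structure(yc, frequencies = yc_freq[keep],
                                class = c("reference_set", "matrix"))),
            class = "bcca_references")
}

#' Bifold CCA frequency recognition
#'
#' For each target of a dual-frequency plan, correlates the trial against
#' the target's reference triplet, giving the feature vector
#' `v = (rho1, rho2, rhoc)` and the averaged correlation
#' `rho_a = (rho1 + rho2 + rhoc) / 3`, which is the target's score. The
#' averaged score rescues trials in which only one of the two embedded
#' frequencies produced a strong response. Prediction is the argmax of
#' `rho_a`; the method is unsupervised (no training stage).
#'
#' @param trial An [eeg_trial()] or a channels x samples matrix.
#' @param plan A [assign_dual_frequencies()] frequency plan (or any list
#'   with a `pairs` data frame holding columns `a` and `b`).
#' @param Nh Harmonics per reference set (default 2).
#' @param fs Sampling rate, taken from the trial when omitted.
#' @return A `decoding_result` with per-target scores (rho_a), the
#'   predicted target index, and `features`, a list of per-target
#'   `(rho1, rho2, rhoc, rho_a)` vectors.
#' @export
bcca_classify <- function(trial, plan, Nh = 2L, fs = NULL) {
  X <- if (inherits(trial, "eeg_trial")) trial$data else as.matrix(trial)
  if (is.null(fs)) {
    if (!inherits(trial, "eeg_trial")) stop("'fs' required for a bare matrix")
    fs <- trial$fs
  }
  m <- ncol(X)
  pairs <- plan$pairs
  features <- vector("list", nrow(pairs))
  scores <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    refs <- bcca_reference_triplet(c(pairs$a[i], pairs$b[i]), Nh, fs, m)
    rho1 <- first_canonical_correlation(X, refs$y1)$rho
    rho2 <- first_canonical_correlation(X, refs$y2)$rho
    rhoc <- first_canonical_correlation(X, refs$yc)$rho
    features[[i]] <- c(rho1 = rho1, rho2 = rho2, rhoc = rhoc,
                       rho_a = (rho1 + rho2 + rhoc) / 3)
    scores[i] <- (rho1 + rho2 + rhoc) / 3
  }
  names(scores) <- sprintf("(%gHz,%gHz)", pairs$a, pairs$b)
  decoding_result(scores, "bcca", features = features)
}
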
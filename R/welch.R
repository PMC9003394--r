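# Welch averaged-periodogram spectral estimation, used to verify the evoked
# peaks of a trial and to choose how many harmonics a reference set needs.

#' Welch power spectral density of a single channel
#'
#' Splits the signal into `M` (possibly overlapping) segments of length `L`,
#' windows each, and averages the window-power-normalised periodograms:
#' `P(w) = (1/M) * sum_i (1 / (L * P0)) * |FFT(w * x_i)|^2` with
#' `P0 = (1/L) * sum_n w(n)^2`. Averaging trades frequency resolution
#' (grid spacing `fs / L`) for reduced estimator variance, which is what
#' makes evoked peaks stand out against EEG background noise.
#'
#' @param x Numeric vector of samples (one channel).
#' @param fs Sampling rate in Hz.
#' @param L Segment length in samples (default `fs`, i.e. 1 s; must not
#'   exceed `length(x)`).
#' @param overlap Fractional segment overlap in `[0, 1)` (default 0.5).
#' @param window `"hamming"` (default), `"hann"`, or `"rectangular"`.
#' @return A `psd_estimate`: list with `frequency` (one-sided grid in Hz),
#'   `power`, and the settings `L`, `M`, `window`, `P0`, `fs`.
#' @export
welch_psd <- function(x, fs, L = fs, overlap = 0.5, window = "hamming") {
  x <- as.numeric(x)
  L <- as.integer(L)
  if (L < 2L) stop("'L' must be at least 2 samples")
  if (L > length(x))
    stop(sprintf("segment length L = %d exceeds the signal length %d",
                 L, length(x)))
  if (overlap < 0 || overlap >= 1) stop("'overlap' must be in [0, 1)")
  n <- seq_len(L) - 1L
  w <- switch(match.arg(window, c("hamming", "hann", "rectangular")),
              hamming = 0.54 - 0.46 * cos(2 * pi * n / (L - 1L)),
              hann = 0.5 - 0.5 * cos(2 * pi * n / (L - 1L)),
              rectangular = rep(1, L))
  P0 <- sum(w^2) / L
  step <- max(1L, L - floor(overlap * L))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  M <- length(starts)
  acc <- numeric(L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    acc <- acc + Mod(stats::fft(seg))^2 / (L * P0)
  }
  p <- acc / M
  half <- seq_len(floor(L / 2) + 1L)
  structure(list(frequency = fs * (half - 1L) / L, power = p[half],
                 L = L, M = M, window = window, P0 = P0, fs = fs),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf(
    "Welch PSD: %d segments of %d samples (%s window), grid spacing %g Hz\n",
    x$M, x$L, x$window, x$fs / x$L))
  pk <- x$frequency[which.max(x$power)]
  cat(sprintf(" dominant bin: %g Hz\n", pk))
  invisible(x)
}

# Local maxima of a PSD below a frequency cap, strongest first.
psd_peaks <- function(psd, fmax = Inf) {
  p <- psd$power
  f <- psd$frequency
  idx <- which(diff(sign(diff(p))) == -2) + 1L
  idx <- idx[f[idx] <= fmax]
  idx[order(p[idx], decreasing = TRUE)]
}

#' Choose a harmonic count from a Welch spectrum
#'
#' Returns the largest `h <= max_Nh` such that every multiple `j * f`
#' (`j <= h`) of the stimulation frequency stands above the local noise
#' floor by at least `factor`; the floor at each multiple is the median
#' power over bins within `floor_halfwidth` Hz, excluding the bins within
#' one grid step of the peak itself. Always returns at least 1.
#'
#' @param psd A [welch_psd()] estimate whose grid covers `f * max_Nh`.
#' @param f Stimulation frequency in Hz.
#' @param max_Nh Largest harmonic count to consider.
#' @param factor Peak-over-floor power ratio required (default 3).
#' @param floor_halfwidth Half-width in Hz of the noise-floor neighbourhood
#'   (default 3).
#' @return Integer harmonic count in `[1, max_Nh]`.
#' @export
select_harmonics <- function(psd, f, max_Nh, factor = 3,
                             floor_halfwidth = 3) {
  stopifnot(inherits(psd, "psd_estimate"), f > 0, max_Nh >= 1)
  if (max(psd$frequency) < f * max_Nh)
    stop("PSD grid does not cover harmonic ", max_Nh, " of ", f, " Hz")
  df <- psd$fs / psd$L
  above_floor <- function(ft) {
    i <- which.min(abs(psd$frequency - ft))
    nb <- which(abs(psd$frequency - psd$frequency[i]) <= floor_halfwidth &
                  abs(psd$frequency - psd$frequency[i]) > 1.5 * df)
    if (length(nb) == 0L) return(FALSE)
    psd$power[i] > factor * stats::median(psd$power[nb])
  }
  nh <- 1L
  for (h in seq_len(max_Nh)) {
    if (above_floor(h * f)) nh <- h else break
  }
  max(1L, min(nh, max_Nh))
}
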
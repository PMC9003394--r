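# EEG trial container and pre-processing: zero-phase Chebyshev band-pass
# filtering and epoch extraction.

#' Construct a multi-channel EEG trial
#'
#' @param data Numeric matrix, channels x samples (microvolt scale).
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per channel.
#' @param onset Trial onset in seconds (metadata only).
#' @param true_target Optional ground-truth target index.
#' @param subject,session,run Optional identifiers.
#' @return An object of class `eeg_trial`.
#' @export
eeg_trial <- function(data, fs, channel_labels = NULL, onset = 0,
                      true_target = NA_integer_, subject = NA,
                      session = NA, run = NA) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data)))
    stop("'data' must be a finite numeric matrix")
  if (ncol(data) < 1L) stop("trial must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a positive scalar")
  fs <- as.numeric(fs)
  if (is.null(channel_labels))
    channel_labels <- if (!is.null(rownames(data))) rownames(data)
                      else paste0("ch", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop("channel label count (", length(channel_labels),
         ") does not match channel count (", nrow(data), ")")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 onset = onset, true_target = true_target,
                 subject = subject, session = session, run = run),
            class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("EEG trial: %d channels x %d samples at %g Hz (%.3f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(" channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (!is.na(x$true_target)) cat(" true target:", x$true_target, "\n")
  invisible(x)
}

# Chebyshev type I band-pass coefficients; order is the analog prototype
# order, doubled by the band-pass transform.
cheby_bandpass <- function(low, high, fs, order = 4L, ripple_db = 0.5) {
  signal::cheby1(order, ripple_db, c(low, high) / (fs / 2), type = "pass")
}

#' Zero-phase Chebyshev type I band-pass filter
#'
#' Filters every channel of a trial with a Chebyshev type I band-pass
#' (default 2-40 Hz, the visually evoked band) applied with zero net phase:
#' the squared magnitude response of the designed filter is applied in the
#' frequency domain to an even-reflected extension of each channel. This is
#' the limit of forward-backward time-domain filtering with unbounded
#' reflection padding: the phase response is identically zero, DC and
#' stopband components are attenuated by the two-pass (squared) magnitude,
#' and there are no start-up transients on short trials.
#'
#' @param trial An [eeg_trial()].
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param order Analog prototype order of the Chebyshev design (default 4).
#' @param ripple_db Passband ripple in dB per pass (default 0.5; the
#'   two-pass application doubles it).
#' @return The filtered `eeg_trial` (same shape and metadata).
#' @export
bandpass_filter <- function(trial, low = 2, high = 40, order = 4L,
                            ripple_db = 0.5) {
  stopifnot(inherits(trial, "eeg_trial"))
  fs <- trial$fs
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= fs / 2)
    stop(sprintf("upper band edge %g Hz must be below the Nyquist frequency %g Hz",
                 high, fs / 2))
  bf <- cheby_bandpass(low, high, fs, order, ripple_db)
  padlen <- 3L * (length(bf$a) - 1L)
  m <- ncol(trial$data)
  if (m <= padlen)
    stop(sprintf("trial too short to filter: %d samples <= 3x filter length (%d)",
                 m, padlen))
  # even-reflected extension -> squared magnitude response -> crop
  ext <- cbind(trial$data, trial$data[, rev(seq_len(m)), drop = FALSE])
  z <- exp(-2i * pi * (seq_len(2L * m) - 1L) / (2L * m))
  h <- signal::polyval(rev(bf$b), z) / signal::polyval(rev(bf$a), z)
  gain <- Mod(h)^2
  spec <- t(stats::mvfft(t(ext)))
  filt <- Re(t(stats::mvfft(t(spec * rep(gain, each = nrow(ext))),
                            inverse = TRUE))) / (2L * m)
  out <- trial
  out$data <- filt[, seq_len(m), drop = FALSE]
  rownames(out$data) <- trial$channel_labels
  out
}

#' Extract a time window from a trial
#'
#' Returns the contiguous sub-trial covering `[start, start + length)`
#' seconds, converted to the half-open sample range
#' `[floor(start * fs), floor(start * fs) + floor(length * fs))` with
#' 0-based sample indexing. Metadata is preserved; the onset is shifted by
#' `start`.
#'
#' @param trial An [eeg_trial()].
#' @param start Window start in seconds (>= 0).
#' @param length Window length in seconds (> 0).
#' @return The windowed `eeg_trial`.
#' @export
epoch_window <- function(trial, start, length) {
  stopifnot(inherits(trial, "eeg_trial"))
  if (start < 0) stop("'start' must be non-negative")
  if (length <= 0) stop("'length' must be positive")
  i0 <- floor(start * trial$fs)
  n <- floor(length * trial$fs)
  m <- ncol(trial$data)
  if (i0 + n > m)
    stop(sprintf("window [%g, %g) s exceeds the %g s trial",
                 start, start + length, m / trial$fs))
  out <- trial
  out$data <- trial$data[, (i0 + 1L):(i0 + n), drop = FALSE]
  out$onset <- trial$onset + start
  out
}
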
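# Ground-truthed synthetic SSmVEP-like EEG. The generative model is a
# harmonic evoked component at the target's two frequencies riding on
# occipital-like background noise (1/f "pink" spectrum, a broadband white
# component, and a narrowband alpha rhythm around 10 Hz), mixed into
# channels by per-channel gains. It is a declared test fixture: it gives
# decoders the spectral structure they exploit, not a biophysical forward
# model.

#' Configuration of the synthetic EEG generator
#'
#' Defaults follow the recording protocol the package targets: 6
#' parieto-occipital channels at 500 Hz, 3.5 s trials.
#'
#' @param fs Sampling rate in Hz.
#' @param n_channels Number of channels.
#' @param channel_labels Channel labels.
#' @param trial_length Trial length in seconds.
#' @param nh_signal Number of harmonics in the evoked component.
#' @param harmonic_decay Amplitude ratio between successive harmonics.
#' @param amplitude_imbalance Ratio beta of the secondary (f2) to primary
#'   (f1) evoked amplitude; beta < 1 models trials in which only one of the
#'   two embedded frequencies responds strongly.
#' @param snr_db Evoked-to-noise power ratio in dB, measured across
#'   channels on the raw (unfiltered) trial; `-Inf` switches the evoked
#'   component off.
#' @param pink_exponent Power-law exponent of the background spectrum
#'   (power ~ 1/f^exponent).
#' @param white_fraction Fraction of noise power that is white.
#' @param alpha_fraction Fraction of noise power in the narrowband alpha
#'   rhythm.
#' @param alpha_freq,alpha_bandwidth Centre (Hz) and full bandwidth (Hz) of
#'   the alpha component.
#' @param sum_freq_amplitude Relative amplitude of an optional evoked
#'   component at `f1 + f2` (default 0: no intermodulation is asserted).
#' @param channel_gain_sd Log-scale SD of the per-channel lognormal gains.
#' @param noise_rms Target RMS of the noise in microvolts.
#' @param seed Base seed; identical config + seed reproduce trials
#'   bit-identically.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(fs = 500, n_channels = 6L,
                              channel_labels = c("Po3", "Po4", "Po7", "Po8",
                                                 "Pz", "Oz"),
                              trial_length = 3.5, nh_signal = 2L,
                              harmonic_decay = 0.5,
                              amplitude_imbalance = 1.0, snr_db = 5,
                              pink_exponent = 1.0, white_fraction = 0.1,
                              alpha_fraction = 0.3, alpha_freq = 10,
                              alpha_bandwidth = 2, sum_freq_amplitude = 0,
                              channel_gain_sd = 0.2, noise_rms = 10,
                              seed = 1L) {
  stopifnot(fs > 0, n_channels >= 1, trial_length > 0, nh_signal >= 1,
            harmonic_decay >= 0, amplitude_imbalance >= 0,
            white_fraction >= 0, alpha_fraction >= 0,
            white_fraction + alpha_fraction <= 1, noise_rms > 0)
  if (length(channel_labels) != n_channels)
    stop("channel_labels length must equal n_channels")
  structure(as.list(environment()), class = "simulation_config")
}

# Evaluate a deterministic RNG-consuming expression under a local seed,
# leaving the caller's RNG state untouched.
with_local_seed <- function(seed, expr) {
  if (!is.finite(seed)) stop("seed must be finite")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max), kind = "Mersenne-Twister")
  force(expr)
}

# Per-trial substream: mix the base seed with a counter through a fixed
# affine map mod 2^31 - 1 so every trial is individually reproducible.
trial_seed <- function(base_seed, counter) {
  p <- .Machine$integer.max  # 2^31 - 1
  as.integer((as.numeric(base_seed) * 48271 + as.numeric(counter) * 16807 +
                12345) %% p)
}

# Gaussian noise with a shaped amplitude spectrum, unit RMS, via FFT
# filtering of white noise. `shape(f)` gives the amplitude weight at
# frequency f (>0); DC is zeroed.
shaped_noise <- function(m, fs, shape) {
  x <- stats::rnorm(m)
  sp <- stats::fft(x)
  f <- fs * (seq_len(m) - 1L) / m
  f <- pmin(f, fs - f)  # two-sided -> folded frequency
  wgt <- ifelse(f > 0, shape(f), 0)
  y <- Re(stats::fft(sp * wgt, inverse = TRUE)) / m
  r <- sqrt(mean(y^2))
  if (r > 0) y / r else y
}

#' Simulate one dual-frequency SSmVEP trial
#'
#' Generates `channels x samples` EEG in which the evoked component is
#' `sum_h decay^(h-1) * sin(2*pi*h*f1*t + phase_h)` plus `beta` times the
#' same structure at `f2` (and optionally a sum-frequency term), identical
#' across channels up to multiplicative gains, scaled so that the
#' evoked/noise power ratio over channels equals `snr_db`. Noise is
#' independent per channel: pink + white + narrowband alpha as configured.
#' Phases are drawn per trial; the trial is bit-reproducible from
#' `(config, pair, seed)`.
#'
#' @param config A [simulation_config()].
#' @param pair Length-2 numeric `(f1, f2)` in Hz; all evoked harmonics must
#'   stay below the Nyquist frequency.
#' @param seed Seed for this trial (default `config$seed`).
#' @param channel_gains Optional fixed per-channel gains (e.g. drawn once
#'   per subject); by default lognormal gains are drawn from this trial's
#'   stream.
#' @param true_target,subject,session,run Metadata attached to the trial.
#' @return An [eeg_trial()].
#' @export
simulate_trial <- function(config, pair, seed = config$seed,
                           channel_gains = NULL, true_target = NA_integer_,
                           subject = NA, session = NA, run = NA) {
  stopifnot(inherits(config, "simulation_config"), length(pair) == 2L)
  f1 <- pair[1]; f2 <- pair[2]
  fmax_evoked <- max(config$nh_signal * max(f1, f2), f1 + f2)
  if (fmax_evoked >= config$fs / 2)
    stop(sprintf("evoked content up to %g Hz violates the Nyquist frequency %g Hz",
                 fmax_evoked, config$fs / 2))
  m <- round(config$trial_length * config$fs)
  t <- seq_len(m) / config$fs
  with_local_seed(seed, {
    if (is.null(channel_gains))
      channel_gains <- stats::rlnorm(config$n_channels,
                                     sdlog = config$channel_gain_sd)
    harmonic_sum <- function(f, nh) {
      s <- numeric(m)
      for (h in seq_len(nh)) {
        phase <- stats::runif(1, 0, 2 * pi)
        s <- s + config$harmonic_decay^(h - 1) * sin(2 * pi * h * f * t + phase)
      }
      s
    }
    evoked <- harmonic_sum(f1, config$nh_signal) +
      config$amplitude_imbalance * harmonic_sum(f2, config$nh_signal)
    if (config$sum_freq_amplitude > 0)
      evoked <- evoked + config$sum_freq_amplitude *
        sin(2 * pi * (f1 + f2) * t + stats::runif(1, 0, 2 * pi))
    pink_w <- max(0, 1 - config$white_fraction - config$alpha_fraction)
    noise <- matrix(0, config$n_channels, m)
    for (ch in seq_len(config$n_channels)) {
      nz <- sqrt(pink_w) *
        shaped_noise(m, config$fs,
                     function(f) f^(-config$pink_exponent / 2))
      if (config$white_fraction > 0)
        nz <- nz + sqrt(config$white_fraction) * shaped_noise(m, config$fs,
                                                              function(f) 1)
      if (config$alpha_fraction > 0)
        nz <- nz + sqrt(config$alpha_fraction) *
          shaped_noise(m, config$fs, function(f)
            exp(-(f - config$alpha_freq)^2 /
                  (2 * (config$alpha_bandwidth / 2.355)^2)))
      noise[ch, ] <- config$noise_rms * nz
    }
    evoked_mat <- outer(channel_gains, evoked)
    snr <- 10^(config$snr_db / 10)
    if (!is.finite(snr) || snr <= 0) {
      scale <- 0
    } else {
      pe <- mean(evoked_mat^2)
      pn <- mean(noise^2)
      scale <- sqrt(snr * pn / pe)
    }
    eeg_trial(evoked_mat * scale + noise, config$fs, config$channel_labels,
              true_target = true_target, subject = subject,
              session = session, run = run)
  })
}

#' Simulate a full multi-subject SSmVEP dataset
#'
#' Emulates the protocol structure the package targets: per subject, two
#' sessions in which each of the plan's targets is attended for several
#' trials. Per-subject channel gains are drawn once, and each subject's SNR
#' is jittered around `config$snr_db` (SD 1 dB) to mimic inter-subject
#' variability; every trial then draws its own phases and noise from a
#' counter-derived substream.
#'
#' @param config A [simulation_config()].
#' @param plan A dual-frequency plan from [assign_dual_frequencies()].
#' @param n_subjects,n_sessions,n_trials_per_target Protocol dimensions
#'   (defaults 10, 2, 4: 400 trials for a 5-target plan).
#' @param subject_snr_sd SD in dB of the per-subject SNR jitter (default 1).
#' @return A `ssmvep_dataset`: list with `trials` (list of [eeg_trial()]),
#'   `manifest` (data frame: trial, subject, session, run, target, a, b,
#'   seed), `plan`, `config`.
#' @export
simulate_dataset <- function(config, plan, n_subjects = 10L,
                             n_sessions = 2L, n_trials_per_target = 4L,
                             subject_snr_sd = 1) {
  stopifnot(inherits(config, "simulation_config"),
            n_subjects >= 1, n_sessions >= 1, n_trials_per_target >= 1)
  pairs <- plan$pairs
  n_targets <- nrow(pairs)
  trials <- list()
  manifest <- NULL
  counter <- 0L
  for (s in seq_len(n_subjects)) {
    subj <- with_local_seed(trial_seed(config$seed, 1e6 + s), list(
      gains = stats::rlnorm(config$n_channels, sdlog = config$channel_gain_sd),
      snr = config$snr_db + stats::rnorm(1, 0, subject_snr_sd)))
    cfg_s <- config
    cfg_s$snr_db <- subj$snr
    for (sess in seq_len(n_sessions)) {
      for (tg in seq_len(n_targets)) {
        for (tr in seq_len(n_trials_per_target)) {
          counter <- counter + 1L
          sd_i <- trial_seed(config$seed, counter)
          trial <- simulate_trial(cfg_s, c(pairs$a[tg], pairs$b[tg]),
                                  seed = sd_i, channel_gains = subj$gains,
                                  true_target = tg, subject = s,
                                  session = sess, run = tr)
          trials[[counter]] <- trial
          manifest <- rbind(manifest, data.frame(
            trial = counter, subject = s, session = sess, run = tr,
            target = tg, a = pairs$a[tg], b = pairs$b[tg], seed = sd_i))
        }
      }
    }
  }
  structure(list(trials = trials, manifest = manifest, plan = plan,
                 config = config),
            class = "ssmvep_dataset")
}

#' @export
print.ssmvep_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "Synthetic SSmVEP dataset: %d trials (%d subjects x %d sessions x %d targets x %d trials)\n",
    nrow(m), max(m$subject), max(m$session), max(m$target), max(m$run)))
  cat(sprintf(" fs = %g Hz, trial length = %g s, SNR = %g dB\n",
              x$config$fs, x$config$trial_length, x$config$snr_db))
  invisible(x)
}
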
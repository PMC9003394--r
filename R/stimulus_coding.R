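# Binary stimulus sequencing and dual-frequency target coding.
#
# A motion stimulus on a monitor reverses direction at its target frequency;
# the per-frame direction pattern is the sign of a square wave sampled at the
# frame instants. Targets in the dual-frequency paradigm carry two motions at
# once, so each of N targets is assigned a (primary, secondary) frequency pair
# built from the N base frequencies and the N midpoints between them.

#' Binary stimulus frame sequence for a motion target
#'
#' Samples a square wave of frequency `f` at the frame instants of a monitor
#' running at `refresh_rate` frames per second. Frame `i` (0-based) holds
#' `square(2 * pi * f * i / refresh_rate)` with the usual square-wave
#' convention: `+1` on the first half of each period (where the sine is
#' positive, so the first half-cycle is "expansion") and `-1` on the
#' second, the boundary instants belonging to the half-cycle they start.
#' When `f` does not divide the refresh rate evenly the
#' half-cycles contain unequal numbers of frames; this asymmetric sampling is
#' deliberate and requires no rounding scheme.
#'
#' @param f Stimulus frequency in Hz. Must satisfy `f <= refresh_rate / 2`:
#'   faster oscillations cannot be represented with at least one frame per
#'   half-cycle.
#' @param refresh_rate Monitor refresh rate in frames per second.
#' @param n_frames Number of frames to generate.
#' @return An object of class `stimulus_sequence`: a list with elements
#'   `frames` (integer vector of +1/-1), `f`, `refresh_rate`.
#' @examples
#' s <- binary_stimulus_sequence(5, 60, 12)
#' s$frames  # six +1 frames then six -1 frames
#' @export
binary_stimulus_sequence <- function(f, refresh_rate, n_frames) {
  stopifnot(is.numeric(f), length(f) == 1L, is.numeric(refresh_rate),
            length(refresh_rate) == 1L, is.numeric(n_frames),
            length(n_frames) == 1L)
  if (f <= 0 || refresh_rate <= 0)
    stop("'f' and 'refresh_rate' must be positive")
  if (n_frames < 1) stop("'n_frames' must be at least 1")
  if (f > refresh_rate / 2)
    stop(sprintf(
      "stimulus frequency %g Hz exceeds refresh_rate/2 = %g Hz and cannot be rendered",
      f, refresh_rate / 2))
  i <- seq_len(n_frames) - 1L
  # phase position within the period decides the sign; comparing the
  # fractional phase (not sin()) keeps the exact half-period boundaries on
  # the correct side despite floating-point sin(k*pi) != 0
  frac <- (f * i / refresh_rate) %% 1
  s <- ifelse(frac < 0.5 - 1e-9, 1L, -1L)
  structure(list(frames = s, f = f, refresh_rate = refresh_rate),
            class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("Stimulus sequence: f = %g Hz at %g frames/s, %d frames\n",
              x$f, x$refresh_rate, length(x$frames)))
  n <- min(24L, length(x$frames))
  cat(" first frames:", paste(sprintf("%+d", x$frames[seq_len(n)]),
                              collapse = " "),
      if (length(x$frames) > n) "..." else "", "\n")
  invisible(x)
}

#' Highest renderable stimulus frequency for a refresh rate
#'
#' A comfortable, interpretable motion stimulus needs at least `k` frames per
#' half-cycle, bounding the stimulus frequency by `refresh_rate / k`.
#'
#' @param refresh_rate Monitor refresh rate in frames per second.
#' @param k Minimum number of frames per half-cycle (integer >= 1; the
#'   package default elsewhere is 3).
#' @return Upper frequency bound in Hz.
#' @examples
#' max_target_frequency(60, 3)  # 20 Hz
#' @export
max_target_frequency <- function(refresh_rate, k = 3L) {
  stopifnot(is.numeric(refresh_rate), length(refresh_rate) == 1L)
  if (refresh_rate <= 0) stop("'refresh_rate' must be positive")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("'k' must be a positive integer")
  refresh_rate / k
}

#' Midpoint (secondary) frequencies between sorted base frequencies
#'
#' For base frequencies `f[1] < ... < f[N]`, the i-th midpoint is
#' `g[i] = (f[i] + f[i+1]) / 2` for `i < N`, and the last one is
#' `g[N] = f[N] + M` where the margin `M` is the smallest half-gap
#' `min((f[i+1] - f[i]) / 2)`. Each `g[i]` (i < N) is adjacent to `f[i]`
#' and `f[i+1]`.
#'
#' @param base_frequencies Numeric vector of at least two strictly
#'   increasing frequencies in Hz.
#' @return A list with `midpoints` (same length as the input) and
#'   `margin` (Hz).
#' @examples
#' compute_midpoints(c(5, 6, 7, 8, 9))
#' @export
compute_midpoints <- function(base_frequencies) {
  f <- as.numeric(base_frequencies)
  if (length(f) < 2L) stop("need at least two base frequencies")
  if (any(!is.finite(f))) stop("base frequencies must be finite")
  if (any(diff(f) <= 0))
    stop("base frequencies must be strictly increasing (no duplicates)")
  n <- length(f)
  margin <- min(diff(f)) / 2
  g <- c((f[-n] + f[-1]) / 2, f[n] + margin)
  list(midpoints = g, margin = margin)
}

#' Dual-frequency pair assignment for N targets
#'
#' Builds the frequency plan of the dual-frequency paradigm: each of the N
#' targets is assigned a primary frequency `a[i]` drawn from the base
#' frequencies and a secondary frequency `b[i]` drawn from the midpoints,
#' arranged so that no two targets share more than one adjacent frequency
#' (see [adjacency_audit()]). The assignment is
#' `a = (f1, f3, f4, ..., fN, f2)` paired with
#' `b = (g[N-1], g1, g2, ..., g[N-2], gN)`.
#'
#' The construction is defined for `N >= 5` targets; fewer targets are
#' rejected because the rotation pattern of the assignment does not apply.
#'
#' @param base_frequencies Numeric vector of at least five strictly
#'   increasing base frequencies in Hz.
#' @param fmin,fmax Optional bounds of the usable frequency band; when given,
#'   all base frequencies must lie inside.
#' @return An object of class `frequency_plan`: a list with
#'   `base` (sorted base frequencies), `midpoints`, `margin`, and `pairs`,
#'   a data frame with columns `target`, `a`, `b`.
#' @examples
#' plan <- assign_dual_frequencies(c(5, 6, 7, 8, 9))
#' plan$pairs
#' @export
assign_dual_frequencies <- function(base_frequencies, fmin = NULL, fmax = NULL) {
  f <- as.numeric(base_frequencies)
  n <- length(f)
  if (n < 5L)
    stop("the dual-frequency coding algorithm requires N >= 5 targets; got ",
         n)
  if (any(diff(f) <= 0))
    stop("base frequencies must be strictly increasing")
  if (!is.null(fmin) && any(f < fmin))
    stop("base frequencies below fmin")
  if (!is.null(fmax) && any(f > fmax))
    stop("base frequencies above fmax")
  mg <- compute_midpoints(f)
  g <- mg$midpoints
  # target 1 gets (f1, g[N-1]); targets 2..N-1 get (f[i+1], g[i-1]);
  # target N gets (f2, gN)
  a <- c(f[1L], f[seq(3L, n)], f[2L])
  b <- c(g[n - 1L], g[seq_len(n - 2L)], g[n])
  all_freq <- c(f, g)
  if (any(abs(diff(sort(all_freq))) < 1e-9))
    stop("plan frequencies are not pairwise distinct at 1e-9 Hz tolerance")
  plan <- structure(
    list(base = f, midpoints = g, margin = mg$margin,
         pairs = data.frame(target = seq_len(n), a = a, b = b)),
    class = "frequency_plan")
  audit <- adjacency_audit(plan)
  if (!audit$pass)
    stop("internal error: generated plan fails its adjacency audit")
  plan
}

#' @export
print.frequency_plan <- function(x, ...) {
  cat(sprintf("Dual-frequency plan: %d targets, margin M = %g Hz\n",
              nrow(x$pairs), x$margin))
  cat(" base:", paste(x$base, collapse = ", "), "Hz\n")
  cat(" midpoints:", paste(x$midpoints, collapse = ", "), "Hz\n")
  for (i in seq_len(nrow(x$pairs)))
    cat(sprintf("  target %d: (%g Hz, %g Hz)\n", i, x$pairs$a[i],
                x$pairs$b[i]))
  invisible(x)
}

#' Audit a frequency plan for shared adjacencies between targets
#'
#' Two frequencies are adjacent when one is a midpoint lying next to the
#' other base frequency: the adjacency relation contains `(f[i], g[i])` and
#' `(f[i+1], g[i])` for `i < N`, plus `(f[N], g[N])`. For every unordered
#' pair of distinct targets the audit counts how many cross adjacencies the
#' four assigned frequencies generate; the plan passes when every count is
#' at most one, so that no two targets look alike to the decoder through
#' their neighbouring frequencies.
#'
#' @param plan A `frequency_plan` (or a list with `base`, `midpoints`, and
#'   `pairs` in the same layout).
#' @return A list with `pass` (logical), `counts` (data frame of target
#'   pairs and their shared-adjacency counts), and `offending` (the subset
#'   with count > 1).
#' @export
adjacency_audit <- function(plan) {
  f <- plan$base
  g <- plan$midpoints
  n <- length(f)
  stopifnot(length(g) == n, nrow(plan$pairs) >= 2L)
  near <- function(u, v) abs(u - v) < 1e-9
  is_adjacent <- function(u, v) {
    for (i in seq_len(n - 1L)) {
      if ((near(u, f[i]) || near(u, f[i + 1L])) && near(v, g[i])) return(TRUE)
      if ((near(v, f[i]) || near(v, f[i + 1L])) && near(u, g[i])) return(TRUE)
    }
    (near(u, f[n]) && near(v, g[n])) || (near(v, f[n]) && near(u, g[n]))
  }
  pairs <- plan$pairs
  m <- nrow(pairs)
  res <- NULL
  for (i in seq_len(m - 1L)) {
    for (j in seq((i + 1L), m)) {
      fi <- c(pairs$a[i], pairs$b[i])
      fj <- c(pairs$a[j], pairs$b[j])
      cnt <- sum(outer(fi, fj, Vectorize(is_adjacent)))
      res <- rbind(res, data.frame(target_i = pairs$target[i],
                                   target_j = pairs$target[j],
                                   shared_adjacencies = cnt))
    }
  }
  list(pass = all(res$shared_adjacencies <= 1L),
       counts = res,
       offending = res[res$shared_adjacencies > 1L, , drop = FALSE])
}
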
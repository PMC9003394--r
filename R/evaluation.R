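# Performance evaluation: information transfer rate, confusion matrices with
# per-class indices, and accuracy/ITR across decoding window lengths.

#' Information transfer rate of a K-choice selection
#'
#' Computes the ITR in bits per minute,
#' `(60 / T) * (log2(K) + sigma * log2(sigma) +
#'  (1 - sigma) * log2((1 - sigma) / (K - 1)))`,
#' with the convention `0 * log2(0) = 0`. At chance accuracy
#' `sigma = 1 / K` the rate is zero; below chance the formula turns
#' positive again (it measures deviation from chance, and systematic
#' miscoding carries information), so sub-chance inputs are returned as
#' computed but flagged with a message.
#'
#' @param sigma Recognition accuracy in `[0, 1]`.
#' @param K Number of selectable stimuli (>= 2).
#' @param T_s Seconds consumed per selection. By convention this is the
#'   decoding window length; add inter-trial rest time to `T_s` if the
#'   duty cycle should be charged.
#' @return ITR in bits/min.
#' @examples
#' itr(0.925, K = 5, T_s = 3.5)
#' @export
itr <- function(sigma, K, T_s) {
  if (!is.numeric(K) || length(K) != 1L || K < 2 || K != round(K))
    stop("'K' must be an integer >= 2")
  if (!is.numeric(T_s) || length(T_s) != 1L || T_s <= 0)
    stop("'T_s' must be positive")
  if (!is.numeric(sigma) || any(sigma < 0) || any(sigma > 1))
    stop("'sigma' must lie in [0, 1]")
  xlog2x <- function(p) ifelse(p > 0, p * log2(p), 0)
  bits <- log2(K) + xlog2x(sigma) +
    ifelse(sigma < 1, (1 - sigma) * log2((1 - sigma) / (K - 1)), 0)
  out <- 60 / T_s * bits
  if (any(sigma < 1 / K))
    message("itr: accuracy below chance 1/K; the rate reflects systematic ",
            "miscoding, not usable throughput")
  out
}

#' Confusion matrix and per-class performance indices
#'
#' Tabulates predictions against ground truth over `K` classes and derives,
#' per class, sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)`,
#' precision `TP / (TP + FP)`, and per-class accuracy
#' `(TP + TN) / total`. A class never present in the truth has undefined
#' sensitivity and is reported as `NA` (with a message), never as zero.
#'
#' @param truth,predicted Equal-length integer vectors with values in
#'   `1..K`.
#' @param K Number of classes.
#' @return A `confusion_summary`: list with `table` (K x K counts, truth in
#'   rows), `per_class` (data frame of indices), and `overall_accuracy`
#'   (trace / total).
#' @export
confusion_and_indices <- function(truth, predicted, K) {
  if (length(truth) != length(predicted))
    stop("'truth' and 'predicted' must have equal length")
  if (length(truth) == 0L) stop("no trials to score")
  if (any(!(truth %in% seq_len(K))) || any(!(predicted %in% seq_len(K))))
    stop("labels must be integers in 1..", K)
  tab <- table(factor(truth, levels = seq_len(K)),
               factor(predicted, levels = seq_len(K)),
               dnn = c("truth", "predicted"))
  total <- sum(tab)
  per <- data.frame(class = seq_len(K), sensitivity = NA_real_,
                    specificity = NA_real_, precision = NA_real_,
                    accuracy = NA_real_)
  for (c in seq_len(K)) {
    tp <- tab[c, c]
    fn <- sum(tab[c, ]) - tp
    fp <- sum(tab[, c]) - tp
    tn <- total - tp - fn - fp
    per$sensitivity[c] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    per$specificity[c] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    per$precision[c] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    per$accuracy[c] <- (tp + tn) / total
  }
  if (anyNA(per$sensitivity))
    message("confusion_and_indices: class(es) ",
            paste(per$class[is.na(per$sensitivity)], collapse = ", "),
            " have no positives; sensitivity reported as NA")
  structure(list(table = tab, per_class = per,
                 overall_accuracy = sum(diag(tab)) / total),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.4f over %d trials\n",
              x$overall_accuracy, sum(x$table)))
  print(x$table)
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Accuracy and ITR across decoding window lengths
#'
#' For each window length, epochs every trial to `[0, w)` seconds, decodes
#' it with CCA or BCCA, and aggregates recognition accuracy and
#' `itr(accuracy, K, T_s = w)`. Windows longer than a trial are skipped
#' with a message.
#'
#' @param trials List of [eeg_trial()] objects carrying `true_target`.
#' @param plan A frequency plan; BCCA uses the pairs, CCA the primary
#'   (`a`) frequencies.
#' @param method `"bcca"` (default) or `"cca"`.
#' @param windows Numeric vector of window lengths in seconds.
#' @param Nh Harmonics per reference set.
#' @param filter Band-pass filter each trial first (default TRUE).
#' @return Data frame with columns `window`, `n_trials`, `accuracy`,
#'   `itr`.
#' @export
evaluate_windows <- function(trials, plan, method = c("bcca", "cca"),
                             windows, Nh = 2L, filter = TRUE) {
  method <- match.arg(method)
  out <- data.frame(window = numeric(0), n_trials = integer(0),
                    accuracy = numeric(0), itr = numeric(0))
  if (length(windows) == 0L) return(out)
  K <- nrow(plan$pairs)
  if (filter) trials <- lapply(trials, bandpass_filter)
  for (w in windows) {
    ok <- vapply(trials, function(tr) ncol(tr$data) / tr$fs >= w, logical(1))
    if (!any(ok)) {
      message(sprintf("evaluate_windows: window %g s exceeds every trial; skipped", w))
      next
    }
    if (!all(ok))
      message(sprintf("evaluate_windows: window %g s skips %d short trial(s)",
                      w, sum(!ok)))
    use <- trials[ok]
    pred <- vapply(use, function(tr) {
      ep <- epoch_window(tr, 0, w)
      if (method == "bcca") bcca_classify(ep, plan, Nh)$predicted
      else cca_classify(ep, plan$pairs$a, Nh)$predicted
    }, integer(1))
    truth <- vapply(use, function(tr) as.integer(tr$true_target), integer(1))
    acc <- mean(pred == truth)
    out <- rbind(out, data.frame(window = w, n_trials = length(use),
                                 accuracy = acc,
                                 itr = suppressMessages(itr(acc, K, w))))
  }
  out
}
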
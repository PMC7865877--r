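# Shared fixtures and independent oracles used across the suite.

# single-frequency amplitude via the discrete Fourier transform (oracle for
# the filter tests); freq must sit on a bin for an exact read-out
fft_amplitude <- function(x, freq, fs) {
  n <- length(x)
  bin <- round(freq * n / fs)
  2 * Mod(stats::fft(x))[bin + 1] / n
}

rms <- function(x) sqrt(mean(x^2))

# brute-force ROC-AUC by exhaustive positive/negative pair counting
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force confusion-matrix metrics
brute_metrics <- function(probs, truth, threshold = 0.5) {
  calls <- probs >= threshold
  tp <- sum(truth == 1 & calls)
  tn <- sum(truth == 0 & !calls)
  fp <- sum(truth == 0 & calls)
  fn <- sum(truth == 1 & !calls)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  list(accuracy = (tp + tn) / length(truth), precision = prec, recall = rec,
       f1 = if (!is.na(prec) && !is.na(rec) && prec + rec > 0) 2 * prec * rec / (prec + rec) else NA_real_,
       roc_auc = pairwise_auc(probs, truth))
}

# synthetic record shortcut
syn_rec <- function(..., seed = 1) generate_ecg(synthetic_spec(..., seed = seed))

# match detected peak times (s) against ground-truth beat times at a tolerance
match_beats <- function(det_s, truth_s, tol = 0.05) {
  sens <- mean(vapply(truth_s, function(g) any(abs(det_s - g) <= tol), logical(1)))
  ppv <- mean(vapply(det_s, function(p) any(abs(truth_s - p) <= tol), logical(1)))
  list(sens = sens, ppv = ppv)
}

# hand-built wave annotation frame (1-based indices) for measurement tests
make_annotations <- function(fs, qrs_peak, qrs_onset, t_offset,
                             p_onset = NA, p_offset = NA, p_peak = NA,
                             qrs_offset = qrs_peak + 4L, t_onset = t_offset - 10L) {
  n <- length(qrs_peak)
  rep_or <- function(v) if (length(v) == 1L) rep(v, n) else v
  a <- data.frame(beat_index = seq_len(n),
                  p_onset = rep_or(p_onset), p_peak = rep_or(p_peak),
                  p_offset = rep_or(p_offset),
                  qrs_onset = rep_or(qrs_onset), qrs_peak = qrs_peak,
                  qrs_offset = rep_or(qrs_offset),
                  t_onset = rep_or(t_onset), t_peak = rep_or(t_offset) - 5L,
                  t_offset = rep_or(t_offset))
  class(a) <- c("wave_annotations", "data.frame")
  attr(a, "sampling_rate") <- fs
  a
}

# small reduced-width network config used throughout the tests
test_net_config <- function(n_classes = 20L, dropout = 0.1) {
  network_config(base_filters = 4, segment_length = 256, recurrent_hidden = 8,
                 dropout_rate = dropout, n_classes = n_classes)
}
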
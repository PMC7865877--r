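# Per-item classification metrics: accuracy, precision, recall, F1, ROC-AUC
# (one-vs-rest, rank-based with tie handling).

#' Rank-based ROC-AUC
#'
#' Probability that a random positive outranks a random negative
#' (Mann-Whitney); ties contribute 1/2.  `NA` when either class is empty.
#'
#' @param scores numeric scores.
#' @param labels 0/1 truth.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Evaluate diagnosis results against truth
#'
#' Computes per-item accuracy, precision, recall, F1 and one-vs-rest ROC-AUC.
#' Precision (recall) is `NA` when there are no positive calls (no positive
#' truths); ROC-AUC is `NA` for items with single-class truth.
#'
#' @param results list of `diagnosis_result` objects, or a numeric matrix of
#'   probabilities (n_recordings x n_items).
#' @param truth 0/1 matrix (n_recordings x n_items) with matching columns.
#' @param threshold call threshold applied to a probability matrix (ignored
#'   for `diagnosis_result` inputs, which carry their own calls).
#' @return data.frame of class `metric_report`: one row per item with
#'   `accuracy`, `precision`, `recall`, `f1`, `roc_auc`.
#' @export
evaluate_diagnoses <- function(results, truth, threshold = 0.5) {
  if (is.list(results) && !is.matrix(results)) {
    probs <- t(vapply(results, function(r) r$probabilities,
                      numeric(length(results[[1]]$probabilities))))
    calls <- t(vapply(results, function(r) as.numeric(r$calls),
                      numeric(length(results[[1]]$calls))))
  } else {
    probs <- as.matrix(results)
    calls <- (probs >= threshold) * 1
  }
  truth <- as.matrix(truth)
  if (!all(dim(probs) == dim(truth))) stop("results/truth dimensions differ", call. = FALSE)
  items <- colnames(truth)
  if (is.null(items)) items <- colnames(probs)
  if (is.null(items)) items <- paste0("item", seq_len(ncol(truth)))
  out <- lapply(seq_len(ncol(truth)), function(j) {
    y <- truth[, j]
    yhat <- calls[, j]
    tp <- sum(y == 1 & yhat == 1)
    tn <- sum(y == 0 & yhat == 0)
    fp <- sum(y == 0 & yhat == 1)
    fn <- sum(y == 1 & yhat == 0)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
      2 * prec * rec / (prec + rec)
    } else NA_real_
    data.frame(item = items[j], accuracy = (tp + tn) / length(y),
               precision = prec, recall = rec, f1 = f1,
               roc_auc = roc_auc(probs[, j], y))
  })
  out <- do.call(rbind, out)
  class(out) <- c("metric_report", "data.frame")
  out
}
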
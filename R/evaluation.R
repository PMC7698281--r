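# Evaluation metrics: per-class precision/recall/F1, confusion matrices,
# ROC/AUC, and detection-lag analysis.

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR/(P+R)`; defined as 0 when both precision and recall are
#' zero.
#'
#' @param precision,recall Fractions in `[0, 1]` (vectorized).
#' @return F1 fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' f1_from_pr(0.89, 0.85)  # ~0.87
f1_from_pr <- function(precision, recall) {
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1, na.rm = TRUE)) {
    stop_bd("precision and recall must lie in [0, 1]")
  }
  ifelse(precision + recall == 0, 0, 2 * precision * recall / (precision + recall))
}

#' Per-class detection/classification report
#'
#' Computes precision, recall, F1 and support for every class, plus macro and
#' support-weighted averages, the raw confusion-count matrix and its
#' row-normalized percentage form (per true class). Classes with a zero
#' denominator get metric 0 and are listed in `zero_division_classes`.
#'
#' @param truth,predicted Equal-length label vectors drawn from `classes`.
#' @param classes Ordered class set (defaults to [EVENT_CLASSES]).
#' @return An object of class `eval_report`: `per_class` data frame
#'   (precision, recall, f1, support), `macro_f1`, `macro_precision`,
#'   `macro_recall`, `weighted_f1`, `confusion` (counts),
#'   `confusion_pct` (rows summing to 100 where support > 0), `n`.
#' @export
#' @examples
#' classification_report(c("normal","normal","csa"),
#'                       c("normal","csa","csa"))$per_class
classification_report <- function(truth, predicted, classes = EVENT_CLASSES) {
  if (length(truth) != length(predicted)) {
    stop_bd("truth (%d) and predicted (%d) lengths differ",
            length(truth), length(predicted))
  }
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) stop_bd("labels outside the class set: %s", paste(bad, collapse = ", "))
  ft <- factor(truth, levels = classes)
  fp <- factor(predicted, levels = classes)
  confusion <- table(truth = ft, predicted = fp)
  tp <- diag(confusion)
  support <- rowSums(confusion)
  pred_tot <- colSums(confusion)
  precision <- ifelse(pred_tot == 0, 0, tp / pred_tot)
  recall <- ifelse(support == 0, 0, tp / support)
  f1 <- f1_from_pr(precision, recall)
  zero_div <- classes[pred_tot == 0 | support == 0]
  confusion_pct <- confusion
  nz <- support > 0
  confusion_pct[nz, ] <- 100 * confusion[nz, , drop = FALSE] / support[nz]
  confusion_pct[!nz, ] <- NA_real_
  per_class <- data.frame(class = classes, precision = as.numeric(precision),
                          recall = as.numeric(recall), f1 = as.numeric(f1),
                          support = as.integer(support),
                          stringsAsFactors = FALSE)
  structure(list(per_class = per_class,
                 macro_precision = mean(precision),
                 macro_recall = mean(recall),
                 macro_f1 = mean(f1),
                 weighted_f1 = if (sum(support)) sum(f1 * support) / sum(support) else 0,
                 confusion = unclass(confusion),
                 confusion_pct = unclass(confusion_pct),
                 zero_division_classes = zero_div,
                 n = length(truth)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 2, ...) {
  cat(sprintf("<eval_report> %d instances\n", x$n))
  pc <- x$per_class
  pc$precision <- round(pc$precision, digits)
  pc$recall <- round(pc$recall, digits)
  pc$f1 <- round(pc$f1, digits)
  print(pc, row.names = FALSE)
  cat(sprintf("macro F1 %.3f | weighted F1 %.3f\n", x$macro_f1, x$weighted_f1))
  if (length(x$zero_division_classes)) {
    cat("zero-division classes:", paste(x$zero_division_classes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (ties grouped), yielding monotone
#' TPR/FPR sequences; the AUC is the trapezoidal area, which equals the
#' probability that a random positive outscores a random negative with ties
#' counting one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param truth Binary truth (0/1 or logical), both classes present.
#' @return An object of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
#' @examples
#' roc_curve_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc  # 0.75
roc_curve_auc <- function(scores, truth) {
  truth <- as.integer(as.logical(truth))
  if (length(scores) != length(truth)) stop_bd("scores and truth lengths differ")
  n_pos <- sum(truth == 1L); n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L) stop_bd("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- truth[o]
  # group tied scores so the curve steps once per distinct threshold
  last_of_group <- c(diff(s) != 0, TRUE)
  cum_tp <- cumsum(y)[last_of_group]
  cum_fp <- cumsum(1L - y)[last_of_group]
  tpr <- c(0, cum_tp / n_pos)
  fpr <- c(0, cum_fp / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  structure(list(thresholds = c(Inf, s[last_of_group]), tpr = tpr, fpr = fpr,
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f over %d thresholds\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' Convert a per-second label sequence into event spans
#'
#' Runs of identical labels become half-open spans `[start_s, end_s)` in
#' seconds.
#'
#' @param labels Character label vector (one per second).
#' @param drop_normal Drop `normal` runs?
#' @return Data frame with `label`, `start_s`, `end_s`.
#' @export
labels_to_spans <- function(labels, drop_normal = TRUE) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  spans <- data.frame(label = r$values, start_s = ends - r$lengths,
                      end_s = ends, stringsAsFactors = FALSE)
  if (drop_normal) spans <- spans[spans$label != "normal", , drop = FALSE]
  rownames(spans) <- NULL
  spans
}

#' Onset-lag analysis between true and predicted event spans
#'
#' Matches each true event span to the same-class predicted run with the
#' largest temporal overlap (requiring at least some overlap) and reports the
#' signed onset lag `predicted start - true start` in seconds. True events
#' with no overlapping same-class prediction are listed as unmatched.
#'
#' @param true_spans,pred_spans Data frames with `label`, `start_s`, `end_s`
#'   (see [labels_to_spans()]), or per-second label vectors.
#' @return An object of class `lag_report`: `matches` (per-event lag table),
#'   `unmatched` (true events without a match), `mean_lag`.
#' @export
#' @examples
#' detection_lag(data.frame(label = "csa", start_s = 4, end_s = 14),
#'               data.frame(label = "csa", start_s = 5, end_s = 15))$matches$lag  # +1
detection_lag <- function(true_spans, pred_spans) {
  if (is.character(true_spans)) true_spans <- labels_to_spans(true_spans)
  if (is.character(pred_spans)) pred_spans <- labels_to_spans(pred_spans)
  matches <- list()
  unmatched <- list()
  used <- rep(FALSE, nrow(pred_spans))
  for (i in seq_len(nrow(true_spans))) {
    tv <- true_spans[i, ]
    cand <- which(pred_spans$label == tv$label & !used)
    if (length(cand)) {
      ov <- pmin(pred_spans$end_s[cand], tv$end_s) -
        pmax(pred_spans$start_s[cand], tv$start_s)
      cand <- cand[ov > 0]
      ov <- ov[ov > 0]
    } else {
      ov <- numeric()
    }
    if (!length(cand)) {
      unmatched[[length(unmatched) + 1L]] <- tv
      next
    }
    j <- cand[which.max(ov)]
    used[j] <- TRUE
    matches[[length(matches) + 1L]] <-
      data.frame(label = tv$label, true_start = tv$start_s, true_end = tv$end_s,
                 pred_start = pred_spans$start_s[j], pred_end = pred_spans$end_s[j],
                 overlap = max(ov),
                 lag = pred_spans$start_s[j] - tv$start_s,
                 stringsAsFactors = FALSE)
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(label = character(), true_start = numeric(), true_end = numeric(),
               pred_start = numeric(), pred_end = numeric(), overlap = numeric(),
               lag = numeric(), stringsAsFactors = FALSE)
  unmatched <- if (length(unmatched)) do.call(rbind, unmatched) else
    data.frame(label = character(), start_s = numeric(), end_s = numeric(),
               stringsAsFactors = FALSE)
  structure(list(matches = matches, unmatched = unmatched,
                 mean_lag = if (nrow(matches)) mean(matches$lag) else NA_real_),
            class = "lag_report")
}

#' @export
print.lag_report <- function(x, ...) {
  cat(sprintf("<lag_report> %d matched events (mean lag %+.2f s), %d unmatched\n",
              nrow(x$matches), x$mean_lag, nrow(x$unmatched)))
  invisible(x)
}
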
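# Threshold metrics and ranking curves for binary promoter classifiers.
# Balanced accuracy, sensitivity, specificity, precision, F1 and the
# Matthews correlation coefficient follow their standard confusion-count
# definitions; zero-denominator cases return 0 so every metric keeps its
# nominal range. The ROC area is computed by trapezoidal integration over
# the full threshold sweep (equivalent to the tie-corrected pairwise
# concordance probability); the PR area uses the step-wise
# average-precision rule (no interpolation).

#' Confusion counts from labels and hard predictions
#'
#' @param labels,predictions equal-length binary (0/1) vectors.
#' @return named integer vector \code{c(tp, fp, tn, fn)}.
#' @export
confusionCounts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  if (length(labels) && (!all(labels %in% c(0, 1)) ||
                         !all(predictions %in% c(0, 1))))
    stop("labels and predictions must be binary (0/1)")
  c(tp = sum(labels == 1 & predictions == 1),
    fp = sum(labels == 0 & predictions == 1),
    tn = sum(labels == 0 & predictions == 0),
    fn = sum(labels == 1 & predictions == 0))
}

#' The six threshold metrics from confusion counts
#'
#' BA = (SN + SP)/2; SN = TP/(TP+FN); SP = TN/(TN+FP); PR = TP/(TP+FP);
#' F1 = 2 PR SN/(PR + SN);
#' MCC = (TP TN - FP FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Ratios with zero denominator return 0.
#'
#' @param counts named vector with tp, fp, tn, fn.
#' @return named numeric vector \code{c(ba, sn, sp, pr, f1, mcc)}.
#' @export
thresholdMetrics <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); fp <- as.numeric(counts[["fp"]])
  tn <- as.numeric(counts[["tn"]]); fn <- as.numeric(counts[["fn"]])
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative")
  ratio <- function(num, den) if (den == 0) 0 else num / den
  sn <- ratio(tp, tp + fn)
  sp <- ratio(tn, tn + fp)
  pr <- ratio(tp, tp + fp)
  ba <- (sn + sp) / 2
  f1 <- if (pr + sn == 0) 0 else 2 * pr * sn / (pr + sn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  c(ba = ba, sn = sn, sp = sp, pr = pr, f1 = f1, mcc = mcc)
}

#' ROC curve and area
#'
#' Sweeps all distinct scores as thresholds (prediction positive when
#' score >= threshold) and integrates trapezoidally, which equals the
#' pairwise concordance probability with half credit for ties.
#'
#' @param labels binary labels (both classes must be present).
#' @param scores real-valued scores, higher = more promoter-like.
#' @return list with \code{points} (data.frame threshold, fpr, tpr) and
#'   \code{auc}.
#' @export
rocCurveArea <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("ROC is undefined unless both classes are present")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  # collapse tied scores into single sweep points
  grp <- cumsum(!duplicated(sc))
  tpCum <- cumsum(lab == 1); fpCum <- cumsum(lab == 0)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tpCum[last] / npos)
  fpr <- c(0, fpCum[last] / nneg)
  thr <- c(Inf, sc[last])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Precision-recall curve and area
#'
#' Sweeps all distinct scores as thresholds and sums precision over
#' recall increments (the step-wise average-precision rule; no
#' interpolation), so a degenerate all-tied score vector yields the
#' class prevalence.
#'
#' @param labels binary labels (at least one positive required).
#' @param scores real-valued scores.
#' @return list with \code{points} (data.frame threshold, recall,
#'   precision) and \code{auc}.
#' @export
prCurveArea <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  npos <- sum(labels == 1)
  if (npos == 0) stop("PR curve is undefined without positives")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))
  tpCum <- cumsum(lab == 1)
  nCum <- seq_along(lab)
  last <- which(!duplicated(grp, fromLast = TRUE))
  recall <- tpCum[last] / npos
  precision <- tpCum[last] / nCum[last]
  thr <- sc[last]
  auc <- sum(diff(c(0, recall)) * precision)
  list(points = data.frame(threshold = thr, recall = recall,
                           precision = precision),
       auc = auc)
}

#' Evaluate a trained model on a labelled dataset
#'
#' Encodes the sequences, runs the forward pass, thresholds the
#' probabilities (>= threshold is called positive) and assembles the
#' full report: confusion counts, the six threshold metrics, and both
#' curve areas with their coordinates.
#'
#' @param model a fitted \code{TrainedPromoterModel}.
#' @param dataset a \code{LabelledDataset} of uniform-length sequences.
#' @param threshold decision threshold (default 0.5).
#' @return an \code{EvalReport}.
#' @export
evaluateModel <- function(model, dataset, threshold = 0.5) {
  pred <- predictModel(model, sequences(dataset), threshold = threshold)
  lab <- labels(dataset)
  counts <- confusionCounts(lab, pred$label)
  roc <- rocCurveArea(lab, pred$prob)
  pr <- prCurveArea(lab, pred$prob)
  new("EvalReport", counts = counts, metrics = thresholdMetrics(counts),
      aucroc = roc$auc, aucpr = pr$auc, threshold = threshold,
      rocPoints = roc$points, prPoints = pr$points)
}

#' Serialise an EvalReport to JSON
#'
#' @param report an \code{EvalReport}.
#' @param path output path.
#' @return (invisibly) the path.
#' @export
writeEvalReport <- function(report, path) {
  jsonlite::write_json(list(
    counts = as.list(confusion(report)),
    metrics = as.list(round(metrics(report), 2)),
    aucroc = aucroc(report), aucpr = aucpr(report),
    threshold = report@threshold), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
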
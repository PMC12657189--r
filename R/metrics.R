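# Evaluation mathematics: confusion matrix, one-vs-rest reduction,
# precision/recall/F1/accuracy, ROC/AUC (tie-aware, rank-sum equivalent) and
# stepwise average precision.

#' Confusion matrix from label vectors
#'
#' @param y_true,y_pred integer labels in `0..(n_classes-1)`, equal length.
#' @param n_classes number of classes.
#' @return n_classes x n_classes integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  labs <- 0:(n_classes - 1)
  if (length(y_true) > 0 &&
      (!all(y_true %in% labs) || !all(y_pred %in% labs))) {
    stop("labels out of range 0..(n_classes-1)", call. = FALSE)
  }
  m <- table(factor(y_true, levels = labs), factor(y_pred, levels = labs))
  m <- matrix(as.integer(m), n_classes, n_classes,
              dimnames = list(true = labs, pred = labs))
  m
}

#' One-vs-rest binary counts for one class
#'
#' @param m confusion matrix (rows true, columns predicted).
#' @param k class index in `0..(n_classes-1)`.
#' @return list with integer TP, FN, FP, TN.
#' @export
one_vs_rest <- function(m, k) {
  i <- k + 1L
  if (i < 1L || i > nrow(m)) stop("class index out of range", call. = FALSE)
  tp <- m[i, i]
  fn <- sum(m[i, ]) - tp
  fp <- sum(m[, i]) - tp
  tn <- sum(m) - tp - fn - fp
  list(TP = as.integer(tp), FN = as.integer(fn), FP = as.integer(fp),
       TN = as.integer(tn))
}

#' Precision, recall, F1 and accuracy from binary counts
#'
#' Standard definitions: precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = harmonic mean, accuracy = (TP+TN)/total. Any metric whose
#' denominator is 0 is defined as 0 so that aggregates stay finite.
#'
#' @param counts list with TP, FN, FP, TN (as from [one_vs_rest()]).
#' @return named list precision, recall, f1, accuracy.
#' @export
prf_metrics <- function(counts) {
  tp <- counts$TP; fn <- counts$FN; fp <- counts$FP; tn <- counts$TN
  if (any(c(tp, fn, fp, tn) < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  safe_div <- function(a, b) if (b > 0) a / b else 0
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  accuracy <- safe_div(tp + tn, tp + tn + fp + fn)
  list(precision = precision, recall = recall, f1 = f1, accuracy = accuracy)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (descending); tied scores enter
#' together and contribute half credit, making the trapezoidal area exactly
#' the normalized Mann-Whitney rank-sum statistic.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1 or logical).
#' @return list with `fpr`, `tpr`, `thresholds` and scalar `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires at least one positive and one negative",
         call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(labels == 1 & scores >= t),
                     numeric(1)) / n_pos)
  fpr <- c(0, vapply(thr, function(t) sum(labels == 0 & scores >= t),
                     numeric(1)) / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, thr), auc = auc)
}

#' Precision-recall curve and average precision
#'
#' Stepwise average precision
#' \eqn{AP = \sum_i (R_i - R_{i-1}) P_i} over descending-score thresholds
#' (no 11-point interpolation); tied scores enter together.
#'
#' @inheritParams roc_auc
#' @return list with `recall`, `precision`, `thresholds` and scalar `ap`.
#' @export
pr_ap <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  n_pos <- sum(labels == 1)
  if (n_pos == 0) {
    stop("average precision requires at least one positive", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(labels == 1 & scores >= t), numeric(1))
  pred_pos <- vapply(thr, function(t) sum(scores >= t), numeric(1))
  precision <- tp / pred_pos
  recall <- tp / n_pos
  ap <- sum(diff(c(0, recall)) * precision)
  list(recall = recall, precision = precision, thresholds = thr, ap = ap)
}

#' Full evaluation report from labels and class scores
#'
#' Builds the confusion matrix, per-class one-vs-rest
#' precision/recall/F1, macro and support-weighted aggregates, and
#' per-class ROC/AUC and PR/AP from the score matrix.
#'
#' @param y_true integer labels in `0..(n_classes-1)`.
#' @param scores numeric matrix (n_samples x n_classes) of class scores
#'   (e.g. softmax probabilities); predictions are the per-row argmax.
#' @param n_classes number of classes.
#' @return a list of class `metrics_report`.
#' @export
metrics_report <- function(y_true, scores, n_classes) {
  if (length(y_true) == 0) stop("empty evaluation set", call. = FALSE)
  scores <- as.matrix(scores)
  y_pred <- max.col(scores, ties.method = "first") - 1L
  cm <- confusion(y_true, y_pred, n_classes)
  support <- rowSums(cm)
  per_class <- vector("list", n_classes)
  for (k in 0:(n_classes - 1)) {
    pc <- prf_metrics(one_vs_rest(cm, k))
    pc$support <- support[k + 1]
    pc$auc <- NA_real_
    pc$ap <- NA_real_
    is_pos <- as.integer(y_true == k)
    if (sum(is_pos) > 0 && sum(is_pos) < length(y_true)) {
      pc$auc <- roc_auc(scores[, k + 1], is_pos)$auc
      pc$ap <- pr_ap(scores[, k + 1], is_pos)$ap
    }
    per_class[[k + 1]] <- pc
  }
  get <- function(f) vapply(per_class, `[[`, numeric(1), f)
  w <- support / sum(support)
  report <- list(
    confusion = cm,
    accuracy = sum(diag(cm)) / sum(cm),
    per_class = per_class,
    macro = list(precision = mean(get("precision")),
                 recall = mean(get("recall")),
                 f1 = mean(get("f1"))),
    weighted = list(precision = sum(w * get("precision")),
                    recall = sum(w * get("recall")),
                    f1 = sum(w * get("f1"))),
    auc = get("auc"),
    ap = get("ap"))
  class(report) <- "metrics_report"
  report
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("<metrics_report> accuracy %.4f over %d samples\n",
              x$accuracy, sum(x$confusion)))
  tab <- do.call(rbind, lapply(seq_along(x$per_class), function(i) {
    pc <- x$per_class[[i]]
    data.frame(class = i - 1, precision = pc$precision, recall = pc$recall,
               f1 = pc$f1, auc = pc$auc, ap = pc$ap, support = pc$support)
  }))
  print(format(tab, digits = digits), row.names = FALSE)
  cat(sprintf("macro    P %.4f  R %.4f  F1 %.4f\n", x$macro$precision,
              x$macro$recall, x$macro$f1))
  cat(sprintf("weighted P %.4f  R %.4f  F1 %.4f\n", x$weighted$precision,
              x$weighted$recall, x$weighted$f1))
  invisible(x)
}

#' Serialize a metrics report
#'
#' Writes scalars and curves as JSON and the confusion matrix as CSV
#' (when `csv_path` is given).
#'
#' @param report a `metrics_report`.
#' @param json_path output JSON path.
#' @param csv_path optional CSV path for the confusion matrix.
#' @export
write_metrics_report <- function(report, json_path, csv_path = NULL) {
  obj <- unclass(report)
  obj$confusion <- unname(apply(report$confusion, 1, as.integer,
                                simplify = FALSE))
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report$confusion), csv_path,
                     row.names = FALSE)
  }
  invisible(json_path)
}
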
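test_that("confusion matrix counts label pairs", {
  expect_equal(unname(confusion(c(0, 0, 1), c(0, 1, 1), 2)),
               matrix(c(1, 0, 1, 1), 2, 2))
  perfect <- confusion(0:3, 0:3, 4)
  expect_equal(unname(perfect), diag(1L, 4))
  empty <- confusion(integer(0), integer(0), 3)
  expect_true(all(empty == 0))
  expect_error(confusion(0:2, 0:1, 3), "equal length")
  expect_error(confusion(c(0, 5), c(0, 1), 2), "out of range")
})

test_that("one-vs-rest reduction partitions the total count", {
  m <- matrix(c(1, 0, 1, 1), 2, 2)  # true rows: [1,1;0,1]
  b <- one_vs_rest(m, 0)
  expect_equal(b, list(TP = 1L, FN = 1L, FP = 0L, TN = 1L))
  set.seed(4)
  cm <- matrix(sample(0:9, 25, replace = TRUE), 5, 5)
  for (k in 0:4) {
    bc <- one_vs_rest(cm, k)
    expect_equal(bc$TP + bc$FN + bc$FP + bc$TN, sum(cm))
  }
  diagm <- diag(3L, 4)
  for (k in 0:3) {
    bc <- one_vs_rest(diagm, k)
    expect_equal(bc$FP, 0L); expect_equal(bc$FN, 0L)
  }
})

test_that("precision/recall/F1/accuracy follow the standard definitions", {
  m <- prf_metrics(list(TP = 3L, FP = 1L, FN = 2L, TN = 4L))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(m$accuracy, 0.7)
  zero <- prf_metrics(list(TP = 0L, FP = 0L, FN = 0L, TN = 0L))
  expect_equal(unlist(zero), c(precision = 0, recall = 0, f1 = 0,
                               accuracy = 0))
  perfect <- prf_metrics(list(TP = 5L, FP = 0L, FN = 0L, TN = 5L))
  expect_equal(unlist(perfect), c(precision = 1, recall = 1, f1 = 1,
                                  accuracy = 1))
})

test_that("prf_metrics matches an independent recount on fuzzed inputs", {
  set.seed(17)
  for (r in 1:50) {
    n <- sample(5:60, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    pred <- sample(c(TRUE, FALSE), n, replace = TRUE)
    counts <- list(TP = sum(truth & pred), FN = sum(truth & !pred),
                   FP = sum(!truth & pred), TN = sum(!truth & !pred))
    m <- prf_metrics(counts)
    # independent recount straight from the label pairs
    prec <- if (sum(pred) > 0) mean(truth[pred]) else 0
    rec <- if (sum(truth) > 0) mean(pred[truth]) else 0
    expect_equal(m$precision, prec)
    expect_equal(m$recall, rec)
    expect_equal(m$accuracy, mean(truth == pred))
  }
})

test_that("ROC area equals the brute-force Mann-Whitney statistic", {
  mann_whitney <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
    tot / (length(pos) * length(neg))
  }
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  set.seed(23)
  for (r in 1:200) {
    n <- sample(4:30, 1)
    scores <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels)$auc,
                 mann_whitney(scores, labels), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 2), c(1, 1)), "positive and one negative")
})

test_that("ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  scores <- runif(40)
  labels <- sample(0:1, 40, replace = TRUE, prob = c(0.4, 0.6))
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(labels, scores, direction = "<", quiet = TRUE))))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("average precision follows the stepwise definition", {
  expect_equal(pr_ap(c(0.9, 0.8, 0.2), c(1, 1, 0))$ap, 1)
  # single positive ranked last among n: AP = 1/n
  for (n in c(3, 5, 8)) {
    scores <- seq(n, 1)
    labels <- c(rep(0, n - 1), 1)
    expect_equal(pr_ap(scores, labels)$ap, 1 / n)
  }
  set.seed(5)
  for (r in 1:30) {
    n <- sample(4:25, 1)
    scores <- runif(n)
    labels <- c(1, sample(0:1, n - 1, replace = TRUE))
    ap <- pr_ap(scores, labels)$ap
    expect_gte(ap, 0); expect_lte(ap, 1)
  }
  expect_error(pr_ap(1:3, c(0, 0, 0)), "positive")
})

test_that("metrics_report assembles a consistent multiclass report", {
  set.seed(41)
  n <- 90; k <- 6
  y <- sample(0:(k - 1), n, replace = TRUE)
  # perfect classifier: one-hot scores from the labels themselves
  hot <- matrix(0, n, k); hot[cbind(1:n, y + 1)] <- 1
  rep_perfect <- metrics_report(y, hot, k)
  expect_equal(rep_perfect$accuracy, 1)
  expect_true(all(rep_perfect$auc == 1))
  expect_true(all(rep_perfect$ap == 1))
  expect_length(rep_perfect$per_class, 6L)

  # noisy scores: identities that must hold for any single-label task
  scores <- matrix(runif(n * k), n, k)
  rp <- metrics_report(y, scores, k)
  expect_equal(rp$accuracy, sum(diag(rp$confusion)) / sum(rp$confusion))
  expect_equal(rp$weighted$recall, rp$accuracy, tolerance = 1e-12)
  # micro-averaged one-vs-rest precision = recall = accuracy
  tot_tp <- sum(diag(rp$confusion))
  micro <- tot_tp / sum(rp$confusion)
  expect_equal(micro, rp$accuracy)
  expect_error(metrics_report(integer(0), scores[0, , drop = FALSE], k),
               "empty")
})

test_that("report serialization writes JSON scalars and a CSV matrix", {
  set.seed(2)
  y <- sample(0:2, 30, replace = TRUE)
  scores <- matrix(runif(90), 30, 3)
  rp <- metrics_report(y, scores, 3)
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_metrics_report(rp, jp, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$accuracy, rp$accuracy, tolerance = 1e-12)
  cm <- read.csv(cp)
  expect_equal(sum(cm), sum(rp$confusion))
  unlink(c(jp, cp))
})
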
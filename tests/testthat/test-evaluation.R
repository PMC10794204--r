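# independent O(n^2) pairwise oracle: P(score_pos > score_neg) + 0.5 ties
auc_pairwise <- function(y, score) {
  pos <- score[y == 1]
  neg <- score[y == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

test_that("overall accuracy counts exact matches", {
  expect_equal(overall_accuracy(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(overall_accuracy(c(0, 1, 2), c(1, 2, 0)), 0)
  expect_equal(overall_accuracy(c(0, 1, 2, 1), c(0, 1, 1, 1)), 0.75)
  expect_error(overall_accuracy(0:1, 0:2), "equal-length")
})

test_that("confusion matrix and percentage conventions match hand arithmetic", {
  # small-heart row with counts (30, 3, 0) in a 200-sample set
  y_true <- c(rep(0, 33), rep(1, 91), rep(2, 76))
  y_pred <- c(rep(0, 30), rep(1, 3),                 # small: 30 right
              rep(1, 76), rep(0, 15),                # normal: 76 right
              rep(2, 64), rep(1, 12))                # large: 64 right
  cm <- vhs_confusion(y_true, y_pred)
  expect_equal(cm$n, 200)
  expect_equal(sum(cm$counts), 200)
  expect_equal(unname(diag(cm$counts)), c(30L, 76L, 64L))
  pc <- confusion_percentages(cm)
  expect_equal(unname(pc$row_correct_pct), c(90.9, 83.5, 84.2))
  expect_equal(unname(pc$cell_pct[1, 1]), 15.0)     # 30/200
  expect_equal(unname(pc$row_pct[1, 2]), 9.1)       # 3/33 wrong
  expect_equal(overall_accuracy(y_true, y_pred), 170 / 200)
  # row correct + row errors close at 100% within rounding
  sums <- rowSums(pc$row_pct)
  expect_true(all(abs(sums - 100) < 0.2))
  # identity predictions give a diagonal matrix at 100%
  pc2 <- confusion_percentages(vhs_confusion(y_true, y_true))
  expect_equal(unname(pc2$row_correct_pct), c(100, 100, 100))
  # single sample occupies 100% of the total
  pc3 <- confusion_percentages(vhs_confusion(2L, 2L))
  expect_equal(unname(pc3$cell_pct[3, 3]), 100)
  expect_error(vhs_confusion(c(0, 3), c(0, 1)), "labels")
})

test_that("overall accuracy equals the trace of the confusion matrix", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    yt <- sample(0:2, n, replace = TRUE)
    yp <- sample(0:2, n, replace = TRUE)
    cm <- vhs_confusion(yt, yp)
    expect_equal(overall_accuracy(yt, yp), sum(diag(cm$counts)) / cm$n)
  }
})

test_that("one-vs-rest AUC matches the pairwise oracle, incl. ties", {
  set.seed(62)
  for (i in 1:12) {
    n <- sample(c(20, 80, 200), 1)
    y <- sample(0:2, n, replace = TRUE, prob = c(0.2, 0.4, 0.4))
    # coarse scores induce plenty of ties
    raw <- matrix(round(runif(n * 3), 1), n) + 1e-9
    probs <- raw / rowSums(raw)
    got <- one_vs_rest_metrics(y, probs)
    for (k in 0:2) {
      expect_equal(got$auc[k + 1],
                   auc_pairwise(as.integer(y == k), probs[, k + 1]),
                   tolerance = 1e-12)
    }
  }
  # perfectly separated scores -> AUC 1 for every present class
  y <- c(0, 0, 1, 1, 2, 2)
  probs <- rbind(c(.98, .01, .01), c(.97, .02, .01), c(.01, .98, .01),
                 c(.02, .97, .01), c(.01, .01, .98), c(.01, .02, .97))
  expect_equal(one_vs_rest_metrics(y, probs)$auc, rep(1, 3))
  # label-independent scores -> AUC 1/2 exactly (all scores equal)
  probs0 <- matrix(1 / 3, 6, 3)
  expect_equal(one_vs_rest_metrics(y, probs0)$auc, rep(0.5, 3))
  # absent class reports NA, not zero
  got <- one_vs_rest_metrics(c(0, 0, 1, 1, 1, 0), probs)
  expect_true(is.na(got$auc[3]))
})

test_that("precision/specificity/sensitivity match a hand-tallied table", {
  # class 0: TP=2, FP=1, FN=0, TN=3
  y <- c(0, 0, 1, 1, 2, 2)
  probs <- rbind(c(.9, .05, .05), c(.8, .1, .1),   # both true 0 -> pred 0
                 c(.7, .2, .1),                    # true 1 -> pred 0 (FP)
                 c(.1, .8, .1), c(.1, .1, .8), c(.2, .1, .7))
  got <- one_vs_rest_metrics(y, probs)
  expect_equal(got$precision[1], 2 / 3)
  expect_equal(got$specificity[1], 3 / 4)
  expect_equal(got$sensitivity[1], 1)
  # cross-check AUC against pROC on the same scores
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(63)
    y2 <- sample(0:2, 60, replace = TRUE)
    raw <- matrix(runif(180), 60)
    p2 <- raw / rowSums(raw)
    got2 <- one_vs_rest_metrics(y2, p2)
    for (k in 0:2) {
      ref <- as.numeric(pROC::auc(as.integer(y2 == k), p2[, k + 1],
                                  quiet = TRUE, direction = "<"))
      expect_equal(got2$auc[k + 1], ref, tolerance = 1e-9)
    }
  }
})

test_that("ICC(2,1) matches the hand mean-squares decomposition", {
  # 4 subjects x 2 raters, worked by hand through the two-way ANOVA
  a <- c(9, 6, 8, 7)
  b <- c(8, 5, 9, 6)
  x <- cbind(a, b)
  n <- 4; k <- 2
  gm <- mean(x)
  msr <- k * sum((rowMeans(x) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - gm)^2) / (k - 1)
  mse <- (sum((x - gm)^2) - k * sum((rowMeans(x) - gm)^2) -
            n * sum((colMeans(x) - gm)^2)) / ((n - 1) * (k - 1))
  expected <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc_agreement(a, b), expected, tolerance = 1e-9)
  # symmetry, perfect agreement, and systematic disagreement
  expect_equal(icc_agreement(b, a), icc_agreement(a, b), tolerance = 1e-12)
  expect_equal(icc_agreement(1:10, 1:10), 1)
  m <- mean(1:8)
  expect_lt(icc_agreement(1:8, 2 * m - (1:8)), 0)
  expect_error(icc_agreement(1, 1), "at least 2")
  expect_error(icc_agreement(1:3, 1:4), "paired")
})

test_that("metrics report bundles the pieces and serializes to JSON", {
  set.seed(64)
  y <- sample(0:2, 50, replace = TRUE)
  raw <- matrix(runif(150), 50)
  probs <- raw / rowSums(raw)
  yhat <- max.col(probs) - 1L
  rep <- metrics_report(y, yhat, probs,
                        icc = list(a = rnorm(20), b = rnorm(20)))
  expect_equal(rep$overall_accuracy, mean(y == yhat))
  expect_equal(rep$per_class$sensitivity,
               unname(confusion_percentages(rep$confusion)$row_correct_pct / 100),
               tolerance = 0.005)   # row percentages are rounded to 1 decimal
  path <- withr::local_tempfile(fileext = ".json")
  report_to_json(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$overall_accuracy, rep$overall_accuracy,
               tolerance = 1e-12)
  p <- autoplot(rep$confusion)
  expect_s3_class(p, "ggplot")
})
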
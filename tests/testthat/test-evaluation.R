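test_that("confusion counts partition the sample", {
  cc <- confusion(c(rep(1, 10), rep(0, 10)), c(rep(1, 10), rep(0, 10)))
  expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")]),
               c(TP = 10L, FP = 0L, TN = 10L, FN = 0L))

  all_pos <- confusion(rep(c(1, 0), 8), rep(1, 16))
  expect_equal(all_pos$FN, 0L); expect_equal(all_pos$TN, 0L)

  set.seed(4)
  y <- rbinom(100, 1, 0.4); p <- rbinom(100, 1, 0.6)
  cc2 <- confusion(y, p)
  hand <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (i in 1:100) {
    key <- if (y[i] == 1 && p[i] == 1) "TP" else if (y[i] == 0 && p[i] == 1) "FP"
    else if (y[i] == 0 && p[i] == 0) "TN" else "FN"
    hand[key] <- hand[key] + 1L
  }
  expect_equal(unlist(cc2[c("TP", "FP", "TN", "FN")]), hand)
  expect_error(confusion(c(1, 0), c(1)), "equal length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("metrics follow the confusion-matrix formulas and conventions", {
  perfect <- classification_metrics(list(TP = 50, FP = 0, TN = 50, FN = 0))
  expect_equal(perfect$mcc, 1); expect_equal(perfect$accuracy, 1)

  ## the all-positive classifier on a balanced set
  deg <- classification_metrics(list(TP = 50, FP = 50, TN = 0, FN = 0))
  expect_equal(deg$accuracy, 0.5)
  expect_equal(deg$precision, 0.5)
  expect_equal(deg$recall, 1)
  expect_equal(deg$specificity, 0)
  expect_equal(deg$mcc, 0)
  expect_true(deg$degenerate)

  ## direct formula evaluation as oracle:
  ## TP+FP = 50, TP+FN = 55, TN+FP = 45, TN+FN = 50
  m <- classification_metrics(list(TP = 30, FP = 20, TN = 25, FN = 25))
  expect_equal(m$mcc, (30 * 25 - 20 * 25) / sqrt(50 * 55 * 45 * 50))
  expect_equal(m$mcc, 0.100504, tolerance = 1e-5)

  expect_error(classification_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "empty")
})

test_that("MCC is symmetric under joint swap and antisymmetric under flip", {
  set.seed(8)
  for (i in 1:50) {
    cc <- list(TP = sample(0:30, 1), FP = sample(0:30, 1),
               TN = sample(0:30, 1), FN = sample(0:30, 1))
    if (Reduce(`+`, cc) == 0) next
    m <- classification_metrics(cc)$mcc
    swapped <- classification_metrics(list(TP = cc$TN, FP = cc$FN,
                                           TN = cc$TP, FN = cc$FP))$mcc
    expect_equal(swapped, m)
    flipped <- classification_metrics(list(TP = cc$FN, FP = cc$TN,
                                           TN = cc$FP, FN = cc$TP))$mcc
    den <- with(cc, as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
    if (den > 0) expect_equal(flipped, -m)
  }
})

test_that("AUC equals the Mann-Whitney rank statistic", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)

  ## 6-sample hand case vs exhaustive pair counting
  y <- c(1, 0, 1, 0, 1, 0)
  s <- c(0.9, 0.8, 0.7, 0.7, 0.2, 0.1)
  pairs <- expand.grid(p = which(y == 1), n = which(y == 0))
  rank_stat <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                           ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
  expect_equal(roc_auc(y, s)$auc, rank_stat)

  set.seed(13)
  for (i in 1:20) {
    yy <- c(1, 0, rbinom(18, 1, 0.5))
    ss <- round(runif(20), 2)                 # ties on purpose
    pg <- expand.grid(p = which(yy == 1), n = which(yy == 0))
    rs <- mean(ifelse(ss[pg$p] > ss[pg$n], 1,
                      ifelse(ss[pg$p] == ss[pg$n], 0.5, 0)))
    r <- roc_auc(yy, ss)
    expect_equal(r$auc, rs)
    expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
    expect_equal(tail(r$points$fpr, 1), 1); expect_equal(tail(r$points$tpr, 1), 1)
  }
  expect_error(roc_auc(rep(1, 5), runif(5)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1)
  s <- runif(60)
  ref <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(y, s, quiet = TRUE, direction = "<", levels = c(0, 1)))))
  expect_equal(roc_auc(y, s)$auc, ref, tolerance = 1e-12)
})

test_that("metrics match a brute-force oracle on random confusion matrices", {
  set.seed(99)
  for (i in 1:1000) {
    cc <- list(TP = sample(0:50, 1), FP = sample(0:50, 1),
               TN = sample(0:50, 1), FN = sample(0:50, 1))
    n <- Reduce(`+`, cc)
    if (n == 0) next
    m <- classification_metrics(cc)
    expect_equal(m$accuracy, (cc$TP + cc$TN) / n, tolerance = 1e-12)
    expect_equal(m$precision,
                 if (cc$TP + cc$FP == 0) 0 else cc$TP / (cc$TP + cc$FP),
                 tolerance = 1e-12)
    expect_equal(m$recall,
                 if (cc$TP + cc$FN == 0) 0 else cc$TP / (cc$TP + cc$FN),
                 tolerance = 1e-12)
    expect_equal(m$specificity,
                 if (cc$TN + cc$FP == 0) 0 else cc$TN / (cc$TN + cc$FP),
                 tolerance = 1e-12)
    den <- as.numeric(cc$TP + cc$FP) * (cc$TP + cc$FN) *
      (cc$TN + cc$FP) * (cc$TN + cc$FN)
    expect_equal(m$mcc,
                 if (den == 0) 0 else
                   (as.numeric(cc$TP) * cc$TN - as.numeric(cc$FP) * cc$FN) / sqrt(den),
                 tolerance = 1e-12)
  }
})
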
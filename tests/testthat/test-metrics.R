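# Brute-force oracles, kept deliberately naive and independent of the
# implementations they check.
bruteAucROC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
bruteAucPR <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  ap <- 0; prevRec <- 0
  for (t in thr) {
    tp <- sum(labels == 1 & scores >= t)
    fp <- sum(labels == 0 & scores >= t)
    rec <- tp / P
    ap <- ap + (rec - prevRec) * tp / (tp + fp)
    prevRec <- rec
  }
  ap
}
bruteMaxF1 <- function(scores, labels) {
  best <- 0
  for (t in unique(scores)) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred); rec <- tp / sum(labels == 1)
    f1 <- if (tp == 0) 0 else 2 * prec * rec / (prec + rec)
    best <- max(best, f1)
  }
  best
}

test_that("AUC-ROC handles perfect ranking, ties and errors", {
  expect_equal(aucROC(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(aucROC(c(0.1, 0.9), c(1, 0)), 0)
  expect_equal(aucROC(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(aucROC(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC-PR handles perfect and single-positive cases", {
  expect_equal(aucPR(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(aucPR(c(10, 1:9), c(1, rep(0, 9))), 1)
  expect_error(aucPR(1:3, c(0, 0, 0)), "no positive")
})

test_that("max F1 includes the all-positive threshold", {
  # all-equal scores: only operating point is all-positive, F1 = 2p/(1+p)
  p <- 0.05
  n <- 200
  labels <- c(rep(1, n * p), rep(0, n * (1 - p)))
  expect_equal(maxF1(rep(0.3, n), labels), 2 * p / (1 + p),
               tolerance = 1e-12)
  expect_equal(maxF1(labels + 0, labels), 1)  # perfect separation
  expect_error(maxF1(1:3, c(0, 0, 0)), "no positive")
})

test_that("all three metrics match brute force on random tied instances", {
  set.seed(77)
  worst <- c(roc = 0, pr = 0, f1 = 0)
  for (i in 1:150) {
    n <- sample(5:60, 1)
    x <- randomScoresLabels(n, pCase = runif(1, 0.1, 0.6),
                            seed = sample.int(1e6, 1))
    if (length(unique(x$labels)) < 2) next
    worst["roc"] <- max(worst["roc"],
                        abs(aucROC(x$scores, x$labels) -
                            bruteAucROC(x$scores, x$labels)))
    worst["pr"] <- max(worst["pr"],
                       abs(aucPR(x$scores, x$labels) -
                           bruteAucPR(x$scores, x$labels)))
    worst["f1"] <- max(worst["f1"],
                       abs(maxF1(x$scores, x$labels) -
                           bruteMaxF1(x$scores, x$labels)))
    # dummy-classifier lower bound on max F1
    p <- mean(x$labels)
    expect_gte(maxF1(x$scores, x$labels) + 1e-12, 2 * p / (1 + p))
  }
  expect_lt(max(worst), 1e-12)
})

test_that("metrics are invariant to strictly increasing score transforms", {
  set.seed(13)
  x <- randomScoresLabels(80, pCase = 0.3, seed = 5)
  tr <- function(s) exp(3 * s) - 1
  expect_equal(aucROC(tr(x$scores), x$labels), aucROC(x$scores, x$labels))
  expect_equal(aucPR(tr(x$scores), x$labels), aucPR(x$scores, x$labels))
  expect_equal(maxF1(tr(x$scores), x$labels), maxF1(x$scores, x$labels))
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (i in 1:10) {
    x <- randomScoresLabels(100, pCase = 0.2, seed = i)
    if (length(unique(x$labels)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(x$labels, x$scores,
                                          quiet = TRUE,
                                          direction = "<")))
    expect_equal(aucROC(x$scores, x$labels), ref, tolerance = 1e-12)
  }
})

test_that("uninformative scorers calibrate to 0.5 and the case fraction", {
  set.seed(4242)
  n <- 5000; p <- 0.05
  labels <- rbinom(n, 1, p)
  scores <- runif(n)
  expect_lt(abs(aucROC(scores, labels) - 0.5), 0.03)
  expect_lt(abs(aucPR(scores, labels) - mean(labels)), 0.015)
})

test_that("phenome summary bins by prevalence and counts strict wins", {
  metrics <- expand.grid(phenotype = paste0("ph", 1:6),
                         method = c("phew2p2v", "p2v"),
                         rep = 1:2, stringsAsFactors = FALSE)
  # phew2p2v beats p2v on ph1..ph4, ties on ph5, loses on ph6
  base <- setNames(seq(0.9, 0.4, by = -0.1), paste0("ph", 1:6))
  metrics$auc_roc <- ifelse(metrics$method == "phew2p2v",
                            base[metrics$phenotype] +
                              ifelse(metrics$phenotype %in%
                                       paste0("ph", 1:4), 0.05,
                                     ifelse(metrics$phenotype == "ph6",
                                            -0.05, 0)),
                            base[metrics$phenotype])
  metrics$auc_pr <- metrics$auc_roc / 2
  metrics$max_f1 <- metrics$auc_roc / 3
  prevalence <- setNames(seq(0.6, 0.1, by = -0.1), paste0("ph", 1:6))
  out <- evaluatePhenome(metrics, prevalence, binSize = 3)
  expect_equal(sort(unique(out$summary$bin)), c(1, 2))
  # bin 1 holds the three most prevalent phenotypes
  expect_equal(unique(out$summary$n_phenotypes), 3)
  wins <- out$wins[out$wins$metric == "auc_roc", ]
  expect_equal(wins$wins[wins$bin == 1], 3)  # ph1..ph3
  expect_equal(wins$wins[wins$bin == 2], 1)  # ph4 only; tie and loss don't count

  # single phenotype, single repeat: summary equals the input row
  one <- metrics[metrics$phenotype == "ph1" & metrics$rep == 1 &
                   metrics$method == "p2v", ]
  s1 <- evaluatePhenome(one, prevalence["ph1"], binSize = 300)
  expect_equal(s1$summary$median[s1$summary$metric == "auc_roc"],
               one$auc_roc)
})
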
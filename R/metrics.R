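#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation: the probability that a random case outscores a
#' random control, with ties counted 1/2. Equals the trapezoidal area under
#' the ROC curve; 0.5 means an uninformative scorer.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return A number in `[0, 1]`.
#' @export
aucROC <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0)
    stop("AUC-ROC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' The average-precision estimator: with thresholds at every distinct score
#' (descending) the PR curve is integrated as
#' \eqn{\sum_i (R_i - R_{i-1}) P_i} — no interpolation. An uninformative
#' scorer has expected AUC-PR equal to the case fraction.
#'
#' @inheritParams aucROC
#' @return A number in `(0, 1]`.
#' @export
aucPR <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  P <- sum(labels == 1L)
  if (P == 0) stop("AUC-PR undefined: no positive sample")
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  lastRecall <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1L)
    prec <- tp / sum(sel)
    rec <- tp / P
    ap <- ap + (rec - lastRecall) * prec
    lastRecall <- rec
  }
  ap
}

#' Maximum F1-score over all thresholds
#'
#' Scans every achievable operating point (predict positive when
#' `score >= t`, for `t` at each distinct score) and returns the maximum
#' harmonic mean of precision and recall. The all-positive operating point is
#' always among them, so the result is never below `2p / (1 + p)` at case
#' fraction `p` — the F1 of a classifier that calls everyone a case.
#'
#' @inheritParams aucROC
#' @return A number in `(0, 1]`.
#' @export
maxF1 <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  P <- sum(labels == 1L)
  if (P == 0) stop("max F1 undefined: no positive sample")
  best <- 0
  for (t in unique(scores)) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1L)
    f1 <- 2 * tp / (sum(sel) + P)  # 2TP / (2TP + FP + FN)
    if (f1 > best) best <- f1
  }
  best
}

#' Evaluate one score vector with all three metrics
#'
#' @inheritParams aucROC
#' @return data.frame with `auc_roc`, `auc_pr`, `max_f1`, `n_cases`,
#'   `n_controls`.
#' @export
evaluateScores <- function(scores, labels) {
  labels <- as.integer(labels)
  data.frame(auc_roc = aucROC(scores, labels),
             auc_pr = aucPR(scores, labels),
             max_f1 = maxF1(scores, labels),
             n_cases = sum(labels == 1L),
             n_controls = sum(labels == 0L))
}

#' Summarise phenome-wide prediction results
#'
#' Takes the tidy per-(phenotype, method, repeat) metric table, averages over
#' repeats within each (phenotype, method), bins phenotypes by descending
#' prevalence, and reports per bin and method the median and quartiles of
#' each metric, plus head-to-head win counts of a reference method against
#' every other (strict inequality on the repeat-averaged metric; ties count
#' as not better).
#'
#' @param metrics data.frame with columns `phenotype`, `method`, `rep`,
#'   `auc_roc`, `auc_pr`, `max_f1`.
#' @param prevalence Named numeric vector: prevalence per phenotype (used for
#'   ranking/binning).
#' @param binSize Number of phenotypes per prevalence bin (default 300; the
#'   last bin absorbs the remainder).
#' @param referenceMethod Method compared against all others in the win
#'   counts (default `"phew2p2v"`).
#' @return List with `summary` (bin x method x metric quantiles) and `wins`
#'   (bin x opponent win counts per metric).
#' @export
evaluatePhenome <- function(metrics, prevalence, binSize = 300L,
                            referenceMethod = "phew2p2v") {
  stopifnot(all(c("phenotype", "method", "rep", "auc_roc", "auc_pr",
                  "max_f1") %in% names(metrics)))
  agg <- stats::aggregate(
    metrics[, c("auc_roc", "auc_pr", "max_f1")],
    by = list(phenotype = metrics$phenotype, method = metrics$method),
    FUN = mean)
  phes <- names(sort(prevalence, decreasing = TRUE))
  phes <- phes[phes %in% agg$phenotype]
  nb <- max(1L, ceiling(length(phes) / binSize))
  binOf <- stats::setNames(pmin(ceiling(seq_along(phes) / binSize), nb), phes)
  agg$bin <- binOf[agg$phenotype]

  q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  rows <- list()
  winRows <- list()
  for (b in sort(unique(agg$bin))) {
    sub <- agg[agg$bin == b, ]
    for (m in unique(sub$method)) {
      sm <- sub[sub$method == m, ]
      for (metric in c("auc_roc", "auc_pr", "max_f1")) {
        qq <- q(sm[[metric]])
        rows[[length(rows) + 1L]] <- data.frame(
          bin = b, method = m, metric = metric,
          q1 = qq[1], median = qq[2], q3 = qq[3],
          n_phenotypes = nrow(sm))
      }
    }
    if (referenceMethod %in% sub$method) {
      ref <- sub[sub$method == referenceMethod, ]
      for (m in setdiff(unique(sub$method), referenceMethod)) {
        other <- sub[sub$method == m, ]
        common <- intersect(ref$phenotype, other$phenotype)
        refI <- match(common, ref$phenotype)
        othI <- match(common, other$phenotype)
        for (metric in c("auc_roc", "auc_pr", "max_f1")) {
          winRows[[length(winRows) + 1L]] <- data.frame(
            bin = b, opponent = m, metric = metric,
            wins = sum(ref[[metric]][refI] > other[[metric]][othI]),
            n_phenotypes = length(common))
        }
      }
    }
  }
  list(summary = do.call(rbind, rows),
       wins = if (length(winRows)) do.call(rbind, winRows) else NULL,
       perPhenotype = agg)
}
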
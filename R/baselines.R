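#' Concept count feature matrix
#'
#' Builds the feature matrix the conventional baselines train on: one row per
#' patient, one column per vocabulary concept, entries counting the number of
#' (by default pre-latest) admissions in which the concept appears — presence
#' is binary per admission, so the count is an admission count, not a raw
#' event count.
#'
#' @param records A [PatientRecords-class].
#' @param ids Patient ids (rows), default all.
#' @param vocabulary Character vector fixing the column universe (the
#'   training vocabulary after rare-concept filtering).
#' @param excludeLatest Count only pre-latest admissions (default `TRUE`).
#' @return Integer matrix `length(ids) x length(vocabulary)` with dimnames.
#' @export
buildCountMatrix <- function(records, ids = patientIds(records), vocabulary,
                             excludeLatest = TRUE) {
  stopifnot(is(records, "PatientRecords"), length(vocabulary) > 0)
  X <- matrix(0L, nrow = length(ids), ncol = length(vocabulary),
              dimnames = list(ids, vocabulary))
  for (i in seq_along(ids)) {
    occ <- pastConceptOccurrences(records@records[[ids[i]]],
                                  excludeLatest = excludeLatest)
    occ <- occ[occ %in% vocabulary]
    if (length(occ)) {
      tab <- table(occ)
      X[i, names(tab)] <- as.integer(tab)
    }
  }
  X
}

#' Fit a conventional baseline classifier on count features
#'
#' Three standard supervised baselines over the concept-count matrix, with
#' the hyperparameters fixed to the reference configuration and everything
#' else at the backing implementation's defaults:
#' * `"lasso"` — L1-penalised logistic regression via **glmnet**. The penalty
#'   is parameterised as inverse regularisation strength `C` (default 1.0) in
#'   the per-sample-loss convention, i.e. `lambda = 1 / (C * n)`; features
#'   are not standardised.
#' * `"random_forest"` — **ranger**, 500 trees, Gini impurity, probability
#'   forest, single thread for determinism.
#' * `"gbt"` — **xgboost**, 100 boosting rounds, `binary:logistic`, single
#'   thread.
#'
#' @param kind One of `"lasso"`, `"random_forest"`, `"gbt"`.
#' @param X Numeric matrix of count features (rows = patients).
#' @param y Binary outcome vector (0/1), both classes present.
#' @param seed Seed controlling all training randomness.
#' @param C Inverse regularisation strength for the lasso (default 1.0).
#' @param phenotype Optional label used in error messages.
#' @return An object of class `"phewBaseline"`; score new patients with
#'   [predict.phewBaseline()].
#' @export
fitBaseline <- function(kind = c("lasso", "random_forest", "gbt"), X, y,
                        seed = 1L, C = 1.0, phenotype = NULL) {
  kind <- match.arg(kind)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2)
    stop("cannot fit ", kind, ": outcome has a single class",
         if (!is.null(phenotype)) paste0(" for phenotype ", phenotype))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  model <- switch(kind,
    lasso = {
      lam <- 1 / (C * nrow(X))
      set.seed(seed)
      # descending path ending at the target lambda stabilises the fit; on
      # (nearly) separable draws coordinate descent can hit maxit at the
      # smallest penalty, in which case the closest computed path point is
      # scored instead — silence that advisory
      fit <- tryCatch(
        suppressWarnings(
          glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                         standardize = FALSE, thresh = 1e-5,
                         maxit = 500000, lambda = lam * c(64, 16, 4, 1))),
        error = function(e) NULL)
      # degenerate design (e.g. all labeled patients share one feature row
      # for a rare phenotype): fall back to the intercept-only scorer so a
      # phenome-wide run survives the phenotype instead of aborting
      list(fit = fit, s = lam, const = mean(y))
    },
    random_forest = {
      df <- data.frame(X, check.names = FALSE)
      ranger::ranger(x = df, y = factor(y, levels = c(0L, 1L)),
                     num.trees = 500, splitrule = "gini",
                     probability = TRUE, num.threads = 1, seed = seed)
    },
    gbt = {
      dtr <- xgboost::xgb.DMatrix(X, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", nthread = 1,
                      seed = seed),
        data = dtr, nrounds = 100, verbose = 0)
    })
  structure(list(kind = kind, model = model, features = colnames(X)),
            class = "phewBaseline")
}

#' Score new patients with a fitted baseline
#'
#' @param object A `"phewBaseline"` from [fitBaseline()].
#' @param newX Count matrix with the training feature columns.
#' @param ... Unused.
#' @return Numeric vector of risk scores (case probabilities).
#' @export
predict.phewBaseline <- function(object, newX, ...) {
  newX <- as.matrix(newX[, object$features, drop = FALSE])
  storage.mode(newX) <- "double"
  switch(object$kind,
    lasso = if (is.null(object$model$fit)) {
      rep(object$model$const, nrow(newX))
    } else {
      as.numeric(predict(object$model$fit, newx = newX,
                         s = object$model$s, type = "response"))
    },
    random_forest = {
      df <- data.frame(newX, check.names = FALSE)
      as.numeric(predict(object$model, data = df,
                         num.threads = 1)$predictions[, "1"])
    },
    gbt = as.numeric(predict(object$model, xgboost::xgb.DMatrix(newX))))
}
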
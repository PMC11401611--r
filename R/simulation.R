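#' Configuration of the simulated cohort generator
#'
#' The generator emulates a coded-record cohort with a known ground truth: a
#' pool of `nPool` patients each carrying `nConcepts` correlated binary
#' medical concepts, the first `nSignal` of which drive a binary outcome
#' concept `sim:C0` through a logistic model,
#' \deqn{P(C_0 = 1) = \mathrm{logit}^{-1}(a + \beta \sum_{k \le nSignal} C_k),}
#' with a common coefficient `beta` and the intercept `a` solved numerically
#' so that pool outcome prevalence is 0.5. Concepts are drawn from a latent
#' block-exchangeable Gaussian threshold model: concepts are grouped into
#' blocks of `blockSize`, concepts in one block share a latent factor
#' (`Z = sqrt(rho) W_block + sqrt(1-rho) E`), and the latent variables are
#' thresholded at the marginal probability. This emulates how medical
#' concepts correlate in clusters (comorbidity and care patterns) rather
#' than globally; with the default block size the signal concepts form one
#' correlated cluster and the noise concepts fourteen others.
#'
#' @param nPool Pool size (default 20000).
#' @param nConcepts Number of binary concepts (default 150).
#' @param nSignal Number of signal concepts (default 10).
#' @param beta Logistic coefficient shared by the signal concepts.
#' @param conceptProb Marginal presence probability of each concept
#'   (default 0.2, about 30 concepts per patient record).
#' @param conceptCorrelation Within-block latent correlation in `[0, 1)`
#'   (default 0.5; concepts cluster strongly, as comorbid conditions and
#'   their care patterns do).
#' @param blockSize Number of concepts sharing one latent factor
#'   (default 10).
#' @param nBackground Number of pool patients reserved as the unlabeled
#'   embedding background (default 10000, the first half of the pool);
#'   case-control replicates are drawn only from the remaining patients, so
#'   no test subject ever contributes a sentence to an embedding corpus.
#' @param corpusSize Number of background patients whose sentences form one
#'   replicate's embedding corpus (default 1000).
#' @param nCases,nControls Cases and controls sampled per replicate
#'   (defaults 10 and 190, a 1:19 case-control ratio, i.e. 5% prevalence;
#'   other studied ratios: 1:1, 3:7, 1:9).
#' @param nReps Number of replicates (default 1000).
#' @param seed Master seed.
#' @return A list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(nPool = 20000L, nConcepts = 150L,
                             nSignal = 10L, beta = 0.5, conceptProb = 0.2,
                             conceptCorrelation = 0.5, blockSize = 10L,
                             nCases = 10L, nControls = 190L, nReps = 1000L,
                             nBackground = 10000L, corpusSize = 1000L,
                             seed = 1L) {
  stopifnot(nSignal <= nConcepts, beta >= 0,
            conceptProb > 0, conceptProb < 1,
            conceptCorrelation >= 0, conceptCorrelation < 1,
            blockSize >= 1, nCases >= 1, nControls >= 1, nReps >= 1,
            nBackground < nPool, corpusSize <= nBackground)
  structure(list(nPool = as.integer(nPool), nConcepts = as.integer(nConcepts),
                 nSignal = as.integer(nSignal), beta = beta,
                 conceptProb = conceptProb,
                 conceptCorrelation = conceptCorrelation,
                 blockSize = as.integer(blockSize),
                 nCases = as.integer(nCases),
                 nControls = as.integer(nControls),
                 nReps = as.integer(nReps),
                 nBackground = as.integer(nBackground),
                 corpusSize = as.integer(corpusSize), seed = seed),
            class = "SimulationConfig")
}

# intercept a with mean(plogis(a + beta * s)) = target, by bisection on a
solveIntercept <- function(s, beta, target = 0.5) {
  f <- function(a) mean(plogis(a + beta * s)) - target
  lo <- -50; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-12) break
  }
  (lo + hi) / 2
}

#' Generate the simulated population pool
#'
#' Draws the correlated binary concept matrix and the logistic outcome for
#' the full pool. The intercept is solved by bisection against the pool's
#' empirical signal-sum distribution so that expected outcome prevalence is
#' exactly 0.5; with the default pool size the realised prevalence lies
#' within a fraction of a percent of that.
#'
#' @param config A [simulationConfig()].
#' @return A list of class `"SimulatedPool"` with elements `concepts`
#'   (`nPool x nConcepts` 0/1 matrix, columns `sim:C1` ...), `outcome`
#'   (0/1 vector for `sim:C0`), `signal` (signal column indices),
#'   `intercept`, and `config`.
#' @export
generatePool <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(substreamSeed(config$seed, "pool"))
  n <- config$nPool
  K <- config$nConcepts
  rho <- config$conceptCorrelation
  block <- ceiling(seq_len(K) / config$blockSize)
  W <- matrix(rnorm(n * max(block)), n, max(block))
  Z <- sqrt(rho) * W[, block, drop = FALSE] +
    sqrt(1 - rho) * matrix(rnorm(n * K), n, K)
  X <- (Z < qnorm(config$conceptProb)) + 0L
  colnames(X) <- paste0("sim:C", seq_len(K))
  signal <- seq_len(config$nSignal)
  s <- rowSums(X[, signal, drop = FALSE])
  a <- solveIntercept(s, config$beta)
  outcome <- rbinom(n, 1L, plogis(a + config$beta * s))
  if (sum(outcome) == 0 || sum(outcome) == n)
    stop("degenerate pool: outcome has a single class")
  structure(list(concepts = X, outcome = outcome, signal = signal,
                 intercept = a, config = config),
            class = "SimulatedPool")
}

#' Sample disjoint case-control training and test sets from the pool
#'
#' Draws `nCases` cases and `nControls` controls for the training set and the
#' same for the test set, without replacement and disjoint within one
#' replicate.
#'
#' @param pool A `"SimulatedPool"` from [generatePool()].
#' @param repSeed Seed for this replicate's draw.
#' @param nCases,nControls Per-set counts (default: from the pool's config).
#' @param candidates Integer indices eligible for sampling (default: the
#'   whole pool; the experiment runner restricts draws to the
#'   non-background patients).
#' @return List with integer index vectors `train` and `test`.
#' @export
sampleCaseControl <- function(pool, repSeed,
                              nCases = pool$config$nCases,
                              nControls = pool$config$nControls,
                              candidates = seq_along(pool$outcome)) {
  stopifnot(inherits(pool, "SimulatedPool"))
  caseIdx <- candidates[pool$outcome[candidates] == 1L]
  ctrlIdx <- candidates[pool$outcome[candidates] == 0L]
  if (length(caseIdx) < 2 * nCases || length(ctrlIdx) < 2 * nControls)
    stop("pool too small for the requested case-control draw")
  set.seed(repSeed)
  ca <- sample(caseIdx, 2 * nCases)
  co <- sample(ctrlIdx, 2 * nControls)
  list(train = c(ca[seq_len(nCases)], co[seq_len(nControls)]),
       test = c(ca[nCases + seq_len(nCases)],
                co[nControls + seq_len(nControls)]))
}

#' Render simulated patients as single-admission records
#'
#' Each sampled patient becomes a one-admission record containing their
#' present concepts (the simulation carries no temporal structure). When
#' `includeOutcome = TRUE` — the embedding-corpus rendering — cases
#' additionally carry the outcome concept token `sim:C0`, which is how the
#' outcome concept acquires an embedding vector; in the feature rendering
#' (`includeOutcome = FALSE`, used for all test-time scoring and all count
#' matrices) the token is always withheld.
#'
#' @param pool A `"SimulatedPool"`.
#' @param idx Integer indices of the patients to render.
#' @param includeOutcome Attach `sim:C0` to cases (default `FALSE`).
#' @return A [PatientRecords-class]; patient ids are `"sim_<index>"`.
#' @export
renderPatientSequences <- function(pool, idx, includeOutcome = FALSE) {
  stopifnot(inherits(pool, "SimulatedPool"))
  cn <- colnames(pool$concepts)
  records <- lapply(idx, function(i) {
    present <- cn[pool$concepts[i, ] == 1L]
    if (includeOutcome && pool$outcome[i] == 1L)
      present <- c(present, "sim:C0")
    list(present)
  })
  names(records) <- paste0("sim_", idx)
  new("PatientRecords", records = records)
}

#' Run the simulated method-comparison experiment
#'
#' For each `beta` on the grid: generates a pool whose first `nBackground`
#' patients form an unlabeled embedding background, then for each replicate
#' (1) trains concept embeddings on the sentences of a replicate-specific
#' random subsample of `corpusSize` background patients (cases among them
#' carrying the outcome token, which is how the outcome concept gets a
#' vector — exactly as unlabeled patients' records carry their diagnoses in
#' a real cohort), (2) samples disjoint case-control training and test sets
#' from the non-background patients, (3) scores the test set with the
#' tailored weighted method and the unweighted baseline, (4) fits the
#' count-matrix baselines on the training set, and (5) evaluates AUC-ROC,
#' AUC-PR and max-F1 on the test set. Embeddings are retrained per
#' replicate so that the replicate distribution integrates over embedding
#' noise; test patients never contribute sentences.
#'
#' @param config A [simulationConfig()]; its `beta` is overridden by `betas`.
#' @param betas Numeric grid of signal strengths (default `seq(0.2, 0.8,
#'   by = 0.1)`).
#' @param methods Subset of `c("phew2p2v", "p2v", "lasso", "random_forest",
#'   "gbt")`.
#' @param nReps Replicates per beta (default: from config).
#' @param d,window,epochs Embedding hyperparameters for the per-replicate
#'   trainer (defaults 32, 500, 5 — sized for the simulator's 151-token
#'   vocabulary and 1000-sentence corpora).
#' @return data.frame of class `"simExperiment"` with one row per
#'   (beta, rep, method): columns `beta`, `rep`, `method`, `auc_roc`,
#'   `auc_pr`, `max_f1`.
#' @export
runExperiment <- function(config, betas = seq(0.2, 0.8, by = 0.1),
                          methods = c("phew2p2v", "p2v", "lasso",
                                      "random_forest", "gbt"),
                          nReps = config$nReps, d = 32L, window = 500L,
                          epochs = 5L) {
  stopifnot(inherits(config, "SimulationConfig"), length(methods) >= 1)
  methods <- match.arg(methods, c("phew2p2v", "p2v", "lasso",
                                  "random_forest", "gbt"),
                       several.ok = TRUE)
  baselineKinds <- intersect(methods, c("lasso", "random_forest", "gbt"))
  rows <- list()
  for (b in betas) {
    cfgB <- config
    cfgB$beta <- b
    cfgB$seed <- substreamSeed(config$seed, "poolbeta", round(b * 1000))
    pool <- generatePool(cfgB)
    featureVocab <- colnames(pool$concepts)
    bgIdx <- seq_len(cfgB$nBackground)
    drawIdx <- setdiff(seq_len(cfgB$nPool), bgIdx)
    for (rep in seq_len(nReps)) {
      repSeed <- substreamSeed(cfgB$seed, "rep", rep)
      draw <- sampleCaseControl(pool, repSeed, candidates = drawIdx)
      yTest <- pool$outcome[draw$test]
      scored <- list()
      if (any(c("phew2p2v", "p2v") %in% methods)) {
        set.seed(substreamSeed(repSeed, "corpus"))
        bgSub <- sample(bgIdx, cfgB$corpusSize)
        corpusRec <- renderPatientSequences(pool, bgSub,
                                            includeOutcome = TRUE)
        corpus <- buildCorpus(corpusRec,
                              shuffleSeed = substreamSeed(repSeed, "shuffle"))
        model <- trainEmbeddings(corpus, d = d, window = window,
                                 epochs = epochs,
                                 seed = substreamSeed(repSeed, "embed"))
        testRec <- renderPatientSequences(pool, draw$test,
                                          includeOutcome = FALSE)
        if ("phew2p2v" %in% methods) {
          corr <- correlationMatrix(model, "sim:C0")
          scored$phew2p2v <- scoreCohort(
            testRec, phenotype = "sim:C0", model = model, corr = corr,
            method = "weighted", excludeLatest = FALSE)$score
        }
        if ("p2v" %in% methods) {
          scored$p2v <- scoreCohort(
            testRec, phenotype = "sim:C0", model = model,
            method = "unweighted", excludeLatest = FALSE)$score
        }
      }
      if (length(baselineKinds)) {
        trainRec <- renderPatientSequences(pool, draw$train,
                                           includeOutcome = FALSE)
        testRec <- renderPatientSequences(pool, draw$test,
                                          includeOutcome = FALSE)
        Xtr <- buildCountMatrix(trainRec, vocabulary = featureVocab,
                                excludeLatest = FALSE)
        Xte <- buildCountMatrix(testRec, vocabulary = featureVocab,
                                excludeLatest = FALSE)
        yTrain <- pool$outcome[draw$train]
        for (kind in baselineKinds) {
          fit <- fitBaseline(kind, Xtr, yTrain,
                             seed = substreamSeed(repSeed, kind))
          scored[[kind]] <- predict(fit, Xte)
        }
      }
      for (m in methods) {
        ev <- evaluateScores(scored[[m]], yTest)
        rows[[length(rows) + 1L]] <- data.frame(
          beta = b, rep = rep, method = m, auc_roc = ev$auc_roc,
          auc_pr = ev$auc_pr, max_f1 = ev$max_f1)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("simExperiment", class(out))
  out
}

#' Summarise a simulation experiment
#'
#' Median and quartiles of each metric over replicates, per (beta, method).
#'
#' @param results A `"simExperiment"` data.frame from [runExperiment()].
#' @return Tidy data.frame with columns `beta`, `method`, `metric`,
#'   `median`, `q1`, `q3`, `n_reps`.
#' @export
summarizeExperiment <- function(results) {
  stopifnot(all(c("beta", "method", "auc_roc") %in% names(results)))
  rows <- list()
  for (b in sort(unique(results$beta))) {
    for (m in unique(results$method)) {
      sub <- results[results$beta == b & results$method == m, ]
      for (metric in c("auc_roc", "auc_pr", "max_f1")) {
        qq <- stats::quantile(sub[[metric]], c(0.25, 0.5, 0.75),
                              names = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          beta = b, method = m, metric = metric, median = qq[2],
          q1 = qq[1], q3 = qq[3], n_reps = nrow(sub))
      }
    }
  }
  do.call(rbind, rows)
}

#' Embedding recovery of simulated association strength
#'
#' Measures how well the trained embedding geometry reflects the generative
#' signal: over `nReps` replicates, trains embeddings on a fresh background
#' corpus subsample (the same rendering the experiment uses) and records the
#' cosine similarity between each signal concept and the outcome concept
#' `sim:C0`, and likewise for noise concepts. With informative signals, the
#' median signal cosine grows with `beta` and exceeds the median absolute
#' noise cosine.
#'
#' @param config A [simulationConfig()].
#' @param betas Beta grid to probe.
#' @param nReps Replicates per beta.
#' @param d,window,epochs Embedding hyperparameters.
#' @return data.frame with columns `beta`, `rep`, `median_signal_cosine`,
#'   `median_abs_noise_cosine`.
#' @export
embeddingRecovery <- function(config, betas, nReps = 20L, d = 32L,
                              window = 500L, epochs = 5L) {
  stopifnot(inherits(config, "SimulationConfig"))
  rows <- list()
  for (b in betas) {
    cfgB <- config
    cfgB$beta <- b
    cfgB$seed <- substreamSeed(config$seed, "recpool", round(b * 1000))
    pool <- generatePool(cfgB)
    cn <- colnames(pool$concepts)
    signalConcepts <- cn[pool$signal]
    noiseConcepts <- setdiff(cn, signalConcepts)
    for (rep in seq_len(nReps)) {
      repSeed <- substreamSeed(cfgB$seed, "recrep", rep)
      set.seed(substreamSeed(repSeed, "corpus"))
      bgSub <- sample(cfgB$nBackground, cfgB$corpusSize)
      corpusRec <- renderPatientSequences(pool, bgSub,
                                          includeOutcome = TRUE)
      corpus <- buildCorpus(corpusRec,
                            shuffleSeed = substreamSeed(repSeed, "shuffle"))
      model <- trainEmbeddings(corpus, d = d, window = window,
                               epochs = epochs,
                               seed = substreamSeed(repSeed, "embed"))
      c0 <- conceptVector(model, "sim:C0")
      cosTo <- function(tok) {
        if (!hasConcept(model, tok)) return(NA_real_)
        cosineSim(conceptVector(model, tok), c0)
      }
      sig <- vapply(signalConcepts, cosTo, numeric(1))
      noi <- vapply(noiseConcepts, cosTo, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        beta = b, rep = rep,
        median_signal_cosine = median(sig, na.rm = TRUE),
        median_abs_noise_cosine = median(abs(noi), na.rm = TRUE))
    }
  }
  do.call(rbind, rows)
}

#' Logistic parameter recovery on a generated pool
#'
#' Refits the generative logistic model (outcome on the sum of the signal
#' concepts) on the full pool and returns the estimated coefficient, as a
#' check that the generator realises the requested association strength.
#'
#' @param pool A `"SimulatedPool"`.
#' @return Named numeric: `intercept` and `beta_hat`.
#' @export
refitPoolModel <- function(pool) {
  stopifnot(inherits(pool, "SimulatedPool"))
  s <- rowSums(pool$concepts[, pool$signal, drop = FALSE])
  fit <- glm(pool$outcome ~ s, family = binomial())
  c(intercept = unname(coef(fit)[1]), beta_hat = unname(coef(fit)[2]))
}
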
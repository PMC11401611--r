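# correlation matrix of the hand-set model, rows = all concepts
handCorr <- function(model = handModel())
  correlationMatrix(model, rownames(model@vectors))

test_that("weighted patient vector reduces correctly in closed-form cases", {
  m <- handModel()
  corr <- handCorr(m)
  # single concept with nonzero correlation -> PV is that concept's vector
  pv <- weightedPatientVector("rx:warfarin", "phe:427.2", m, corr)
  expect_equal(pv$vector, unname(conceptVector(m, "rx:warfarin")))
  expect_equal(pv$nConceptsUsed, 1L)
  expect_false(pv$flagged)

  # two concepts with equal |r| -> plain mean
  pv2 <- weightedPatientVector(c("rx:warfarin", "phe:008"), "phe:427.2",
                               m, corr)
  expect_equal(pv2$vector,
               unname((m@vectors["rx:warfarin", ] + m@vectors["phe:008", ]) / 2))

  # +r and -r concepts get equal weight (sign symmetry)
  expect_equal(abs(corr["phe:427.2", "rx:warfarin"]),
               abs(corr["phe:427.2", "phe:008"]))

  # OOV-only input -> flagged zero vector
  pv3 <- weightedPatientVector("rx:unknown", "phe:427.2", m, corr)
  expect_true(pv3$flagged)
  expect_equal(pv3$vector, c(0, 0))
  expect_equal(pv3$nConceptsUsed, 0L)

  # zero-weight input (concept orthogonal to the phenotype) -> flagged
  pv4 <- weightedPatientVector("rx:insulin", "phe:427.2", m, corr)
  expect_true(pv4$flagged)

  expect_error(weightedPatientVector("rx:warfarin", "phe:999", m, corr),
               "unknown phenotype")
})

test_that("weighted vector matches an independent brute-force oracle", {
  set.seed(5)
  maxErr <- 0
  for (i in 1:200) {
    d <- sample(2:16, 1)
    K <- sample(3:30, 1)
    V <- matrix(rnorm(K * d), K, d,
                dimnames = list(paste0("k", 1:K), NULL))
    m <- new("ConceptEmbedding", vectors = V, counts = integer())
    corr <- correlationMatrix(m, "k1")
    occ <- sample(rownames(V), sample(1:25, 1), replace = TRUE)
    pv <- weightedPatientVector(occ, "k1", m, corr)
    # independent loop over the occurrence multiset
    num <- numeric(d); den <- 0
    for (o in occ) {
      r <- sum(V["k1", ] * V[o, ]) /
        (sqrt(sum(V["k1", ]^2)) * sqrt(sum(V[o, ]^2)))
      num <- num + r^2 * V[o, ]
      den <- den + r^2
    }
    maxErr <- max(maxErr, max(abs(pv$vector - num / den)))
    # weights are a convex combination whenever den > 0
    expect_false(pv$flagged)
  }
  expect_lt(maxErr, 1e-12)
})

test_that("unweighted vector is the multiset sum and scale-equivalent", {
  m <- handModel()
  pv <- unweightedPatientVector(c("rx:warfarin", "rx:warfarin"), m)
  expect_equal(pv$vector, unname(2 * m@vectors["rx:warfarin", ]))
  expect_equal(pv$nConceptsUsed, 2L)
  # cosine of sum equals cosine of mean (homogeneity of the score)
  expect_equal(riskScore(pv, "phe:427.2", m),
               riskScore(list(vector = pv$vector / 2, flagged = FALSE),
                         "phe:427.2", m))
  expect_true(unweightedPatientVector("zz", m)$flagged)
})

test_that("risk scores are bounded cosines with hand-checkable values", {
  m <- handModel()
  expect_equal(riskScore(conceptVector(m, "phe:427.2"), "phe:427.2", m), 1)
  expect_equal(riskScore(c(0, 1), "phe:427.2", m), 0)
  expect_equal(riskScore(conceptVector(m, "lab:K50090"), "phe:427.2", m),
               sqrt(0.5), tolerance = 1e-12)
  expect_error(riskScore(c(1, 0), "phe:999", m), "unknown phenotype")

  set.seed(8)
  for (i in 1:100) {
    pv <- rnorm(2)
    s <- riskScore(pv, "lab:K50090", m)
    expect_true(s >= -1 && s <= 1)
    expect_equal(s, cosineSim(pv, m@vectors["lab:K50090", ]),
                 tolerance = 1e-12)
  }
})

test_that("cohort scoring uses only pre-latest admissions and flags degenerates", {
  m <- handModel()
  corr <- handCorr(m)
  rec <- new("PatientRecords", records = list(
    # past = {warfarin}; latest admission must be ignored
    t1 = list(c("rx:warfarin"), c("phe:427.2")),
    # past contains only an OOV concept -> flagged score 0
    t2 = list(c("rx:mystery"), c("phe:008")),
    # identical past to t1 -> identical score
    t3 = list(c("rx:warfarin"), c("rx:insulin"))
  ))
  out <- scoreCohort(rec, phenotype = "phe:427.2", model = m, corr = corr,
                     method = "weighted")
  expect_equal(out$score[1], 1)          # PV = warfarin vector = Phe vector
  expect_equal(out$score[2], 0)
  expect_true(out$flagged[2])
  expect_equal(out$score[3], out$score[1])

  # the latest admission's concepts must not leak into the features
  outU <- scoreCohort(rec, phenotype = "phe:427.2", model = m,
                      method = "unweighted")
  expect_equal(outU$score[1], 1)
  expect_equal(outU$n_concepts_used[1], 1L)
})

test_that("uniform correlations make weighted and unweighted scores equal", {
  # vectors arranged so every concept has the same |r| with the phenotype
  V <- rbind(phe = c(1, 0), a = c(1, 1), b = c(1, -1), c = c(-1, 1))
  V <- V / sqrt(rowSums(V^2))
  m <- new("ConceptEmbedding", vectors = V, counts = integer())
  corr <- correlationMatrix(m, "phe")
  expect_equal(length(unique(round(abs(corr[1, -1]), 12))), 1)
  set.seed(31)
  for (i in 1:25) {
    occ <- sample(c("a", "b", "c"), sample(1:6, 1), replace = TRUE)
    sW <- riskScore(weightedPatientVector(occ, "phe", m, corr), "phe", m)
    sU <- riskScore(unweightedPatientVector(occ, m), "phe", m)
    expect_equal(sW, sU, tolerance = 1e-12)
  }
})

test_that("weight normalisation and sign symmetry hold on random instances", {
  set.seed(14)
  for (i in 1:50) {
    d <- sample(2:10, 1)
    V <- matrix(rnorm(8 * d), 8, d, dimnames = list(paste0("k", 1:8), NULL))
    m <- new("ConceptEmbedding", vectors = V, counts = integer())
    corr <- correlationMatrix(m, "k1")
    occ <- sample(rownames(V)[-1], 5)
    r <- corr["k1", occ]
    w <- r^2 / sum(r^2)
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    # flipping one concept's vector flips r but leaves its weight unchanged
    V2 <- V; V2[occ[1], ] <- -V2[occ[1], ]
    m2 <- new("ConceptEmbedding", vectors = V2, counts = integer())
    corr2 <- correlationMatrix(m2, "k1")
    expect_equal(corr2["k1", occ[1]], -corr["k1", occ[1]],
                 tolerance = 1e-12)
    expect_equal((corr2["k1", occ[1]]^2), (corr["k1", occ[1]]^2),
                 tolerance = 1e-12)
  }
})
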
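# Shared in-code fixtures: a toy phecode map and a 6-patient longitudinal
# cohort with hand-enumerable labels.

toyMapCsv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "icd9,phecode,exclude_range_lo,exclude_range_hi",
    "001.0,008,,",
    "427.31,427.2,427,427.99",
    "427.9,427.5,,",
    "250.00,250.2,249,250.99",
    "585.9,585.3,,"
  ), path)
  path
}

toyMap <- function() loadPhecodeMap(toyMapCsv())

# Six patients against target phenotype 427.2 (exclusion range [427, 427.99]):
#   A: adm1 control (008), adm2 case (427.2)          -> incident_case
#   B: adm1 case, adm2 case                           -> unlabeled (prior case)
#   C: single admission, case                         -> unlabeled (one visit)
#   D: adm1 control, adm2 control                     -> valid_control
#   E: adm1 control, adm2 excluded (427.5 in range)   -> unlabeled (excluded at latest)
#   F: adm1 case, adm2 control                        -> unlabeled (prior case)
toyCohortTables <- function() {
  admissions <- data.frame(
    patient_id = rep(c("A", "B", "C", "D", "E", "F"),
                     times = c(2, 2, 1, 2, 2, 2)),
    admission_id = c("a1", "a2", "b1", "b2", "c1", "d1", "d2",
                     "e1", "e2", "f1", "f2"),
    admit_order = c(1, 2, 1, 2, 1, 1, 2, 1, 2, 1, 2)
  )
  diagnoses <- data.frame(
    admission_id = c("a1", "a2", "b1", "b2", "c1", "d1", "d2",
                     "e1", "e2", "f1", "f2"),
    icd9 = c("001.0", "427.31", "427.31", "427.31", "427.31", "001.0",
             "001.0", "001.0", "427.9", "427.31", "001.0")
  )
  prescriptions <- data.frame(
    admission_id = c("a1", "a1", "d1"),
    drug = c("warfarin", "warfarin", "insulin")  # duplicate rx on purpose
  )
  labs <- data.frame(admission_id = "a2", lab = "K50090")
  list(admissions = admissions, diagnoses = diagnoses,
       prescriptions = prescriptions, labs = labs)
}

toyRecords <- function(map = toyMap()) {
  tb <- toyCohortTables()
  buildPatientRecords(tb$admissions, tb$diagnoses, tb$prescriptions,
                      tb$labs, map)
}

# Hand-set 2-d embedding over a tiny vocabulary for worked-score tests
handModel <- function() {
  V <- rbind(
    "phe:427.2" = c(1, 0),
    "rx:warfarin" = c(1, 0),
    "rx:insulin" = c(0, 1),
    "lab:K50090" = c(sqrt(0.5), sqrt(0.5)),
    "phe:008" = c(-1, 0)
  )
  new("ConceptEmbedding", vectors = V, counts = integer())
}

# tiny deterministic corpus with planted co-occurrence structure
plantedCorpus <- function(nSent = 400, seed = 42) {
  set.seed(seed)
  c(
    replicate(nSent / 2, c("x", "y", sample(c("f1", "f2"), 1)),
              simplify = FALSE),
    replicate(nSent / 2, c("z", sample(c("g1", "g2"), 1)), simplify = FALSE)
  )
}

randomScoresLabels <- function(n, pCase = 0.3, seed = 1) {
  set.seed(seed)
  list(scores = round(runif(n), 2),  # rounding forces ties
       labels = rbinom(n, 1, pCase))
}
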
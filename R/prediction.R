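#' Phenotype-tailored weighted patient vector
#'
#' Summarises a patient's past records as a convex combination of their
#' concept vectors, tailored to one phenotype: with `r_jk` the cosine
#' similarity between phenotype j and concept k,
#' \deqn{PV_{ij} = \frac{\sum_k r_{jk}^2 V_k}{\sum_k r_{jk}^2},}
#' summing over the patient's concept occurrences (by default one occurrence
#' per admission in which the concept appears, so a recurring concept
#' contributes once per admission). Squaring treats positive and negative
#' correlations equally — a strong negative association is as informative as a
#' strong positive one. Concepts absent from the vocabulary are skipped; if
#' no usable concept remains or all squared weights are zero, a flagged zero
#' vector is returned (it scores 0 downstream).
#'
#' @param pastConcepts Character vector: the patient's past concept
#'   occurrences (a multiset; duplicates each contribute).
#' @param phenotype Phenotype concept identifier, a row of `corr`.
#' @param model A [ConceptEmbedding-class].
#' @param corr Correlation matrix from [correlationMatrix()].
#' @param positiveOnly If `TRUE`, only concepts positively correlated with
#'   the phenotype contribute (a sensitivity variant; discards the
#'   information carried by negative associations).
#' @return A list with `vector` (length-d numeric), `nConceptsUsed`, and
#'   `flagged` (`TRUE` when the zero-vector fallback was used).
#' @export
weightedPatientVector <- function(pastConcepts, phenotype, model, corr,
                                  positiveOnly = FALSE) {
  stopifnot(is(model, "ConceptEmbedding"))
  if (!phenotype %in% rownames(corr))
    stop("unknown phenotype in correlation matrix: ", phenotype)
  d <- embeddingDim(model)
  usable <- pastConcepts[pastConcepts %in% rownames(model@vectors)]
  if (positiveOnly && length(usable))
    usable <- usable[corr[phenotype, usable] > 0]
  if (length(usable) == 0)
    return(list(vector = numeric(d), nConceptsUsed = 0L, flagged = TRUE))
  r <- corr[phenotype, usable]
  w <- r * r
  tot <- sum(w)
  if (tot == 0)
    return(list(vector = numeric(d), nConceptsUsed = length(usable),
                flagged = TRUE))
  V <- model@vectors[usable, , drop = FALSE]
  vec <- as.numeric(crossprod(V, w) / tot)
  flagDegenerateVector(vec, V, length(usable))
}

# a patient vector whose norm is negligible relative to its constituent
# concept vectors carries no direction (exactly cancelling combinations
# leave only floating-point residue); flag it so it scores 0 downstream
flagDegenerateVector <- function(vec, V, nUsed) {
  scale <- max(sqrt(rowSums(V * V)))
  if (sqrt(sum(vec * vec)) <= 1e-10 * scale)
    return(list(vector = numeric(length(vec)), nConceptsUsed = nUsed,
                flagged = TRUE))
  list(vector = vec, nConceptsUsed = nUsed, flagged = FALSE)
}

#' Unweighted patient vector (plain embedding sum)
#'
#' The untailored baseline representation: the plain sum of the embedding
#' vectors of the patient's past concept occurrences. Because the downstream
#' risk score is a cosine similarity, the sum and the mean are equivalent.
#'
#' @inheritParams weightedPatientVector
#' @return A list with `vector`, `nConceptsUsed` and `flagged`, as for
#'   [weightedPatientVector()].
#' @export
unweightedPatientVector <- function(pastConcepts, model) {
  stopifnot(is(model, "ConceptEmbedding"))
  d <- embeddingDim(model)
  usable <- pastConcepts[pastConcepts %in% rownames(model@vectors)]
  if (length(usable) == 0)
    return(list(vector = numeric(d), nConceptsUsed = 0L, flagged = TRUE))
  V <- model@vectors[usable, , drop = FALSE]
  flagDegenerateVector(as.numeric(colSums(V)), V, length(usable))
}

#' Incidence risk score of a patient vector for a phenotype
#'
#' The risk score is the cosine similarity between the patient vector and the
#' phenotype's embedding vector; it lies in `[-1, 1]`, higher meaning higher
#' incidence risk. A flagged (zero) patient vector scores exactly 0.
#'
#' @param pv A patient-vector list from [weightedPatientVector()] /
#'   [unweightedPatientVector()], or a bare numeric vector.
#' @param phenotype Phenotype concept identifier (must be in the vocabulary).
#' @param model A [ConceptEmbedding-class].
#' @return A single number in `[-1, 1]`.
#' @export
riskScore <- function(pv, phenotype, model) {
  stopifnot(is(model, "ConceptEmbedding"))
  if (!hasConcept(model, phenotype))
    stop("unknown phenotype concept: ", phenotype)
  vec <- if (is.list(pv)) pv$vector else pv
  cosineSim(vec, conceptVector(model, phenotype))
}

# concept occurrences of one patient's past admissions: one occurrence per
# admission in which the concept appears; excludeLatest drops the final
# admission (prediction uses past records only)
pastConceptOccurrences <- function(patient, excludeLatest = TRUE,
                                   uniqueConcepts = FALSE) {
  n <- length(patient)
  use <- if (excludeLatest) {
    if (n < 2) list() else patient[seq_len(n - 1L)]
  } else patient
  occ <- unlist(use, use.names = FALSE)
  if (is.null(occ)) occ <- character()
  if (uniqueConcepts) occ <- unique(occ)
  occ
}

#' Score a set of patients for one phenotype
#'
#' Computes the tailored (weighted) or baseline (unweighted) risk score for
#' each listed patient, using only the patient's pre-latest admissions by
#' default: the latest visit is the prediction target and its records stay
#' hidden. Patients with no usable past concepts receive score 0 and are
#' flagged, so every patient in a screening run remains scoreable.
#'
#' @param records A [PatientRecords-class].
#' @param ids Patient ids to score (default: all).
#' @param phenotype Phenotype concept identifier (row of `corr` for the
#'   weighted method).
#' @param model A [ConceptEmbedding-class].
#' @param corr Correlation matrix (required for `method = "weighted"`).
#' @param method `"weighted"` (tailored) or `"unweighted"` (plain-sum
#'   baseline).
#' @param excludeLatest Use only pre-latest admissions (default `TRUE`; set
#'   `FALSE` for single-admission cohorts such as the simulator's).
#' @param uniqueConcepts Collapse the occurrence multiset to a set
#'   (sensitivity analysis; default `FALSE`).
#' @param positiveOnly Passed to [weightedPatientVector()].
#' @return data.frame with columns `patient_id`, `phenotype`, `score`,
#'   `n_concepts_used`, `flagged`.
#' @export
scoreCohort <- function(records, ids = patientIds(records), phenotype, model,
                        corr = NULL, method = c("weighted", "unweighted"),
                        excludeLatest = TRUE, uniqueConcepts = FALSE,
                        positiveOnly = FALSE) {
  stopifnot(is(records, "PatientRecords"), is(model, "ConceptEmbedding"))
  method <- match.arg(method)
  if (method == "weighted" && is.null(corr))
    stop("the weighted method needs a correlation matrix")
  out <- data.frame(patient_id = ids, phenotype = phenotype,
                    score = NA_real_, n_concepts_used = NA_integer_,
                    flagged = NA)
  for (i in seq_along(ids)) {
    occ <- pastConceptOccurrences(records@records[[ids[i]]],
                                  excludeLatest = excludeLatest,
                                  uniqueConcepts = uniqueConcepts)
    pv <- if (method == "weighted") {
      weightedPatientVector(occ, phenotype, model, corr,
                            positiveOnly = positiveOnly)
    } else {
      unweightedPatientVector(occ, model)
    }
    out$score[i] <- if (pv$flagged) 0 else riskScore(pv, phenotype, model)
    out$n_concepts_used[i] <- pv$nConceptsUsed
    out$flagged[i] <- pv$flagged
  }
  out
}
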
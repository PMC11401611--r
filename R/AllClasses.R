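#' PhecodeMap: ICD-9 to phecode mapping with exclusion ranges
#'
#' Holds the many-to-many ICD-9 -> phecode mapping together with per-phecode
#' exclusion ranges. An exclusion range is an inclusive numeric interval over
#' phecodes (phecodes are hierarchical decimals, so e.g. 427.5 lies inside
#' \[427, 427.99\]); a patient carrying a phecode inside a target phenotype's
#' exclusion range cannot serve as a control for that phenotype.
#'
#' @slot mapping data.frame with character columns `icd9` and `phecode`;
#'   (icd9, phecode) pairs are unique.
#' @slot exclusions data.frame with columns `phecode` (character), `lo`, `hi`
#'   (numeric, inclusive bounds, `lo <= hi`).
#' @slot stripDots logical; whether ICD-9 codes were normalised by removing
#'   decimal points at load time (MIMIC-style undotted codes).
#' @export
setClass("PhecodeMap",
  slots = c(mapping = "data.frame", exclusions = "data.frame",
            stripDots = "logical"),
  prototype = prototype(
    mapping = data.frame(icd9 = character(), phecode = character()),
    exclusions = data.frame(phecode = character(), lo = numeric(),
                            hi = numeric()),
    stripDots = FALSE
  )
)

setValidity("PhecodeMap", function(object) {
  m <- object@mapping
  e <- object@exclusions
  msgs <- character()
  if (!all(c("icd9", "phecode") %in% names(m)))
    msgs <- c(msgs, "mapping must have columns 'icd9' and 'phecode'")
  else {
    if (anyDuplicated(paste(m$icd9, m$phecode, sep = "\r")))
      msgs <- c(msgs, "(icd9, phecode) pairs must be unique")
    if (any(!nzchar(m$icd9)) || any(!nzchar(m$phecode)))
      msgs <- c(msgs, "mapping rows must have non-empty icd9 and phecode")
  }
  if (!all(c("phecode", "lo", "hi") %in% names(e)))
    msgs <- c(msgs, "exclusions must have columns 'phecode', 'lo', 'hi'")
  else if (nrow(e) > 0 && any(e$lo > e$hi))
    msgs <- c(msgs, "every exclusion range needs lo <= hi")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn PhecodeMap-class compact display
#' @param object A `PhecodeMap`.
#' @export
setMethod("show", "PhecodeMap", function(object) {
  cat("PhecodeMap:", nrow(object@mapping), "ICD-9 -> phecode mappings (",
      length(unique(object@mapping$phecode)), "phecodes ),",
      nrow(object@exclusions), "exclusion ranges\n")
})

#' PatientRecords: ordered per-admission concept sets
#'
#' One element per patient; each patient is an ordered list of admissions and
#' each admission a character vector of namespaced concept identifiers
#' (`phe:`, `rx:`, `lab:`, `sim:`). Within one admission a concept appears at
#' most once (binary presence). Admissions are ordered by admission time, ties
#' broken by admission identifier.
#'
#' @slot records named list; `records[[patient]]` is a list of character
#'   vectors, one per admission in chronological order.
#' @export
setClass("PatientRecords", slots = c(records = "list"))

setValidity("PatientRecords", function(object) {
  r <- object@records
  if (length(r) && (is.null(names(r)) || anyDuplicated(names(r))))
    return("records must be uniquely named by patient id")
  for (p in r) {
    if (!is.list(p)) return("each patient must be a list of admissions")
    for (adm in p) {
      if (!is.character(adm)) return("each admission must be a character vector")
      if (anyDuplicated(adm)) return("concepts must be unique within an admission")
    }
  }
  TRUE
})

#' @describeIn PatientRecords-class number of patients
#' @param x A `PatientRecords`.
#' @export
setMethod("length", "PatientRecords", function(x) length(x@records))

#' @describeIn PatientRecords-class subset to a set of patients
#' @param i Patient ids or indices.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "PatientRecords", function(x, i, j, ..., drop = FALSE) {
  new("PatientRecords", records = x@records[i])
})

#' @describeIn PatientRecords-class admissions of one patient
#' @export
setMethod("[[", "PatientRecords", function(x, i) x@records[[i]])

#' @describeIn PatientRecords-class compact display
#' @param object A `PatientRecords`.
#' @export
setMethod("show", "PatientRecords", function(object) {
  nadm <- vapply(object@records, length, integer(1))
  cat("PatientRecords:", length(object@records), "patients,",
      sum(nadm), "admissions,",
      length(unique(unlist(object@records, use.names = FALSE))),
      "distinct concepts\n")
})

#' Patient identifiers of a PatientRecords object
#' @param x A `PatientRecords`.
#' @return Character vector of patient ids.
#' @export
patientIds <- function(x) {
  stopifnot(is(x, "PatientRecords"))
  names(x@records)
}

#' ConceptEmbedding: vocabulary of concept vectors
#'
#' A `K x d` matrix of embedding vectors, one row per concept; row names are
#' the vocabulary. Lookup of an out-of-vocabulary concept is an explicit miss
#' (error in [conceptVector()], `FALSE` in [hasConcept()]), never a silent
#' zero vector.
#'
#' @slot vectors numeric matrix with unique, non-empty row names and all
#'   finite entries.
#' @slot counts integer vector of corpus frequencies, parallel to the rows.
#' @export
setClass("ConceptEmbedding", slots = c(vectors = "matrix", counts = "integer"))

setValidity("ConceptEmbedding", function(object) {
  v <- object@vectors
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("vectors must have unique row names (the vocabulary)")
  if (!all(is.finite(v))) return("all embedding entries must be finite")
  if (length(object@counts) && length(object@counts) != nrow(v))
    return("counts must be parallel to the vocabulary")
  TRUE
})

#' @describeIn ConceptEmbedding-class compact display
#' @param object A `ConceptEmbedding`.
#' @export
setMethod("show", "ConceptEmbedding", function(object) {
  cat("ConceptEmbedding:", nrow(object@vectors), "concepts x",
      ncol(object@vectors), "dimensions\n")
})

#' Vocabulary of an embedding model
#' @param model A `ConceptEmbedding`.
#' @return Character vector of concept identifiers.
#' @export
vocabulary <- function(model) {
  stopifnot(is(model, "ConceptEmbedding"))
  rownames(model@vectors)
}

#' Embedding dimension
#' @param model A `ConceptEmbedding`.
#' @return Integer dimension `d`.
#' @export
embeddingDim <- function(model) {
  stopifnot(is(model, "ConceptEmbedding"))
  ncol(model@vectors)
}

#' Is a concept in the vocabulary?
#' @param model A `ConceptEmbedding`.
#' @param concept Character vector of concept identifiers.
#' @return Logical vector.
#' @export
hasConcept <- function(model, concept) {
  stopifnot(is(model, "ConceptEmbedding"))
  concept %in% rownames(model@vectors)
}

#' Vector of one concept
#' @param model A `ConceptEmbedding`.
#' @param concept A single concept identifier.
#' @return Numeric vector of length `embeddingDim(model)`.
#' @export
conceptVector <- function(model, concept) {
  stopifnot(is(model, "ConceptEmbedding"), length(concept) == 1L)
  if (!hasConcept(model, concept))
    stop("concept not in vocabulary: ", concept)
  model@vectors[concept, ]
}

#' CohortLabels: incident-case / valid-control labels per phenotype
#'
#' Per (patient, phenotype) label produced by [labelCohort()]: an incident
#' case became a case of the phenotype at the latest visit having never been
#' one before (and has at least two visits); a valid control has at least two
#' visits, was never a case before the latest visit, and is a control (not
#' excluded) at the latest visit; everyone else is unlabeled and is still
#' usable for embedding. Prevalence is the incident-case fraction among
#' labeled subjects.
#'
#' @slot labels data.frame with columns `patient_id`, `phecode`, `status`
#'   (one of `"incident_case"`, `"valid_control"`, `"unlabeled"`).
#' @slot prevalence data.frame with columns `phecode`, `n_incident_cases`,
#'   `n_valid_controls`, `prevalence`.
#' @slot patients character vector: the full patient universe of the cohort.
#' @export
setClass("CohortLabels",
  slots = c(labels = "data.frame", prevalence = "data.frame",
            patients = "character"))

setValidity("CohortLabels", function(object) {
  l <- object@labels
  if (!all(c("patient_id", "phecode", "status") %in% names(l)))
    return("labels must have columns patient_id, phecode, status")
  ok <- c("incident_case", "valid_control", "unlabeled")
  if (nrow(l) > 0 && !all(l$status %in% ok))
    return("status must be incident_case, valid_control or unlabeled")
  p <- object@prevalence
  if (!all(c("phecode", "n_incident_cases", "n_valid_controls",
             "prevalence") %in% names(p)))
    return("prevalence table is malformed")
  if (nrow(p) > 0 && any(p$prevalence < 0 | p$prevalence > 1, na.rm = TRUE))
    return("prevalence must lie in [0, 1]")
  TRUE
})

#' @describeIn CohortLabels-class compact display
#' @param object A `CohortLabels`.
#' @export
setMethod("show", "CohortLabels", function(object) {
  l <- object@labels
  cat("CohortLabels:", length(unique(l$phecode)), "phenotypes,",
      length(object@patients), "patients;",
      sum(l$status == "incident_case"), "incident cases,",
      sum(l$status == "valid_control"), "valid controls\n")
})

#' Label table of a CohortLabels object
#' @param x A `CohortLabels`.
#' @return data.frame of per (patient, phenotype) labels.
#' @export
cohortLabelTable <- function(x) {
  stopifnot(is(x, "CohortLabels"))
  x@labels
}

#' Prevalence table of a CohortLabels object
#' @param x A `CohortLabels`.
#' @return data.frame with one row per phenotype.
#' @export
phenotypePrevalence <- function(x) {
  stopifnot(is(x, "CohortLabels"))
  x@prevalence
}
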
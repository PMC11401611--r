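#' Build per-patient admission-ordered concept sequences
#'
#' Joins the four input tables into one [PatientRecords-class] object. Each
#' admission's concept set is the union of the phecodes mapped from that
#' admission's ICD-9 diagnoses (namespaced `phe:`), the drugs prescribed
#' (`rx:`), and the lab tests performed (`lab:`); presence is binary within an
#' admission. Admissions are ordered by `admit_order` (a sortable time or
#' sequence column), ties broken by admission id.
#'
#' @param admissions data.frame with columns `patient_id`, `admission_id`,
#'   `admit_order`.
#' @param diagnoses data.frame with columns `admission_id`, `icd9`.
#' @param prescriptions Optional data.frame with columns `admission_id`,
#'   `drug`.
#' @param labs Optional data.frame with columns `admission_id`, `lab`.
#' @param map A [PhecodeMap-class] used to map diagnoses.
#' @return A [PatientRecords-class] object, with attribute `unmapped`: a
#'   data.frame (`icd9`, `count`) of diagnosis codes that had no phecode
#'   mapping.
#' @export
buildPatientRecords <- function(admissions, diagnoses, prescriptions = NULL,
                                labs = NULL, map) {
  needCols <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    if (length(missing))
      stop(what, " table is missing column(s): ",
           paste(missing, collapse = ", "))
  }
  needCols(admissions, c("patient_id", "admission_id", "admit_order"),
           "admissions")
  needCols(diagnoses, c("admission_id", "icd9"), "diagnoses")
  if (!is.null(prescriptions))
    needCols(prescriptions, c("admission_id", "drug"), "prescriptions")
  if (!is.null(labs)) needCols(labs, c("admission_id", "lab"), "labs")

  admissions$patient_id <- as.character(admissions$patient_id)
  admissions$admission_id <- as.character(admissions$admission_id)
  known <- admissions$admission_id
  checkRefs <- function(df, what) {
    if (is.null(df)) return(invisible())
    bad <- setdiff(unique(as.character(df$admission_id)), known)
    if (length(bad))
      stop(what, " table references unknown admission id(s): ",
           paste(head(bad, 10), collapse = ", "))
  }
  checkRefs(diagnoses, "diagnoses")
  checkRefs(prescriptions, "prescriptions")
  checkRefs(labs, "labs")

  ord <- order(admissions$patient_id, admissions$admit_order,
               admissions$admission_id)
  admissions <- admissions[ord, ]

  perAdm <- function(df, col, ns) {
    if (is.null(df) || nrow(df) == 0) return(list())
    split(paste0(ns, ":", trimws(as.character(df[[col]]))),
          as.character(df$admission_id))
  }
  rxByAdm <- perAdm(prescriptions, "drug", "rx")
  labByAdm <- perAdm(labs, "lab", "lab")
  dxByAdm <- if (nrow(diagnoses) > 0)
    split(trimws(as.character(diagnoses$icd9)),
          as.character(diagnoses$admission_id)) else list()

  unmapped <- list()
  records <- list()
  for (pid in unique(admissions$patient_id)) {
    adms <- admissions$admission_id[admissions$patient_id == pid]
    patient <- vector("list", length(adms))
    for (i in seq_along(adms)) {
      aid <- adms[i]
      concepts <- character()
      dx <- dxByAdm[[aid]]
      if (!is.null(dx)) {
        phe <- mapIcdToPhecodes(dx, map)
        if (length(attr(phe, "unmapped")))
          unmapped[[length(unmapped) + 1L]] <- attr(phe, "unmapped")
        if (length(phe)) concepts <- c(concepts, paste0("phe:", phe))
      }
      concepts <- c(concepts, rxByAdm[[aid]], labByAdm[[aid]])
      patient[[i]] <- sort(unique(concepts))
    }
    records[[pid]] <- patient
  }
  out <- new("PatientRecords", records = records)
  attr(out, "unmapped") <- unmappedReport(unmapped)
  out
}

#' Remove concepts appearing in few admissions
#'
#' Concepts observed in fewer than `minAdmissions` distinct admissions across
#' the whole cohort are removed from every admission (they are too rare to
#' receive stable embedding vectors). Counting happens once over the full
#' input cohort, before any removal, so the operation is idempotent on its
#' own output. The boundary is strict: a concept in exactly `minAdmissions`
#' admissions is kept.
#'
#' @param records A [PatientRecords-class].
#' @param minAdmissions Minimum number of distinct admissions (default 50).
#' @return A list with elements `records` (filtered [PatientRecords-class])
#'   and `removed` (character vector of removed concepts).
#' @export
filterRareConcepts <- function(records, minAdmissions = 50L) {
  stopifnot(is(records, "PatientRecords"), minAdmissions >= 1)
  counts <- table(unlist(records@records, use.names = FALSE))
  removed <- names(counts)[counts < minAdmissions]
  if (length(removed)) {
    rec <- lapply(records@records, function(p)
      lapply(p, function(adm) setdiff(adm, removed)))
    records <- new("PatientRecords", records = rec)
  }
  list(records = records, removed = sort(removed))
}

# per-admission phecode sets of one patient (bare phecodes, no namespace)
admissionPhecodes <- function(patient) {
  lapply(patient, function(adm) conceptBody(adm[startsWith(adm, "phe:")]))
}

#' Label incident cases and valid controls at the latest visit
#'
#' For each phenotype and each patient with at least two admissions, assigns
#' per-visit case/control/excluded status with [assignStatus()] and derives:
#' *incident case* — case at the latest visit and never a case at any earlier
#' visit; *valid control* — never a case at any earlier visit and a control
#' (not excluded) at the latest visit. All other patients — including
#' single-visit patients and patients excluded at the latest visit — are
#' *unlabeled*; they contribute no labels but remain usable for embedding.
#' Phenotype prevalence is the incident-case fraction among labeled subjects.
#'
#' @param records A [PatientRecords-class] (already rare-concept filtered).
#' @param phenotypes Character vector of target phecodes.
#' @param map A [PhecodeMap-class].
#' @return A [CohortLabels-class] object.
#' @export
labelCohort <- function(records, phenotypes, map) {
  stopifnot(is(records, "PatientRecords"), is(map, "PhecodeMap"))
  if (length(phenotypes) == 0) stop("phenotype list is empty")
  phenotypes <- unique(as.character(phenotypes))
  pids <- patientIds(records)
  pheSets <- lapply(records@records, admissionPhecodes)

  rows <- vector("list", length(phenotypes))
  prev <- data.frame(phecode = phenotypes, n_incident_cases = 0L,
                     n_valid_controls = 0L, prevalence = NA_real_)
  for (j in seq_along(phenotypes)) {
    ph <- phenotypes[j]
    status <- vapply(pids, function(pid) {
      adm <- pheSets[[pid]]
      n <- length(adm)
      if (n < 2) return("unlabeled")
      st <- vapply(adm, assignStatus, character(1), target = ph, map = map)
      caseEarlier <- any(st[-n] == "case")
      if (st[n] == "case") {
        if (!caseEarlier) "incident_case" else "unlabeled"
      } else if (st[n] == "control" && !caseEarlier) {
        "valid_control"
      } else {
        "unlabeled"
      }
    }, character(1))
    nc <- sum(status == "incident_case")
    nv <- sum(status == "valid_control")
    prev$n_incident_cases[j] <- nc
    prev$n_valid_controls[j] <- nv
    prev$prevalence[j] <- if (nc + nv > 0) nc / (nc + nv) else NA_real_
    rows[[j]] <- data.frame(patient_id = pids, phecode = ph, status = status,
                            row.names = NULL)
  }
  new("CohortLabels", labels = do.call(rbind, rows), prevalence = prev,
      patients = pids)
}

#' Keep phenotypes prevalent enough to evaluate
#'
#' Drops phenotypes with prevalence below `minPrevalence` (strictly; a
#' phenotype exactly at the threshold is kept) or with no incident case.
#'
#' @param labels A [CohortLabels-class].
#' @param minPrevalence Minimum prevalence (default 0.0005, i.e. 0.05%).
#' @return Character vector of retained phecodes.
#' @export
filterPhenotypes <- function(labels, minPrevalence = 0.0005) {
  stopifnot(is(labels, "CohortLabels"))
  p <- labels@prevalence
  keep <- !is.na(p$prevalence) & p$prevalence >= minPrevalence &
    p$n_incident_cases >= 1
  p$phecode[keep]
}

#' Repeated stratified train/test splits of labeled subjects
#'
#' For each repeat and phenotype, splits the labeled subjects (incident cases
#' and valid controls) 50/50, stratified by case status so that rare
#' phenotypes keep cases on both sides; with an odd stratum the extra subject
#' goes to the training side. Every unlabeled patient is always in the
#' training set (they feed the embedding corpus). Splits are reproducible:
#' repeat `r` uses the seed sub-stream `("split", r)` of the master seed.
#'
#' @param labels A [CohortLabels-class].
#' @param nRepeats Number of repeated splits (default 10).
#' @param seed Master seed.
#' @param phenotypes Optional subset of phecodes to split (default: all in
#'   `labels`). Phenotypes with fewer than 2 incident cases are skipped with
#'   a warning.
#' @return A list of split plans; each is a list with `repeatIndex` and
#'   `phenotypes`, a named list of `list(train = ids, test = ids)` where
#'   `train` includes the unlabeled patients.
#' @export
makeSplits <- function(labels, nRepeats = 10L, seed = 1L,
                       phenotypes = NULL) {
  stopifnot(is(labels, "CohortLabels"), nRepeats >= 1)
  lt <- labels@labels
  if (is.null(phenotypes)) phenotypes <- unique(lt$phecode)
  phenotypes <- sort(phenotypes)
  plans <- vector("list", nRepeats)
  for (r in seq_len(nRepeats)) {
    set.seed(substreamSeed(seed, "split", r))
    perPhe <- list()
    for (ph in phenotypes) {
      sub <- lt[lt$phecode == ph, ]
      cases <- sub$patient_id[sub$status == "incident_case"]
      controls <- sub$patient_id[sub$status == "valid_control"]
      unlabeled <- setdiff(labels@patients, c(cases, controls))
      if (length(cases) < 2) {
        warning("phenotype ", ph, " has fewer than 2 incident cases; ",
                "skipped in split ", r)
        next
      }
      half <- function(x) sample(x, length(x) %/% 2)
      testCases <- half(cases)
      testControls <- half(controls)
      perPhe[[ph]] <- list(
        train = c(unlabeled, setdiff(cases, testCases),
                  setdiff(controls, testControls)),
        test = c(testCases, testControls)
      )
    }
    plans[[r]] <- list(repeatIndex = r, phenotypes = perPhe)
  }
  plans
}
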
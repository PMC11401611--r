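test_that("patient records join domains, namespace and deduplicate concepts", {
  rec <- toyRecords()
  expect_s4_class(rec, "PatientRecords")
  expect_length(rec, 6)
  # A: adm1 = mapped phecode + deduplicated drug, adm2 = phecode + lab
  expect_setequal(rec[["A"]][[1]], c("phe:008", "rx:warfarin"))
  expect_setequal(rec[["A"]][[2]], c("phe:427.2", "lab:K50090"))
  # duplicate warfarin rows collapse to one occurrence
  expect_equal(sum(rec[["A"]][[1]] == "rx:warfarin"), 1)
  # admission with no concept rows stays present (ordering intact)
  expect_length(rec[["C"]], 1)

  # unknown admission id in a domain table -> error naming it
  tb <- toyCohortTables()
  tb$diagnoses$admission_id[1] <- "zzz"
  expect_error(
    buildPatientRecords(tb$admissions, tb$diagnoses, map = toyMap()),
    "zzz")

  # missing column -> error naming it
  expect_error(
    buildPatientRecords(tb$admissions[, 1:2], tb$diagnoses, map = toyMap()),
    "admit_order")
})

test_that("admissions are ordered by time with id tie-break", {
  map <- toyMap()
  adm <- data.frame(patient_id = "P",
                    admission_id = c("a9", "a2", "a1"),
                    admit_order = c(2, 1, 1))
  dx <- data.frame(admission_id = c("a9", "a2", "a1"),
                   icd9 = c("427.31", "001.0", "585.9"))
  rec <- buildPatientRecords(adm, dx, map = map)
  expect_equal(unlist(rec[["P"]]),
               c("phe:585.3", "phe:008", "phe:427.2"))
})

test_that("rare-concept filter uses strict admission-count threshold", {
  rec <- toyRecords()
  # phe:008 appears in admissions a1,d1,d2,e1,f2 = 5; phe:427.2 in a2,b1,b2,c1,f1 = 5
  # rx:warfarin 1, rx:insulin 1, lab:K50090 1, phe:427.5 1
  out <- filterRareConcepts(rec, minAdmissions = 5)
  expect_setequal(out$removed,
                  c("rx:warfarin", "rx:insulin", "lab:K50090", "phe:427.5"))
  expect_setequal(unique(unlist(out$records@records)),
                  c("phe:008", "phe:427.2"))

  # boundary: a concept in exactly minAdmissions admissions is kept
  out2 <- filterRareConcepts(rec, minAdmissions = 1)
  expect_length(out2$removed, 0)
  expect_identical(out2$records@records, rec@records)

  # idempotence on own output
  again <- filterRareConcepts(out$records, minAdmissions = 5)
  expect_length(again$removed, 0)
  expect_identical(again$records@records, out$records@records)
})

test_that("incident cases and valid controls follow the three visit rules", {
  labels <- labelCohort(toyRecords(), "427.2", toyMap())
  lt <- cohortLabelTable(labels)
  st <- setNames(lt$status, lt$patient_id)
  expect_equal(st[["A"]], "incident_case")   # control then case
  expect_equal(st[["B"]], "unlabeled")       # case at a prior visit
  expect_equal(st[["C"]], "unlabeled")       # single visit
  expect_equal(st[["D"]], "valid_control")   # control throughout
  expect_equal(st[["E"]], "unlabeled")       # excluded at latest visit
  expect_equal(st[["F"]], "unlabeled")       # prior case, control at latest

  prev <- phenotypePrevalence(labels)
  expect_equal(prev$n_incident_cases, 1L)
  expect_equal(prev$n_valid_controls, 1L)
  expect_equal(prev$prevalence, 0.5)

  expect_error(labelCohort(toyRecords(), character(), toyMap()), "empty")
})

test_that("label statuses partition every (patient, phenotype) pair", {
  labels <- labelCohort(toyRecords(), c("427.2", "008", "250.2"), toyMap())
  lt <- cohortLabelTable(labels)
  expect_equal(nrow(lt), 6 * 3)
  expect_true(all(table(lt$patient_id, lt$phecode) == 1))
  expect_true(all(lt$status %in%
    c("incident_case", "valid_control", "unlabeled")))
})

test_that("phenotype prevalence filter is strict below threshold", {
  prev <- data.frame(phecode = c("a", "b", "c", "d"),
                     n_incident_cases = c(2L, 1L, 0L, 3L),
                     n_valid_controls = c(3998L, 1999L, 100L, 4997L),
                     prevalence = c(0.0005, 0.0005, 0, 0.0006))
  prev$prevalence[3] <- NA
  labels <- new("CohortLabels",
                labels = data.frame(patient_id = "p", phecode = "a",
                                    status = "unlabeled"),
                prevalence = prev, patients = "p")
  expect_setequal(filterPhenotypes(labels, 0.0005), c("a", "b", "d"))
  expect_setequal(filterPhenotypes(labels, 0.00051), "d")
})

test_that("splits are stratified 50/50, reproducible, unlabeled in train", {
  # 10 cases + 190 controls + 100 unlabeled
  pats <- sprintf("p%03d", 1:300)
  status <- c(rep("incident_case", 10), rep("valid_control", 190),
              rep("unlabeled", 100))
  labels <- new("CohortLabels",
                labels = data.frame(patient_id = pats, phecode = "x",
                                    status = status),
                prevalence = data.frame(phecode = "x",
                                        n_incident_cases = 10L,
                                        n_valid_controls = 190L,
                                        prevalence = 0.05),
                patients = pats)
  sp <- makeSplits(labels, nRepeats = 2, seed = 99)
  s1 <- sp[[1]]$phenotypes$x
  cases <- pats[1:10]; controls <- pats[11:200]; unlab <- pats[201:300]
  expect_length(intersect(s1$train, s1$test), 0)
  expect_true(all(unlab %in% s1$train))
  expect_equal(sum(s1$test %in% cases), 5)
  expect_equal(sum(s1$test %in% controls), 95)
  expect_equal(sum(s1$train %in% cases), 5)

  # determinism and repeat-index variation
  sp2 <- makeSplits(labels, nRepeats = 2, seed = 99)
  expect_identical(sp, sp2)
  expect_false(setequal(sp[[1]]$phenotypes$x$test,
                        sp[[2]]$phenotypes$x$test))

  # prevalence preserved within each side up to one subject
  prevTrain <- sum(s1$train %in% cases) /
    (sum(s1$train %in% cases) + sum(s1$train %in% controls))
  expect_equal(prevTrain, 0.05, tolerance = 0.01)

  # a phenotype with <2 incident cases is skipped with a warning
  labels2 <- labels
  labels2@labels$status[2:10] <- "unlabeled"
  expect_warning(sp3 <- makeSplits(labels2, nRepeats = 1, seed = 1),
                 "fewer than 2")
  expect_length(sp3[[1]]$phenotypes, 0)
})
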
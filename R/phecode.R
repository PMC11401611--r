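#' Load a phecode map from CSV
#'
#' Reads a flat-file dialect of the PheWAS phecode map: columns `icd9`,
#' `phecode`, and optionally `exclude_range_lo`, `exclude_range_hi`. Rows with
#' a non-empty `icd9` define ICD-9 -> phecode mappings; rows with non-missing
#' range bounds attach an inclusive exclusion range to their `phecode` (one
#' row may do both). Duplicated (icd9, phecode) pairs are dropped with a
#' warning.
#'
#' @param path Path to the CSV file.
#' @param stripDots If `TRUE`, decimal points are removed from ICD-9 codes at
#'   load time, so that undotted codes (as stored in MIMIC-style exports)
#'   match dotted map files. Queries through [mapIcdToPhecodes()] are
#'   normalised the same way. Default `FALSE` (codes compared as-is, trimmed).
#' @return A [PhecodeMap-class] object.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("icd9,phecode,exclude_range_lo,exclude_range_hi",
#'              "001.0,008,,", "427.31,427.2,427,427.99", "427.9,427.5,,"),
#'            tf)
#' loadPhecodeMap(tf)
#' @export
loadPhecodeMap <- function(path, stripDots = FALSE) {
  if (!file.exists(path)) stop("phecode map file not found: ", path)
  raw <- tryCatch(
    read.csv(path, colClasses = "character", strip.white = TRUE),
    error = function(e) stop("failed to parse phecode map: ",
                             conditionMessage(e))
  )
  if (nrow(raw) == 0) stop("phecode map is empty: ", path)
  if (!all(c("icd9", "phecode") %in% names(raw)))
    stop("phecode map must have columns 'icd9' and 'phecode'; found: ",
         paste(names(raw), collapse = ", "))
  raw$icd9 <- trimws(raw$icd9)
  raw$phecode <- trimws(raw$phecode)
  bad <- which(!nzchar(raw$phecode))
  if (length(bad))
    stop("malformed phecode map rows (missing phecode) at line(s): ",
         paste(bad + 1L, collapse = ", "))
  if (stripDots) raw$icd9 <- gsub(".", "", raw$icd9, fixed = TRUE)

  mapRows <- raw[nzchar(raw$icd9), c("icd9", "phecode")]
  dup <- duplicated(paste(mapRows$icd9, mapRows$phecode, sep = "\r"))
  if (any(dup)) {
    warning(sum(dup), " duplicated (icd9, phecode) mapping row(s) dropped")
    mapRows <- mapRows[!dup, ]
  }
  rownames(mapRows) <- NULL

  excl <- data.frame(phecode = character(), lo = numeric(), hi = numeric())
  if (all(c("exclude_range_lo", "exclude_range_hi") %in% names(raw))) {
    has <- nzchar(raw$exclude_range_lo) | nzchar(raw$exclude_range_hi)
    if (any(has)) {
      lo <- suppressWarnings(as.numeric(raw$exclude_range_lo[has]))
      hi <- suppressWarnings(as.numeric(raw$exclude_range_hi[has]))
      badr <- which(is.na(lo) | is.na(hi))
      if (length(badr))
        stop("malformed exclusion range at line(s): ",
             paste(which(has)[badr] + 1L, collapse = ", "))
      excl <- unique(data.frame(phecode = raw$phecode[has], lo = lo, hi = hi))
      rownames(excl) <- NULL
      if (any(excl$lo > excl$hi))
        stop("exclusion range with lower bound above upper bound for phecode(s): ",
             paste(excl$phecode[excl$lo > excl$hi], collapse = ", "))
    }
  }
  new("PhecodeMap", mapping = mapRows, exclusions = excl,
      stripDots = stripDots)
}

#' All phecodes known to a map
#' @param map A [PhecodeMap-class].
#' @return Sorted character vector of phecodes.
#' @export
phecodeUniverse <- function(map) {
  stopifnot(is(map, "PhecodeMap"))
  sort(unique(c(map@mapping$phecode, map@exclusions$phecode)))
}

#' Map ICD-9 codes to phecodes
#'
#' Returns the union of phecodes mapped to by any of the input codes. Codes
#' absent from the map are not an error; they are reported via the
#' `"unmapped"` attribute so callers can aggregate an unmapped-code report.
#'
#' @param codes Character vector of ICD-9 codes (a set; duplicates ignored).
#' @param map A [PhecodeMap-class].
#' @return Character vector of phecodes (sorted, unique), with attribute
#'   `unmapped`: the input codes that had no mapping.
#' @export
mapIcdToPhecodes <- function(codes, map) {
  stopifnot(is(map, "PhecodeMap"))
  codes <- unique(trimws(as.character(codes)))
  codes <- codes[nzchar(codes)]
  if (map@stripDots) codes <- gsub(".", "", codes, fixed = TRUE)
  if (length(codes) == 0) {
    out <- character()
    attr(out, "unmapped") <- character()
    return(out)
  }
  hit <- map@mapping$icd9 %in% codes
  out <- sort(unique(map@mapping$phecode[hit]))
  attr(out, "unmapped") <- setdiff(codes, map@mapping$icd9)
  out
}

#' Case/control/excluded status for one phenotype
#'
#' Implements PheWAS-style control cleaning: a patient is a *case* for the
#' target phenotype if their phecodes contain the target; otherwise, if any of
#' their phecodes falls inside one of the target's exclusion ranges, they are
#' *excluded* (a patient with a related but distinct condition cannot serve as
#' a control — e.g. an unspecified arrhythmia disqualifies a patient as an
#' atrial-fibrillation control); otherwise they are a *control*. Case status
#' dominates: carrying the target phecode makes a case even though the target
#' typically lies inside its own exclusion range.
#'
#' @param patientPhecodes Character vector: the patient's phecodes (a set).
#' @param target A single phecode present in the map's phecode universe.
#' @param map A [PhecodeMap-class].
#' @return One of `"case"`, `"control"`, `"excluded"`.
#' @export
assignStatus <- function(patientPhecodes, target, map) {
  stopifnot(is(map, "PhecodeMap"), length(target) == 1L)
  if (!target %in% phecodeUniverse(map))
    stop("unknown target phecode: ", target)
  patientPhecodes <- unique(as.character(patientPhecodes))
  if (target %in% patientPhecodes) return("case")
  ranges <- map@exclusions[map@exclusions$phecode == target, , drop = FALSE]
  if (nrow(ranges) > 0 && length(patientPhecodes) > 0) {
    vals <- suppressWarnings(as.numeric(patientPhecodes))
    vals <- vals[!is.na(vals)]
    for (i in seq_len(nrow(ranges))) {
      if (any(vals >= ranges$lo[i] & vals <= ranges$hi[i]))
        return("excluded")
    }
  }
  "control"
}

#' Aggregate an unmapped ICD-9 code report
#'
#' @param unmappedList List of character vectors of unmapped codes (e.g. one
#'   per admission).
#' @return data.frame with columns `icd9`, `count`, sorted by decreasing
#'   count.
#' @export
unmappedReport <- function(unmappedList) {
  codes <- unlist(unmappedList, use.names = FALSE)
  if (length(codes) == 0)
    return(data.frame(icd9 = character(), count = integer()))
  tab <- sort(table(codes), decreasing = TRUE)
  data.frame(icd9 = names(tab), count = as.integer(tab),
             row.names = NULL)
}
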
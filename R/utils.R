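#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one master seed. Named sub-streams
#' (splitting, shuffling, embedding initialisation, simulation) derive their
#' own seeds deterministically from the master seed, a stream label, and an
#' index, so that repeats are independent yet reproducible and adding a new
#' stream never perturbs an existing one.
#'
#' @param seed Master seed (integer).
#' @param stream Character label of the sub-stream, e.g. `"split"`.
#' @param index Nonnegative integer index within the stream (e.g. repeat
#'   number).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @examples
#' substreamSeed(42L, "split", 3L)
#' @export
substreamSeed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  ch <- utf8ToInt(stream)
  h <- sum(ch * seq_along(ch))
  m <- 2147483647
  v <- (abs(as.numeric(seed)) %% m) * 48271 + h * 9973 + as.numeric(index) * 7919
  as.integer(v %% (m - 2)) + 1L
}

# split "phe:427.2" -> prefix/body helpers
conceptNamespace <- function(x) sub(":.*$", "", x)

conceptBody <- function(x) sub("^[^:]*:", "", x)

#' Build the concept identifier of a phenotype
#'
#' Phecodes enter the embedding vocabulary namespaced as `"phe:<code>"`; this
#' helper converts a bare phecode to its concept identifier.
#'
#' @param phecode Character vector of phecodes.
#' @return Character vector of namespaced concept identifiers.
#' @examples
#' phenotypeConcept("427.2")
#' @export
phenotypeConcept <- function(phecode) paste0("phe:", phecode)
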
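#' Build the embedding corpus from patient records
#'
#' One sentence per patient: admissions are concatenated in chronological
#' order and concepts are randomly permuted *within* each admission (concept
#' order inside one admission carries no information, so shuffling prevents
#' the trainer from learning spurious within-admission order effects).
#' Patients whose record is empty after filtering yield no sentence; their
#' number is reported via the `"dropped"` attribute.
#'
#' @param records A [PatientRecords-class].
#' @param shuffleSeed Seed for the within-admission permutations.
#' @return A named list of character vectors (one sentence per patient), with
#'   attribute `dropped`: the number of empty records skipped.
#' @export
buildCorpus <- function(records, shuffleSeed = 1L) {
  stopifnot(is(records, "PatientRecords"))
  set.seed(shuffleSeed)
  sentences <- lapply(records@records, function(p) {
    unlist(lapply(p, function(adm) {
      if (length(adm) <= 1) adm else sample(adm)
    }), use.names = FALSE)
  })
  empty <- vapply(sentences, function(s) length(s) == 0, logical(1))
  out <- sentences[!empty]
  attr(out, "dropped") <- sum(empty)
  out
}

#' Train skip-gram concept embeddings
#'
#' Trains skip-gram word2vec embeddings with negative sampling on a corpus of
#' patient sentences, using the package's deterministic single-threaded
#' trainer: one seed yields byte-identical vectors across runs. The default
#' window of 500 makes every concept in a typical patient sentence context
#' for every other (per-admission concept sets are far smaller than that), so
#' co-occurrence within and across admissions drives the geometry.
#'
#' @param corpus List of character vectors (sentences), e.g. from
#'   [buildCorpus()].
#' @param d Embedding dimension (default 100).
#' @param window Maximum context window (default 500).
#' @param minCount Minimum corpus frequency for a token to enter the
#'   vocabulary (default 1; rare-concept removal normally happens upstream).
#' @param epochs Training epochs (default 10).
#' @param negative Number of negative samples per context pair (default 5).
#' @param alpha,minAlpha Initial and floor learning rates.
#' @param sample Frequent-word subsampling threshold (default `1e-3`): a
#'   token with corpus frequency `f > sample` is kept at each position with
#'   probability `(sqrt(f/sample) + 1) * sample / f`. Subsampling keeps very
#'   frequent concepts from dominating every context and collapsing the
#'   embedding geometry onto one direction; set 0 to disable.
#' @param center Subtract the vocabulary mean vector after training (default
#'   `TRUE`). Skip-gram vectors trained on small corpora share a large
#'   common component that inflates every pairwise cosine toward 1;
#'   removing the mean (the first step of standard embedding
#'   post-processing) restores contrast so that unrelated concepts sit near
#'   cosine 0.
#' @param seed Seed for vector initialisation, window shrinking and negative
#'   draws.
#' @return A [ConceptEmbedding-class].
#' @export
trainEmbeddings <- function(corpus, d = 100L, window = 500L, minCount = 1L,
                            epochs = 10L, negative = 5L, alpha = 0.025,
                            minAlpha = 1e-4, sample = 1e-3, center = TRUE,
                            seed = 1L) {
  if (length(corpus) == 0) stop("corpus is empty")
  stopifnot(d >= 2, window >= 1, epochs >= 1)
  tokens <- unlist(corpus, use.names = FALSE)
  if (length(tokens) == 0) stop("corpus is empty")
  counts <- table(tokens)
  counts <- counts[counts >= minCount]
  if (length(counts) == 0) stop("no token reaches minCount")
  # frequency-descending vocabulary, ties broken lexicographically
  ordv <- order(-as.integer(counts), names(counts))
  vocab <- names(counts)[ordv]
  vcount <- as.integer(counts)[ordv]
  idx <- stats::setNames(seq_along(vocab) - 1L, vocab)
  coded <- lapply(corpus, function(s) {
    s <- s[s %in% vocab]
    unname(idx[s])
  })
  coded <- coded[vapply(coded, length, integer(1)) > 0]
  if (length(coded) == 0) stop("corpus is empty after vocabulary filtering")
  vec <- .sgnsTrain(coded, vcount, as.integer(d), as.integer(window),
                    as.integer(negative), as.integer(epochs), alpha,
                    minAlpha, sample, as.numeric(seed))
  if (center) vec <- sweep(vec, 2, colMeans(vec))
  rownames(vec) <- vocab
  new("ConceptEmbedding", vectors = vec, counts = vcount)
}

#' Cosine similarity of two vectors
#'
#' Returns `u . v / (||u|| ||v||)`, the standard similarity used throughout
#' the package. A zero-norm operand yields 0 by definition — the uninformative
#' midpoint — so degenerate (flagged all-zero) patient vectors score 0 rather
#' than propagate NaN.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @examples
#' cosineSim(c(1, 0), c(0, 1))
#' @export
cosineSim <- function(u, v) {
  if (length(u) != length(v))
    stop("dimension mismatch: ", length(u), " vs ", length(v))
  nu <- sqrt(sum(u * u))
  nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) return(0)
  s <- sum(u * v) / (nu * nv)
  max(-1, min(1, s))
}

#' Phenotype-by-concept cosine correlation matrix
#'
#' Computes the dense `J x K` matrix whose (j, k) entry is the cosine
#' similarity between phenotype j's embedding vector and concept k's. The row
#' for a phenotype at its own concept column equals 1.
#'
#' @param model A [ConceptEmbedding-class].
#' @param phenotypes Character vector of phenotype concept identifiers (e.g.
#'   `"phe:427.2"`); those absent from the vocabulary are dropped with a
#'   warning, and an error is raised if none remain.
#' @return Numeric matrix with rownames = phenotype concepts, colnames = the
#'   full vocabulary.
#' @export
correlationMatrix <- function(model, phenotypes) {
  stopifnot(is(model, "ConceptEmbedding"))
  phenotypes <- unique(as.character(phenotypes))
  miss <- phenotypes[!hasConcept(model, phenotypes)]
  if (length(miss)) {
    warning("phenotype concept(s) not in vocabulary, dropped: ",
            paste(head(miss, 10), collapse = ", "))
    phenotypes <- setdiff(phenotypes, miss)
  }
  if (length(phenotypes) == 0)
    stop("no phenotype concept is in the embedding vocabulary")
  V <- model@vectors
  norms <- sqrt(rowSums(V * V))
  Vn <- V / ifelse(norms == 0, 1, norms)
  Vn[norms == 0, ] <- 0
  P <- Vn[phenotypes, , drop = FALSE]
  out <- P %*% t(Vn)
  out[out > 1] <- 1
  out[out < -1] <- -1
  rownames(out) <- phenotypes
  out
}

#' Write embeddings in word2vec text format
#'
#' Standard interchange format: a header line `"K d"` followed by one line
#' per token (`token v1 ... vd`).
#'
#' @param model A [ConceptEmbedding-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeWord2vec <- function(model, path) {
  stopifnot(is(model, "ConceptEmbedding"))
  V <- model@vectors
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(V), ncol(V)), con)
  for (i in seq_len(nrow(V)))
    writeLines(paste(rownames(V)[i],
                     paste(format(V[i, ], digits = 17, scientific = TRUE,
                                  trim = TRUE), collapse = " ")), con)
  invisible(path)
}

#' Read embeddings from word2vec text format
#'
#' @param path Path to a file written in the `"K d"` header text format.
#' @return A [ConceptEmbedding-class].
#' @export
readWord2vec <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("not a word2vec text file: ", path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || any(is.na(hdr)))
    stop("malformed word2vec header: ", lines[1])
  K <- hdr[1]; d <- hdr[2]
  if (length(lines) < K + 1) stop("word2vec file truncated")
  toks <- character(K)
  V <- matrix(0, K, d)
  for (i in seq_len(K)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(parts) != d + 1) stop("malformed vector line ", i + 1)
    toks[i] <- parts[1]
    V[i, ] <- as.numeric(parts[-1])
  }
  rownames(V) <- toks
  new("ConceptEmbedding", vectors = V, counts = integer())
}
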
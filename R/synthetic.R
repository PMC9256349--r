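#' @include AllClasses.R repio.R features.R
NULL

#' Parameters of the synthetic two-class residue-representation generator
#'
#' The defaults are the study conditions the pipeline is validated under:
#' 200 proteins per class, lengths uniform on 50-100 (the length filter keeps
#' chains of at least 50 residues), a d = 50 representation with 5
#' class-informative dimensions, a raw-score shift of 3 noise standard
#' deviations for positives, and unit noise.
#'
#' @param nPos,nNeg class sizes (positives = DNA-binding analogue).
#' @param lengthRange inclusive protein-length range.
#' @param d representation dimension.
#' @param informativeDims number of class-informative dimensions m <= d.
#' @param effectSize raw-score mean shift delta added to every entry of the
#'   informative dimensions in positive proteins.
#' @param noiseSd raw-score noise standard deviation sigma.
#' @param seed RNG seed.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nPos = 200L, nNeg = 200L, lengthRange = c(50L, 100L),
                          d = 50L, informativeDims = 5L, effectSize = 3,
                          noiseSd = 1, seed = 1L) {
  new("SyntheticSpec", nPos = as.integer(nPos), nNeg = as.integer(nNeg),
      lengthRange = as.integer(lengthRange), d = as.integer(d),
      informativeDims = as.integer(informativeDims),
      effectSize = as.numeric(effectSize), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

#' Generate a labelled synthetic dataset of residue matrices
#'
#' Raw matrix entries are Normal(0, sigma^2); positive-class proteins get
#' `effectSize` added to every entry of the informative dimensions, planted
#' in raw-score space so sigmoid normalization is exercised downstream.
#' Sequences are drawn uniformly over the 20 standard letters, independent
#' of the matrices, so the per-amino-acid-type operators act as a randomized
#' partition. Deterministic under the spec seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with `records` (an `AAStringSet`), `matrices` (list of raw
#'   [ResidueMatrix-class]), `labels` (1 for the first `nPos`), and
#'   `informative` (the planted dimension indices, sorted).
#' @export
generateDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nPos + spec@nNeg
  labels <- c(rep(1L, spec@nPos), rep(0L, spec@nNeg))
  informative <- sort(sample.int(spec@d, spec@informativeDims))
  ids <- sprintf("prot%04d", seq_len(n))
  seqs <- character(n)
  matrices <- vector("list", n)
  for (i in seq_len(n)) {
    L <- sample(seq.int(spec@lengthRange[1], spec@lengthRange[2]), 1L)
    seqs[i] <- paste(sample(.PSSM_ALPHABET, L, replace = TRUE), collapse = "")
    m <- matrix(stats::rnorm(L * spec@d, 0, spec@noiseSd), L, spec@d)
    if (labels[i] == 1L && length(informative))
      m[, informative] <- m[, informative] + spec@effectSize
    matrices[[i]] <- ResidueMatrix(m, ids[i], "embedding")
  }
  records <- Biostrings::AAStringSet(seqs)
  names(records) <- ids
  list(records = records, matrices = matrices, labels = labels,
       informative = informative)
}

#' Assemble a synthetic dataset into a labelled FeatureTable
#'
#' Convenience wrapper: sigmoid-normalizes the raw matrices and builds the
#' table for the given feature-set specification (full 29d set by default).
#'
#' @param ds result of [generateDataset()].
#' @param spec a [FeatureSetSpec-class] or NULL for the full set.
#' @return A [FeatureTable-class].
#' @export
datasetToTable <- function(ds, spec = NULL) {
  normed <- lapply(ds$matrices, sigmoidNormalize)
  buildFeatureTable(normed, ds$records, ds$labels, spec = spec)
}

#' Write a PSI-BLAST-style ASCII PSSM fixture
#'
#' Emits the `-out_ascii_pssm` layout (two header lines; one row per
#' residue: index, letter, 20 log-odds integers, 20 percentage columns,
#' two trailing floats) that [readPssmAscii()] consumes, round-tripping the
#' score matrix exactly.
#'
#' @param record the protein sequence (string, `AAString` or single-record
#'   `AAStringSet`).
#' @param rawScores integer L x 20 matrix with entries in [-15, 15].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePssmFixture <- function(record, rawScores, path) {
  rec <- .asSequence(record)
  L <- nchar(rec$sequence)
  rawScores <- as.matrix(rawScores)
  if (nrow(rawScores) != L || ncol(rawScores) != 20L)
    stop("score matrix must be ", L, " x 20, got ",
         nrow(rawScores), " x ", ncol(rawScores))
  if (any(rawScores != round(rawScores)) ||
      any(rawScores < -15) || any(rawScores > 15))
    stop("scores must be integers in [-15, 15]")
  letters <- strsplit(rec$sequence, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weight ratio 1.0",
    paste0("            ", paste(sprintf("%3s", .PSSM_ALPHABET), collapse = ""),
           "   ", paste(sprintf("%3s", .PSSM_ALPHABET), collapse = ""))), con)
  for (i in seq_len(L)) {
    writeLines(sprintf("%5d %s %s  %s  %5.2f %5.2f",
                       i, letters[i],
                       paste(sprintf("%3d", rawScores[i, ]), collapse = " "),
                       paste(sprintf("%3d", rep(0L, 20L)), collapse = " "),
                       0, 0), con)
  }
  writeLines(c("", "                      K         Lambda"), con)
  invisible(path)
}

#' Write a dataset to files (FASTA + per-protein matrices + labels TSV)
#'
#' Emits the exact input contract of the pipeline: `sequences.fasta`,
#' one whitespace-text embedding matrix `<id>.txt` per protein under
#' `matrices/`, and `labels.tsv` with columns `id` and `label`.
#'
#' @param ds result of [generateDataset()].
#' @param dir output directory (created if needed).
#' @return list of written paths.
#' @export
writeDatasetFiles <- function(ds, dir) {
  dir.create(file.path(dir, "matrices"), recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "sequences.fasta")
  Biostrings::writeXStringSet(ds$records, fasta)
  ids <- names(ds$records)
  mdir <- file.path(dir, "matrices")
  mfiles <- vapply(seq_along(ds$matrices), function(i) {
    f <- file.path(mdir, paste0(ids[i], ".txt"))
    utils::write.table(residueValues(ds$matrices[[i]]), f,
                       row.names = FALSE, col.names = FALSE)
    f
  }, character(1))
  labf <- file.path(dir, "labels.tsv")
  utils::write.table(data.frame(id = ids, label = ds$labels), labf,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, matrices = mfiles, labels = labf)
}

#' Read a dataset previously written with writeDatasetFiles
#'
#' @param dir dataset directory.
#' @return list with `records`, `matrices` (raw [ResidueMatrix-class]) and
#'   `labels`, aligned by id.
#' @export
readDatasetFiles <- function(dir) {
  records <- readFasta(file.path(dir, "sequences.fasta"))
  lab <- utils::read.delim(file.path(dir, "labels.tsv"))
  records <- records[lab$id]
  matrices <- lapply(seq_along(records), function(i) {
    readEmbedding(file.path(dir, "matrices", paste0(lab$id[i], ".txt")),
                  records[i])
  })
  list(records = records, matrices = matrices, labels = as.integer(lab$label))
}
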
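#' @include AllClasses.R
NULL

# PSI-BLAST PSSM column order (its ASCII header order)
.PSSM_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' The 20-letter amino-acid alphabet in PSI-BLAST PSSM column order
#'
#' A R N D C Q E G H I L K M F P S T W Y V — the order used both for PSSM
#' score columns and for the per-amino-acid-type feature block, so feature
#' names are unambiguous across representation sources.
#' @return character vector of 20 one-letter codes.
#' @export
pssmAlphabet <- function() .PSSM_ALPHABET

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased; entry order is preserved. Nonstandard letters
#' are allowed at read time and handled by [filterRecords()] and the
#' per-amino-acid-type operators downstream.
#'
#' @param path FASTA file path.
#' @return A [Biostrings::AAStringSet] (possibly empty), names from headers.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) &&
      !startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA: sequence before header at line ", nonblank[1])
  if (!length(nonblank)) return(Biostrings::AAStringSet())
  seqs <- Biostrings::readBStringSet(path)
  Biostrings::AAStringSet(toupper(as.character(seqs)))
}

#' Filter sequences by minimum length and forbidden letters
#'
#' Drops chains shorter than `minLen` residues and chains containing any
#' forbidden letter (by default the unknown-residue code `X`), the cleaning
#' rule applied to the benchmark collections. The filter is total and
#' idempotent; order is preserved.
#'
#' @param records an [Biostrings::AAStringSet].
#' @param minLen minimum sequence length kept (default 50).
#' @param forbidden character vector of forbidden letters (default `"X"`).
#' @return The surviving subset, same class as the input.
#' @export
filterRecords <- function(records, minLen = 50L, forbidden = "X") {
  stopifnot(minLen >= 1L)
  if (!length(records)) return(records)
  keep <- Biostrings::width(records) >= minLen
  if (length(forbidden)) {
    pat <- paste0("[", paste(forbidden, collapse = ""), "]")
    has <- grepl(pat, as.character(records))
    keep <- keep & !has
  }
  records[keep]
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the `-out_ascii_pssm` layout (two header lines, then one row per
#' residue: position index, residue letter, 20 log-odds integers, 20
#' weighted-percentage columns, two trailing floats). Only the first 20
#' numeric columns — the log-odds substitution scores — are kept; the
#' percentage block and trailing information-content columns are ignored.
#'
#' @param path PSSM file path.
#' @param record the bound protein sequence (an `AAString`, single-element
#'   `AAStringSet`, or plain character); row count and residue letters are
#'   checked against it.
#' @return A raw (unnormalized) [ResidueMatrix-class] with
#'   `sourceKind = "pssm"` and columns named by [pssmAlphabet()].
#' @export
readPssmAscii <- function(path, record) {
  rec <- .asSequence(record)
  lines <- readLines(path)
  rows <- grep("^\\s*[0-9]+\\s+[A-Za-z]\\s", lines, value = TRUE)
  if (!length(rows)) stop("no PSSM data rows found in ", path)
  parsed <- lapply(seq_along(rows), function(i) {
    tok <- strsplit(trimws(rows[i]), "\\s+")[[1]]
    if (length(tok) < 22L)
      stop("PSSM row ", i, " has ", length(tok) - 2L,
           " numeric columns; expected at least 20 log-odds scores")
    sc <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(sc))
      stop("non-numeric score cell in PSSM row ", i)
    list(letter = toupper(tok[2]), scores = sc)
  })
  letters <- vapply(parsed, `[[`, character(1), "letter")
  L <- nchar(rec$sequence)
  if (length(parsed) != L)
    stop("PSSM has ", length(parsed), " rows but sequence '", rec$id,
         "' has length ", L)
  seqChars <- strsplit(rec$sequence, "")[[1]]
  bad <- which(letters != seqChars)
  if (length(bad))
    stop("PSSM residue letter mismatch at position ", bad[1], ": file has '",
         letters[bad[1]], "', sequence has '", seqChars[bad[1]], "'")
  m <- do.call(rbind, lapply(parsed, `[[`, "scores"))
  colnames(m) <- .PSSM_ALPHABET
  ResidueMatrix(m, rec$id, "pssm", normalized = FALSE)
}

#' Read a per-residue embedding matrix
#'
#' Accepts a whitespace-delimited numeric text table (one residue per row) or
#' an RDS binary container holding a numeric matrix; the dialect is chosen by
#' extension (`.rds` vs anything else). The number of rows must equal the
#' bound sequence length; the dimension d is inferred from the file.
#'
#' @inheritParams readPssmAscii
#' @return A raw [ResidueMatrix-class] with `sourceKind = "embedding"`.
#' @export
readEmbedding <- function(path, record) {
  rec <- .asSequence(record)
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    m <- readRDS(path)
    if (!is.matrix(m) || !is.numeric(m))
      stop("RDS embedding container must hold a numeric matrix")
  } else {
    rows <- strsplit(trimws(readLines(path)), "\\s+")
    rows <- rows[lengths(rows) > 0L]
    if (!length(rows)) stop("empty embedding file: ", path)
    if (length(unique(lengths(rows))) != 1L)
      stop("ragged rows in embedding file ", path)
    m <- do.call(rbind, lapply(rows, function(r) {
      v <- suppressWarnings(as.numeric(r))
      if (anyNA(v)) stop("non-numeric cell in embedding file ", path)
      v
    }))
  }
  L <- nchar(rec$sequence)
  if (nrow(m) != L)
    stop("embedding has ", nrow(m), " rows but sequence '", rec$id,
         "' has length ", L)
  ResidueMatrix(m, rec$id, "embedding", normalized = FALSE)
}

#' Sigmoid-normalize a residue matrix
#'
#' Replaces every entry x by 1 / (1 + exp(-x)), mapping raw substitution
#' scores or embedding activations into (0, 1). Applying it twice is an
#' error: the transform is recorded in the `normalized` flag.
#'
#' @param m a raw [ResidueMatrix-class].
#' @return The normalized [ResidueMatrix-class]; shape unchanged.
#' @export
sigmoidNormalize <- function(m) {
  stopifnot(is(m, "ResidueMatrix"))
  if (m@normalized) stop("matrix of '", m@proteinId, "' is already normalized")
  v <- stats::plogis(m@values)
  dimnames(v) <- dimnames(m@values)
  new("ResidueMatrix", proteinId = m@proteinId, sourceKind = m@sourceKind,
      values = v, normalized = TRUE)
}

#' @rdname sigmoidNormalize
#' @param x a ResidueMatrix.
#' @export
isNormalized <- function(x) x@normalized

#' @rdname ResidueMatrix
#' @param x a ResidueMatrix.
#' @export
residueValues <- function(x) x@values

#' @rdname ResidueMatrix
#' @export
proteinId <- function(x) x@proteinId

# normalize the many ways a sequence can be handed in
.asSequence <- function(record) {
  if (is(record, "AAStringSet") || is(record, "BStringSet")) {
    if (length(record) != 1L) stop("expected a single sequence record")
    return(list(id = names(record) %||% "seq1",
                sequence = toupper(as.character(record[[1]]))))
  }
  if (is(record, "XString"))
    return(list(id = "seq1", sequence = toupper(as.character(record))))
  if (is.character(record) && length(record) == 1L)
    return(list(id = names(record) %||% "seq1", sequence = toupper(record)))
  stop("unsupported sequence record type: ", class(record)[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
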
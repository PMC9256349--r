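#' @include AllClasses.R repio.R
NULL

#' Describe a sequence-level feature set
#'
#' With all four categories and the defaults, assembly yields
#' d + 5d + 20d + 3d = 29d features per protein: the all-residue average, the
#' five k-separation averages over (k, s) in (2,1), (2,2), (3,1), (3,2),
#' (3,3), the twenty per-amino-acid-type averages, and the three lagged
#' squared-difference correlation averages (phi = 1, 2, 3).
#'
#' @param d representation dimension (20 for PSSM, e.g. 1280 for a
#'   transformer embedding).
#' @param categories which blocks to assemble.
#' @param kValues separation distances.
#' @param phiValues correlation lags.
#' @param aaAlphabet ordered amino-acid alphabet (default [pssmAlphabet()]).
#' @return A [FeatureSetSpec-class].
#' @examples
#' length(featureNameGrammar(featureSetSpec(20)))  # 580
#' @export
featureSetSpec <- function(d, categories = c("avg", "sep", "aa", "corr"),
                           kValues = 2:3, phiValues = 1:3,
                           aaAlphabet = pssmAlphabet()) {
  new("FeatureSetSpec", categories = categories,
      kValues = as.integer(kValues), phiValues = as.integer(phiValues),
      aaAlphabet = aaAlphabet, d = as.integer(d))
}

#' Deterministic feature names of a feature-set specification
#'
#' Grammar: `avg_j`, `sep_k{k}_s{s}_j`, `aa_{T}_j`, `corr_phi{p}_j` with a
#' 0-based dimension index j, concatenated in the fixed order
#' avg, sep, aa, corr.
#'
#' @param spec a [FeatureSetSpec-class].
#' @return character vector of feature names.
#' @export
featureNameGrammar <- function(spec) {
  j <- seq_len(spec@d) - 1L
  out <- character()
  if ("avg" %in% spec@categories)
    out <- c(out, paste0("avg_", j))
  if ("sep" %in% spec@categories)
    for (k in spec@kValues) for (s in seq_len(k))
      out <- c(out, sprintf("sep_k%d_s%d_%d", k, s, j))
  if ("aa" %in% spec@categories)
    for (t in spec@aaAlphabet)
      out <- c(out, sprintf("aa_%s_%d", t, j))
  if ("corr" %in% spec@categories)
    for (p in spec@phiValues)
      out <- c(out, sprintf("corr_phi%d_%d", p, j))
  out
}

.mValues <- function(m) if (is(m, "ResidueMatrix")) m@values else as.matrix(m)

#' Average representation over all residues
#'
#' Component j is the mean over residues i of m[i, j], collapsing the L x d
#' residue-level representation to d sequence-level features.
#'
#' @param m a [ResidueMatrix-class] or plain numeric matrix (rows = residues).
#' @return numeric vector of length d.
#' @export
avgAll <- function(m) {
  v <- .mValues(m)
  if (nrow(v) < 1L) stop("empty matrix")
  colMeans(v)
}

#' Average representation over k-separation residues
#'
#' Averages the rows at 1-based positions s, s+k, s+2k, ... <= L. The subset
#' size is floor((L - s + k) / k); for each k the subsets over s = 1..k
#' partition the residues.
#'
#' @inheritParams avgAll
#' @param k separation distance (>= s).
#' @param s start position, 1 <= s <= k.
#' @return numeric vector of length d.
#' @export
avgSeparation <- function(m, k, s) {
  v <- .mValues(m)
  L <- nrow(v)
  if (s < 1L || s > k) stop("need 1 <= s <= k")
  if (s > L) stop("start position s = ", s, " exceeds sequence length ", L)
  pos <- seq.int(s, L, by = k)
  colSums(v[pos, , drop = FALSE]) / length(pos)
}

#' Average representation over residues of one amino-acid type
#'
#' Mean of the rows whose residue letter equals `t`. When the sequence
#' contains no residue of type `t` the zero vector is returned, keeping the
#' per-type block at a fixed 20d dimensions for every sequence.
#'
#' @inheritParams avgAll
#' @param seq the protein sequence (single string), length = nrow(m).
#' @param t one of the 20 standard one-letter codes.
#' @return numeric vector of length d.
#' @export
avgByAA <- function(m, seq, t) {
  v <- .mValues(m)
  seq <- toupper(.asSequence(seq)$sequence)
  if (nchar(seq) != nrow(v))
    stop("sequence length ", nchar(seq), " does not match matrix rows ", nrow(v))
  if (!t %in% .PSSM_ALPHABET)
    stop("'", t, "' is not one of the 20 standard amino acids")
  idx <- which(strsplit(seq, "")[[1]] == t)
  if (!length(idx)) return(numeric(ncol(v)))
  colSums(v[idx, , drop = FALSE]) / length(idx)
}

#' Average squared-difference correlation at lag phi
#'
#' Component j is the mean over i of (m[i, j] - m[i + phi, j])^2, the
#' sequence-order descriptor used in pseudo-PSSM style features. Degenerate
#' sequences with L <= phi yield the zero vector with a warning.
#'
#' @inheritParams avgAll
#' @param phi sequence lag, >= 1.
#' @return numeric vector of length d.
#' @export
avgCorrelation <- function(m, phi) {
  v <- .mValues(m)
  if (phi < 1L) stop("phi must be >= 1")
  L <- nrow(v)
  if (L <= phi) {
    warning("sequence length ", L, " <= lag ", phi, "; returning zeros")
    return(numeric(ncol(v)))
  }
  dif <- v[seq_len(L - phi), , drop = FALSE] - v[seq_len(L - phi) + phi, , drop = FALSE]
  colSums(dif * dif) / (L - phi)
}

#' Assemble the sequence-level feature vector of one protein
#'
#' Concatenates, in fixed order, the avg (d), separation (5d),
#' per-amino-acid-type (20d) and correlation (3d) blocks — 29d features for
#' the full specification — with names from [featureNameGrammar()].
#'
#' @param m a sigmoid-normalized [ResidueMatrix-class].
#' @param seq the bound protein sequence (string or AAString), length L.
#' @param spec a [FeatureSetSpec-class] with `d = ncol(m)`.
#' @return named numeric feature vector.
#' @export
assembleFeatures <- function(m, seq, spec = featureSetSpec(ncol(.mValues(m)))) {
  v <- .mValues(m)
  if (is(m, "ResidueMatrix") && !m@normalized)
    stop("assembleFeatures expects a sigmoid-normalized matrix; ",
         "call sigmoidNormalize() first")
  if (ncol(v) != spec@d)
    stop("spec d = ", spec@d, " does not match matrix dimension ", ncol(v))
  sq <- .asSequence(seq)$sequence
  if (nchar(sq) != nrow(v))
    stop("sequence length ", nchar(sq), " does not match matrix rows ", nrow(v))
  out <- numeric()
  if ("avg" %in% spec@categories) out <- c(out, avgAll(v))
  if ("sep" %in% spec@categories)
    for (k in spec@kValues) for (s in seq_len(k))
      out <- c(out, avgSeparation(v, k, s))
  if ("aa" %in% spec@categories)
    for (t in spec@aaAlphabet) out <- c(out, avgByAA(v, sq, t))
  if ("corr" %in% spec@categories)
    for (p in spec@phiValues) out <- c(out, avgCorrelation(v, p))
  names(out) <- featureNameGrammar(spec)
  out
}

#' Build a labelled FeatureTable from (sequence, matrix) pairs
#'
#' One feature row per protein, consistent names, deterministic row order
#' equal to input order. All matrices must share the representation
#' dimension d; labels must align with the inputs.
#'
#' @param matrices list of sigmoid-normalized [ResidueMatrix-class] objects.
#' @param seqs sequences aligned with `matrices` (an `AAStringSet` or
#'   character vector).
#' @param labels binary vector (1 = DNA-binding).
#' @param spec a [FeatureSetSpec-class]; defaults to the full 29d set.
#' @return A [FeatureTable-class].
#' @export
buildFeatureTable <- function(matrices, seqs, labels,
                              spec = NULL) {
  if (!length(matrices)) stop("empty input: no matrices")
  ds <- vapply(matrices, function(m) ncol(.mValues(m)), integer(1))
  if (length(unique(ds)) != 1L)
    stop("mixed representation dimensions: ", paste(unique(ds), collapse = ", "))
  if (length(labels) != length(matrices))
    stop("label length ", length(labels), " does not match ", length(matrices),
         " matrices")
  if (length(seqs) != length(matrices))
    stop("sequence count does not match matrix count")
  if (is.null(spec)) spec <- featureSetSpec(ds[1])
  seqChar <- if (is.character(seqs)) seqs else as.character(seqs)
  rows <- lapply(seq_along(matrices), function(i)
    assembleFeatures(matrices[[i]], seqChar[i], spec))
  values <- do.call(rbind, rows)
  ids <- vapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    if (is(m, "ResidueMatrix")) m@proteinId else paste0("protein", i)
  }, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  rownames(values) <- ids
  FeatureTable(values, labels, ids = ids)
}
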
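#' @importClassesFrom Biostrings AAStringSet
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
NULL

#' The 20-letter amino-acid alphabet and the 6-letter exchange groups
#'
#' `AMINO_ACIDS` is the standard 20-residue alphabet; `EXCHANGE_GROUPS`
#' partitions it into the six biochemical exchange groups
#' A = \{H, R, K\}, B = \{D, E, N, Q\}, C = \{C\}, D = \{S, T, P, A, G\},
#' E = \{M, I, L, V\}, F = \{F, Y, W\}.  `EXCHANGE_MAP` is the induced
#' residue -> group-label lookup.
#'
#' @format `AMINO_ACIDS`: character(20); `EXCHANGE_GROUPS`: named list of 6
#'   character vectors; `EXCHANGE_MAP`: named character(20).
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AMINO_ACIDS
#' @export
EXCHANGE_GROUPS <- list(
  A = c("H", "R", "K"),
  B = c("D", "E", "N", "Q"),
  C = c("C"),
  D = c("S", "T", "P", "A", "G"),
  E = c("M", "I", "L", "V"),
  F = c("F", "Y", "W"))

#' @rdname AMINO_ACIDS
#' @export
EXCHANGE_MAP <- local({
  m <- unlist(lapply(names(EXCHANGE_GROUPS), function(g)
    stats::setNames(rep(g, length(EXCHANGE_GROUPS[[g]])), EXCHANGE_GROUPS[[g]])))
  m[AMINO_ACIDS]
})

GROUP_LETTERS <- names(EXCHANGE_GROUPS)

## fixed 56-slot layout: 36 exchange 2-grams (lexicographic AA..FF),
## then 20 residue 1-grams (alphabetic)
E2_GRAMS <- as.vector(t(outer(GROUP_LETTERS, GROUP_LETTERS, paste0)))

#' Names of the 56 feature slots
#'
#' The fixed column layout of every feature matrix: 36 exchange-group
#' 2-gram slots `e2_AA` ... `e2_FF` (lexicographic) followed by 20 residue
#' 1-gram slots `a1_A` ... `a1_Y` (alphabetic).  The same gram always
#' occupies the same index across calls and processes.
#'
#' @return character(56).
#' @export
featureNames <- function() {
  c(paste0("e2_", E2_GRAMS), paste0("a1_", AMINO_ACIDS))
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()]: record ids are the
#' first whitespace-delimited token of each header, residues are uppercased.
#' No residue validation is performed here; see [validateSequences()].
#'
#' @param path path to a FASTA file.
#' @return an `AAStringSet` with one element per FASTA record.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 example", "VAAGTVAGT"), tf)
#' readProteinFasta(tf)
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- readAAStringSet(path, format = "fasta")
  seqs <- AAStringSet(toupper(as.character(seqs)))
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Validate residues against the 20-letter alphabet
#'
#' Under `policy = "strict"` any character outside the 20-letter alphabet
#' (ambiguity codes B/Z/X, U, O, gaps, ...) is an error naming the first
#' offending record, residue and position.  Under `policy = "drop"`
#' offending characters are removed with a warning.
#'
#' @param seqs an `AAStringSet` or character vector of sequences.
#' @param policy `"strict"` (default) or `"drop"`.
#' @return an `AAStringSet` of validated sequences.
#' @export
validateSequences <- function(seqs, policy = c("strict", "drop")) {
  policy <- match.arg(policy)
  ids <- names(seqs)
  x <- toupper(as.character(seqs))
  bad <- gsub(paste0("[", paste(AMINO_ACIDS, collapse = ""), "]"), "", x)
  hit <- which(nzchar(bad))
  if (length(hit)) {
    if (policy == "strict") {
      i <- hit[1L]
      ch <- substring(bad[i], 1L, 1L)
      pos <- regexpr(ch, x[i], fixed = TRUE)
      stop("invalid residue '", ch, "' at position ", pos,
           " in sequence '", if (is.null(ids)) i else ids[i], "'")
    }
    warning(length(hit), " sequence(s) contained non-standard residues; ",
            "offending characters dropped")
    x[hit] <- vapply(x[hit], function(s) {
      paste(strsplit(s, "")[[1]][strsplit(s, "")[[1]] %in% AMINO_ACIDS],
            collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  if (any(!nzchar(x))) stop("validation left an empty sequence")
  out <- AAStringSet(x)
  names(out) <- ids
  out
}

#' Translate residues to exchange-group labels
#'
#' Applies the residue -> group pointwise map (`EXCHANGE_MAP`), producing a
#' same-length string over \{A..F\}; e.g. `"VAAGTVAGT"` becomes
#' `"EDDDDEDDD"`.
#'
#' @param seqs an `AAStringSet` or character vector of validated sequences.
#' @return character vector of exchange-group strings.
#' @export
toExchangeString <- function(seqs) {
  x <- as.character(seqs)
  old <- paste(AMINO_ACIDS, collapse = "")
  new <- paste(unname(EXCHANGE_MAP), collapse = "")
  if (any(grepl(paste0("[^", old, "]"), x)))
    stop("sequence contains residues outside the 20-letter alphabet")
  chartr(old, new, x)
}

#' Count contiguous n-grams of a sequence
#'
#' Tallies every length-`n` contiguous substring.  For a sequence of
#' length l >= n the counts sum to l - n + 1; for l < n an empty count set
#' is returned.  Zero counts are omitted.
#'
#' @param sequence a single character string.
#' @param n gram length (>= 1).
#' @return a list with elements `n`, `seqLength` and `counts` (a named
#'   integer vector of gram counts).
#' @examples
#' countNgrams("VAAGTVAGT", 2)$counts  # VA:2 AA:1 AG:2 GT:2 TV:1
#' @export
countNgrams <- function(sequence, n) {
  stopifnot(is.character(sequence), length(sequence) == 1L, n >= 1)
  n <- as.integer(n)
  l <- nchar(sequence)
  if (l < n) {
    counts <- integer(0)
  } else {
    grams <- substring(sequence, seq_len(l - n + 1L), n:l)
    tab <- table(grams)
    counts <- stats::setNames(as.integer(tab), names(tab))
  }
  list(n = n, seqLength = l, counts = counts)
}

#' Normalise n-gram counts by the number of gram positions
#'
#' Each count x becomes x / (l - n + 1), so the normalised values are in
#' (0, 1] and sum to 1.
#'
#' @param ngrams result of [countNgrams()].
#' @return named numeric vector of normalised frequencies.
#' @export
normalizeCounts <- function(ngrams) {
  l <- ngrams$seqLength
  n <- ngrams$n
  if (l < n) stop("sequence shorter than the gram length: nothing to normalise")
  ngrams$counts / (l - n + 1L)
}

## vectorised 56-dim extraction; seqs assumed validated
.featureRows <- function(x) {
  grpOfAA <- unname(match(EXCHANGE_MAP, GROUP_LETTERS))  # per residue code
  t(vapply(x, function(s) {
    codes <- match(strsplit(s, "", fixed = TRUE)[[1]], AMINO_ACIDS)
    l <- length(codes)
    a1 <- tabulate(codes, 20L) / l
    g <- grpOfAA[codes]
    idx2 <- (g[-l] - 1L) * 6L + g[-1L]
    e2 <- tabulate(idx2, 36L) / (l - 1L)
    c(e2, a1)
  }, numeric(56L), USE.NAMES = FALSE))
}

#' Build the 56-dimensional feature vector(s)
#'
#' For each sequence: the normalised 2-gram frequencies of its
#' exchange-group translation fill the 36 lexicographic `e2` slots
#' (absent grams are 0), and the normalised residue 1-gram frequencies
#' fill the 20 alphabetic `a1` slots.  The two blocks are concatenated
#' (e2 first) into a 56-dimensional vector; the `e2` block sums to 1, the
#' `a1` block sums to 1.
#'
#' @param seqs an `AAStringSet` or character vector of validated sequences,
#'   each of length >= 2.
#' @return numeric matrix, one row per sequence, 56 named columns
#'   ([featureNames()]); rownames are the sequence ids when present.
#' @examples
#' v <- buildFeatureVector("VAAGTVAGT")
#' v[, c("e2_DD", "e2_ED", "e2_DE", "a1_A")]
#' @export
buildFeatureVector <- function(seqs) {
  ids <- names(seqs)
  x <- as.character(seqs)
  if (length(x) == 0L)
    return(matrix(numeric(0), 0L, 56L, dimnames = list(NULL, featureNames())))
  if (any(nchar(x) < 2L))
    stop("sequences must have length >= 2 (2-gram features undefined)")
  bad <- grepl(paste0("[^", paste(AMINO_ACIDS, collapse = ""), "]"), x)
  if (any(bad))
    stop("unvalidated residues in sequence(s): ",
         paste(head(which(bad), 3L), collapse = ", "))
  m <- .featureRows(x)
  dimnames(m) <- list(ids, featureNames())
  m
}

#' Fit and apply the [-1, 1] feature scaler
#'
#' `fitScaler` learns per-column minima and maxima from a training matrix;
#' `applyScaler` maps each column affinely so the training range becomes
#' [-1, 1] (constant columns map to 0).  Fit on the training split only
#' and reuse on test data, which may then exceed [-1, 1].
#'
#' @param x numeric matrix (rows = samples).
#' @return `fitScaler`: a [FeatureScaler-class]; `applyScaler`: the
#'   transformed matrix.
#' @export
fitScaler <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 1L)
  new("FeatureScaler",
      min = apply(x, 2L, min),
      max = apply(x, 2L, max))
}

#' @rdname fitScaler
#' @param scaler a fitted [FeatureScaler-class].
#' @export
applyScaler <- function(scaler, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(scaler@min))
    stop("matrix has ", ncol(x), " columns; scaler expects ",
         length(scaler@min))
  rng <- scaler@max - scaler@min
  const <- rng <= 0
  rng[const] <- 1
  out <- sweep(sweep(x, 2L, scaler@min), 2L, rng, "/") * 2 - 1
  out[, const] <- 0
  out
}

#' Write a feature matrix as CSV
#'
#' Writes the fixed 56-column layout with an `id` column first and one row
#' per sequence, in input order.
#'
#' @param features matrix from [buildFeatureVector()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureCSV <- function(features, path) {
  df <- data.frame(id = rownames(features) %||% seq_len(nrow(features)),
                   features, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
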
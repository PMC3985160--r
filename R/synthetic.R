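## Synthetic protein superfamily data with class-specific residue
## composition and PIR-like class imbalance presets.

## per-superfamily class sizes of the two PIR benchmark databases
## (Cytochrome c, Cytochrome c6, Cytochrome b, Cytochrome b5,
##  Triosephosphate isomerase, Plastocyanin, Photosystem II D2,
##  Ferredoxin, Globin, Cytochrome b6-f complex 4.2K)
PIR_SUPERFAMILIES <- c("Cytochrome_c", "Cytochrome_c6", "Cytochrome_b",
                       "Cytochrome_b5", "Triosephosphate_isomerase",
                       "Plastocyanin", "Photosystem_II_D2", "Ferredoxin",
                       "Globin", "Cytochrome_b6f_4.2K")

#' PIR-like class-size presets
#'
#' The per-superfamily sample counts of the two benchmark databases:
#' `"pir1"` has 949 sequences over 10 superfamilies
#' (113, 45, 73, 11, 14, 42, 30, 65, 548, 8) and `"pir2"`
#' (17, 14, 100, 14, 44, 56, 45, 33, 204, 6), which sum to 533 (the
#' database is usually quoted as 534 sequences; the published per-class
#' breakdown sums to one fewer, and the breakdown is what is reproduced
#' here).  Both layouts are strongly imbalanced (Globin dominates).
#'
#' @param preset `"pir1"` or `"pir2"`.
#' @return named integer vector of 10 class sizes.
#' @export
pirClassSizes <- function(preset = c("pir1", "pir2")) {
  preset <- match.arg(preset)
  sizes <- switch(preset,
    pir1 = c(113L, 45L, 73L, 11L, 14L, 42L, 30L, 65L, 548L, 8L),
    pir2 = c(17L, 14L, 100L, 14L, 44L, 56L, 45L, 33L, 204L, 6L))
  stats::setNames(sizes, PIR_SUPERFAMILIES)
}

#' Draw class-specific residue composition profiles
#'
#' Each profile's composition is a convex blend of the uniform composition
#' with an independent flat-Dirichlet draw over the 20 residues:
#' weights = (1 - separation)/20 + separation * Dirichlet(1, ..., 1).
#' `separation` is the single knob for class overlap: near 0 every profile
#' approaches the uniform composition (classes indistinguishable from
#' 1-/2-gram features), near 1 the profiles are sharply distinct.
#'
#' @param nClasses number of superfamilies (>= 2).
#' @param separation class-separation knob in (0, 1].
#' @param seed integer seed.
#' @param lengthRange integer (min, max) sequence lengths (default
#'   `c(50, 400)`).
#' @param names optional profile names; defaults to the 10 PIR superfamily
#'   names when `nClasses == 10`, else `class01`, `class02`, ...
#' @return list of [SuperfamilyProfile-class].
#' @export
makeProfiles <- function(nClasses, separation = 0.5, seed,
                         lengthRange = c(50L, 400L), names = NULL) {
  stopifnot(nClasses >= 2, separation > 0, separation <= 1)
  if (is.null(names))
    names <- if (nClasses == 10L) PIR_SUPERFAMILIES else
      sprintf("class%02d", seq_len(nClasses))
  withSeed(seed, lapply(seq_len(nClasses), function(i) {
    dirich <- rgamma(20L, shape = 1)
    dirich <- dirich / sum(dirich)
    w <- (1 - separation) / 20 + separation * dirich
    new("SuperfamilyProfile", name = names[i],
        residueWeights = stats::setNames(w / sum(w), AMINO_ACIDS),
        lengthRange = as.integer(lengthRange), transitionBias = NULL)
  }))
}

.sampleSequence <- function(profile) {
  l <- sample.int(profile@lengthRange[2] - profile@lengthRange[1] + 1L, 1L) +
    profile@lengthRange[1] - 1L
  w <- profile@residueWeights
  if (is.null(profile@transitionBias)) {
    paste(sample(AMINO_ACIDS, l, replace = TRUE, prob = w), collapse = "")
  } else {
    trans <- profile@transitionBias * rep(w, each = 20L)
    trans <- trans / rowSums(trans)
    res <- integer(l)
    res[1] <- sample.int(20L, 1L, prob = w)
    for (i in seq_len(l - 1L))
      res[i + 1L] <- sample.int(20L, 1L, prob = trans[res[i], ])
    paste(AMINO_ACIDS[res], collapse = "")
  }
}

#' Generate a labelled synthetic superfamily dataset
#'
#' Samples `classSizes[i]` sequences from profile i, residues i.i.d. from
#' the profile composition (or first-order Markov when the profile carries
#' a transition bias), lengths uniform in the profile length range.
#' Use `classSizes = pirClassSizes("pir1")` / `"pir2"` for the benchmark
#' imbalance layout.
#'
#' @param profiles list of [SuperfamilyProfile-class].
#' @param classSizes integer vector, one size (>= 1) per profile.
#' @param seed integer seed.
#' @param idPrefix prefix for record ids (default `"seq"`); use distinct
#'   prefixes when generating separate train and test datasets.
#' @return a [ProteinDataset-class].
#' @export
generateDataset <- function(profiles, classSizes, seed, idPrefix = "seq") {
  stopifnot(length(classSizes) == length(profiles))
  classSizes <- as.integer(classSizes)
  if (any(classSizes < 1L)) stop("every class size must be >= 1")
  withSeed(seed, {
    seqs <- unlist(lapply(seq_along(profiles), function(i)
      vapply(seq_len(classSizes[i]), function(j)
        .sampleSequence(profiles[[i]]), character(1))))
    labels <- factor(rep(vapply(profiles, function(p) p@name, character(1)),
                         classSizes))
    ss <- AAStringSet(seqs)
    names(ss) <- paste0(idPrefix, seq_along(ss))
    new("ProteinDataset", sequences = ss, labels = labels,
        profiles = profiles, seed = as.integer(seed))
  })
}

#' Split a dataset into training and testing sets
#'
#' `mode = "random"` shuffles the records and assigns `nTrain` of them to
#' the training set (the mixed-then-split scenario); `mode = "fixed"`
#' keeps two pre-built datasets as-is (the fixed train/test scenario) and
#' errors if their record ids overlap.
#'
#' @param dataset a [ProteinDataset-class] (random mode).
#' @param nTrain number of training records (random mode).
#' @param seed integer split seed (random mode).
#' @param train,test two [ProteinDataset-class] objects (fixed mode).
#' @return list with elements `train` and `test`.
#' @export
splitDataset <- function(dataset = NULL, nTrain = NULL, seed = NULL,
                         train = NULL, test = NULL) {
  if (!is.null(train) || !is.null(test)) {
    stopifnot(is(train, "ProteinDataset"), is(test, "ProteinDataset"))
    if (length(intersect(names(train@sequences), names(test@sequences))))
      stop("fixed train and test datasets share record ids")
    return(list(train = train, test = test))
  }
  stopifnot(is(dataset, "ProteinDataset"), !is.null(nTrain), !is.null(seed))
  n <- length(dataset@sequences)
  if (nTrain >= n) stop("nTrain must be smaller than the dataset size")
  idx <- withSeed(seed, sample.int(n))
  take <- function(i) new("ProteinDataset",
                          sequences = dataset@sequences[i],
                          labels = droplevels(dataset@labels[i]),
                          profiles = dataset@profiles, seed = dataset@seed)
  list(train = take(idx[seq_len(nTrain)]),
       test = take(idx[(nTrain + 1L):n]))
}

#' Write a dataset as FASTA plus a label table
#'
#' @param dataset a [ProteinDataset-class].
#' @param fasta output FASTA path.
#' @param labels output path for the two-column tab-separated label file
#'   (id, class); omit to skip.
#' @return `fasta`, invisibly.
#' @export
writeProteinFasta <- function(dataset, fasta, labels = NULL) {
  writeXStringSet(dataset@sequences, fasta)
  if (!is.null(labels))
    utils::write.table(
      data.frame(id = names(dataset@sequences),
                 label = as.character(dataset@labels)),
      labels, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta)
}

#' Read a two-column label table
#'
#' Reads a delimited file of (id, class label); a header row is detected
#' and skipped when its first field is `id`.
#'
#' @param path label file path.
#' @return named character vector (names = ids).
#' @export
readLabelTable <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE,
                          col.names = c("id", "label"))
  if (nrow(df) && identical(tolower(df$id[1]), "id")) df <- df[-1L, ]
  stats::setNames(as.character(df$label), df$id)
}

setMethod("show", "ProteinDataset", function(object) {
  cat(sprintf("ProteinDataset: %d sequences, %d classes\n",
              length(object@sequences), nlevels(object@labels)))
  if (length(object@sequences))
    print(table(object@labels))
})

#' Feature matrix of a dataset
#'
#' Convenience wrapper building the 56-dimensional feature matrix of all
#' sequences of a dataset ([buildFeatureVector()]).
#'
#' @param dataset a [ProteinDataset-class].
#' @return numeric matrix, one row per sequence.
#' @export
datasetFeatures <- function(dataset) {
  buildFeatureVector(dataset@sequences)
}
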
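## Majority-voting ensembles of independently trained SLFNs:
## V-ELM (base learner = basic ELM) and VOP-ELM (base learner = OP-ELM).

#' Train a majority-voting ensemble (V-ELM / VOP-ELM)
#'
#' Trains `K` base SLFNs independently on the full training set (no
#' bagging: diversity comes solely from the random hidden parameters),
#' all sharing the same architecture and activation.  Member seeds are
#' drawn from a deterministic stream seeded by `masterSeed`, so the first
#' members of a larger ensemble coincide with a smaller ensemble built
#' from the same master seed.
#'
#' @param X numeric N x d training feature matrix.
#' @param labels class labels, one per row.
#' @param K ensemble size (default 7 for `"elm"`, 3 for `"opelm"`,
#'   following the experimental protocol; ensembles larger than ~15 bring
#'   little further gain).
#' @param baseKind `"elm"` (V-ELM) or `"opelm"` (VOP-ELM).
#' @param J hidden nodes per member (`"elm"`) or initial pool size `Jmax`
#'   (`"opelm"`); OP-ELM members may end up with different pruned sizes.
#' @param kind activation kind shared by all members.
#' @param masterSeed integer master seed.
#' @param classLevels optional fixed class ordering.
#' @param scaler optional [FeatureScaler-class] stored with each member.
#' @return an [ELMEnsemble-class].
#' @export
trainEnsemble <- function(X, labels, K = NULL,
                          baseKind = c("elm", "opelm"), J = 100,
                          kind = "sigmoid", masterSeed,
                          classLevels = NULL, scaler = NULL) {
  baseKind <- match.arg(baseKind)
  if (is.null(K)) K <- if (baseKind == "elm") 7L else 3L
  stopifnot(K >= 1)
  if (is.null(classLevels)) classLevels <- sort(unique(as.character(labels)))
  seeds <- deriveSeeds(masterSeed, K)
  trainer <- if (baseKind == "elm") {
    function(s) trainELM(X, labels, J = J, kind = kind, seed = s,
                         classLevels = classLevels, scaler = scaler)
  } else {
    function(s) trainOPELM(X, labels, Jmax = J, kind = kind, seed = s,
                           classLevels = classLevels, scaler = scaler)
  }
  new("ELMEnsemble", baseKind = baseKind, members = lapply(seeds, trainer),
      masterSeed = as.integer(masterSeed), classLevels = classLevels)
}

#' Per-class vote tallies of an ensemble
#'
#' Each member classifies every row of `newdata`; the tally vector of a
#' sample counts, per class, how many members chose it.  Tallies always
#' sum to K.
#'
#' @param model an [ELMEnsemble-class].
#' @param newdata numeric feature matrix.
#' @param members optional integer subset of members to poll (default all);
#'   nested prefixes give paired sub-ensembles for K sweeps.
#' @return integer N x C matrix of tallies (`colnames` = class levels).
#' @export
voteTallies <- function(model, newdata, members = NULL) {
  idx <- members %||% seq_along(model@members)
  C <- length(model@classLevels)
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  votes <- matrix(0L, n, length(idx))
  for (j in seq_along(idx))
    votes[, j] <- max.col(decisionMatrix(model@members[[idx[j]]], newdata),
                          ties.method = "first")
  tallies <- t(apply(votes, 1L, tabulate, nbins = C))
  matrix(as.integer(tallies), nrow = n, ncol = C,
         dimnames = list(rownames(newdata), model@classLevels))
}

#' Predict class labels by majority vote
#'
#' The final class of each sample is the argmax of its vote tally; ties go
#' to the smallest class index by default (`tieBreak = "index"`), or to a
#' random tied class drawn reproducibly from the master seed
#' (`tieBreak = "random"`).
#'
#' @param object an [ELMEnsemble-class].
#' @param newdata numeric feature matrix.
#' @param tieBreak `"index"` (default) or `"random"`.
#' @param members optional integer subset of members to poll.
#' @return character vector of predicted labels.
#' @export
setMethod("predict", "ELMEnsemble",
  function(object, newdata, tieBreak = c("index", "random"),
           members = NULL) {
    tieBreak <- match.arg(tieBreak)
    tallies <- voteTallies(object, newdata, members)
    win <- if (tieBreak == "index") {
      max.col(tallies, ties.method = "first")
    } else {
      withSeed(object@masterSeed, max.col(tallies, ties.method = "random"))
    }
    object@classLevels[win]
  })

setMethod("show", "ELMEnsemble", function(object) {
  cat(sprintf(
    "%s ensemble: K = %d %s members, %d classes (master seed %d)\n",
    if (object@baseKind == "elm") "V-ELM" else "VOP-ELM",
    length(object@members), object@members[[1]]@hidden@kind,
    length(object@classLevels), object@masterSeed))
})

#' Monte-Carlo majority-vote accuracy versus ensemble size
#'
#' Simulates the asymptotic argument for voting: if a single base
#' classifier picks the correct class with probability `pCorrect` and each
#' wrong class i with probability `pOthers[i]`, and `pCorrect` strictly
#' exceeds every `pOthers[i]`, then the majority vote over K independent
#' classifiers is correct with probability approaching 1 as K grows.  Each
#' trial draws K votes from the multinomial and applies the argmax
#' (smallest-index tie-break, correct class first).
#'
#' @param pCorrect probability the base classifier is correct.
#' @param pOthers probabilities of the C - 1 wrong classes;
#'   `c(pCorrect, pOthers)` must be a probability vector.
#' @param Kgrid integer vector of ensemble sizes to simulate.
#' @param trials Monte-Carlo trials per K (default 1e4).
#' @param seed integer seed.
#' @return numeric vector of estimated accuracies, named by K.
#' @examples
#' simulateMajorityVote(0.5, c(0.3, 0.2), Kgrid = c(1, 11, 101), seed = 1)
#' @export
simulateMajorityVote <- function(pCorrect, pOthers, Kgrid, trials = 1e4,
                                 seed) {
  p <- c(pCorrect, pOthers)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("c(pCorrect, pOthers) must be a probability vector summing to 1")
  withSeed(seed, {
    acc <- vapply(Kgrid, function(K) {
      tallies <- rmultinom(trials, size = K, prob = p)
      mean(max.col(t(tallies), ties.method = "first") == 1L)
    }, numeric(1))
    stats::setNames(acc, paste0("K", Kgrid))
  })
}
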
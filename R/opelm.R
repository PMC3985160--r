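## Optimally pruned ELM: multiresponse sparse regression ranking of the
## hidden neurons followed by PRESS leave-one-out selection of the count.

#' Rank hidden neurons by multiresponse forward selection
#'
#' Multiresponse sparse-regression style ranking of the columns of the
#' hidden output matrix against the multi-output target: starting from an
#' empty active set, each step adds the column j maximising the L1 norm
#' over responses of |h_j' R|, where R is the residual of a full
#' least-squares refit on the current active set.  After J steps the active
#' set ordering is the neuron ranking (most relevant first).  Only the
#' ranking is consumed downstream; the coefficient path is not needed.
#'
#' Zero-variance (constant) columns are ranked last with a warning.
#'
#' @param H numeric N x J hidden-output matrix (N >= 2).
#' @param T numeric N x C target matrix.
#' @return integer permutation of `1:J`, most relevant neuron first.
#' @export
mrsrRank <- function(H, T) {
  H <- as.matrix(H); T <- as.matrix(T)
  stopifnot(nrow(H) >= 2L, nrow(H) == nrow(T))
  J <- ncol(H)
  if (J == 1L) return(1L)
  colVar <- apply(H, 2L, var)
  degenerate <- which(colVar < .Machine$double.eps^2)
  if (length(degenerate))
    warning(length(degenerate), " zero-variance hidden neuron(s) ranked last")
  candidates <- setdiff(seq_len(J), degenerate)
  ## Incremental Gram-Schmidt formulation: after orthonormalising the
  ## active columns into q_1..q_l, the least-squares residual is
  ## R = T - sum_l q_l (q_l' T) and h_j' R equals (orthogonalised h_j)' R,
  ## so the score matrix G = Hc' R admits a rank-one downdate per step.
  ## Identical ranking to refitting at every step, at O(N J^2) cost.
  Hc <- H[, candidates, drop = FALSE]
  R <- T
  G <- crossprod(Hc, R)
  remaining <- candidates
  active <- integer(0)
  while (length(remaining)) {
    i <- which.max(rowSums(abs(G)))
    j <- remaining[i]
    q <- Hc[, i]
    Hc <- Hc[, -i, drop = FALSE]
    G <- G[-i, , drop = FALSE]
    remaining <- remaining[-i]
    active <- c(active, j)
    nq <- sqrt(sum(q^2))
    if (nq > 1e-10 && length(remaining)) {
      q <- q / nq
      v <- crossprod(R, q)
      R <- R - tcrossprod(q, v)
      u <- crossprod(Hc, q)
      Hc <- Hc - tcrossprod(q, u)
      G <- G - tcrossprod(u, v)
    }
  }
  as.integer(c(active, degenerate))
}

## (H'H)^-1 via eigen/SVD; ridge-stabilised only when numerically singular
.pressContext <- function(H, condMax = 1e12, ridgeScale = 1e-8) {
  HtH <- crossprod(H)
  k <- ncol(H)
  e <- eigen(HtH, symmetric = TRUE)
  lambda <- 0
  if (min(e$values) <= 0 ||
      max(e$values) / max(min(e$values), 1e-300) > condMax)
    lambda <- max(ridgeScale * sum(diag(HtH)) / k, 1e-12)
  P <- e$vectors %*% ((1 / (e$values + lambda)) * t(e$vectors))
  list(P = P, lambda = lambda)
}

#' PRESS leave-one-out error of a linear-in-parameters fit
#'
#' Closed-form leave-one-out error of the least-squares fit of `T` on the
#' columns of `H`: with beta = (H'H)^-1 H'T fitted on all N samples and
#' P = (H'H)^-1, the LOO residual of sample i is
#' (t_i - h_i beta) / (1 - h_i P h_i'), and the returned error is the mean
#' of its squares over all samples and output columns.  P is
#' ridge-stabilised (lambda = 1e-8 tr(H'H)/k) only when H'H is numerically
#' singular (condition number > 1e12); leverages within 1e-10 of 1 have
#' their denominator floored with a warning.
#'
#' @param H numeric N x k regressor matrix (k >= 1).
#' @param T numeric N x C target matrix.
#' @return mean squared leave-one-out residual (a single number).
#' @export
pressLooError <- function(H, T) {
  H <- as.matrix(H); T <- as.matrix(T)
  ctx <- .pressContext(H)
  beta <- ctx$P %*% crossprod(H, T)
  res <- T - H %*% beta
  lev <- rowSums((H %*% ctx$P) * H)
  denom <- 1 - lev
  if (any(denom < 1e-10)) {
    warning("leverage ~ 1 for ", sum(denom < 1e-10),
            " sample(s); denominator floored")
    denom <- pmax(denom, 1e-10)
  }
  mean((res / denom)^2)
}

#' Select the neuron count minimising the leave-one-out error
#'
#' Given a hidden-output matrix whose columns are already in ranking order,
#' computes the PRESS leave-one-out error for every prefix size k = 1..J
#' and selects the smallest k attaining the minimum (parsimony tie-break).
#'
#' @param Hranked numeric N x J matrix, columns ordered by [mrsrRank()].
#' @param T numeric N x C target matrix.
#' @return list with `looError` (numeric J) and `selectedK` (integer).
#' @export
selectNeuronCount <- function(Hranked, T) {
  Hranked <- as.matrix(Hranked); T <- as.matrix(T)
  N <- nrow(Hranked)
  J <- ncol(Hranked)
  ## Fast path: one unpivoted QR of the ranked matrix gives every prefix
  ## hat matrix at once -- leverage of prefix k is the running row sum of
  ## Q^2 and the prefix residual is a rank-one downdate per column, so
  ## the whole curve costs O(N J (J + C)).  Algebraically identical to
  ## calling pressLooError() on every prefix; that slower route is kept
  ## for short/ill-conditioned problems where the prefixes may be rank
  ## deficient and the ridge stabilisation matters.
  wellConditioned <- J < N && {
    qrH <- qr(Hranked)  # unpivoted for full-rank input; pivot checked below
    dR <- abs(diag(qr.R(qrH)))
    qrH$rank == J && identical(qrH$pivot, seq_len(J)) &&
      all(dR > 1e-8 * max(dR))
  }
  if (wellConditioned) {
    Q <- qr.Q(qrH)
    Tq <- crossprod(Q, T)
    R <- T
    lev <- numeric(N)
    loo <- numeric(J)
    for (k in seq_len(J)) {
      R <- R - tcrossprod(Q[, k], Tq[k, ])
      lev <- lev + Q[, k]^2
      loo[k] <- mean((R / pmax(1 - lev, 1e-10))^2)
    }
  } else {
    loo <- vapply(seq_len(J), function(k)
      pressLooError(Hranked[, seq_len(k), drop = FALSE], T), numeric(1))
  }
  list(looError = loo, selectedK = which.min(loo))
}

#' Train an optimally pruned ELM
#'
#' Three steps: (1) build a standard ELM hidden layer with `Jmax` random
#' nodes; (2) rank the hidden neurons by multiresponse forward selection
#' ([mrsrRank()]); (3) evaluate the PRESS leave-one-out error for every
#' prefix of the ranking ([selectNeuronCount()]), keep the best-ranked
#' `selectedK` neurons and refit the output weights on them.
#'
#' @inheritParams trainELM
#' @param Jmax size of the initial hidden-node pool (default 100).
#' @return an [OPELMModel-class]; its hidden layer holds the selected
#'   neurons, and [pressCurve()] exposes the LOO sweep.
#' @export
trainOPELM <- function(X, labels, Jmax = 100, kind = "sigmoid", seed,
                       classLevels = NULL, scaler = NULL) {
  X <- as.matrix(X)
  T <- encodeTargets(labels, classLevels)
  layer <- initHiddenLayer(Jmax, ncol(X), kind, seed)
  H <- hiddenOutput(X, layer)
  ord <- mrsrRank(H, T)
  sel <- selectNeuronCount(H[, ord, drop = FALSE], T)
  keep <- ord[seq_len(sel$selectedK)]
  pruned <- new("HiddenLayer", kind = layer@kind,
                weights = layer@weights[keep, , drop = FALSE],
                bias = layer@bias[keep], seed = layer@seed)
  W <- solveOutputWeights(H[, keep, drop = FALSE], T)
  new("OPELMModel", hidden = pruned, outputWeights = W,
      classLevels = colnames(T), scaler = scaler,
      ranking = as.integer(ord), looError = sel$looError,
      selectedK = as.integer(sel$selectedK))
}

#' Leave-one-out error curve of an OP-ELM model
#'
#' @param model an [OPELMModel-class].
#' @return data.frame with columns `k` (neuron count) and `looError`,
#'   suitable for CSV export and node-sweep plots.
#' @export
pressCurve <- function(model) {
  stopifnot(is(model, "OPELMModel"))
  data.frame(k = seq_along(model@looError), looError = model@looError)
}

setMethod("show", "OPELMModel", function(object) {
  cat(sprintf(
    "SLFN trained by OP-ELM: %d of %d %s hidden nodes kept (seed %d)\n",
    object@selectedK, length(object@ranking), object@hidden@kind,
    object@hidden@seed))
})
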
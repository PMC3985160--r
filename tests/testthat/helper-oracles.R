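# Independent brute-force oracles the implementation is checked against.

# forward-selection ranking with a full least-squares refit at every step
naiveMrsrRank <- function(H, T) {
  J <- ncol(H)
  candidates <- seq_len(J)
  active <- integer(0)
  R <- T
  while (length(candidates)) {
    sc <- rowSums(abs(crossprod(H[, candidates, drop = FALSE], R)))
    j <- candidates[which.max(sc)]
    active <- c(active, j)
    candidates <- setdiff(candidates, j)
    if (length(candidates)) {
      Ha <- H[, active, drop = FALSE]
      R <- T - Ha %*% qr.solve(Ha, T)
    }
  }
  as.integer(active)
}

# explicit leave-one-out: retrain N times on the normal equations and
# score the held-out row; mean of squared residuals over samples/columns
explicitLooError <- function(H, T) {
  N <- nrow(H)
  sq <- vapply(seq_len(N), function(i) {
    Hi <- H[-i, , drop = FALSE]
    beta <- solve(crossprod(Hi), crossprod(Hi, T[-i, , drop = FALSE]))
    sum((T[i, ] - H[i, , drop = FALSE] %*% beta)^2)
  }, numeric(1))
  sum(sq) / (N * ncol(T))
}

# Frobenius norm of the least-squares residual via an SVD projection,
# independent of solveOutputWeights
svdResidual <- function(H, T) {
  s <- svd(H)
  keep <- s$d > max(dim(H)) * .Machine$double.eps * max(s$d, 0)
  U <- s$u[, keep, drop = FALSE]
  sqrt(sum((T - U %*% crossprod(U, T))^2))
}

# a hand-built SLFN that always outputs the given constant decision row
constantModel <- function(decision, classLevels, d = 3L) {
  layer <- new("HiddenLayer", kind = "linear",
               weights = matrix(0, 1L, d), bias = 1, seed = 0L)
  new("SLFNModel", hidden = layer,
      outputWeights = matrix(decision, nrow = 1L),
      classLevels = classLevels, scaler = NULL)
}

# small scaled classification problem built through the synthetic module
smallProblem <- function(seed, nClasses = 4, perClassTrain = 15,
                         perClassTest = 10, separation = 0.6) {
  pr <- makeProfiles(nClasses, separation = separation, seed = seed,
                     lengthRange = c(30L, 80L))
  tr <- generateDataset(pr, rep(perClassTrain, nClasses), seed = seed + 1L,
                        idPrefix = "tr")
  te <- generateDataset(pr, rep(perClassTest, nClasses), seed = seed + 2L,
                        idPrefix = "te")
  sc <- fitScaler(datasetFeatures(tr))
  list(Xtrain = applyScaler(sc, datasetFeatures(tr)),
       ytrain = as.character(tr@labels),
       Xtest = applyScaler(sc, datasetFeatures(te)),
       ytest = as.character(te@labels))
}
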
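## Basic extreme learning machine: random hidden parameters, closed-form
## output weights via the Moore-Penrose pseudoinverse.

## run expr with a local RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## deterministic per-member seed stream; prefix-stable in k
deriveSeeds <- function(masterSeed, k) {
  withSeed(masterSeed, sample.int(.Machine$integer.max - 1L, k))
}

#' One-against-all target encoding
#'
#' Encodes a label vector as an N x C matrix over \{+1, -1\}: row i carries
#' +1 in the column of its class and -1 elsewhere.  The class index is the
#' sorted order of the label levels, fixed for reproducibility.
#'
#' @param labels factor or character vector of class labels.
#' @param classLevels optional fixed class ordering; labels outside it are
#'   an error.  Defaults to `sort(unique(labels))`.
#' @return numeric N x C matrix with `colnames = classLevels`.
#' @export
encodeTargets <- function(labels, classLevels = NULL) {
  labels <- as.character(labels)
  if (is.null(classLevels)) classLevels <- sort(unique(labels))
  idx <- match(labels, classLevels)
  if (anyNA(idx))
    stop("label(s) not in classLevels: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  C <- length(classLevels)
  if (C < 2L) stop("at least two classes required")
  T <- matrix(-1, length(labels), C, dimnames = list(NULL, classLevels))
  T[cbind(seq_along(idx), idx)] <- 1
  T
}

#' Draw a random hidden layer
#'
#' Node weights are i.i.d. uniform on [-1, 1] (matching the [-1, 1] input
#' scaling); biases are uniform on [-1, 1] for linear and sigmoid nodes and
#' widths uniform on (0, 1] for Gaussian nodes.  Fully determined by `seed`.
#'
#' @param J number of hidden nodes (>= 1).
#' @param d input dimension (>= 1).
#' @param kind `"sigmoid"` (default), `"linear"` or `"gaussian"`.
#' @param seed integer seed.
#' @return a [HiddenLayer-class].
#' @export
initHiddenLayer <- function(J, d, kind = c("sigmoid", "linear", "gaussian"),
                            seed) {
  kind <- match.arg(kind)
  stopifnot(J >= 1, d >= 1)
  withSeed(seed, {
    A <- matrix(runif(J * d, -1, 1), nrow = J, ncol = d)
    b <- if (kind == "gaussian") runif(J, 0, 1) else runif(J, -1, 1)
    new("HiddenLayer", kind = kind, weights = A, bias = b,
        seed = as.integer(seed))
  })
}

#' Hidden-layer output matrix
#'
#' Computes the N x J matrix H with H_ij = g(a_j, b_j, x_i):
#' sigmoid g = 1 / (1 + exp(-(a_j . x_i + b_j))), linear g = a_j . x_i +
#' b_j, Gaussian g = exp(-b_j ||x_i - a_j||^2).
#'
#' @param X numeric N x d matrix of inputs (rows = samples).
#' @param layer a [HiddenLayer-class] with matching `d`.
#' @return numeric N x J matrix.
#' @export
hiddenOutput <- function(X, layer) {
  X <- as.matrix(X)
  A <- layer@weights
  if (ncol(X) != ncol(A))
    stop("input has ", ncol(X), " columns; hidden layer expects ", ncol(A))
  switch(layer@kind,
    linear = sweep(X %*% t(A), 2L, layer@bias, "+"),
    sigmoid = 1 / (1 + exp(-sweep(X %*% t(A), 2L, layer@bias, "+"))),
    gaussian = {
      d2 <- outer(rowSums(X^2), rowSums(A^2), "+") - 2 * X %*% t(A)
      exp(-sweep(pmax(d2, 0), 2L, layer@bias, "*"))
    })
}

#' Minimum-norm least-squares output weights
#'
#' Solves W = H^+ T with the Moore-Penrose pseudoinverse computed by SVD
#' (singular values below `.Machine$double.eps * max(N, J) * s_max` are
#' dropped).  W minimises the Frobenius residual ||H W - T||_F, with the
#' minimum-norm tie-break when H is rank deficient.  No ridge term.
#'
#' @param H numeric N x J hidden-output matrix.
#' @param T numeric N x C target matrix.
#' @return numeric J x C weight matrix.
#' @export
solveOutputWeights <- function(H, T) {
  H <- as.matrix(H); T <- as.matrix(T)
  if (nrow(H) != nrow(T)) stop("H and T must have equal row counts")
  s <- svd(H)
  tol <- .Machine$double.eps * max(dim(H)) * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(H), ncol(T),
                                dimnames = list(NULL, colnames(T))))
  W <- s$v[, keep, drop = FALSE] %*%
    (crossprod(s$u[, keep, drop = FALSE], T) / s$d[keep])
  colnames(W) <- colnames(T)
  W
}

#' Train a single SLFN by the basic ELM
#'
#' Draws `J` random hidden nodes ([initHiddenLayer()]), computes the hidden
#' output matrix and solves the output weights in closed form
#' ([solveOutputWeights()]).  Deterministic given `seed`.
#'
#' @param X numeric N x d feature matrix (typically scaled to [-1, 1]).
#' @param labels class labels, one per row of `X`.
#' @param J number of hidden nodes.
#' @param kind activation kind, see [initHiddenLayer()].
#' @param seed integer seed.
#' @param classLevels optional fixed class ordering.
#' @param scaler optional [FeatureScaler-class] stored with the model.
#' @return an [SLFNModel-class].
#' @examples
#' set.seed(1)
#' X <- matrix(runif(40), 20, 2)
#' y <- ifelse(X[, 1] > X[, 2], "a", "b")
#' m <- trainELM(X, y, J = 10, seed = 7)
#' mean(predict(m, X) == y)
#' @export
trainELM <- function(X, labels, J = 100, kind = "sigmoid", seed,
                     classLevels = NULL, scaler = NULL) {
  X <- as.matrix(X)
  T <- encodeTargets(labels, classLevels)
  layer <- initHiddenLayer(J, ncol(X), kind, seed)
  W <- solveOutputWeights(hiddenOutput(X, layer), T)
  new("SLFNModel", hidden = layer, outputWeights = W,
      classLevels = colnames(T), scaler = scaler)
}

#' Network decision values
#'
#' Returns the raw SLFN outputs O = H W, one column per class; the
#' predicted class of a row is its largest entry (ties -> smallest class
#' index).
#'
#' @param model an [SLFNModel-class].
#' @param X numeric matrix with the training input dimension.
#' @return numeric N x C matrix.
#' @export
decisionMatrix <- function(model, X) {
  hiddenOutput(X, model@hidden) %*% model@outputWeights
}

.argmaxLabels <- function(O, classLevels) {
  classLevels[max.col(O, ties.method = "first")]
}

#' Predict class labels with a fitted SLFN
#'
#' @param object an [SLFNModel-class].
#' @param newdata numeric feature matrix (same columns as training).
#' @param type `"class"` (default) for labels or `"decision"` for the raw
#'   output matrix.
#' @return character vector of labels, or the decision matrix.
#' @export
setMethod("predict", "SLFNModel", function(object, newdata,
                                           type = c("class", "decision")) {
  type <- match.arg(type)
  O <- decisionMatrix(object, newdata)
  if (type == "decision") O else .argmaxLabels(O, object@classLevels)
})

setMethod("show", "SLFNModel", function(object) {
  cat(sprintf("SLFN trained by ELM: %d %s hidden nodes, %d classes (seed %d)\n",
              nrow(object@hidden@weights), object@hidden@kind,
              length(object@classLevels), object@hidden@seed))
})

#' Save / load a fitted model
#'
#' Serialises a model (single SLFN or ensemble) with all hidden parameters,
#' output weights, class ordering and scaler, so that a reloaded model
#' reproduces bit-identical predictions.
#'
#' @param model model object.
#' @param path archive path.
#' @return `saveModel`: `path` invisibly; `loadModel`: the model.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
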
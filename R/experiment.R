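## Repeated-trial experiment runner: the fixed-split and the
## mixed-then-randomly-split evaluation protocols, averaged over trials.

#' Accuracy and confusion counts of a fitted model
#'
#' @param model an [SLFNModel-class] or [ELMEnsemble-class].
#' @param X numeric test feature matrix.
#' @param labels true labels; labels unseen in training are counted as
#'   errors with a warning.
#' @return list with `accuracy` (correct / total) and `confusion` (a
#'   contingency table, rows = truth, columns = prediction).
#' @export
evaluateModel <- function(model, X, labels) {
  labels <- as.character(labels)
  lv <- if (is(model, "ELMEnsemble")) model@classLevels else model@classLevels
  if (any(!labels %in% lv))
    warning("test labels unseen in training counted as errors: ",
            paste(unique(setdiff(labels, lv)), collapse = ", "))
  pred <- predict(model, X)
  list(accuracy = mean(pred == labels),
       confusion = table(truth = factor(labels, unique(c(lv, labels))),
                         prediction = factor(pred, lv)))
}

.defaultSeparation <- 0.40

.trainByName <- function(algorithm, X, labels, J, K, activation, seed,
                         classLevels, scaler) {
  switch(algorithm,
    elm = trainELM(X, labels, J = J, kind = activation, seed = seed,
                   classLevels = classLevels, scaler = scaler),
    opelm = trainOPELM(X, labels, Jmax = J, kind = activation, seed = seed,
                       classLevels = classLevels, scaler = scaler),
    velm = trainEnsemble(X, labels, K = K %||% 7L, baseKind = "elm", J = J,
                         kind = activation, masterSeed = seed,
                         classLevels = classLevels, scaler = scaler),
    vopelm = trainEnsemble(X, labels, K = K %||% 3L, baseKind = "opelm",
                           J = J, kind = activation, masterSeed = seed,
                           classLevels = classLevels, scaler = scaler))
}

## one train/test replicate: generate data, scale features on the training
## split only, fit, and score; returns scaled features too so callers can
## fit several algorithms on the identical replicate
.makeReplicate <- function(profiles, trainSizes, testSizes, splitMode,
                           nTrain, trialSeed) {
  seeds <- deriveSeeds(trialSeed, 3L)
  if (splitMode == "fixed") {
    train <- generateDataset(profiles, trainSizes, seeds[1], idPrefix = "tr")
    test <- generateDataset(profiles, testSizes, seeds[2], idPrefix = "te")
  } else {
    pool <- generateDataset(profiles, trainSizes + testSizes, seeds[1])
    sp <- splitDataset(pool, nTrain = nTrain, seed = seeds[2])
    train <- sp$train
    test <- sp$test
  }
  scaler <- fitScaler(datasetFeatures(train))
  list(Xtrain = applyScaler(scaler, datasetFeatures(train)),
       ytrain = as.character(train@labels),
       Xtest = applyScaler(scaler, datasetFeatures(test)),
       ytest = as.character(test@labels),
       scaler = scaler, modelSeed = seeds[3])
}

#' Run a repeated-trial classification experiment on synthetic data
#'
#' Mirrors the benchmark protocol: per trial a synthetic superfamily
#' dataset is drawn (profiles fixed across trials), features are scaled to
#' [-1, 1] on the training split only, the chosen algorithm is trained and
#' its test classification rate recorded; the mean rate and its standard
#' deviation over trials summarise the run.  `splitMode = "fixed"` draws a
#' training set with `trainSizes` and a test set with `testSizes`
#' (defaults: the pir1 / pir2 imbalance layouts); `splitMode = "random"`
#' mixes both and splits `nTrain` / rest at random each trial.
#'
#' @param algorithm `"elm"`, `"opelm"`, `"velm"` or `"vopelm"`.
#' @param trials number of independent trials (default 50).
#' @param activation activation kind (default `"sigmoid"`).
#' @param J hidden nodes (ELM members) or initial pool `Jmax` (OP-ELM).
#' @param K ensemble size; defaults to 7 (`velm`) / 3 (`vopelm`).
#' @param nClasses,separation,lengthRange synthetic-profile parameters,
#'   see [makeProfiles()].  The default `separation` places a single ELM
#'   in the 85-90% test-rate regime under the default layout.
#' @param trainSizes,testSizes per-class sizes of the fixed-mode train and
#'   test sets (and of the random-mode pool, summed).
#' @param splitMode `"fixed"` or `"random"`.
#' @param nTrain training size in random mode (default 949).
#' @param seed master seed; every reported number is a pure function of
#'   the configuration and this seed.
#' @return a [TrialReport-class].
#' @export
runExperiment <- function(algorithm = c("elm", "opelm", "velm", "vopelm"),
                          trials = 50, activation = "sigmoid", J = 500,
                          K = NULL, nClasses = 10,
                          separation = .defaultSeparation,
                          lengthRange = c(50L, 400L),
                          trainSizes = pirClassSizes("pir1"),
                          testSizes = pirClassSizes("pir2"),
                          splitMode = c("fixed", "random"), nTrain = 949,
                          seed) {
  algorithm <- match.arg(algorithm)
  splitMode <- match.arg(splitMode)
  stopifnot(trials >= 1)
  profiles <- makeProfiles(nClasses, separation, seed = seed,
                           lengthRange = lengthRange)
  classLevels <- sort(vapply(profiles, function(p) p@name, character(1)))
  trialSeeds <- deriveSeeds(seed, trials)
  acc <- numeric(trials)
  wall <- numeric(trials)
  for (t in seq_len(trials)) {
    rep <- .makeReplicate(profiles, trainSizes, testSizes, splitMode,
                          nTrain, trialSeeds[t])
    t0 <- proc.time()[["elapsed"]]
    model <- .trainByName(algorithm, rep$Xtrain, rep$ytrain, J, K,
                          activation, rep$modelSeed, classLevels,
                          rep$scaler)
    wall[t] <- proc.time()[["elapsed"]] - t0
    acc[t] <- evaluateModel(model, rep$Xtest, rep$ytest)$accuracy
  }
  new("TrialReport", algorithm = algorithm, accuracy = acc,
      wallTime = wall,
      config = list(algorithm = algorithm, trials = trials,
                    activation = activation, J = J, K = K,
                    nClasses = nClasses, separation = separation,
                    splitMode = splitMode, nTrain = nTrain, seed = seed))
}

#' Paired sweep of the V-ELM ensemble size
#'
#' For each trial one ensemble of `max(Kgrid)` members is trained and the
#' vote is re-taken with the first K members for every K in the grid, so
#' the per-K accuracies are paired within a trial (the member-seed stream
#' is prefix-stable).  Returns the mean-rate curve over trials.
#'
#' @inheritParams runExperiment
#' @param Kgrid increasing ensemble sizes, e.g. `c(5, 7, 15)` or
#'   `seq(1, 51, by = 2)`.
#' @param baseKind base learner, `"elm"` (default) or `"opelm"`.
#' @return data.frame with columns `K`, `meanAccuracy`, `sdAccuracy`;
#'   attribute `"perTrial"` holds the trials x K accuracy matrix.
#' @export
sweepEnsembleSize <- function(Kgrid, trials = 50, baseKind = "elm",
                              activation = "sigmoid", J = 100,
                              nClasses = 10,
                              separation = .defaultSeparation,
                              lengthRange = c(50L, 400L),
                              trainSizes = pirClassSizes("pir1"),
                              testSizes = pirClassSizes("pir2"),
                              splitMode = c("fixed", "random"),
                              nTrain = 949, seed) {
  splitMode <- match.arg(splitMode)
  Kgrid <- sort(as.integer(Kgrid))
  profiles <- makeProfiles(nClasses, separation, seed = seed,
                           lengthRange = lengthRange)
  classLevels <- sort(vapply(profiles, function(p) p@name, character(1)))
  trialSeeds <- deriveSeeds(seed, trials)
  acc <- matrix(NA_real_, trials, length(Kgrid),
                dimnames = list(NULL, paste0("K", Kgrid)))
  for (t in seq_len(trials)) {
    rep <- .makeReplicate(profiles, trainSizes, testSizes, splitMode,
                          nTrain, trialSeeds[t])
    ens <- trainEnsemble(rep$Xtrain, rep$ytrain, K = max(Kgrid),
                         baseKind = baseKind, J = J, kind = activation,
                         masterSeed = rep$modelSeed,
                         classLevels = classLevels, scaler = rep$scaler)
    for (i in seq_along(Kgrid)) {
      pred <- predict(ens, rep$Xtest, members = seq_len(Kgrid[i]))
      acc[t, i] <- mean(pred == rep$ytest)
    }
  }
  out <- data.frame(K = Kgrid,
                    meanAccuracy = colMeans(acc),
                    sdAccuracy = apply(acc, 2L, sd))
  attr(out, "perTrial") <- acc
  out
}

#' Per-trial accuracies of a report
#'
#' @param report a [TrialReport-class].
#' @return numeric vector of per-trial test accuracies.
#' @export
trialAccuracy <- function(report) report@accuracy

#' Mean rate and deviation of a report
#'
#' @param report a [TrialReport-class].
#' @return named numeric: `rate` (mean accuracy) and `dev` (standard
#'   deviation; 0 for a single trial).
#' @export
rateDev <- function(report) {
  a <- report@accuracy
  c(rate = mean(a), dev = if (length(a) > 1L) sd(a) else 0)
}

setMethod("show", "TrialReport", function(object) {
  rd <- rateDev(object)
  cat(sprintf("%s: %d trial(s), testing rate %.2f%% (dev %.2f%%)\n",
              toupper(object@algorithm), length(object@accuracy),
              100 * rd[["rate"]], 100 * rd[["dev"]]))
})
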
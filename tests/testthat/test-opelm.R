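test_that("PRESS equals the retrain-per-sample leave-one-out error", {
  set.seed(41)
  for (i in 1:40) {
    N <- sample(15:40, 1); k <- sample(1:8, 1); C <- sample(1:3, 1)
    H <- matrix(rnorm(N * k), N)
    T <- matrix(rnorm(N * C), N)
    expect_equal(pressLooError(H, T), explicitLooError(H, T),
                 tolerance = 1e-6)
  }
})

test_that("PRESS closed forms: mean predictor and consistent systems", {
  set.seed(42)
  # single constant column: LOO residuals are (t_i - mean) * N / (N - 1)
  N <- 25
  t <- matrix(rnorm(N), N)
  expect_equal(pressLooError(matrix(1, N, 1), t),
               mean(((t - mean(t)) * N / (N - 1))^2))
  # exactly consistent target: zero LOO error
  H <- matrix(rnorm(N * 3), N)
  expect_equal(pressLooError(H, H %*% matrix(c(1, -2, 0.5, 3, 1, 1), 3)), 0,
               tolerance = 1e-20)
})

test_that("ranking matches the refit-at-every-step oracle", {
  set.seed(43)
  for (i in 1:25) {
    N <- sample(15:35, 1); J <- sample(2:9, 1); C <- sample(1:3, 1)
    H <- matrix(rnorm(N * J), N)
    T <- matrix(rnorm(N * C), N)
    expect_identical(mrsrRank(H, T), naiveMrsrRank(H, T))
  }
  expect_identical(mrsrRank(matrix(rnorm(10), 10, 1), matrix(rnorm(10))), 1L)
})

test_that("a regressor matching the response is ranked first", {
  set.seed(44)
  for (i in 1:20) {
    H <- matrix(rnorm(30 * 6), 30)
    j <- sample(6, 1)
    T <- H[, j, drop = FALSE] + 1e-4 * rnorm(30)
    expect_identical(mrsrRank(H, T)[1], j)
  }
})

test_that("on orthonormal designs the ranking sorts |correlation|", {
  set.seed(45)
  H <- qr.Q(qr(matrix(rnorm(40 * 6), 40)))
  T <- matrix(rnorm(40), 40)
  expect_identical(mrsrRank(H, T),
                   order(abs(crossprod(H, T)), decreasing = TRUE))
})

test_that("zero-variance neurons are ranked last with a warning", {
  set.seed(46)
  H <- cbind(matrix(rnorm(60), 20), 0.7)  # constant fourth column
  T <- matrix(rnorm(40), 20)
  expect_warning(ord <- mrsrRank(H, T), "zero-variance")
  expect_identical(ord[4], 4L)
})

test_that("ranking is invariant to duplicating the dataset rows", {
  set.seed(47)
  H <- matrix(rnorm(25 * 7), 25)
  T <- matrix(rnorm(50), 25)
  expect_identical(mrsrRank(H, T),
                   mrsrRank(rbind(H, H), rbind(T, T)))
})

test_that("the neuron-count curve selects the smallest argmin", {
  set.seed(48)
  H <- matrix(rnorm(30 * 6), 30)
  T <- matrix(rnorm(60), 30)
  sel <- selectNeuronCount(H, T)
  expect_length(sel$looError, 6L)
  expect_identical(sel$selectedK, which.min(sel$looError))
  loo <- vapply(1:6, function(k)
    pressLooError(H[, 1:k, drop = FALSE], T), numeric(1))
  expect_equal(sel$looError, loo, tolerance = 1e-10)
  # single candidate
  expect_identical(selectNeuronCount(H[, 1, drop = FALSE], T)$selectedK, 1L)
})

test_that("LOO selection recovers a known number of informative neurons", {
  hit <- 0
  for (s in 1:50) {
    set.seed(s)
    H <- matrix(rnorm(300 * 12), 300)
    B <- matrix(rnorm(5 * 3), 5)
    T <- H[, 1:5] %*% B + 0.1 * matrix(rnorm(300 * 3), 300)
    ord <- mrsrRank(H, T)
    sel <- selectNeuronCount(H[, ord], T)$selectedK
    if (abs(sel - 5) <= 2) hit <- hit + 1
  }
  expect_gte(hit, 40)  # >= 80% of seeds
})

test_that("pure-noise targets inflate the LOO curve beyond small k", {
  rising <- 0
  for (s in 1:25) {
    set.seed(s + 500)
    H <- matrix(rnorm(60 * 20), 60)
    T <- matrix(sample(c(-1, 1), 120, replace = TRUE), 60)
    ord <- mrsrRank(H, T)
    cur <- selectNeuronCount(H[, ord], T)$looError
    if (cur[20] > min(cur)) rising <- rising + 1
  }
  expect_gte(rising, 20)  # overfit detected in >= 80% of seeds
})

test_that("pruning keeps at most Jmax neurons and is deterministic", {
  p <- smallProblem(51)
  m1 <- trainOPELM(p$Xtrain, p$ytrain, Jmax = 40, seed = 9)
  m2 <- trainOPELM(p$Xtrain, p$ytrain, Jmax = 40, seed = 9)
  expect_identical(m1@outputWeights, m2@outputWeights)
  expect_identical(m1@selectedK, m2@selectedK)
  expect_lte(nrow(m1@hidden@weights), 40L)
  expect_identical(nrow(m1@hidden@weights), m1@selectedK)
  cv <- pressCurve(m1)
  expect_identical(cv$k, 1:40)
  expect_identical(which.min(cv$looError), m1@selectedK)
})

test_that("pruned fit trades training residual for LOO error", {
  p <- smallProblem(52, perClassTrain = 20)
  mo <- trainOPELM(p$Xtrain, p$ytrain, Jmax = 50, seed = 13)
  T <- encodeTargets(p$ytrain)
  layer <- initHiddenLayer(50, ncol(p$Xtrain), "sigmoid", seed = 13)
  H <- hiddenOutput(p$Xtrain, layer)
  resFull <- sum((H %*% solveOutputWeights(H, T) - T)^2)
  Hp <- hiddenOutput(p$Xtrain, mo@hidden)
  resPruned <- sum((Hp %*% mo@outputWeights - T)^2)
  expect_gte(resPruned, resFull - 1e-8)
  expect_lte(mo@looError[mo@selectedK], mo@looError[50] + 1e-12)
})

test_that("pruning does not hurt generalisation in the overfitting regime", {
  wins <- 0
  for (s in 1:15) {
    p <- smallProblem(s * 11, nClasses = 6, perClassTrain = 30,
                      perClassTest = 30, separation = 0.4)
    aELM <- mean(predict(trainELM(p$Xtrain, p$ytrain, J = 100,
                                  seed = s), p$Xtest) == p$ytest)
    aOP <- mean(predict(trainOPELM(p$Xtrain, p$ytrain, Jmax = 100,
                                   seed = s), p$Xtest) == p$ytest)
    if (aOP >= aELM) wins <- wins + 1
  }
  expect_gte(wins, 11)  # >= 70% of seeds
})
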
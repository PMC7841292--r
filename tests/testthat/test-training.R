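tinyDataset <- function(n = 2L, canvas = 16L, seed = 9L)
  makeDataset(nTrain = n, nTest = 1L, canvas = c(canvas, canvas),
              nFrames = 4L, seed = seed)

tinySchedule <- function(seed = 3L)
  trainSchedule(tTrain = 50, seed = seed, readoutEpochs = 50L)

test_that("layer-wise staging never touches other layers", {
  cfg <- networkConfig(inputShape = c(16L, 16L),
                       layers = list(convLayerSpec(3L, 2L),
                                     convLayerSpec(3L, 2L)), seed = 2L)
  net <- buildNetwork(cfg)
  k2 <- layerKernels(net, 2); m1 <- memoryKernels(net, 1)
  s <- tinyDataset()$train[[1]]
  r <- framesToSpikes(s@frames, tObs = 50, seed = 1)
  runRaster(net, r, learnLayer = 1)
  expect_identical(layerKernels(net, 2), k2)   # upper layer untouched
  expect_identical(memoryKernels(net, 1), m1)  # memory frozen until transfer
  ## and training layer 2 leaves layer 1 alone
  transferConductance(net, 1)
  k1 <- layerKernels(net, 1)
  resetNetworkState(net)
  runRaster(net, r, learnLayer = 2)
  expect_identical(layerKernels(net, 1), k1)
})

test_that("training is reproducible from the seed", {
  ds <- tinyDataset()
  cfg <- smallConfig(depth = 2L)
  run <- function() {
    net <- buildNetwork(cfg)
    layerwiseTrain(net, ds$train, tinySchedule(), stdpParams())
    layerKernels(net, 1)
  }
  expect_identical(run(), run())
})

test_that("features reset between sequences and respect their bounds", {
  ds <- tinyDataset()
  net <- buildNetwork(smallConfig(depth = 2L))
  layerwiseTrain(net, ds$train, tinySchedule())
  sch <- tinySchedule()
  f1 <- extractRateFeatures(net, ds$train[[1]], sch)
  ## run something else in between; features must not change
  extractRateFeatures(net, ds$train[[2]], sch)
  f1again <- extractRateFeatures(net, ds$train[[1]], sch)
  expect_identical(f1, f1again)
  ## refractory ceiling: 1000/r Hz with r = 10 ms memory neurons
  expect_true(all(f1 >= 0 & f1 <= 100))
  ## all-zero input gives a zero feature vector
  dark <- new("SequenceSample",
              frames = array(0, c(2, 16, 16)), classLabel = "dark",
              rotationLabel = "static", translationLabel = "static")
  expect_true(all(extractRateFeatures(net, dark, sch) == 0))
})

test_that("the readout solves linearly separable sections exactly", {
  set.seed(5)
  n <- 60
  cls <- factor(rep(c("a", "b"), each = n / 2))
  mot <- factor(rep(c("x", "y"), times = n / 2))
  X <- cbind(ifelse(cls == "a", 1, -1) + rnorm(n, 0, 0.05),
             ifelse(mot == "x", 1, -1) + rnorm(n, 0, 0.05),
             matrix(rnorm(n * 5, 0, 0.1), n))
  labels <- data.frame(class = cls, motion = mot)
  ro <- trainReadout(X, labels, trainSchedule(lr = 1, readoutEpochs = 200L))
  pred <- predictLabels(ro, X)
  expect_equal(jointAccuracy(pred, labels), 1)
})

test_that("full-batch descent never increases the loss", {
  set.seed(6)
  X <- matrix(rnorm(40 * 4), 40)
  labels <- data.frame(y = factor(rep(c("p", "q"), 20)))
  ro <- trainReadout(X, labels,
                     trainSchedule(lr = 0.05, readoutEpochs = 100L,
                                   batchSize = Inf))
  expect_true(all(diff(ro$loss) <= 1e-12))
})

test_that("a planted linear model is recovered in sign", {
  set.seed(17)
  n <- 500; p <- 12
  X <- matrix(rnorm(n * p), n)
  ## antisymmetric unit pairs: the class boundary direction is identifiable
  w1 <- sample(c(-1, 1), p, replace = TRUE)
  w3 <- sample(c(-1, 1), p, replace = TRUE)
  Wtrue <- cbind(w1, -w1, w3, -w3)
  Z <- X %*% Wtrue
  labels <- data.frame(
    s1 = factor(c("u", "v")[max.col(Z[, 1:2])]),
    s2 = factor(c("u", "v")[max.col(Z[, 3:4])]))
  ro <- trainReadout(X, labels,
                     trainSchedule(lr = 1, readoutEpochs = 400L,
                                   batchSize = 64L))
  What <- ro$W[-1, ]                   # drop bias
  agree <- mean(sign(What) == sign(Wtrue))
  expect_gte(agree, 0.95)
})

test_that("objective sections are independent at prediction time", {
  set.seed(8)
  X <- matrix(rnorm(30 * 6), 30)
  labels <- data.frame(a = factor(rep(c("1", "2"), 15)),
                       b = factor(rep(c("3", "4"), each = 15)))
  ro <- trainReadout(X, labels, trainSchedule(readoutEpochs = 50L))
  base <- predictLabels(ro, X)
  ## scrambling section b's weight block leaves section a untouched
  ro2 <- ro
  ro2$W[, 3:4] <- ro$W[, sample(3:4)] * rnorm(2)
  expect_identical(predictLabels(ro2, X)$a, base$a)
  ## one-section binary prediction is a thresholded score
  roBin <- trainReadout(X, labels["a"], trainSchedule(readoutEpochs = 50L))
  Xs <- cbind(1, sweep(sweep(X, 2, roBin$center), 2, roBin$scale, "/"))
  scores <- Xs %*% roBin$W
  manual <- ifelse(scores[, 1] >= scores[, 2], "1", "2")
  expect_equal(as.character(predictLabels(roBin, X)$a), manual)
})

test_that("STDP learning extracts oriented bar kernels", {
  ## train one stack on a moving vertical bar, another on a horizontal one;
  ## the most-adapted kernel of each must match its own orientation
  ## (offset-invariant single-line templates) and differ from the other's
  thinbar <- function(orient) {
    m <- matrix(0, 9, 9)
    if (orient == "v") m[, 5] <- 1 else m[5, ] <- 1
    m
  }
  trainOn <- function(orient, dir) {
    samples <- lapply(1:3, function(i)
      renderSequence(thinbar(orient), motionSpec("constant", speed = 1),
                     motionSpec("static", "rotation"), canvas = c(24L, 24L),
                     nFrames = 6L, direction = dir, classLabel = orient))
    net <- buildNetwork(networkConfig(inputShape = c(24L, 24L),
                                      layers = list(convLayerSpec(5L, 4L)),
                                      seed = 6L), gInit = c(0.3, 0.7))
    k0 <- layerKernels(net, 1)
    layerwiseTrain(net, samples,
                   trainSchedule(tTrain = 50, seed = 12L, epochs = 4L))
    K <- layerKernels(net, 1)
    drift <- vapply(1:4, function(d) sum(abs(K[, , d] - k0[, , d])),
                    numeric(1))
    K[, , which.max(drift)]
  }
  cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  lineMask <- function(orient, i) {
    m <- matrix(0, 5, 5)
    if (orient == "v") m[, i] <- 1 else m[i, ] <- 1
    as.vector(t(m))
  }
  bestMatch <- function(k, orient)
    max(vapply(1:5, function(i) cosine(k, lineMask(orient, i)), numeric(1)))
  kV <- trainOn("v", 0)
  kH <- trainOn("h", 90)
  expect_gt(bestMatch(kV, "v"), 0.7)
  expect_gt(bestMatch(kH, "h"), 0.7)
  expect_gt(bestMatch(kV, "v"), bestMatch(kV, "h"))
  expect_gt(bestMatch(kH, "h"), bestMatch(kH, "v"))
  ## the two learned kernels encode different patterns
  expect_lt(cosine(kV, kH), 0.5)
})
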
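## Layer-wise unsupervised STDP training, rate-feature extraction, and the
## supervised multi-objective readout (a single sigmoid layer trained with
## mini-batch SGD on binary cross-entropy, one one-hot block per objective).

#' Training schedule
#'
#' @param tTrain observation time per frame in ms (default 300).
#' @param fMaxHz encoder rate of a saturated pixel (default 100 Hz).
#' @param mode spike encoding mode, "poisson" or "periodic".
#' @param epochs passes over the training sequences per layer (default 1).
#' @param seed master seed; fans out to named sub-seeds for sequence
#'   shuffling, encoding and readout initialization so components can be
#'   re-run independently.
#' @param lr readout learning rate.
#' @param readoutEpochs readout SGD epochs.
#' @param batchSize readout mini-batch size (\code{Inf} = full batch).
#' @return a list of class \code{trainSchedule}.
#' @export
trainSchedule <- function(tTrain = 300, fMaxHz = 100,
                          mode = c("poisson", "periodic"), epochs = 1L,
                          seed = 1L, lr = 0.5, readoutEpochs = 300L,
                          batchSize = 16L) {
  stopifnot(tTrain > 0)
  structure(list(tTrain = tTrain, fMaxHz = fMaxHz, mode = match.arg(mode),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 lr = lr, readoutEpochs = as.integer(readoutEpochs),
                 batchSize = batchSize),
            class = "trainSchedule")
}

## deterministic sub-seed derivation, kept well below 2^31
.subSeed <- function(seed, ...) {
  k <- c(seed, ...)
  s <- 0
  for (x in k) s <- (s * 131 + as.numeric(x) + 7) %% 2147483629
  as.integer(s)
}

.encodeSample <- function(sample, schedule, seed) {
  framesToSpikes(sample@frames, fMaxHz = schedule$fMaxHz,
                 tObs = schedule$tTrain, mode = schedule$mode, seed = seed)
}

#' Layer-wise unsupervised STDP training
#'
#' Trains the convolution stack one layer at a time: for layer k, the
#' already-frozen memory modules of layers 1..k-1 run in perception mode and
#' drive layer k's learner module, which adapts its kernels by STDP over all
#' training sequences (shuffled across class and motion categories); the
#' learned kernels are then transferred to layer k's memory module before
#' layer k+1 starts.  Neuron states are reset between sequences, and layers
#' other than k are never modified.
#'
#' @param net a [Network-class] (modified in place and returned).
#' @param samples list of [SequenceSample-class] training sequences.
#' @param schedule a [trainSchedule()].
#' @param stdp a [StdpParams-class].
#' @param verbose print per-layer progress.
#' @return the trained network, invisibly.
#' @export
layerwiseTrain <- function(net, samples, schedule = trainSchedule(),
                           stdp = stdpParams(), verbose = FALSE) {
  if (length(samples) == 0L) stop("training dataset is empty")
  L <- length(net@geometry)
  for (k in seq_len(L)) {
    for (ep in seq_len(schedule$epochs)) {
      set.seed(.subSeed(schedule$seed, 1, k, ep))
      ord <- sample.int(length(samples))
      for (idx in ord) {
        raster <- .encodeSample(samples[[idx]], schedule,
                                seed = .subSeed(schedule$seed, 2, k, ep,
                                                idx))
        resetNetworkState(net)
        runRaster(net, raster, learnLayer = k, stdp = stdp,
                  accumulate = FALSE)
      }
    }
    transferConductance(net, k)
    if (verbose)
      message("layer ", k, " trained and transferred")
  }
  invisible(net)
}

#' Rate features of one sequence
#'
#' Runs a sequence through the perception path and returns the spike
#' frequency (Hz) of every last-layer memory neuron: first the long-term
#' population, then the short-term population, each flattened position-major
#' then depth.  Neuron state is reset first, so features do not depend on
#' the preceding sequence.  Values are bounded by the refractory ceiling
#' 1000/r Hz.
#'
#' @param net a trained [Network-class].
#' @param sample a [SequenceSample-class].
#' @param schedule a [trainSchedule()]; its seed (with the sample index
#'   offset \code{seedOffset}) fixes the encoder randomness.
#' @param seedOffset integer distinguishing samples (default 0).
#' @return numeric feature vector (Hz).
#' @export
extractRateFeatures <- function(net, sample, schedule = trainSchedule(),
                                seedOffset = 0L) {
  raster <- .encodeSample(sample, schedule,
                          seed = .subSeed(schedule$seed, 3, seedOffset))
  resetNetworkState(net)
  res <- runRaster(net, raster, learnLayer = 0L)
  totalMs <- res$bins
  1000 * c(as.vector(res$counts$long), as.vector(res$counts$short)) / totalMs
}

#' @rdname extractRateFeatures
#' @param samples list of samples.
#' @return \code{extractFeatureMatrix}: samples x features matrix.
#' @export
extractFeatureMatrix <- function(net, samples, schedule = trainSchedule()) {
  t(vapply(seq_along(samples), function(i)
    extractRateFeatures(net, samples[[i]], schedule, seedOffset = i),
    numeric(2 * net@geometry[[length(net@geometry)]]$nPos *
              net@geometry[[length(net@geometry)]]$depth)))
}

#' Labels of a sample list as a data.frame
#' @param samples list of [SequenceSample-class].
#' @param objectives subset of c("class", "rotation", "translation").
#' @return data.frame of factors, one column per objective.
#' @export
sampleLabelFrame <- function(samples,
                             objectives = c("class", "translation")) {
  df <- data.frame(
    class = vapply(samples, function(s) s@classLabel, character(1)),
    rotation = vapply(samples, function(s) s@rotationLabel, character(1)),
    translation = vapply(samples, function(s) s@translationLabel,
                         character(1)),
    stringsAsFactors = TRUE)
  df[, objectives, drop = FALSE]
}

#' Train the multi-objective readout
#'
#' Fits a fully connected sigmoid layer on rate features by mini-batch SGD,
#' minimizing binary cross-entropy between the concatenated per-objective
#' one-hot label blocks and the unit outputs.  Features are standardized
#' internally (the scaling is stored with the weights).
#'
#' @param features samples x features numeric matrix.
#' @param labels data.frame of factors, one column per objective (section).
#' @param schedule a [trainSchedule()] supplying lr, epochs, batch size and
#'   the initialization seed.
#' @return an object of class \code{hsnnReadout}: weights, feature scaling,
#'   section sizes and factor levels, plus the per-epoch loss trace.
#' @export
trainReadout <- function(features, labels, schedule = trainSchedule()) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (!is.data.frame(labels) || nrow(labels) != n)
    stop("labels must be a data.frame with one row per sample")
  labels[] <- lapply(labels, as.factor)
  levs <- lapply(labels, levels)
  sections <- vapply(levs, length, integer(1))
  if (any(sections < 2L))
    stop("every objective needs at least two classes")
  Y <- do.call(cbind, lapply(names(labels), function(nm) {
    m <- matrix(0, n, sections[[nm]])
    m[cbind(seq_len(n), as.integer(labels[[nm]]))] <- 1
    m
  }))
  ctr <- colMeans(features)
  scl <- apply(features, 2, sd)
  scl[scl < 1e-8] <- 1
  X <- cbind(1, sweep(sweep(features, 2, ctr), 2, scl, "/"))
  U <- ncol(Y); p <- ncol(X)
  set.seed(.subSeed(schedule$seed, 4))
  W <- matrix(rnorm(p * U, sd = 0.01), p, U)
  bs <- if (is.finite(schedule$batchSize)) min(schedule$batchSize, n) else n
  lossTrace <- numeric(schedule$readoutEpochs)
  for (ep in seq_len(schedule$readoutEpochs)) {
    ord <- if (bs < n) sample.int(n) else seq_len(n)
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      Z <- X[idx, , drop = FALSE] %*% W
      out <- 1 / (1 + exp(-Z))
      grad <- crossprod(X[idx, , drop = FALSE],
                        out - Y[idx, , drop = FALSE]) / length(idx)
      W <- W - schedule$lr * grad
    }
    out <- 1 / (1 + exp(-(X %*% W)))
    out <- pmin(pmax(out, 1e-12), 1 - 1e-12)
    lossTrace[ep] <- -mean(Y * log(out) + (1 - Y) * log(1 - out))
  }
  structure(list(W = W, center = ctr, scale = scl, sections = sections,
                 levels = levs, loss = lossTrace),
            class = "hsnnReadout")
}

#' Predict per-objective labels from rate features
#'
#' Applies the readout and takes, independently for each objective section,
#' the argmax over that section's units.  Permuting or retraining one
#' section never changes another section's prediction (disjoint weight
#' blocks over a shared feature vector).
#'
#' @param readout an \code{hsnnReadout}.
#' @param features samples x features matrix (or a single feature vector).
#' @return data.frame of predicted factors, one column per objective.
#' @export
predictLabels <- function(readout, features) {
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  X <- cbind(1, sweep(sweep(features, 2, readout$center), 2,
                      readout$scale, "/"))
  Z <- X %*% readout$W
  stopP <- cumsum(readout$sections)
  startP <- c(1L, head(stopP, -1L) + 1L)
  out <- lapply(seq_along(readout$sections), function(s) {
    block <- Z[, startP[s]:stopP[s], drop = FALSE]
    factor(readout$levels[[s]][max.col(block, ties.method = "first")],
           levels = readout$levels[[s]])
  })
  names(out) <- names(readout$sections)
  as.data.frame(out)
}

#' Joint accuracy over all objectives
#' @param pred,truth data.frames with matching objective columns.
#' @return fraction of samples with every objective predicted correctly.
#' @export
jointAccuracy <- function(pred, truth) {
  ok <- rep(TRUE, nrow(pred))
  for (nm in names(pred))
    ok <- ok & as.character(pred[[nm]]) == as.character(truth[[nm]])
  mean(ok)
}

#' End-to-end training of network and readout
#'
#' Convenience wrapper: layer-wise STDP training, conductance transfer,
#' rate-feature extraction and readout fitting on one call.
#'
#' @param samples training sequences.
#' @param config a [NetworkConfig-class].
#' @param schedule a [trainSchedule()].
#' @param objectives label columns to predict.
#' @param stdp a [StdpParams-class].
#' @return list of class \code{hsnnModel} with \code{net}, \code{readout},
#'   \code{schedule}, \code{objectives}.
#' @export
hsnnFit <- function(samples, config, schedule = trainSchedule(),
                    objectives = c("class", "translation"),
                    stdp = stdpParams()) {
  net <- buildNetwork(config)
  layerwiseTrain(net, samples, schedule, stdp)
  features <- extractFeatureMatrix(net, samples, schedule)
  readout <- trainReadout(features, sampleLabelFrame(samples, objectives),
                          schedule)
  structure(list(net = net, readout = readout, schedule = schedule,
                 objectives = objectives),
            class = "hsnnModel")
}

#' @rdname hsnnFit
#' @param model an \code{hsnnModel}.
#' @return \code{hsnnPredict}: data.frame of per-objective predictions.
#' @export
hsnnPredict <- function(model, samples) {
  features <- extractFeatureMatrix(model$net, samples, model$schedule)
  predictLabels(model$readout, features)
}
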
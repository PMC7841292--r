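## The heterogeneous spiking convolutional network: per-layer learner +
## memory modules, dual inhibition, crossover memory pathways, and the
## multi-objective prediction module (MoPM).
##
## Data flow per convolution layer:
##   learning path:   previous memory output -> learner module (plastic)
##   transfer path:   learner kernels -> memory kernels (same layer, frozen)
##   perception path: memory output (long + short populations) -> next layer
##
## Conductance tensors are stored as (kh*kw, inDepth, depth) arrays; spatial
## maps as (positions x depth) matrices with row-major positions.

## ---------------------------------------------------------------------------
## Geometry
## ---------------------------------------------------------------------------

## Output grid and per-offset input index maps for one conv layer.
## Positions are row-major; index nPixIn + 1 is the zero-padding row.
.convGeometry <- function(inH, inW, inDepth, spec) {
  kh <- spec@kernel[1]; kw <- spec@kernel[2]; s <- spec@stride
  if (spec@padding == "same") {
    outH <- ceiling(inH / s); outW <- ceiling(inW / s)
    padTop <- floor((kh - 1) / 2); padLeft <- floor((kw - 1) / 2)
  } else {
    if (kh > inH || kw > inW)
      stop("configuration error: kernel larger than feature map (",
           kh, "x", kw, " on ", inH, "x", inW, ")")
    outH <- (inH - kh) %/% s + 1L; outW <- (inW - kw) %/% s + 1L
    padTop <- 0L; padLeft <- 0L
  }
  if (outH < 1L || outW < 1L)
    stop("configuration error: empty output grid")
  nPos <- outH * outW
  oy <- rep(seq_len(outH), each = outW)   # row-major positions
  ox <- rep(seq_len(outW), times = outH)
  cy <- (oy - 1L) * s + 1L - padTop       # top-left input row of the patch
  cx <- (ox - 1L) * s + 1L - padLeft
  nOff <- kh * kw
  offsetIdx <- matrix(0L, nPos, nOff)
  o <- 0L
  for (ky in seq_len(kh)) for (kx in seq_len(kw)) {
    o <- o + 1L
    iy <- cy + ky - 1L
    ix <- cx + kx - 1L
    ok <- iy >= 1L & iy <= inH & ix >= 1L & ix <= inW
    idx <- rep(inH * inW + 1L, nPos)      # padding row
    idx[ok] <- (iy[ok] - 1L) * inW + ix[ok]
    offsetIdx[, o] <- idx
  }
  list(inH = inH, inW = inW, inDepth = inDepth, outH = outH, outW = outW,
       kh = kh, kw = kw, depth = spec@depth, nPos = nPos, nOff = nOff,
       offsetIdx = offsetIdx, thresholdScale = spec@thresholdScale)
}

## Synaptic impulse (positions x depth) from input spikes (pixels x inDepth)
## through a kernel array (nOff, inDepth, depth).
.convImpulse <- function(X, kernels, geom) {
  Xp <- rbind(X, 0)                      # padding row
  acc <- matrix(0, geom$nPos, geom$depth)
  for (o in seq_len(geom$nOff)) {
    rows <- Xp[geom$offsetIdx[, o], , drop = FALSE]
    if (any(rows != 0)) {
      k <- kernels[o, , , drop = FALSE]
      dim(k) <- c(geom$inDepth, geom$depth)
      acc <- acc + rows %*% k
    }
  }
  acc
}

## ---------------------------------------------------------------------------
## Construction
## ---------------------------------------------------------------------------

#' Count trainable parameters and state variables
#'
#' Trainable parameters are the convolution conductances,
#' \eqn{\sum_l k_h k_w d_{in} d_{out}} (single-channel input to layer 1, full
#' depth connectivity, no bias terms), plus the MoPM weight matrix when
#' prediction sections are configured.  Memory modules share the transferred
#' learner kernels and add no parameters.  State variables count one
#' membrane potential per neuron.
#'
#' @param config a [NetworkConfig-class].
#' @return named integer vector \code{c(trainable, stateVars)}.
#' @examples
#' countParameters(networkConfig())["trainable"]  # 474400
#' @export
countParameters <- function(config) {
  inDepth <- 1L
  inH <- config@inputShape[1]; inW <- config@inputShape[2]
  trainable <- 0; neurons <- 0
  for (spec in config@layers) {
    g <- .convGeometry(inH, inW, inDepth, spec)
    trainable <- trainable + g$nOff * inDepth * spec@depth
    neurons <- neurons + g$nPos * spec@depth * 3L   # learner + long + short
    inDepth <- spec@depth
    inH <- g$outH; inW <- g$outW
  }
  if (length(config@sections)) {
    nFeat <- 2L * inH * inW * inDepth    # long + short rate features
    trainable <- trainable + nFeat * sum(config@sections)
    neurons <- neurons + sum(config@sections)
  }
  c(trainable = as.integer(trainable), stateVars = as.integer(neurons))
}

#' Build a heterogeneous spiking convolutional network
#'
#' Instantiates, per convolution layer, a learner module (all learner
#' neurons, plastic) and a memory module (one long-term and one short-term
#' population sharing the transferred kernels, frozen).  Both populations
#' project forward, so every ordered long/short sequence across layers is
#' realized as a memory pathway ([networkPathways()] enumerates them by
#' traversal).  Neuron presets are taken at the calibrated operating point
#' ([calibratedNeuron()]); memory-module thresholds are scaled down by each
#' layer's \code{thresholdScale}.
#'
#' @param config a [NetworkConfig-class].
#' @param gInit range of the uniform conductance initialization.
#' @return a [Network-class].
#' @export
buildNetwork <- function(config, gInit = c(0.4, 0.6)) {
  state <- new.env(parent = emptyenv())
  geometry <- list()
  inDepth <- 1L
  inH <- config@inputShape[1]; inW <- config@inputShape[2]
  set.seed(config@seed)
  state$layers <- list()
  for (i in seq_along(config@layers)) {
    spec <- config@layers[[i]]
    g <- .convGeometry(inH, inW, inDepth, spec)
    geometry[[i]] <- g
    K <- array(runif(g$nOff * inDepth * spec@depth, gInit[1], gInit[2]),
               dim = c(g$nOff, inDepth, spec@depth))
    neurons <- list(
      learner = calibratedNeuron("learner"),
      long = .scaledThreshold(calibratedNeuron("long"), spec@thresholdScale),
      short = .scaledThreshold(calibratedNeuron("short"),
                               spec@thresholdScale))
    state$layers[[i]] <- list(learnerK = K, memK = K, neurons = neurons)
    inDepth <- spec@depth
    inH <- g$outH; inW <- g$outW
  }
  state$readout <- NULL
  net <- new("Network", config = config, geometry = geometry, state = state)
  resetNetworkState(net)
  net
}

.scaledThreshold <- function(p, scale) {
  p@vThreshold <- p@vReset + (p@vThreshold - p@vReset) * scale
  p
}

#' Reset all neuron state to defaults
#'
#' Sets every membrane to its reset potential, clears refractory counters
#' and forgets afferent spike-timing memory.  Called between sequences so
#' that features are independent of presentation order.
#'
#' @param net a [Network-class].
#' @return the network, invisibly.
#' @export
resetNetworkState <- function(net) {
  st <- net@state
  for (i in seq_along(st$layers)) {
    g <- net@geometry[[i]]
    zero <- matrix(0, g$nPos, g$depth)
    nrn <- st$layers[[i]]$neurons
    st$layers[[i]]$v <- list(learner = zero + nrn$learner@vReset,
                             long = zero + nrn$long@vReset,
                             short = zero + nrn$short@vReset)
    st$layers[[i]]$refrac <- list(learner = zero, long = zero, short = zero)
    st$layers[[i]]$lastPre <-
      matrix(-Inf, g$inH * g$inW, g$inDepth)
  }
  invisible(net)
}

#' Per-layer conductance accessors
#'
#' @param net a [Network-class].
#' @param layer layer index.
#' @return conductance array (kh*kw, inDepth, depth).
#' @export
layerKernels <- function(net, layer) net@state$layers[[layer]]$learnerK

#' @rdname layerKernels
#' @export
memoryKernels <- function(net, layer) net@state$layers[[layer]]$memK

#' Transfer learned conductances to the memory module
#'
#' Copies the learner module's kernel tensor onto the memory module of the
#' same layer; both the long-term and the short-term population read the
#' same transferred kernels.  Idempotent; memory kernels change through no
#' other operation.
#'
#' @param net a [Network-class].
#' @param layer layer index.
#' @return the network, invisibly.
#' @export
transferConductance <- function(net, layer) {
  net@state$layers[[layer]]$memK <- net@state$layers[[layer]]$learnerK
  invisible(net)
}

#' Enumerate the memory pathways of a network
#'
#' Traverses the perception-path wiring graph (every memory population of
#' layer l feeds both populations of layer l+1 through the crossover
#' connections) and returns every realized ordered type sequence.
#'
#' @param net a [Network-class].
#' @return character vector of pathways like "long-short-long".
#' @export
networkPathways <- function(net) {
  L <- length(net@geometry)
  paths <- c("long", "short")
  if (L >= 2L) for (i in 2:L) {
    ## crossover wiring: each existing trace extends into both populations
    paths <- as.vector(outer(paths, c("long", "short"), paste, sep = "-"))
  }
  sort(paths)
}

## ---------------------------------------------------------------------------
## Inhibition
## ---------------------------------------------------------------------------

#' Cross-depth inhibition
#'
#' Competition among neurons of different kernels sharing one receptive
#' field: at each spatial position with spiking candidates, exactly one
#' winner survives - the candidate with the highest pre-update membrane
#' potential, ties broken by the lowest depth index.  Losers' spikes are
#' removed and their membranes reset.
#'
#' @param spikes binary (positions x depth) candidate matrix.
#' @param vPre pre-update membrane potentials, same shape.
#' @return list with \code{spikes} (winners only) and \code{suppressed}
#'   (logical matrix of losers to reset).
#' @export
crossDepthInhibit <- function(spikes, vPre) {
  suppressed <- matrix(FALSE, nrow(spikes), ncol(spikes))
  multi <- which(rowSums(spikes) > 1)
  for (pos in multi) {
    cand <- which(spikes[pos, ] > 0)
    win <- cand[which.max(vPre[pos, cand])]   # ties: lowest depth index
    lose <- setdiff(cand, win)
    spikes[pos, lose] <- 0
    suppressed[pos, lose] <- TRUE
  }
  list(spikes = spikes, suppressed = suppressed)
}

#' Local (within-depth) inhibition
#'
#' Within one depth map, a spiking unit suppresses all other spiking units
#' within Chebyshev radius \code{radius} for the current timestep.
#' Deterministic greedy winner selection: candidates are visited in order of
#' decreasing pre-update membrane potential (ties by lowest linear index);
#' an unsuppressed candidate survives and suppresses its neighborhood.
#'
#' @param spikes binary (positions x depth) matrix.
#' @param vPre pre-update membrane potentials, same shape.
#' @param geom layer geometry (uses \code{outH}, \code{outW}).
#' @param radius Chebyshev radius (>= 1).
#' @return list with \code{spikes} and \code{suppressed} as in
#'   [crossDepthInhibit()].
#' @export
localInhibit <- function(spikes, vPre, geom, radius = 1L) {
  suppressed <- matrix(FALSE, nrow(spikes), ncol(spikes))
  if (radius < 1L) return(list(spikes = spikes, suppressed = suppressed))
  outH <- geom$outH; outW <- geom$outW
  for (d in seq_len(ncol(spikes))) {
    cand <- which(spikes[, d] > 0)
    if (length(cand) < 2L) next
    ord <- cand[order(-vPre[cand, d], cand)]
    dead <- logical(nrow(spikes))
    for (pos in ord) {
      if (dead[pos]) {
        spikes[pos, d] <- 0
        suppressed[pos, d] <- TRUE
        next
      }
      py <- (pos - 1L) %/% outW; px <- (pos - 1L) %% outW
      ys <- max(0L, py - radius):min(outH - 1L, py + radius)
      xs <- max(0L, px - radius):min(outW - 1L, px + radius)
      nb <- rep(ys * outW, each = length(xs)) + xs + 1L
      dead[nb] <- TRUE
      dead[pos] <- FALSE                 # winner itself stays
    }
  }
  list(spikes = spikes, suppressed = suppressed)
}

#' Section-lateral inhibition of the prediction module
#'
#' A spike of neuron (i, j) suppresses all other neurons of section i for
#' the current timestep; other sections are unaffected, so independent
#' objectives never interact.  Winner per section by highest membrane
#' potential, ties by lowest index within the section.
#'
#' @param spikes binary vector over MoPM units (concatenated sections).
#' @param potentials membrane potentials, same length.
#' @param sections named integer vector of section sizes; must sum to
#'   \code{length(spikes)}.
#' @return binary vector with at most one spike per section.
#' @export
sectionLateralInhibit <- function(spikes, potentials, sections) {
  if (sum(sections) != length(spikes))
    stop("section sizes must sum to the number of units")
  stopP <- cumsum(sections)
  startP <- c(1L, head(stopP, -1L) + 1L)
  out <- spikes
  for (s in seq_along(sections)) {
    idx <- startP[s]:stopP[s]
    cand <- idx[spikes[idx] > 0]
    if (length(cand) > 1L) {
      win <- cand[which.max(potentials[cand])]
      out[setdiff(cand, win)] <- 0
    }
  }
  out
}

## ---------------------------------------------------------------------------
## Forward dynamics
## ---------------------------------------------------------------------------

## One Euler step of a vectorized neuron population (dt = 1 ms).
## impulse: synaptic impulse area per unit.  Returns spikes before
## inhibition plus pre-update potentials.
.populationStep <- function(v, refrac, params, impulse) {
  vPre <- v
  active <- refrac <= 0
  vNew <- v + (params@a + params@b * v) + params@c * impulse
  v[active] <- vNew[active]
  refrac[!active] <- refrac[!active] - 1
  v[!active] <- params@vReset
  spikes <- (active & v > params@vThreshold) * 1
  list(v = v, refrac = refrac, spikes = spikes, vPre = vPre)
}

## Apply spike resets after inhibition.
.applySpikes <- function(pop, spikes, suppressed, params) {
  fired <- spikes > 0
  pop$v[fired] <- params@vReset
  pop$refrac[fired] <- params@rRefrac
  pop$v[suppressed] <- params@vReset
  pop
}

#' Advance the network by one timestep
#'
#' Propagates one 1 ms slice of input spikes along the perception path:
#' each layer's memory populations (long and short) integrate the afferent
#' spikes through the frozen memory kernels, fire, undergo local inhibition,
#' and their superimposed spike maps drive the next layer.  When
#' \code{learnLayer} is set, that layer's learner module also integrates the
#' same afferents through its plastic kernels, with cross-depth followed by
#' local inhibition, and STDP updates its kernels at each post-synaptic
#' spike (nearest afferent spike within the LTD window potentiates;
#' afferents silent over the window are depressed at the window edge).
#'
#' @param net a [Network-class].
#' @param inputSpikes binary vector over input pixels (row-major), or a
#'   (pixels x 1) matrix.
#' @param t current time in ms (used for STDP lags).
#' @param learnLayer layer index to train this step, or 0 for pure
#'   perception.
#' @param stdp a [StdpParams-class] (used when \code{learnLayer > 0}).
#' @param upToLayer run the perception path only through this many layers
#'   (default: all).
#' @return list of per-layer memory spike matrices
#'   (\code{long}, \code{short}), plus \code{learner} for the learning
#'   layer.
#' @export
forwardStep <- function(net, inputSpikes, t, learnLayer = 0L,
                        stdp = stdpParams(), upToLayer = NULL) {
  st <- net@state
  L <- if (is.null(upToLayer)) length(net@geometry)
       else min(upToLayer, length(net@geometry))
  X <- matrix(inputSpikes, ncol = 1)
  out <- vector("list", L)
  radius <- net@config@inhibitionRadius
  for (i in seq_len(L)) {
    g <- net@geometry[[i]]
    lay <- st$layers[[i]]
    if (ncol(X) != g$inDepth) stop("input depth mismatch at layer ", i)

    ## afferent timing memory first, so a spike arriving this step can pair
    ## at delta-t = 0 with the post spike it causes
    newPre <- X > 0
    lay$lastPre[newPre] <- t

    if (learnLayer == i) {
      ## learning path: afferents drive the plastic learner module
      imp <- .convImpulse(X, lay$learnerK, g)
      pop <- .populationStep(lay$v$learner, lay$refrac$learner,
                             lay$neurons$learner, imp)
      cd <- crossDepthInhibit(pop$spikes, pop$vPre)
      li <- localInhibit(cd$spikes, pop$vPre, g, radius)
      sup <- cd$suppressed | li$suppressed
      ## a winner owns its receptive field: every other depth at a winning
      ## location restarts from reset, so no two kernels accumulate toward
      ## the same pattern
      winPos <- which(rowSums(li$spikes) > 0)
      if (length(winPos)) {
        all_d <- matrix(FALSE, g$nPos, g$depth)
        all_d[winPos, ] <- TRUE
        all_d[li$spikes > 0] <- FALSE
        sup <- sup | all_d
      }
      popL <- .applySpikes(list(v = pop$v, refrac = pop$refrac), li$spikes,
                           sup, lay$neurons$learner)
      lay$v$learner <- popL$v
      lay$refrac$learner <- popL$refrac
      if (any(li$spikes > 0))
        lay$learnerK <- .stdpOnline(lay$learnerK, li$spikes, lay$lastPre,
                                    g, t, stdp)
      out[[i]]$learner <- li$spikes
    }

    ## perception path through the frozen memory populations
    memImp <- .convImpulse(X, lay$memK, g)
    spikesByPop <- list()
    for (popName in c("long", "short")) {
      pop <- .populationStep(lay$v[[popName]], lay$refrac[[popName]],
                             lay$neurons[[popName]], memImp)
      li <- localInhibit(pop$spikes, pop$vPre, g, radius)
      popS <- .applySpikes(list(v = pop$v, refrac = pop$refrac), li$spikes,
                           li$suppressed, lay$neurons[[popName]])
      lay$v[[popName]] <- popS$v
      lay$refrac[[popName]] <- popS$refrac
      spikesByPop[[popName]] <- li$spikes
      out[[i]][[popName]] <- li$spikes
    }

    st$layers[[i]] <- lay

    ## crossover superposition: both populations drive the next layer
    X <- spikesByPop$long + spikesByPop$short
  }
  out
}

## Online STDP at the post-synaptic spikes of one step.
.stdpOnline <- function(K, postSpikes, lastPre, geom, t, p) {
  posts <- which(postSpikes > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(posts))) {
    pos <- posts[r, 1]; d <- posts[r, 2]
    preIdx <- geom$offsetIdx[pos, ]
    valid <- preIdx <= nrow(lastPre)
    G <- matrix(K[, , d], geom$nOff, geom$inDepth)
    lag <- matrix(p@ltdWindow + 1, geom$nOff, geom$inDepth)
    lag[valid, ] <- t - lastPre[preIdx[valid], , drop = FALSE]
    ltp <- lag <= p@ltdWindow            # recent afferent spike: potentiate
    if (any(ltp))
      G[ltp] <- pmin(p@gMax, G[ltp] + ltpDelta(lag[ltp], G[ltp], p))
    ltd <- !ltp & valid                  # silent afferent: depress at edge
    if (any(ltd))
      G[ltd] <- pmax(p@gMin, G[ltd] - ltdDelta(p@ltdWindow, G[ltd], p))
    K[, , d] <- G
  }
  K
}

#' Run a full spike raster through the perception path
#'
#' @param net a [Network-class].
#' @param raster a [SpikeRaster-class] over the input pixels.
#' @param learnLayer layer to train (0 = perception only).
#' @param stdp a [StdpParams-class].
#' @param accumulate record last-layer memory spike counts (default TRUE).
#' @return named list: \code{counts} with per-population spike counts of the
#'   last simulated layer (matrices positions x depth), \code{bins} the
#'   number of steps.
#' @export
runRaster <- function(net, raster, learnLayer = 0L, stdp = stdpParams(),
                      accumulate = TRUE) {
  L <- length(net@geometry)
  upTo <- if (learnLayer > 0L) learnLayer else L
  gLast <- net@geometry[[upTo]]
  counts <- list(long = matrix(0, gLast$nPos, gLast$depth),
                 short = matrix(0, gLast$nPos, gLast$depth))
  bins <- nBins(raster)
  sp <- raster@spikes
  for (b in seq_len(bins)) {
    res <- forwardStep(net, sp[, b], t = b - 1, learnLayer = learnLayer,
                       stdp = stdp, upToLayer = upTo)
    if (accumulate) {
      counts$long <- counts$long + res[[upTo]]$long
      counts$short <- counts$short + res[[upTo]]$short
    }
  }
  list(counts = counts, bins = bins)
}
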
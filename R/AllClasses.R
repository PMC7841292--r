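#' @import methods
NULL

## ---------------------------------------------------------------------------
## NeuronParams
## ---------------------------------------------------------------------------

#' Leaky integrate-and-fire neuron parameters
#'
#' Parameterizes the membrane equation \eqn{dv/dt = a + b v + c I} together
#' with the spiking discontinuity (reset to \code{vReset} and a refractory
#' period of \code{rRefrac} ms once \eqn{v > vThreshold}).  The mapping to the
#' classical LIF constants is \eqn{b = -1/\tau_m} and \eqn{c = R_m/\tau_m},
#' so membrane time constant and resistance are recoverable as
#' \eqn{\tau_m = -1/b} and \eqn{R_m = -c/b}.
#'
#' @slot a numeric(1), drive term (potential units per ms).
#' @slot b numeric(1), leak coefficient (1/ms); must be negative.
#' @slot c numeric(1), input gain (potential units per unit synaptic current).
#' @slot rRefrac numeric(1), refractory period in ms (>= 0).
#' @slot vReset numeric(1), reset potential.
#' @slot vThreshold numeric(1), spiking threshold; must exceed \code{vReset}.
#'
#' @seealso [neuronParams()], [learnerNeuron()], [shortTermNeuron()],
#'   [longTermNeuron()]
#' @exportClass NeuronParams
setClass("NeuronParams",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 rRefrac = "numeric", vReset = "numeric",
                 vThreshold = "numeric"))

setValidity("NeuronParams", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!all(vapply(list(object@a, object@b, object@c, object@rRefrac,
                       object@vReset, object@vThreshold), one, logical(1))))
    msg <- c(msg, "all slots must be finite scalars")
  else {
    if (object@b >= 0) msg <- c(msg, "leak coefficient b must be negative")
    if (object@rRefrac < 0) msg <- c(msg, "refractory period must be >= 0")
    if (object@vThreshold <= object@vReset)
      msg <- c(msg, "vThreshold must exceed vReset")
  }
  if (length(msg)) msg else TRUE
})

#' Construct neuron parameters
#'
#' @param a drive term (potential units / ms).
#' @param b leak coefficient (1/ms, negative); \code{b = -1/tau_m}.
#' @param c input gain; \code{c = R_m/tau_m}.
#' @param rRefrac refractory period (ms).
#' @param vReset reset potential (defaults to 0; arbitrary potential units).
#' @param vThreshold spiking threshold (defaults to 1).
#' @return A [NeuronParams-class] object.
#' @examples
#' p <- neuronParams(a = -4.1, b = -0.01, c = 0.31, rRefrac = 20)
#' membraneTau(p)  # 100 ms
#' @export
neuronParams <- function(a, b, c, rRefrac, vReset = 0, vThreshold = 1) {
  new("NeuronParams", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      rRefrac = as.numeric(rRefrac), vReset = as.numeric(vReset),
      vThreshold = as.numeric(vThreshold))
}

#' @describeIn neuronParams membrane time constant \eqn{\tau_m = -1/b} (ms).
#' @param params a [NeuronParams-class] object.
#' @export
membraneTau <- function(params) -1 / params@b

#' @describeIn neuronParams membrane resistance \eqn{R_m = -c/b}.
#' @export
membraneResistance <- function(params) -params@c / params@b

setMethod("show", "NeuronParams", function(object) {
  cat(sprintf(
    "NeuronParams: a=%g/ms  b=%g/ms  c=%g  r=%g ms  vReset=%g  vThreshold=%g\n",
    object@a, object@b, object@c, object@rRefrac, object@vReset,
    object@vThreshold))
  invisible(object)
})

## ---------------------------------------------------------------------------
## StdpParams
## ---------------------------------------------------------------------------

#' Conductance-dependent STDP parameters
#'
#' Soft-bounded pair-based STDP.  Potentiation of a synapse at conductance G
#' decays exponentially both in the pre/post spike lag and in the distance of
#' G from its bound, so conductances approach \code{gMax}/\code{gMin}
#' asymptotically and never leave the interval.
#'
#' @slot alphaP numeric(1), LTP scale (conductance units).
#' @slot alphaD numeric(1), LTD scale.
#' @slot gMax,gMin numeric(1), conductance bounds (\code{gMax > gMin}).
#' @slot tauPot numeric(1), potentiation time constant (ms).
#' @slot tauDep numeric(1), depression time constant (ms).
#' @slot ltdWindow numeric(1), pairing horizon (ms): a post-synaptic spike with
#'   no pre-synaptic spike within this window triggers LTD at the window edge.
#'
#' @exportClass StdpParams
setClass("StdpParams",
  representation(alphaP = "numeric", alphaD = "numeric",
                 gMax = "numeric", gMin = "numeric",
                 tauPot = "numeric", tauDep = "numeric",
                 ltdWindow = "numeric"))

setValidity("StdpParams", function(object) {
  msg <- character()
  if (object@gMax <= object@gMin) msg <- c(msg, "gMax must exceed gMin")
  if (object@alphaP <= 0 || object@alphaD <= 0)
    msg <- c(msg, "alphaP and alphaD must be positive")
  if (object@tauPot <= 0 || object@tauDep <= 0)
    msg <- c(msg, "time constants must be positive")
  if (object@ltdWindow <= 0) msg <- c(msg, "ltdWindow must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct STDP parameters
#'
#' Defaults are the tuned values used throughout: small learning-rate scales
#' to avoid early convergence of the conductance distribution.
#'
#' @param alphaP LTP scale (default 0.1).
#' @param alphaD LTD scale (default 0.03).
#' @param gMax,gMin conductance bounds (default \[0, 1\]).
#' @param tauPot potentiation time constant, ms (default 10).
#' @param tauDep depression time constant, ms (default 80).
#' @param ltdWindow pairing horizon, ms (default 50); see [applyStdp()].
#' @return A [StdpParams-class] object.
#' @export
stdpParams <- function(alphaP = 0.1, alphaD = 0.03, gMax = 1.0, gMin = 0,
                       tauPot = 10, tauDep = 80, ltdWindow = 50) {
  new("StdpParams", alphaP = alphaP, alphaD = alphaD, gMax = gMax,
      gMin = gMin, tauPot = tauPot, tauDep = tauDep, ltdWindow = ltdWindow)
}

setMethod("show", "StdpParams", function(object) {
  cat(sprintf(
    "StdpParams: alphaP=%g alphaD=%g G in [%g, %g] tauPot=%g ms tauDep=%g ms ltdWindow=%g ms\n",
    object@alphaP, object@alphaD, object@gMin, object@gMax,
    object@tauPot, object@tauDep, object@ltdWindow))
  invisible(object)
})

## ---------------------------------------------------------------------------
## SpikeRaster
## ---------------------------------------------------------------------------

#' Binary spike raster on a 1 ms grid
#'
#' The universal currency between modules: a units x time-bins binary matrix,
#' at most one spike per unit per bin.  Bin k covers the half-open interval
#' \[k-1, k) ms (bins are 1-based columns).
#'
#' @slot spikes binary matrix, rows = units, columns = time bins.
#' @slot dt numeric(1), bin width in ms (fixed at 1 for rasters produced by
#'   the encoders; finer grids are used internally by the oracle simulators).
#'
#' @exportClass SpikeRaster
setClass("SpikeRaster", representation(spikes = "matrix", dt = "numeric"))

setValidity("SpikeRaster", function(object) {
  s <- object@spikes
  if (!is.numeric(s) && !is.logical(s)) return("spikes must be numeric")
  if (any(!(s %in% c(0, 1)))) return("raster must be binary (<=1 spike/bin)")
  if (length(object@dt) != 1L || object@dt <= 0) return("dt must be positive")
  TRUE
})

#' Construct a spike raster
#' @param spikes units x bins binary matrix (a vector is treated as one unit).
#' @param dt bin width in ms.
#' @return A [SpikeRaster-class] object.
#' @export
spikeRaster <- function(spikes, dt = 1) {
  if (is.vector(spikes)) spikes <- matrix(spikes, nrow = 1L)
  storage.mode(spikes) <- "double"
  new("SpikeRaster", spikes = spikes, dt = dt)
}

#' @describeIn spikeRaster number of units (rows).
#' @param x a \code{SpikeRaster}.
#' @export
nUnits <- function(x) nrow(x@spikes)

#' @describeIn spikeRaster number of time bins (columns).
#' @export
nBins <- function(x) ncol(x@spikes)

#' @describeIn spikeRaster spike times (ms, bin left edges) for one unit.
#' @param unit row index.
#' @export
spikeTimes <- function(x, unit = 1L) (which(x@spikes[unit, ] > 0) - 1) * x@dt

#' @describeIn spikeRaster total spike count per unit.
#' @export
spikeCounts <- function(x) rowSums(x@spikes)

setMethod("show", "SpikeRaster", function(object) {
  cat(sprintf("SpikeRaster: %d units x %d bins (dt = %g ms), %d spikes\n",
              nUnits(object), nBins(object), object@dt, sum(object@spikes)))
  invisible(object)
})

## ---------------------------------------------------------------------------
## PathwaySpec
## ---------------------------------------------------------------------------

#' Memory-pathway specification
#'
#' An ordered chain of neurons tagged by retention type, each with its
#' spike-accumulation count gamma (the minimal number of input spikes needed
#' to reach threshold), sharing a uniform refractory period r.  The chain's
#' rate-transfer behavior is given by [pathwayResponse()] and its retention
#' length by [retentionLength()].
#'
#' @slot types character vector of stage tags ("long", "short" or "learner").
#' @slot gamma integer vector, per-stage gamma (>= 1).
#' @slot r numeric(1), shared refractory period (ms, >= 0).
#'
#' @exportClass PathwaySpec
setClass("PathwaySpec",
  representation(types = "character", gamma = "integer", r = "numeric"))

setValidity("PathwaySpec", function(object) {
  msg <- character()
  if (length(object@types) < 1L) msg <- c(msg, "pathway must have >= 1 stage")
  if (length(object@gamma) != length(object@types))
    msg <- c(msg, "types and gamma must have equal length")
  if (any(object@gamma < 1L)) msg <- c(msg, "all gamma must be >= 1")
  if (length(object@r) != 1L || object@r < 0)
    msg <- c(msg, "r must be a single non-negative number")
  bad <- setdiff(object@types, c("long", "short", "learner"))
  if (length(bad)) msg <- c(msg, paste("unknown neuron type:", bad[1]))
  if (length(msg)) msg else TRUE
})

#' Construct a memory-pathway specification
#'
#' @param types character vector of stage neuron types, in connection order
#'   ("long", "short", or "learner").
#' @param gamma per-stage spike-accumulation counts; defaults to the per-type
#'   stage gammas of [pathwayDefaults()].
#' @param r shared refractory period in ms (default 10).
#' @return A [PathwaySpec-class] object.
#' @examples
#' pathwaySpec(c("long", "short"))
#' @export
pathwaySpec <- function(types, gamma = NULL, r = 10) {
  if (is.null(gamma)) gamma <- pathwayDefaults()$gamma[types]
  new("PathwaySpec", types = as.character(types),
      gamma = as.integer(gamma), r = as.numeric(r))
}

#' @describeIn pathwaySpec number of stages.
#' @param spec a \code{PathwaySpec}.
#' @export
pathwayLength <- function(spec) length(spec@types)

setMethod("show", "PathwaySpec", function(object) {
  cat(sprintf("PathwaySpec: %s (gamma = %s, r = %g ms)\n",
              paste(object@types, collapse = " -> "),
              paste(object@gamma, collapse = ","), object@r))
  invisible(object)
})

## ---------------------------------------------------------------------------
## CutoffModel
## ---------------------------------------------------------------------------

#' Cut-off frequency model for one neuron/synapse pair
#'
#' Holds the quantities needed to evaluate the cut-off input frequency below
#' which a post-synaptic neuron can never fire: either via the exact
#' exponential-leak form (using the effective offset \code{X}, see
#' [cutoffFrequencyExact()]) or via the constant-leak approximation (using
#' the leak slope \code{s}, see [cutoffFrequencyLinear()]).  Because the
#' reset/threshold operating point of the reference parameterization is not
#' part of the printed presets, \code{X} and \code{s} are typically calibrated
#' from a single measured cut-off with [calibrateOffset()] /
#' [calibrateLeakSlope()].
#'
#' @slot params a [NeuronParams-class].
#' @slot G numeric(1), synapse conductance.
#' @slot X numeric(1), effective offset \code{vReset + a/b} (possibly
#'   calibrated); NA when unused.
#' @slot s numeric(1), constant leak slope in potential units per ms; NA when
#'   unused.
#' @exportClass CutoffModel
setClass("CutoffModel",
  representation(params = "NeuronParams", G = "numeric",
                 X = "numeric", s = "numeric"))

#' Construct a cut-off model
#' @param params a [NeuronParams-class].
#' @param G synapse conductance (> 0).
#' @param X effective offset (potential units); default \code{vReset + a/b}
#'   from \code{params}.
#' @param s constant-leak slope (potential units per ms), optional.
#' @return A [CutoffModel-class] object.
#' @export
cutoffModel <- function(params, G, X = params@vReset + params@a / params@b,
                        s = NA_real_) {
  stopifnot(G > 0)
  new("CutoffModel", params = params, G = as.numeric(G),
      X = as.numeric(X), s = as.numeric(s))
}

setMethod("show", "CutoffModel", function(object) {
  cat(sprintf("CutoffModel: G=%g X=%g s=%s\n", object@G, object@X,
              ifelse(is.na(object@s), "NA", format(object@s))))
  invisible(object)
})

## ---------------------------------------------------------------------------
## MotionSpec
## ---------------------------------------------------------------------------

#' Motion dynamic specification
#'
#' One of the five motion dynamics applied to a sprite, for either the
#' translation or the rotation channel: static, constant speed, accelerating,
#' decelerating, or oscillating (sinusoidal).  Units are pixels/frame (and
#' pixels/frame^2) for translation, degrees/frame for rotation; oscillation
#' amplitude is in pixels (or degrees) with period in frames.
#'
#' @slot kind one of "static", "constant", "accelerating", "decelerating",
#'   "oscillating".
#' @slot appliesTo "translation" or "rotation".
#' @slot speed base speed (px/frame or deg/frame).
#' @slot accel acceleration magnitude (px/frame^2 or deg/frame^2).
#' @slot amplitude oscillation amplitude (px or deg).
#' @slot period oscillation period (frames).
#' @exportClass MotionSpec
setClass("MotionSpec",
  representation(kind = "character", appliesTo = "character",
                 speed = "numeric", accel = "numeric",
                 amplitude = "numeric", period = "numeric"))

setValidity("MotionSpec", function(object) {
  kinds <- c("static", "constant", "accelerating", "decelerating",
             "oscillating")
  msg <- character()
  if (!object@kind %in% kinds)
    msg <- c(msg, paste("kind must be one of:", paste(kinds, collapse = ", ")))
  if (!object@appliesTo %in% c("translation", "rotation"))
    msg <- c(msg, "appliesTo must be 'translation' or 'rotation'")
  vals <- c(object@speed, object@accel, object@amplitude, object@period)
  if (any(!is.finite(vals))) msg <- c(msg, "parameters must be finite")
  if (object@period <= 0) msg <- c(msg, "period must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a motion dynamic
#'
#' Default base parameters are the generator's training-set parameters
#' (P_train); see [makeDataset()].
#'
#' @param kind "static", "constant", "accelerating", "decelerating" or
#'   "oscillating".
#' @param appliesTo "translation" (default) or "rotation".
#' @param speed base speed; default 2 px/frame (translation) or 15 deg/frame
#'   (rotation).
#' @param accel acceleration magnitude; default \code{speed/5} per frame.
#' @param amplitude oscillation amplitude; default 4 px or 30 deg.
#' @param period oscillation period in frames; default 8.
#' @return A [MotionSpec-class] object.
#' @export
motionSpec <- function(kind, appliesTo = c("translation", "rotation"),
                       speed = NULL, accel = NULL, amplitude = NULL,
                       period = 8) {
  appliesTo <- match.arg(appliesTo)
  if (is.null(speed)) speed <- if (appliesTo == "translation") 2 else 15
  if (is.null(accel)) accel <- speed / 5
  if (is.null(amplitude))
    amplitude <- if (appliesTo == "translation") 4 else 30
  new("MotionSpec", kind = kind, appliesTo = appliesTo,
      speed = as.numeric(speed), accel = as.numeric(accel),
      amplitude = as.numeric(amplitude), period = as.numeric(period))
}

setMethod("show", "MotionSpec", function(object) {
  cat(sprintf("MotionSpec: %s %s (speed=%g accel=%g amp=%g period=%g)\n",
              object@kind, object@appliesTo, object@speed, object@accel,
              object@amplitude, object@period))
  invisible(object)
})

## ---------------------------------------------------------------------------
## SequenceSample
## ---------------------------------------------------------------------------

#' A rendered frame sequence with labels
#'
#' @slot frames numeric array (T, H, W) of intensities in \[0, 1\].
#' @slot classLabel character(1).
#' @slot rotationLabel character(1), the rotation dynamic kind.
#' @slot translationLabel character(1), the translation dynamic kind.
#' @exportClass SequenceSample
setClass("SequenceSample",
  representation(frames = "array", classLabel = "character",
                 rotationLabel = "character", translationLabel = "character"))

setValidity("SequenceSample", function(object) {
  f <- object@frames
  if (length(dim(f)) != 3L) return("frames must be a (T, H, W) array")
  if (any(f < 0 | f > 1)) return("frame intensities must lie in [0, 1]")
  TRUE
})

#' @describeIn renderSequence number of frames in a sample.
#' @param sample a \code{SequenceSample}.
#' @export
nFrames <- function(sample) dim(sample@frames)[1]

#' @describeIn renderSequence the (class, rotation, translation) label triple.
#' @export
sampleLabels <- function(sample) {
  c(class = sample@classLabel, rotation = sample@rotationLabel,
    translation = sample@translationLabel)
}

setMethod("show", "SequenceSample", function(object) {
  d <- dim(object@frames)
  cat(sprintf("SequenceSample: %d frames of %dx%d [class=%s rot=%s trans=%s]\n",
              d[1], d[2], d[3], object@classLabel, object@rotationLabel,
              object@translationLabel))
  invisible(object)
})

## ---------------------------------------------------------------------------
## ConvLayerSpec / NetworkConfig
## ---------------------------------------------------------------------------

#' Spiking convolution layer specification
#'
#' Each layer holds a learner module (plastic, all learner neurons) and a
#' memory module (frozen copies of the learned kernels, one long-term and one
#' short-term population).  Memory-module thresholds are scaled down by
#' \code{thresholdScale} to counteract diminishing spike frequency along the
#' layer stack.
#'
#' @slot kernel integer(2), odd (h, w) kernel size.
#' @slot depth integer(1), number of output channels (kernels).
#' @slot stride integer(1).
#' @slot padding character(1), "same" (zero padding before stride) or "valid".
#' @slot thresholdScale numeric(1) in (0, 1].
#' @slot memoryMix named numeric, fractions of long/short-term neurons in the
#'   memory module (must sum to 1); the default duplicates every depth slice
#'   into one full long-term and one full short-term population.
#' @exportClass ConvLayerSpec
setClass("ConvLayerSpec",
  representation(kernel = "integer", depth = "integer", stride = "integer",
                 padding = "character", thresholdScale = "numeric",
                 memoryMix = "numeric"))

setValidity("ConvLayerSpec", function(object) {
  msg <- character()
  if (any(object@kernel %% 2L == 0L)) msg <- c(msg, "kernel must be odd-sized")
  if (object@depth < 1L) msg <- c(msg, "depth must be >= 1")
  if (object@stride < 1L) msg <- c(msg, "stride must be >= 1")
  if (!object@padding %in% c("same", "valid"))
    msg <- c(msg, "padding must be 'same' or 'valid'")
  if (object@thresholdScale <= 0 || object@thresholdScale > 1)
    msg <- c(msg, "thresholdScale must lie in (0, 1]")
  if (abs(sum(object@memoryMix) - 1) > 1e-9)
    msg <- c(msg, "memoryMix fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a convolution layer specification
#' @param kernel (h, w) kernel size, odd.
#' @param depth number of kernels (output channels).
#' @param stride convolution stride (default 2).
#' @param padding "same" (default) or "valid".
#' @param thresholdScale memory-module threshold scaling in (0, 1].
#' @param memoryMix named fractions of long/short neurons (default 50/50,
#'   realized as one full population of each type).
#' @return A [ConvLayerSpec-class] object.
#' @export
convLayerSpec <- function(kernel, depth, stride = 2L, padding = "same",
                          thresholdScale = 1.0,
                          memoryMix = c(long = 0.5, short = 0.5)) {
  if (length(kernel) == 1L) kernel <- c(kernel, kernel)
  new("ConvLayerSpec", kernel = as.integer(kernel), depth = as.integer(depth),
      stride = as.integer(stride), padding = padding,
      thresholdScale = as.numeric(thresholdScale),
      memoryMix = memoryMix)
}

setMethod("show", "ConvLayerSpec", function(object) {
  cat(sprintf("ConvLayerSpec: [%dx%d, %d] stride %d, %s, thrScale=%g\n",
              object@kernel[1], object@kernel[2], object@depth, object@stride,
              object@padding, object@thresholdScale))
  invisible(object)
})

#' Network configuration
#'
#' @slot inputShape integer(2), (H, W) of the input frames.
#' @slot layers list of [ConvLayerSpec-class].
#' @slot sections named integer, class count per prediction objective of the
#'   multi-objective prediction module (MoPM); empty for a feature-only stack.
#' @slot inhibitionRadius integer(1), Chebyshev radius of local inhibition.
#' @slot seed integer(1), master seed for conductance initialization.
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  representation(inputShape = "integer", layers = "list",
                 sections = "integer", inhibitionRadius = "integer",
                 seed = "integer"))

setValidity("NetworkConfig", function(object) {
  if (length(object@inputShape) != 2L || any(object@inputShape < 1L))
    return("inputShape must be two positive integers")
  if (!all(vapply(object@layers, is, logical(1), "ConvLayerSpec")))
    return("layers must all be ConvLayerSpec objects")
  TRUE
})

#' Construct a network configuration
#'
#' With no arguments this returns the reference 4-layer stack
#' Conv2D\{\[3x3,32\],\[3x3,64\],\[5x5,128\],\[7x7,40\]\} with per-layer
#' memory threshold scales (1.0, 0.8, 0.6, 0.5).
#'
#' @param inputShape (H, W) input frame shape.
#' @param layers list of [ConvLayerSpec-class]; default the reference stack.
#' @param sections named integer vector of per-objective class counts
#'   (default: none, feature extractor only).
#' @param inhibitionRadius local-inhibition Chebyshev radius (default 1).
#' @param seed master seed for conductance initialization (default 1).
#' @return A [NetworkConfig-class] object.
#' @examples
#' countParameters(networkConfig())  # 474400 convolution conductances
#' @export
networkConfig <- function(inputShape = c(128L, 128L), layers = NULL,
                          sections = integer(), inhibitionRadius = 1L,
                          seed = 1L) {
  if (is.null(layers)) {
    scales <- c(1.0, 0.8, 0.6, 0.5)
    geom <- list(c(3L, 32L), c(3L, 64L), c(5L, 128L), c(7L, 40L))
    layers <- lapply(seq_along(geom), function(i)
      convLayerSpec(geom[[i]][1], geom[[i]][2], thresholdScale = scales[i]))
  }
  if (length(sections)) sections <- structure(as.integer(sections),
                                             names = names(sections))
  new("NetworkConfig", inputShape = as.integer(inputShape), layers = layers,
      sections = sections, inhibitionRadius = as.integer(inhibitionRadius),
      seed = as.integer(seed))
}

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf("NetworkConfig: input %dx%d, %d conv layer(s)\n",
              object@inputShape[1], object@inputShape[2],
              length(object@layers)))
  for (l in object@layers) show(l)
  if (length(object@sections))
    cat("  MoPM sections:",
        paste(sprintf("%s(%d)", names(object@sections), object@sections),
              collapse = ", "), "\n")
  invisible(object)
})

## ---------------------------------------------------------------------------
## Network
## ---------------------------------------------------------------------------

#' A built spiking convolutional network
#'
#' Created by [buildNetwork()].  Conductances and membrane state live in an
#' environment slot so that simulation functions can advance the network
#' without copying tensors; use the accessors ([layerKernels()],
#' [memoryKernels()], [resetNetworkState()]) rather than touching the
#' environment directly.
#'
#' @slot config the [NetworkConfig-class] used to build the network.
#' @slot geometry list of per-layer spatial grids and patch index maps.
#' @slot state environment holding conductance tensors and neuron state.
#' @exportClass Network
setClass("Network",
  representation(config = "NetworkConfig", geometry = "list",
                 state = "environment"))

setMethod("show", "Network", function(object) {
  g <- object@geometry
  cat(sprintf("Spiking convolutional network: %d layer(s)\n", length(g)))
  for (i in seq_along(g)) {
    cat(sprintf("  layer %d: %dx%dx%d units, kernels %dx%dx%d->%d\n", i,
                g[[i]]$outH, g[[i]]$outW, g[[i]]$depth,
                g[[i]]$kh, g[[i]]$kw, g[[i]]$inDepth, g[[i]]$depth))
  }
  cat(sprintf("  trainable conductances: %d\n",
              countParameters(object@config)["trainable"]))
  invisible(object)
})
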
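## Membrane dynamics of the three heterogeneous LIF neuron types:
## stepwise (forward Euler) simulation plus the closed-form solutions of the
## linear membrane ODE dv/dt = a + b v + c I.

#' Instantaneous neuron state
#'
#' @slot v numeric(1), membrane potential.
#' @slot refractoryRemaining numeric(1), ms left in the refractory period.
#' @slot lastSpikeTime numeric(1), ms, or NA if the neuron has not spiked.
#' @slot t numeric(1), elapsed simulation time in ms.
#' @exportClass NeuronState
setClass("NeuronState",
  representation(v = "numeric", refractoryRemaining = "numeric",
                 lastSpikeTime = "numeric", t = "numeric"))

#' Create a fresh neuron state
#' @param params a [NeuronParams-class]; the state starts at \code{vReset}.
#' @return A [NeuronState-class] at reset potential, non-refractory.
#' @export
neuronState <- function(params) {
  new("NeuronState", v = params@vReset, refractoryRemaining = 0,
      lastSpikeTime = NA_real_, t = 0)
}

setMethod("show", "NeuronState", function(object) {
  cat(sprintf("NeuronState: v=%g, refractory=%g ms, t=%g ms\n",
              object@v, object@refractoryRemaining, object@t))
  invisible(object)
})

## ---------------------------------------------------------------------------
## Presets
## ---------------------------------------------------------------------------

#' The three heterogeneous neuron presets
#'
#' Reference parameterizations of the three neuron types.  The learner neuron
#' has a balanced decay rate tuned for STDP learning; the short-term neuron
#' decays faster (larger \eqn{|b|}) to capture transient structure; the
#' long-term neuron decays an order of magnitude more slowly to retain input
#' over long windows.  The defining ordering constraints are
#' \eqn{a_{stn} < a_{ln} < a_{ltn}}, \eqn{b_{stn} < b_{ln} < b_{ltn}} (in
#' magnitude: short leaks fastest) and \eqn{c_{stn} > c_{ltn}} (so that the
#' slow neuron cannot also dominate in gain).
#'
#' The reset and threshold potentials are not part of the reference set and
#' default to 0 and 1; see [calibratedNeuron()] for the operating point used
#' inside networks.
#'
#' @param vReset,vThreshold reset and threshold potentials.
#' @return A [NeuronParams-class] object.
#' @examples
#' learnerNeuron()
#' @export
learnerNeuron <- function(vReset = 0, vThreshold = 1)
  neuronParams(a = -4.1, b = -0.01, c = 0.31, rRefrac = 20,
               vReset = vReset, vThreshold = vThreshold)

#' @rdname learnerNeuron
#' @export
shortTermNeuron <- function(vReset = 0, vThreshold = 1)
  neuronParams(a = -5.1, b = -0.02, c = 0.45, rRefrac = 10,
               vReset = vReset, vThreshold = vThreshold)

#' @rdname learnerNeuron
#' @export
longTermNeuron <- function(vReset = 0, vThreshold = 1)
  neuronParams(a = -1.6, b = -0.001, c = 0.16, rRefrac = 10,
               vReset = vReset, vThreshold = vThreshold)

#' @rdname learnerNeuron
#' @param type "learner", "short" or "long".
#' @export
neuronPreset <- function(type = c("learner", "short", "long"),
                         vReset = 0, vThreshold = 1) {
  switch(match.arg(type),
         learner = learnerNeuron(vReset, vThreshold),
         short = shortTermNeuron(vReset, vThreshold),
         long = longTermNeuron(vReset, vThreshold))
}

## ---------------------------------------------------------------------------
## Stepwise simulation
## ---------------------------------------------------------------------------

#' Advance a neuron by one Euler step
#'
#' Forward-Euler update of the membrane equation.  While refractory, the
#' membrane is held at \code{vReset}, input is discarded and only the
#' refractory counter advances; the refractory window blocks exactly
#' \code{rRefrac} ms of input following a spike.  The spike condition is
#' strict (\code{v > vThreshold}), evaluated after the update.
#'
#' @param state a [NeuronState-class].
#' @param params a [NeuronParams-class].
#' @param inputCurrent synaptic current for this step.  For spike input with
#'   impulse area \code{G} arriving within the step, pass \code{G/dt} so the
#'   per-spike potential jump is \code{c*G} independent of \code{dt}.
#' @param dt step size in ms (> 0); the production grid is 1 ms, finer grids
#'   serve as integration oracles.
#' @return list with elements \code{state} (updated [NeuronState-class]) and
#'   \code{spiked} (logical).
#' @examples
#' p <- learnerNeuron()
#' st <- neuronState(p)
#' stepNeuron(st, p, inputCurrent = 0, dt = 1)$state@v  # one Euler step: -4.1
#' @export
stepNeuron <- function(state, params, inputCurrent, dt = 1) {
  if (!is.finite(inputCurrent)) stop("inputCurrent must be finite")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  t <- state@t + dt
  if (state@refractoryRemaining > 0) {
    state@refractoryRemaining <- max(0, state@refractoryRemaining - dt)
    state@v <- params@vReset
    state@t <- t
    return(list(state = state, spiked = FALSE))
  }
  v <- state@v + dt * (params@a + params@b * state@v +
                         params@c * inputCurrent)
  spiked <- v > params@vThreshold
  if (spiked) {
    v <- params@vReset
    state@refractoryRemaining <- params@rRefrac
    state@lastSpikeTime <- t
  }
  state@v <- v
  state@t <- t
  list(state = state, spiked = spiked)
}

#' Simulate a neuron over a spike-train input (Euler)
#'
#' Drives a single neuron with per-bin synaptic impulse areas (sum of
#' conductances of afferents spiking in that bin) on a fixed grid.
#'
#' @param params a [NeuronParams-class].
#' @param impulse numeric vector, synaptic impulse area per bin
#'   (\code{sum(G)} of afferent spikes in the bin); converted internally to a
#'   current \code{impulse/dt}.
#' @param dt bin width in ms.
#' @param keepTrace return the full membrane trajectory (default TRUE).
#' @return list with \code{spikeBins} (1-based bin indices of output spikes),
#'   \code{spikeTimes} (ms, bin end times), and optionally \code{v}.
#' @export
simulateNeuron <- function(params, impulse, dt = 1, keepTrace = TRUE) {
  if (any(!is.finite(impulse))) stop("impulse must be finite")
  if (dt <= 0) stop("dt must be positive")
  n <- length(impulse)
  a <- params@a; b <- params@b; cc <- params@c
  vre <- params@vReset; vth <- params@vThreshold
  refSteps <- ceiling(params@rRefrac / dt)
  v <- vre
  refr <- 0L
  trace <- if (keepTrace) numeric(n) else NULL
  spikes <- integer(0)
  for (k in seq_len(n)) {
    if (refr > 0L) {
      refr <- refr - 1L
      v <- vre
    } else {
      v <- v + dt * (a + b * v) + cc * impulse[k]
      if (v > vth) {
        v <- vre
        refr <- refSteps
        spikes <- c(spikes, k)
      }
    }
    if (keepTrace) trace[k] <- v
  }
  list(spikeBins = spikes, spikeTimes = spikes * dt, v = trace)
}

#' Simulate a neuron event-by-event (exact between spikes)
#'
#' Exact integration of the membrane equation between afferent spikes (the
#' solution of the linear ODE), with a jump of \code{c*G} at each afferent
#' spike.  Input spikes falling within \code{rRefrac} ms after an output
#' spike are discarded, matching the stepwise convention.  Orders of
#' magnitude faster than fine-step Euler for sparse inputs, and used as such
#' by the cut-off bisection.
#'
#' @param params a [NeuronParams-class].
#' @param inputTimes sorted afferent spike times (ms).
#' @param G synapse conductance.
#' @return numeric vector of output spike times (ms).
#' @export
runNeuronExact <- function(params, inputTimes, G) {
  if (is.unsorted(inputTimes)) stop("inputTimes must be sorted")
  a <- params@a; b <- params@b; cc <- params@c
  vinf <- -a / b  # equilibrium of a + b v = 0
  vre <- params@vReset; vth <- params@vThreshold
  v <- vre
  tv <- 0                # time at which v is valid
  blockedUntil <- -Inf
  out <- numeric(0)
  for (ti in inputTimes) {
    if (ti <= blockedUntil) next
    if (blockedUntil > tv) {       # refractory ended: restart from reset
      v <- vre
      tv <- blockedUntil
    }
    v <- (v - vinf) * exp(b * (ti - tv)) + vinf
    v <- v + cc * G
    tv <- ti
    if (v > vth) {
      out <- c(out, ti)
      v <- vre
      blockedUntil <- ti + params@rRefrac
    }
  }
  out
}

## ---------------------------------------------------------------------------
## Closed forms
## ---------------------------------------------------------------------------

#' Membrane decay time after a single input pulse
#'
#' Time for the membrane, kicked from \code{vReset} to \code{vReset + c*I} by
#' a single input pulse at t = 0, to decay back to \code{vReset}:
#' \deqn{t_{decay} = \frac{1}{b}\left[\ln(v_{reset} + a/b) -
#'   \ln(v_{reset} + a/b + cI)\right].}
#' Both logarithm arguments must be positive, i.e. the effective offset
#' \code{X = vReset + a/b} must be positive.
#'
#' @param params a [NeuronParams-class].
#' @param inputCurrentPulse pulse amplitude I (>= 0 gives a non-negative
#'   decay time).
#' @return decay time in ms.
#' @examples
#' p <- neuronParams(a = -0.01, b = -0.01, c = 0.5, rRefrac = 0)  # X = 1
#' decayTime(p, 1)  # 100 * log(1.5) ~ 40.55 ms
#' @export
decayTime <- function(params, inputCurrentPulse) {
  X <- params@vReset + params@a / params@b
  arg2 <- X + params@c * inputCurrentPulse
  if (X <= 0)
    stop("domain error: vReset + a/b = ", format(X), " is not positive")
  if (any(arg2 <= 0))
    stop("domain error: vReset + a/b + c*I = ", format(arg2[arg2 <= 0][1]),
         " is not positive")
  (log(X) - log(arg2)) / params@b
}

#' Closed-form membrane potential under a list of afferent spikes
#'
#' The exact solution of the membrane ODE with delta-function synaptic input:
#' \deqn{v(t) = v_{reset} e^{bt} - \frac{a}{b}(1 - e^{bt}) +
#'   c\, e^{bt} \sum_i G e^{-b t_i}.}
#' Pure function of the spike history; valid while no output spike/reset has
#' occurred, which makes it the reference for sub-threshold Euler
#' trajectories.
#'
#' @param params a [NeuronParams-class].
#' @param preSpikeTimes sorted afferent spike times (ms), all <= \code{t}.
#' @param G synapse conductance (shared by the listed spikes).
#' @param t evaluation time in ms (>= 0).
#' @return membrane potential at \code{t}.
#' @export
membraneClosedForm <- function(params, preSpikeTimes, G, t) {
  if (t < 0) stop("t must be >= 0")
  if (is.unsorted(preSpikeTimes)) stop("preSpikeTimes must be sorted")
  if (length(preSpikeTimes) && any(preSpikeTimes > t))
    stop("all preSpikeTimes must be <= t")
  b <- params@b
  base <- params@vReset * exp(b * t) - (params@a / b) * (1 - exp(b * t))
  if (length(preSpikeTimes) == 0L) return(base)
  base + params@c * exp(b * t) * sum(G * exp(-b * preSpikeTimes))
}

#' Minimal number of input spikes to reach threshold (gamma)
#'
#' The per-neuron accumulation count gamma underlying the pathway response
#' calculus: the smallest number of periodic afferent spikes at rate
#' \code{fIn} that drives the membrane from reset above threshold.  The
#' leak-free approximation is
#' \code{ceiling((vThreshold - vReset)/(c*G))}; the simulated value accounts
#' for decay between spikes and is never smaller.
#'
#' @param params a [NeuronParams-class].
#' @param G synapse conductance (> 0).
#' @param fIn input spike rate in spikes/ms (> 0).
#' @param method "simulate" (event-driven, default) or "no-decay".
#' @param maxSpikes give up after this many input spikes.
#' @return integer gamma, or \code{NA_integer_} (the no-spike signal) when
#'   \code{fIn} is at or below the neuron's cut-off so that no number of
#'   spikes suffices.
#' @examples
#' p <- neuronParams(a = -1e-6, b = -1e-6, c = 0.31, rRefrac = 10)
#' gammaMinSpikes(p, G = 1, fIn = 0.1, method = "no-decay")  # ceiling(1/0.31) = 4
#' @export
gammaMinSpikes <- function(params, G, fIn,
                           method = c("simulate", "no-decay"),
                           maxSpikes = 10000L) {
  if (G <= 0 || fIn <= 0) stop("G and fIn must be positive")
  method <- match.arg(method)
  span <- params@vThreshold - params@vReset
  if (method == "no-decay") return(as.integer(ceiling(span / (params@c * G))))
  b <- params@b
  vinf <- -params@a / b
  lambda <- exp(b / fIn)
  jump <- params@c * G
  v <- params@vReset
  vPrev <- -Inf
  for (n in seq_len(maxSpikes)) {
    v <- v + jump
    if (v > params@vThreshold) return(as.integer(n))
    if (v - vPrev < 1e-14) break  # converged below threshold
    vPrev <- v
    v <- (v - vinf) * lambda + vinf
  }
  ## converged (or capped) below threshold: input rate is below cut-off
  NA_integer_
}
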
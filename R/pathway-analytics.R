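## Closed-form calculus of memory pathways (response functions, cut-off
## frequencies, retention lengths) and its cross-validation against
## event-driven spiking simulation.
##
## Internal frequency unit is spikes/ms; every user-facing argument or value
## named *Hz is in Hz (x1000).

#' Reference cut-off frequencies used for calibration
#'
#' Measured cut-off frequencies (Hz) of the three neuron presets driven by a
#' single pre-synaptic neuron through a synapse of conductance
#' \code{GRef = 0.1}.  Because the presets do not pin down the reset and
#' threshold potentials, these reference values fix the one remaining degree
#' of freedom per neuron type: [calibrateOffset()] recovers the effective
#' offset \code{X} for the exact cut-off form, and [calibrateLeakSlope()] the
#' slope of the constant-leak approximation.
#'
#' @return list with \code{f0Hz} (named vector, Hz at \code{GRef}) and
#'   \code{GRef}.
#' @export
cutoffReference <- function() {
  list(f0Hz = c(learner = 105.8, short = 78.9, long = 63.5), GRef = 0.1)
}

#' @title Neuron and pathway response functions
#' @description
#' \code{neuronResponse()} is the single-neuron rate transfer function: a
#' neuron that needs \code{gamma} input spikes to reach threshold and is
#' refractory for \code{r} ms after each output spike converts an input rate
#' \eqn{f_{in}} into
#' \deqn{F(f_{in}) = \frac{f_{in}}{\gamma + r f_{in}},}
#' i.e. one output spike per (collection time \eqn{\gamma/f_{in}} +
#' refractory \eqn{r}).  It saturates at \eqn{1/r} and vanishes at zero
#' input.
#'
#' @param fIn input spike rate(s) in spikes/ms (>= 0); vectorized.
#' @param gamma spikes needed to reach threshold (integer >= 1).
#' @param r refractory period (ms).
#' @return output rate(s) in spikes/ms.
#' @examples
#' neuronResponse(0.1, gamma = 2, r = 10)  # 1/30 spikes/ms = 33.3 Hz
#' @export
neuronResponse <- function(fIn, gamma, r) {
  if (any(fIn < 0)) stop("fIn must be >= 0")
  if (gamma < 1 || r < 0) stop("gamma must be >= 1 and r >= 0")
  ifelse(fIn == 0, 0, fIn / (gamma + r * fIn))
}

#' @rdname neuronResponse
#' @description
#' \code{pathwayResponse()} is the chained transfer function
#' \eqn{\Phi(f_{in})} of an ordered pathway \eqn{\{n_1 \dots n_m\}} with
#' per-stage counts \eqn{\gamma_i} and uniform refractory \eqn{r}:
#' \deqn{\Phi(f_{in}) = \Big(r + \frac{\prod_i \gamma_i}{f_{in}} +
#'   r \sum_{k=0}^{m-2} \prod_{j=0}^{k} \gamma_{m-j}\Big)^{-1},}
#' which is exactly the m-fold composition of \code{neuronResponse} along the
#' stage order (an algebraic identity, asserted in the test suite).  The
#' response depends on the \emph{order} of the \eqn{\gamma_i}, which is what
#' makes differently-composed memory pathways distinguishable.
#'
#' @param spec a [PathwaySpec-class].
#' @export
pathwayResponse <- function(fIn, spec) {
  if (any(fIn < 0)) stop("fIn must be >= 0")
  g <- spec@gamma
  m <- length(g)
  if (m == 0L) stop("empty pathway spec")
  r <- spec@r
  ## r * sum_{k=0}^{m-2} prod_{j=0}^{k} gamma_{m-j}
  tail_sum <- 0
  if (m >= 2L) {
    prods <- cumprod(rev(g)[seq_len(m - 1L)])  # gamma_m, gamma_m*gamma_{m-1}, ...
    tail_sum <- sum(prods)
  }
  ifelse(fIn == 0, 0, 1 / (r + prod(g) / fIn + r * tail_sum))
}

#' Are two pathway response functions distinct?
#'
#' Two pathways with the same refractory period have identical response
#' functions iff their ordered gamma sequences coincide; otherwise the
#' responses differ at every positive frequency.  Returns the verdict
#' together with a witness frequency at which the responses differ.
#'
#' @param spec1,spec2 [PathwaySpec-class] objects with equal \code{r}.
#' @param grid frequencies (spikes/ms) to scan for a witness.
#' @return list with \code{distinct} (logical) and \code{witness} (spikes/ms,
#'   or NA when the responses coincide).
#' @export
responsesDistinct <- function(spec1, spec2,
                              grid = seq(0.01, 0.2, by = 0.01)) {
  if (spec1@r != spec2@r) stop("pathways must share one refractory period")
  d <- abs(pathwayResponse(grid, spec1) - pathwayResponse(grid, spec2))
  rel <- d / pmax(pathwayResponse(grid, spec1), .Machine$double.xmin)
  hit <- which(rel > 1e-9)
  if (length(hit)) list(distinct = TRUE, witness = grid[hit[1]])
  else list(distinct = FALSE, witness = NA_real_)
}

## ---------------------------------------------------------------------------
## Cut-off frequency
## ---------------------------------------------------------------------------

#' Exact cut-off frequency of a neuron/synapse pair
#'
#' Below the cut-off input rate, the per-period leak exceeds the per-spike
#' gain \code{c*G} and a periodically driven membrane can never accumulate:
#' the post-synaptic neuron cannot fire no matter how long the input lasts.
#' Setting the per-period potential gain to zero gives
#' \deqn{f_0 = \frac{b}{\ln\!\big(X/(X + cG)\big)},}
#' with effective offset \code{X = vReset + a/b > 0}.  (The equivalent
#' algebra with a \code{-cG} denominator yields a negative period and is a
#' sign error; this form is the one whose predictions are positive and match
#' simulation.)
#'
#' @param model a [CutoffModel-class]; uses \code{X}, \code{G} and the neuron
#'   \code{b}, \code{c}.
#' @return cut-off frequency in Hz.
#' @seealso [calibrateOffset()], [cutoffFrequencyLinear()], [simulateCutoff()]
#' @export
cutoffFrequencyExact <- function(model) {
  X <- model@X
  cG <- model@params@c * model@G
  if (!is.finite(X) || X <= 0)
    stop("domain error: effective offset X = ", format(X),
         " must be positive")
  if (cG <= 0) stop("c*G must be positive")
  1000 * model@params@b / log(X / (X + cG))
}

#' Calibrate the effective offset X from one measured cut-off
#'
#' Inverts the exact cut-off form for \code{X} given one (G, f0) pair:
#' \code{X = cG * rho / (1 - rho)} with \code{rho = exp(b / f0)}.
#'
#' @param f0Hz measured cut-off (Hz) at conductance \code{GRef}.
#' @param params a [NeuronParams-class].
#' @param GRef the conductance of the measurement.
#' @return the effective offset X (potential units).
#' @examples
#' calibrateOffset(105.8, learnerNeuron(), 0.1)  # ~0.3127
#' @export
calibrateOffset <- function(f0Hz, params, GRef) {
  rho <- exp(params@b / (f0Hz / 1000))
  params@c * GRef * rho / (1 - rho)
}

#' Constant-leak cut-off frequency
#'
#' In the small-\code{cG} regime the exponential leak is indistinguishable
#' from a constant downward slope \code{s} (potential units per ms), and the
#' cut-off is where per-spike gain balances leak per input period:
#' \deqn{f_0 = \frac{s}{cG},}
#' so the cut-off scales exactly as \code{1/G}.
#'
#' @param s leak slope, potential units per ms (> 0).
#' @param c neuron input gain (> 0).
#' @param G synapse conductance (> 0).
#' @return cut-off frequency in Hz; vectorized over \code{G}.
#' @export
cutoffFrequencyLinear <- function(s, c, G) {
  if (s <= 0 || c <= 0 || any(G <= 0)) stop("s, c and G must be positive")
  1000 * s / (c * G)
}

#' @rdname cutoffFrequencyLinear
#' @param f0Hz measured cut-off (Hz) at \code{GRef}.
#' @param GRef conductance of the reference measurement.
#' @return \code{calibrateLeakSlope}: the leak slope \code{s}.
#' @export
calibrateLeakSlope <- function(f0Hz, c, GRef) {
  if (f0Hz <= 0 || c <= 0 || GRef <= 0) stop("arguments must be positive")
  (f0Hz / 1000) * c * GRef
}

#' Cut-off frequency table over a conductance grid
#'
#' Reproduces the per-type cut-off table: for each neuron type the single
#' free constant is calibrated from the [cutoffReference()] column and the
#' remaining conductances are predicted, by default with the constant-leak
#' law (exact \code{1/G} scaling).
#'
#' @param G conductance grid (default 0.1 to 0.6).
#' @param types neuron types to include.
#' @param form "linear" (constant-leak, default) or "exact".
#' @return data.frame with columns \code{type}, \code{G}, \code{f0Hz}.
#' @examples
#' subset(cutoffTable(), G == 0.6)
#' @export
cutoffTable <- function(G = seq(0.1, 0.6, by = 0.1),
                        types = c("learner", "short", "long"),
                        form = c("linear", "exact")) {
  form <- match.arg(form)
  ref <- cutoffReference()
  out <- do.call(rbind, lapply(types, function(ty) {
    p <- neuronPreset(ty)
    f0 <- if (form == "linear") {
      s <- calibrateLeakSlope(ref$f0Hz[[ty]], p@c, ref$GRef)
      cutoffFrequencyLinear(s, p@c, G)
    } else {
      X <- calibrateOffset(ref$f0Hz[[ty]], p, ref$GRef)
      vapply(G, function(g)
        cutoffFrequencyExact(cutoffModel(p, g, X = X)), numeric(1))
    }
    data.frame(type = ty, G = G, f0Hz = f0)
  }))
  rownames(out) <- NULL
  out
}

#' Neuron presets at the calibrated operating point
#'
#' The presets leave reset and threshold free; inside a network they must be
#' chosen so that rate-coded input (0 to 100 Hz) can actually drive spiking.
#' This constructor anchors the reset so that the effective offset
#' \code{vReset + a/b} equals the per-type value calibrated from
#' [cutoffReference()] - the same single constant that reproduces the
#' measured cut-offs - and places the threshold \code{span} units above
#' reset.
#'
#' @param type "learner", "short" or "long".
#' @param span threshold minus reset (potential units, default 1).
#' @return a [NeuronParams-class].
#' @export
calibratedNeuron <- function(type = c("learner", "short", "long"), span = 1) {
  type <- match.arg(type)
  p <- neuronPreset(type)
  ref <- cutoffReference()
  X <- calibrateOffset(ref$f0Hz[[type]], p, ref$GRef)
  vReset <- X - p@a / p@b
  neuronParams(p@a, p@b, p@c, p@rRefrac, vReset = vReset,
               vThreshold = vReset + span)
}

## ---------------------------------------------------------------------------
## Retention length
## ---------------------------------------------------------------------------

#' Default per-type stage parameters for pathway specs
#'
#' Stage gammas and per-type cut-off frequencies (at unit conductance, via
#' the calibrated \code{1/G} law) used when a [pathwaySpec()] or
#' [retentionLength()] call does not override them.  Long-term stages
#' integrate with negligible decay and are assigned the smaller
#' spike-accumulation count; short-term stages leak between spikes and need
#' more.  These stage defaults realize the qualitative retention ordering of
#' the model (all-short pathways shortest, all-long longest).
#'
#' @return list with \code{gamma} (named integer) and \code{fcHz} (named
#'   numeric, cut-off at G = 1).
#' @export
pathwayDefaults <- function() {
  ref <- cutoffReference()
  list(gamma = c(long = 2L, short = 3L, learner = 4L),
       fcHz = ref$f0Hz * ref$GRef)   # 1/G law evaluated at G = 1
}

#' Retention length of a memory pathway
#'
#' The longest duration over which a pathway of m >= 2 neurons can carry
#' information: the inverse of the lowest original input rate that still
#' propagates to the last stage, obtained by mapping the last neuron's
#' cut-off \eqn{f_c^m} backwards through the first m-1 stages:
#' \deqn{T = \Big(\frac{1}{f_c^m} - r - r \sum_{k=0}^{m-3}
#'   \prod_{j=0}^{k} \gamma_{m-1-j}\Big)
#'   \Big(\prod_{i=1}^{m-1} \gamma_i\Big)^{-1}.}
#' For m = 2 both sums are empty and \eqn{T = (1/f_c - r)/\gamma_1}.
#'
#' @param spec a [PathwaySpec-class] of length >= 2.
#' @param fcLast cut-off rate of the last stage in spikes/ms; default the
#'   [pathwayDefaults()] cut-off for that stage's type.
#' @return retention length in ms.  A non-positive value signals (with a
#'   warning, not an error) that the pathway cannot retain information at
#'   this cut-off.
#' @examples
#' retentionLength(pathwaySpec(c("long", "long"), gamma = c(2, 2)),
#'                 fcLast = 0.02)  # (50 - 10)/2 = 20 ms
#' @export
retentionLength <- function(spec, fcLast = NULL) {
  g <- spec@gamma
  m <- length(g)
  if (m < 2L) stop("retention is defined for pathways of length >= 2")
  if (is.null(fcLast))
    fcLast <- pathwayDefaults()$fcHz[[spec@types[m]]] / 1000
  if (fcLast <= 0) stop("fcLast must be positive")
  r <- spec@r
  tail_sum <- 0
  if (m >= 3L) {
    ## sum_{k=0}^{m-3} prod_{j=0}^{k} gamma_{m-1-j}
    prods <- cumprod(g[seq(m - 1L, 2L)])
    tail_sum <- sum(prods)
  }
  T <- (1 / fcLast - r - r * tail_sum) / prod(g[seq_len(m - 1L)])
  if (T <= 0)
    warning("pathway cannot retain information at this cut-off (T <= 0)")
  T
}

#' Numerically invert a pathway response function
#'
#' Monotone bisection for the input rate that produces a given output rate;
#' used to map downstream cut-offs back to the pathway input.
#'
#' @param spec a [PathwaySpec-class].
#' @param fOut target output rate (spikes/ms), below the saturation
#'   \code{1/r}.
#' @param tol bisection tolerance (spikes/ms).
#' @return input rate in spikes/ms.
#' @export
invertPathwayResponse <- function(spec, fOut, tol = 1e-9) {
  if (fOut <= 0) return(0)
  hi <- 1
  while (pathwayResponse(hi, spec) < fOut) {
    hi <- hi * 2
    if (hi > 1e9) stop("fOut exceeds the pathway's saturation rate")
  }
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pathwayResponse(mid, spec) < fOut) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## ---------------------------------------------------------------------------
## Simulation oracles
## ---------------------------------------------------------------------------

#' Realize a pathway stage as an integrate-and-fire neuron
#'
#' Builds neuron parameters and a conductance that implement a given
#' spike-accumulation count gamma: per-spike jump \code{c*G} slightly above
#' \code{span/gamma} with negligible leak, so exactly \code{gamma} afferent
#' spikes cross threshold.
#'
#' @param gamma target accumulation count.
#' @param r refractory period (ms).
#' @param span threshold minus reset (default 1).
#' @param leak small negative leak coefficient b (default -1e-9, effectively
#'   a pure integrator).
#' @return list with \code{params} ([NeuronParams-class]) and \code{G}.
#' @export
stageNeuron <- function(gamma, r, span = 1, leak = -1e-9) {
  params <- neuronParams(a = 0, b = leak, c = 1, rRefrac = r,
                         vReset = 0, vThreshold = span)
  list(params = params, G = span * (1 + 1e-6) / gamma)
}

#' Simulate a memory pathway and measure its output rate
#'
#' Drives a chain of spiking neurons realizing \code{spec} with periodic
#' input and returns the measured steady-state output frequency.
#'
#' Two drive conventions are provided.  \code{"aligned"} (default) simulates
#' each stage as an event-driven membrane whose afferent train restarts one
#' full input period after refractory release - the timing convention under
#' which the response calculus is derived - and chains stages by their
#' measured steady-state periods.  \code{"free"} runs the full chain on a
#' fixed Euler grid with free-running afferent phases; because a
#' free-running drive can deliver its next spike anywhere inside the
#' post-refractory window, it systematically produces rates at or above the
#' closed-form prediction unless the refractory period is commensurate with
#' the stage input period (see the methods vignette).
#'
#' @param fInHz input rate to the first stage, Hz.
#' @param spec a [PathwaySpec-class].
#' @param duration simulated time in ms (free mode) or maximum per-stage
#'   simulated time (aligned mode).
#' @param dt Euler step for free mode (ms).
#' @param mode "aligned" or "free".
#' @return measured steady-state output rate in Hz.
#' @export
simulatePathway <- function(fInHz, spec, duration = 20000, dt = 1,
                            mode = c("aligned", "free")) {
  mode <- match.arg(mode)
  f <- fInHz / 1000
  if (f <= 0) return(0)
  if (mode == "aligned") {
    periodIn <- 1 / f
    for (i in seq_along(spec@gamma)) {
      st <- stageNeuron(spec@gamma[i], spec@r)
      periodIn <- .alignedStagePeriod(st$params, st$G, periodIn, duration)
      if (!is.finite(periodIn)) return(0)
    }
    return(1000 / periodIn)
  }
  ## free-running Euler chain
  nbins <- ceiling(duration / dt)
  times <- seq(1 / f, duration, by = 1 / f)
  bins <- pmin(nbins, floor(times / dt) + 1L)
  for (i in seq_along(spec@gamma)) {
    st <- stageNeuron(spec@gamma[i], spec@r)
    impulse <- numeric(nbins)
    impulse[bins] <- impulse[bins] + st$G
    out <- simulateNeuron(st$params, impulse, dt = dt, keepTrace = FALSE)
    bins <- out$spikeBins
    if (length(bins) == 0L) return(0)
  }
  t <- bins * dt
  if (length(t) < 2L) return(0)
  keep <- t > duration * 0.2          # drop transient
  t <- t[keep]
  if (length(t) < 2L) t <- tail(bins * dt, 2L)
  1000 * (length(t) - 1) / (t[length(t)] - t[1])
}

## Steady-state output period of one stage under aligned periodic drive:
## after each output spike the afferent train restarts one period after
## refractory release.  Event-driven, exact membrane decay between spikes.
.alignedStagePeriod <- function(params, G, periodIn, duration) {
  b <- params@b
  vinf <- -params@a / b
  jump <- params@c * G
  release <- 0
  v <- params@vReset
  tv <- 0
  lastSpike <- NA_real_
  periods <- numeric(0)
  t <- release + periodIn
  while (t <= duration) {
    v <- (v - vinf) * exp(b * (t - tv)) + vinf
    v <- v + jump
    tv <- t
    if (v > params@vThreshold) {
      if (!is.na(lastSpike)) periods <- c(periods, t - lastSpike)
      lastSpike <- t
      v <- params@vReset
      release <- t + params@rRefrac
      tv <- release
      t <- release + periodIn
      if (length(periods) >= 5L &&
          abs(periods[length(periods)] - periods[length(periods) - 1L]) <
            1e-9)
        return(periods[length(periods)])
    } else {
      t <- t + periodIn
    }
  }
  if (length(periods)) periods[length(periods)] else Inf
}

#' Locate a neuron's cut-off frequency by simulation
#'
#' Bisection on "does a long periodic drive elicit any output spike",
#' using the event-driven exact simulator.  The closed-form cut-off
#' ([cutoffFrequencyExact()]) describes the input rate below which the
#' membrane can never rise above reset at spike arrival; it coincides with
#' the simulated firing boundary when the threshold sits one per-spike jump
#' above reset (\code{vThreshold - vReset = c*G}); with higher thresholds
#' the simulated boundary is strictly higher.
#'
#' @param params a [NeuronParams-class].
#' @param G synapse conductance.
#' @param bracketHz initial (low, high) bracket in Hz; low must not elicit
#'   spikes, high must.
#' @param tolHz bisection tolerance in Hz.
#' @param duration drive duration per probe (ms).
#' @return the simulated cut-off frequency (Hz).
#' @export
simulateCutoff <- function(params, G, bracketHz, tolHz = 0.5,
                           duration = 10000) {
  spikesAt <- function(fHz) {
    times <- seq(1000 / fHz, duration, by = 1000 / fHz)
    length(runNeuronExact(params, times, G)) > 0L
  }
  lo <- bracketHz[1]; hi <- bracketHz[2]
  if (spikesAt(lo)) stop("lower bracket already elicits spikes")
  if (!spikesAt(hi)) stop("upper bracket elicits no spikes")
  while (hi - lo > tolHz) {
    mid <- (lo + hi) / 2
    if (spikesAt(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
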
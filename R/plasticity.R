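## Conductance-dependent STDP with soft bounds.
##
## The update magnitudes depend on both the spike-pair lag and the current
## conductance, so repeated potentiation slows down as G approaches gMax
## (and symmetrically for depression toward gMin): conductances are soft-
## bounded and, with explicit clamping, never leave [gMin, gMax].

#' LTP increment for one spike pair
#'
#' \deqn{\Delta G_p = \alpha_p \exp\!\left(-\frac{\Delta t\,(G - G_{min})}
#'   {\tau_{pot}(G_{max} - G_{min})}\right)}
#' Vectorized over \code{deltaT} and \code{G}.  The caller clamps
#' \code{G + deltaG} to \code{gMax}.
#'
#' @param deltaT pre-to-post lag \code{tPost - tPre} in ms (>= 0).
#' @param G current conductance(s), within \code{[gMin, gMax]}.
#' @param p a [StdpParams-class].
#' @return conductance increment(s).
#' @examples
#' ltpDelta(0, 0, stdpParams())          # alphaP = 0.1
#' ltpDelta(10, 1, stdpParams())         # 0.1 * exp(-1)
#' @export
ltpDelta <- function(deltaT, G, p) {
  if (any(deltaT < 0)) stop("deltaT must be >= 0 for LTP")
  if (any(G < p@gMin - 1e-12 | G > p@gMax + 1e-12))
    stop("G outside [gMin, gMax]")
  p@alphaP * exp(-deltaT * (G - p@gMin) / (p@tauPot * (p@gMax - p@gMin)))
}

#' LTD decrement for one spike pair
#'
#' \deqn{\Delta G_d = \alpha_d \exp\!\left(-\frac{\Delta t\,(G_{max} - G)}
#'   {\tau_{dep}(G_{max} - G_{min})}\right)}
#' \code{deltaT} is the absolute lag \code{|tPost - tPre|} (a post spike that
#' precedes its nearest pre spike depresses with the absolute time
#' difference).  The caller clamps \code{G - deltaG} to \code{gMin}.
#'
#' @inheritParams ltpDelta
#' @return conductance decrement(s).
#' @export
ltdDelta <- function(deltaT, G, p) {
  if (any(deltaT < 0)) stop("deltaT must be >= 0 (use the absolute lag)")
  if (any(G < p@gMin - 1e-12 | G > p@gMax + 1e-12))
    stop("G outside [gMin, gMax]")
  p@alphaD * exp(-deltaT * (p@gMax - G) / (p@tauDep * (p@gMax - p@gMin)))
}

#' Apply STDP to a conductance matrix from a pre/post raster pair
#'
#' For every post-synaptic spike, processed in temporal order: an afferent
#' whose most recent pre-synaptic spike precedes (or coincides with) the post
#' spike within \code{ltdWindow} is potentiated with that lag; an afferent
#' whose nearest pre spike instead follows the post spike (within the window)
#' is depressed with the absolute lag; an afferent with no pre spike within
#' the window at all is depressed at the window edge
#' (\code{deltaT = ltdWindow}).  Updates use the current (already updated)
#' conductance and are clamped to \code{[gMin, gMax]} after each post spike.
#'
#' The default pairing policy is nearest-neighbor (one pre spike per post
#' spike); \code{policy = "all-pairs"} sums contributions over every pre
#' spike within the window instead.
#'
#' @param synapses conductance matrix, rows = pre units, columns = post units.
#' @param preRaster,postRaster [SpikeRaster-class] objects on the same time
#'   grid; \code{nUnits(preRaster) == nrow(synapses)} and likewise for post.
#' @param p a [StdpParams-class].
#' @param policy "nearest" (default) or "all-pairs".
#' @return the updated conductance matrix.
#' @export
applyStdp <- function(synapses, preRaster, postRaster, p,
                      policy = c("nearest", "all-pairs")) {
  policy <- match.arg(policy)
  if (!is.matrix(synapses)) synapses <- as.matrix(synapses)
  if (nUnits(preRaster) != nrow(synapses) ||
      nUnits(postRaster) != ncol(synapses))
    stop("synapse matrix shape does not match raster unit counts")
  if (nBins(preRaster) != nBins(postRaster) ||
      preRaster@dt != postRaster@dt)
    stop("pre and post rasters must share one time grid")
  dt <- preRaster@dt
  w <- p@ltdWindow
  preTimes <- lapply(seq_len(nUnits(preRaster)),
                     function(i) spikeTimes(preRaster, i))
  post <- postRaster@spikes
  postBins <- which(colSums(post) > 0)
  for (bin in postBins) {                       # temporal order
    tp <- (bin - 1) * dt
    for (j in which(post[, bin] > 0)) {
      G <- synapses[, j]
      if (policy == "nearest") {
        for (i in seq_along(preTimes)) {
          ts <- preTimes[[i]]
          before <- ts[ts <= tp & ts >= tp - w]
          if (length(before)) {
            dG <- ltpDelta(tp - max(before), G[i], p)
            G[i] <- min(p@gMax, G[i] + dG)
          } else {
            after <- ts[ts > tp & ts <= tp + w]
            lag <- if (length(after)) min(after) - tp else w
            dG <- ltdDelta(lag, G[i], p)
            G[i] <- max(p@gMin, G[i] - dG)
          }
        }
      } else {                                  # all-pairs
        for (i in seq_along(preTimes)) {
          ts <- preTimes[[i]]
          before <- ts[ts <= tp & ts >= tp - w]
          after <- ts[ts > tp & ts <= tp + w]
          if (length(before) == 0L && length(after) == 0L) {
            G[i] <- max(p@gMin, G[i] - ltdDelta(w, G[i], p))
            next
          }
          for (tb in sort(tp - before))
            G[i] <- min(p@gMax, G[i] + ltpDelta(tb, G[i], p))
          for (ta in sort(after - tp))
            G[i] <- max(p@gMin, G[i] - ltdDelta(ta, G[i], p))
        }
      }
      synapses[, j] <- G
    }
  }
  synapses
}
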
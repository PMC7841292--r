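## Rate encoding of frames into spike rasters, and accumulation of event-
## camera streams into frames.

#' Rate-encode frames into a spike raster
#'
#' Each pixel with intensity p in \[0, 1\] fires at rate \code{p * fMaxHz}
#' (zero intensity, zero spikes) for \code{tObs} ms per frame, on a 1 ms
#' grid.  Units are pixels in row-major order (row 1 left-to-right, then row
#' 2, ...).  Poisson mode (default, and the biologically standard choice for
#' a rate code) draws an independent Bernoulli(p * fMax * dt) per bin;
#' periodic mode emits evenly spaced spikes starting one full period into
#' the frame, which is the regime the response-function calculus assumes.
#' Multi-frame input is encoded frame by frame and concatenated; periodic
#' phase restarts at each frame boundary.
#'
#' @param frames numeric matrix (H, W) or array (T, H, W) with values in
#'   \[0, 1\] (divide 8-bit input by 255 on load).
#' @param fMaxHz firing rate of a saturated pixel (default 100 Hz).
#' @param tObs observation time per frame in ms (default 300).
#' @param mode "poisson" or "periodic".
#' @param seed integer seed for poisson mode (required there for
#'   reproducibility).
#' @return a [SpikeRaster-class] with H*W units and
#'   \code{tObs * nframes} bins.
#' @examples
#' r <- framesToSpikes(matrix(1, 1, 1), mode = "periodic")
#' spikeCounts(r)  # 30 spikes: 100 Hz for 300 ms
#' @export
framesToSpikes <- function(frames, fMaxHz = 100, tObs = 300,
                           mode = c("poisson", "periodic"), seed = NULL) {
  mode <- match.arg(mode)
  if (is.matrix(frames)) frames <- array(frames, c(1L, dim(frames)))
  if (length(dim(frames)) != 3L) stop("frames must be (H,W) or (T,H,W)")
  if (any(frames < 0 | frames > 1))
    stop("pixel intensities must lie in [0, 1]")
  nT <- dim(frames)[1]; H <- dim(frames)[2]; W <- dim(frames)[3]
  nPix <- H * W
  bins <- as.integer(tObs)
  out <- matrix(0, nrow = nPix, ncol = bins * nT)
  if (mode == "poisson" && !is.null(seed)) set.seed(seed)
  for (k in seq_len(nT)) {
    ## row-major pixel order: row index varies slowest
    inten <- as.vector(t(frames[k, , ]))
    cols <- (k - 1L) * bins + seq_len(bins)
    if (mode == "poisson") {
      prob <- inten * fMaxHz / 1000
      out[, cols] <- matrix(runif(nPix * bins) < prob, nPix, bins)
    } else {
      f <- inten * fMaxHz / 1000            # spikes per ms
      for (i in which(f > 0)) {
        n <- floor(f[i] * tObs)
        if (n < 1) next
        tms <- seq_len(n) / f[i]
        b <- pmin(bins, as.integer(ceiling(tms - 1e-9)))
        out[i, cols[unique(b)]] <- 1
      }
    }
  }
  spikeRaster(out, dt = 1)
}

#' Accumulate an event stream into frames
#'
#' Superimposes (t, x, y, polarity) events onto frames over fixed half-open
#' time windows: frame k collects events with
#' \code{t in [k*window, (k+1)*window)}.  Counts are normalized to \[0, 1\]
#' by the maximum bin count of the sequence.  Coordinates are 0-based with x
#' as column and y as row; out-of-bounds rows are skipped and counted.
#'
#' @param events data.frame with columns \code{t} (ms), \code{x}, \code{y},
#'   \code{p} (polarity; any coding).
#' @param window accumulation window in ms (default 20).
#' @param resolution (H, W) of the output frames.
#' @param polarity "both" (default): accumulate both polarities additively;
#'   "positive": keep only rows with \code{p > 0}.
#' @return list with \code{frames} (array (T, H, W) in \[0, 1\]),
#'   \code{counts} (same shape, raw counts) and \code{skipped} (number of
#'   out-of-bounds rows dropped).
#' @export
eventsToFrames <- function(events, window = 20, resolution,
                           polarity = c("both", "positive")) {
  polarity <- match.arg(polarity)
  stopifnot(all(c("t", "x", "y", "p") %in% names(events)))
  H <- resolution[1]; W <- resolution[2]
  if (polarity == "positive") events <- events[events$p > 0, , drop = FALSE]
  ok <- events$x >= 0 & events$x < W & events$y >= 0 & events$y < H &
    events$t >= 0
  skipped <- sum(!ok)
  if (skipped > 0)
    warning(skipped, " event(s) outside the frame bounds were skipped")
  events <- events[ok, , drop = FALSE]
  nT <- if (nrow(events)) floor(max(events$t) / window) + 1L else 1L
  counts <- array(0, c(nT, H, W))
  if (nrow(events)) {
    k <- floor(events$t / window) + 1L
    idx <- cbind(k, events$y + 1L, events$x + 1L)
    for (r in seq_len(nrow(idx)))
      counts[idx[r, 1], idx[r, 2], idx[r, 3]] <-
        counts[idx[r, 1], idx[r, 2], idx[r, 3]] + 1
  }
  mx <- max(counts)
  frames <- if (mx > 0) counts / mx else counts
  list(frames = frames, counts = counts, skipped = skipped)
}
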
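## Synthetic moving-object sequences: procedurally generated sprites placed
## on a canvas under controlled translation and rotation dynamics, plus toy
## spike patterns for unit-level fixtures.

#' Procedural sprites
#'
#' Small grayscale patches with distinct spatial structure, so that no
#' external imagery is ever required: an oriented bar, a cross, a smooth
#' Gaussian blob and a ring.  Intensities in \[0, 1\].
#'
#' @param shape "bar", "cross", "blob" or "ring".
#' @param size odd patch side length (default 9).
#' @param orientation for "bar": "vertical" or "horizontal".
#' @return numeric matrix (size, size).
#' @export
makeSprite <- function(shape = c("bar", "cross", "blob", "ring"), size = 9,
                       orientation = c("vertical", "horizontal")) {
  shape <- match.arg(shape)
  orientation <- match.arg(orientation)
  mid <- (size + 1) / 2
  idx <- seq_len(size)
  m <- matrix(0, size, size)
  thick <- max(1, round(size / 3))
  band <- abs(idx - mid) <= (thick - 1) / 2
  switch(shape,
    bar = {
      if (orientation == "vertical") m[, band] <- 1 else m[band, ] <- 1
    },
    cross = {
      m[, band] <- 1
      m[band, ] <- 1
    },
    blob = {
      d2 <- outer((idx - mid)^2, (idx - mid)^2, "+")
      m <- exp(-d2 / (2 * (size / 5)^2))
    },
    ring = {
      d <- sqrt(outer((idx - mid)^2, (idx - mid)^2, "+"))
      m[abs(d - size / 3) <= 1] <- 1
    })
  m
}

## Kinematics: scalar offset (px or deg) of one motion channel at frame t
## (t = 0, 1, ...).  Deceleration clamps the speed at zero.
.motionOffset <- function(spec, t) {
  switch(spec@kind,
    static = rep(0, length(t)),
    constant = spec@speed * t,
    accelerating = spec@speed * t + 0.5 * spec@accel * t^2,
    decelerating = {
      t0 <- if (spec@accel > 0) spec@speed / spec@accel else Inf
      ifelse(t <= t0,
             spec@speed * t - 0.5 * spec@accel * t^2,
             spec@speed * t0 - 0.5 * spec@accel * t0^2)
    },
    oscillating = spec@amplitude * sin(2 * pi * t / spec@period))
}

## Paint a sprite onto a canvas at real-valued center (cy, cx), rotated by
## theta degrees, with bilinear resampling (inverse mapping).
.placeSprite <- function(canvas, sprite, cy, cx, thetaDeg) {
  H <- nrow(canvas); W <- ncol(canvas)
  h <- nrow(sprite); w <- ncol(sprite)
  scy <- (h + 1) / 2; scx <- (w + 1) / 2
  rad <- ceiling(sqrt(h^2 + w^2) / 2) + 1
  rows <- max(1, floor(cy - rad)):min(H, ceiling(cy + rad))
  cols <- max(1, floor(cx - rad)):min(W, ceiling(cx + rad))
  if (!length(rows) || !length(cols)) return(canvas)
  th <- thetaDeg * pi / 180
  dy <- rep(rows - cy, times = length(cols))
  dx <- rep(cols - cx, each = length(rows))
  ## inverse rotation into sprite coordinates
  u <- cos(th) * dy + sin(th) * dx + scy
  v <- -sin(th) * dy + cos(th) * dx + scx
  u0 <- floor(u); v0 <- floor(v)
  fu <- u - u0; fv <- v - v0
  samp <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    out <- numeric(length(r))
    out[ok] <- sprite[cbind(r[ok], c[ok])]
    out
  }
  val <- samp(u0, v0) * (1 - fu) * (1 - fv) +
    samp(u0 + 1, v0) * fu * (1 - fv) +
    samp(u0, v0 + 1) * (1 - fu) * fv +
    samp(u0 + 1, v0 + 1) * fu * fv
  patch <- matrix(val, nrow = length(rows))
  canvas[rows, cols] <- pmax(canvas[rows, cols], patch)
  canvas
}

#' Render a moving-sprite frame sequence
#'
#' Places a sprite on a black canvas and animates it over \code{nFrames}
#' frames: frame t sits at the translation offset and orientation given by
#' the two motion dynamics (static: constant pose; constant: linear;
#' accelerating/decelerating: quadratic, with deceleration clamping the
#' speed at zero; oscillating: sinusoidal).  Rotation uses bilinear
#' resampling about the sprite center.  The start position is auto-centered
#' so the trajectory midpoint sits at the canvas center; if the sprite would
#' still leave the canvas the position is clamped at the edge (or an error
#' is raised, per \code{edge}).
#'
#' @param sprite intensity matrix in \[0, 1\].
#' @param translation,rotation [MotionSpec-class] objects (a kind string is
#'   also accepted).
#' @param canvas (H, W) canvas size (default 32 x 32).
#' @param nFrames number of frames (default 10).
#' @param seed integer; seeds the translation direction draw.
#' @param direction translation direction in degrees (0 = rightward);
#'   default drawn uniformly using \code{seed}.
#' @param classLabel label stored on the sample (default "sprite").
#' @param edge "clamp" (default) or "error" when the sprite would leave the
#'   canvas.
#' @return a [SequenceSample-class].
#' @examples
#' s <- renderSequence(makeSprite("bar"), motionSpec("constant"),
#'                     motionSpec("static", "rotation"), seed = 1)
#' nFrames(s)
#' @export
renderSequence <- function(sprite, translation, rotation,
                           canvas = c(32L, 32L), nFrames = 10L, seed = 1L,
                           direction = NULL, classLabel = "sprite",
                           edge = c("clamp", "error")) {
  edge <- match.arg(edge)
  if (is.character(translation)) translation <- motionSpec(translation)
  if (is.character(rotation)) rotation <- motionSpec(rotation, "rotation")
  H <- canvas[1]; W <- canvas[2]
  t <- seq_len(nFrames) - 1
  off <- .motionOffset(translation, t)
  ang <- .motionOffset(rotation, t)
  if (is.null(direction)) {
    set.seed(seed)
    direction <- runif(1, 0, 360)
  }
  dirR <- direction * pi / 180
  dy <- off * sin(dirR)
  dx <- off * cos(dirR)
  ## auto-center the trajectory midpoint
  cy <- (H + 1) / 2 - (min(dy) + max(dy)) / 2 + dy
  cx <- (W + 1) / 2 - (min(dx) + max(dx)) / 2 + dx
  rad <- sqrt(nrow(sprite)^2 + ncol(sprite)^2) / 2
  lo <- 1 + rad; hiY <- H - rad; hiX <- W - rad
  if (any(cy < lo | cy > hiY | cx < lo | cx > hiX)) {
    if (edge == "error") stop("sprite trajectory leaves the canvas")
    cy <- pmin(pmax(cy, lo), hiY)
    cx <- pmin(pmax(cx, lo), hiX)
  }
  frames <- array(0, c(nFrames, H, W))
  for (k in seq_len(nFrames))
    frames[k, , ] <- .placeSprite(matrix(0, H, W), sprite, cy[k], cx[k],
                                  ang[k])
  frames[frames > 1] <- 1
  new("SequenceSample", frames = frames, classLabel = classLabel,
      rotationLabel = rotation@kind, translationLabel = translation@kind)
}

#' Intensity centroid of one frame
#' @param frame intensity matrix.
#' @return c(y, x) centroid in pixel coordinates.
#' @export
frameCentroid <- function(frame) {
  s <- sum(frame)
  if (s == 0) return(c(NA_real_, NA_real_))
  c(sum(row(frame) * frame), sum(col(frame) * frame)) / s
}

## Gaussian perturbation of the dynamic parameters of one motion spec
## (test-set condition: parameters drawn around the training values).
.perturbMotion <- function(spec, sigma) {
  if (sigma == 0) return(spec)
  spec@speed <- spec@speed + rnorm(1, 0, sigma)
  spec@accel <- abs(spec@accel + rnorm(1, 0, sigma / 5))
  spec@amplitude <- spec@amplitude + rnorm(1, 0, sigma)
  spec
}

#' Generate a labeled train/test dataset of moving-sprite sequences
#'
#' Renders every combination of object class, rotation dynamic and
#' translation dynamic, \code{nTrain}/\code{nTest} sequences each, shuffled
#' across class and motion categories.  Training sequences use the exact
#' base (training) motion parameters; test sequences redraw each dynamic
#' parameter from a Gaussian centered on the training value with standard
#' deviation \code{sigmaTs}.  Hold-out experiments are supported by listing
#' the classes or dynamics to reserve for the test set.
#'
#' @param sprites named list of sprite matrices (one per object class);
#'   default two procedural classes ("bar", "cross").
#' @param translationKinds,rotationKinds character vectors of dynamics to
#'   cover (subset of static/constant/accelerating/decelerating/oscillating).
#' @param nTrain,nTest sequences per (class x rotation x translation) cell.
#' @param sigmaTs Gaussian sd of the test-set parameter perturbation.
#' @param canvas,nFrames passed to [renderSequence()].
#' @param seed master seed (shuffling, directions, perturbations).
#' @param holdoutClasses classes to exclude from training and reserve for
#'   the test set (class-agnostic motion prediction).
#' @param holdoutTranslation,holdoutRotation dynamics reserved for the test
#'   set (motion-agnostic class prediction).
#' @return list with \code{train} and \code{test}, each a list of
#'   [SequenceSample-class].
#' @export
makeDataset <- function(sprites = NULL,
                        translationKinds = c("static", "constant"),
                        rotationKinds = "static",
                        nTrain = 5L, nTest = 5L, sigmaTs = 1,
                        canvas = c(32L, 32L), nFrames = 10L, seed = 1L,
                        holdoutClasses = character(),
                        holdoutTranslation = character(),
                        holdoutRotation = character()) {
  if (is.null(sprites))
    sprites <- list(bar = makeSprite("bar"), cross = makeSprite("cross"))
  if (length(sprites) == 0L) stop("at least one object class is required")
  if (sigmaTs < 0) stop("sigmaTs must be >= 0")
  set.seed(seed)
  classes <- names(sprites)
  trClasses <- setdiff(classes, holdoutClasses)
  trTrans <- setdiff(translationKinds, holdoutTranslation)
  trRot <- setdiff(rotationKinds, holdoutRotation)
  teClasses <- if (length(holdoutClasses)) holdoutClasses else classes
  teTrans <- if (length(holdoutTranslation)) holdoutTranslation
             else translationKinds
  teRot <- if (length(holdoutRotation)) holdoutRotation else rotationKinds
  gen <- function(cls, trans, rot, n, perturb) {
    out <- list()
    for (cl in cls) for (tk in trans) for (rk in rot) for (i in seq_len(n)) {
      tSpec <- motionSpec(tk, "translation")
      rSpec <- motionSpec(rk, "rotation")
      if (perturb) {
        tSpec <- .perturbMotion(tSpec, sigmaTs)
        rSpec <- .perturbMotion(rSpec, sigmaTs)
      }
      out[[length(out) + 1L]] <- renderSequence(
        sprites[[cl]], tSpec, rSpec, canvas = canvas, nFrames = nFrames,
        direction = runif(1, 0, 360), classLabel = cl)
    }
    out[sample.int(length(out))]
  }
  list(train = gen(trClasses, trTrans, trRot, nTrain, FALSE),
       test = gen(teClasses, teTrans, teRot, nTest, TRUE))
}

#' Toy spike patterns for fixtures
#'
#' Deterministic (given the seed) single- or two-unit rasters used by the
#' plasticity and pathway tests: a periodic train, a Poisson train, a
#' two-phase frequency step, and a correlated pair with a fixed lag.
#'
#' @param pattern "periodic", "poisson", "step" or "pair".
#' @param duration raster length in ms.
#' @param seed integer seed (poisson and pair).
#' @param rateHz rate of the pattern (first phase for "step").
#' @param rate2Hz second-phase rate for "step".
#' @param stepAt phase boundary for "step" (ms; default midpoint).
#' @param lagMs lag of the second unit for "pair" (default 2 ms).
#' @return a [SpikeRaster-class] (two units for "pair", one otherwise).
#' @export
toySpikePattern <- function(pattern = c("periodic", "poisson", "step",
                                        "pair"),
                            duration = 1000, seed = 1L, rateHz = 50,
                            rate2Hz = 80, stepAt = duration / 2,
                            lagMs = 2) {
  pattern <- match.arg(pattern)
  bins <- as.integer(duration)
  periodicRow <- function(f, nb, offset = 0) {
    row <- numeric(nb)
    if (f > 0) {
      n <- floor(f * nb / 1000)
      if (n >= 1) {
        b <- as.integer(ceiling(seq_len(n) * 1000 / f - 1e-9)) + offset
        row[b[b >= 1 & b <= nb]] <- 1
      }
    }
    row
  }
  switch(pattern,
    periodic = spikeRaster(periodicRow(rateHz, bins)),
    poisson = {
      set.seed(seed)
      spikeRaster(as.numeric(runif(bins) < rateHz / 1000))
    },
    step = {
      nb1 <- as.integer(stepAt)
      spikeRaster(c(periodicRow(rateHz, nb1),
                    periodicRow(rate2Hz, bins - nb1)))
    },
    pair = {
      set.seed(seed)
      first <- as.numeric(runif(bins) < rateHz / 1000)
      lag <- as.integer(lagMs)
      second <- c(numeric(lag), first)[seq_len(bins)]
      spikeRaster(rbind(first, second))
    })
}
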
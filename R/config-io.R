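## Structured-text run configuration, raster/frame/event file formats.
##
## Formats:
##  - run configuration: YAML, strict top-level schema (unknown keys
##    rejected), lossless round-trip
##  - rasters: packed binary doubles, column-per-bin, with a one-line text
##    sidecar header "<units> <bins> <dt>"
##  - frames: directories of grayscale PNGs, or a packed array file with an
##    ASCII header line "hsnn-frames <T> <H> <W> double" followed by
##    little-endian doubles, frames in sequence order, each row-major
##  - events: delimited text with header t,x,y,p

.configKeys <- c("seed", "outputDir", "neuron", "stdp", "network",
                 "schedule", "motion")

#' Read and validate a run configuration
#'
#' @param path YAML file.
#' @return named list with the configuration.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .configKeys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' @rdname readRunConfig
#' @param cfg configuration list.
#' @export
writeRunConfig <- function(cfg, path) {
  unknown <- setdiff(names(cfg), .configKeys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Default run configuration
#' @return configuration list accepted by [readRunConfig()] consumers.
#' @export
runConfigTemplate <- function() {
  list(seed = 1L,
       outputDir = "hsnn-out",
       stdp = list(alphaP = 0.1, alphaD = 0.03, gMax = 1.0, gMin = 0,
                   tauPot = 10, tauDep = 80, ltdWindow = 50),
       network = list(inputShape = c(32L, 32L),
                      layers = list(list(kernel = 5L, depth = 8L,
                                         stride = 2L,
                                         thresholdScale = 1.0)),
                      sections = c("class", "translation"),
                      inhibitionRadius = 1L),
       schedule = list(tTrain = 100, fMaxHz = 100, mode = "poisson",
                       epochs = 1L, lr = 0.5, readoutEpochs = 300L,
                       batchSize = 16L),
       motion = list(translationKinds = c("static", "constant"),
                     rotationKinds = "static", nTrain = 5L, nTest = 8L,
                     sigmaTs = 1))
}

#' Build package objects from a configuration list
#' @param cfg configuration list (see [runConfigTemplate()]).
#' @return \code{configNetwork}: a [NetworkConfig-class].
#' @export
configNetwork <- function(cfg) {
  nw <- cfg$network
  layers <- lapply(nw$layers, function(l)
    convLayerSpec(kernel = l$kernel, depth = l$depth,
                  stride = if (is.null(l$stride)) 2L else l$stride,
                  thresholdScale = if (is.null(l$thresholdScale)) 1.0
                                   else l$thresholdScale))
  networkConfig(inputShape = nw$inputShape, layers = layers,
                sections = integer(),
                inhibitionRadius = if (is.null(nw$inhibitionRadius)) 1L
                                   else nw$inhibitionRadius,
                seed = cfg$seed)
}

#' @rdname configNetwork
#' @export
configSchedule <- function(cfg) {
  s <- cfg$schedule
  do.call(trainSchedule, c(s, list(seed = cfg$seed)))
}

#' @rdname configNetwork
#' @export
configStdp <- function(cfg) do.call(stdpParams, cfg$stdp)

## ---------------------------------------------------------------------------
## Raster IO
## ---------------------------------------------------------------------------

#' Write / read a spike raster
#'
#' Packed little-endian doubles (unit-major: all bins of unit 1, then unit
#' 2, ...) with a sidecar text header \code{<path>.hdr} holding
#' "units bins dt".
#'
#' @param raster a [SpikeRaster-class].
#' @param path output file; the header goes to \code{<path>.hdr}.
#' @return \code{writeRaster}: the path, invisibly.
#' @export
writeRaster <- function(raster, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(raster@spikes)), con, size = 8, endian = "little")
  writeLines(sprintf("%d %d %g", nUnits(raster), nBins(raster), raster@dt),
             paste0(path, ".hdr"))
  invisible(path)
}

#' @rdname writeRaster
#' @return \code{readRaster}: the [SpikeRaster-class].
#' @export
readRaster <- function(path) {
  hdr <- scan(paste0(path, ".hdr"), quiet = TRUE)
  units <- as.integer(hdr[1]); bins <- as.integer(hdr[2])
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = units * bins, size = 8,
               endian = "little")
  spikeRaster(matrix(x, nrow = units, byrow = TRUE), dt = hdr[3])
}

## ---------------------------------------------------------------------------
## Frame IO
## ---------------------------------------------------------------------------

#' Write / read frame stacks
#'
#' \code{writeFramesPNG} writes one grayscale PNG per frame into a
#' directory; \code{readFramesDir} reads every PNG back (sorted by name,
#' color images are averaged to gray, intensities already in \[0, 1\]).
#' \code{writePackedFrames}/\code{readPackedFrames} use the single-file
#' packed format (ASCII header line, then doubles, frames in order, each
#' row-major).
#'
#' @param frames (T, H, W) array in \[0, 1\].
#' @param dir,path destination.
#' @return the destination, invisibly (writers) or a (T, H, W) array
#'   (readers).
#' @export
writeFramesPNG <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(dim(frames)[1]))
    png::writePNG(frames[k, , ], file.path(dir,
                                           sprintf("frame_%04d.png", k)))
  invisible(dir)
}

#' @rdname writeFramesPNG
#' @export
readFramesDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames in ", dir)
  imgs <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- apply(m[, , 1:3, drop = FALSE], c(1, 2),
                                         mean)
    m
  })
  out <- array(0, c(length(imgs), nrow(imgs[[1]]), ncol(imgs[[1]])))
  for (k in seq_along(imgs)) out[k, , ] <- imgs[[k]]
  out
}

#' @rdname writeFramesPNG
#' @export
writePackedFrames <- function(frames, path) {
  d <- dim(frames)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("hsnn-frames %d %d %d double\n", d[1], d[2], d[3]),
            con, eos = NULL)
  body <- numeric(prod(d))
  i <- 1L
  for (k in seq_len(d[1])) {            # each frame row-major
    body[i:(i + d[2] * d[3] - 1L)] <- as.vector(t(frames[k, , ]))
    i <- i + d[2] * d[3]
  }
  writeBin(body, con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname writeFramesPNG
#' @export
readPackedFrames <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (!length(ch) || ch == "\n") break
    hdr <- c(hdr, ch)
  }
  parts <- strsplit(paste(hdr, collapse = ""), " ")[[1]]
  if (parts[1] != "hsnn-frames") stop("not a packed frames file")
  d <- as.integer(parts[2:4])
  x <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  out <- array(0, d)
  i <- 1L
  for (k in seq_len(d[1])) {
    out[k, , ] <- matrix(x[i:(i + d[2] * d[3] - 1L)], d[2], d[3],
                         byrow = TRUE)
    i <- i + d[2] * d[3]
  }
  out
}

#' Read a delimited event list
#'
#' Expects a text file with header \code{t,x,y,p}; timestamps in ms (or
#' microseconds with \code{microseconds = TRUE}).
#'
#' @param path CSV file.
#' @param microseconds divide timestamps by 1000 on load.
#' @return data.frame with columns t (ms), x, y, p.
#' @export
readEvents <- function(path, microseconds = FALSE) {
  ev <- read.csv(path)
  need <- c("t", "x", "y", "p")
  if (!all(need %in% names(ev)))
    stop("event file must have columns t,x,y,p")
  if (microseconds) ev$t <- ev$t / 1000
  ev[need]
}
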
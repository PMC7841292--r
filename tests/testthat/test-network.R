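test_that("parameter counting matches hand counts and the reference stack", {
  one <- networkConfig(inputShape = c(16L, 16L),
                       layers = list(convLayerSpec(3L, 8L)))
  expect_equal(unname(countParameters(one)["trainable"]), 72L)  # 3*3*1*8
  two <- networkConfig(inputShape = c(16L, 16L),
                       layers = list(convLayerSpec(3L, 2L),
                                     convLayerSpec(3L, 4L)))
  expect_equal(unname(countParameters(two)["trainable"]), 90L)  # 18 + 72
  ## the reference 4-layer stack: 0.474M conductances
  expect_equal(unname(countParameters(networkConfig())["trainable"]),
               474400L)
  ## MoPM weights are counted when sections are configured
  withSec <- networkConfig(inputShape = c(16L, 16L),
                           layers = list(convLayerSpec(3L, 2L)),
                           sections = c(class = 2L, translation = 2L))
  g <- 8L * 8L * 2L * 2L          # long+short rate features
  expect_equal(unname(countParameters(withSec)["trainable"]),
               18L + g * 4L)
})

test_that("network construction wires crossover pathways completely", {
  net1 <- buildNetwork(smallConfig())
  expect_setequal(networkPathways(net1), c("long", "short"))
  net2 <- buildNetwork(networkConfig(inputShape = c(16L, 16L),
                                     layers = list(convLayerSpec(3L, 2L),
                                                   convLayerSpec(3L, 2L))))
  p2 <- networkPathways(net2)
  expect_length(p2, 4L)           # every ordered {long, short}^2 sequence
  expect_setequal(p2, c("long-long", "long-short", "short-long",
                        "short-short"))
  ## the reference stack builds without error
  expect_s4_class(buildNetwork(networkConfig()), "Network")
  ## geometry errors are configuration errors
  expect_error(buildNetwork(networkConfig(inputShape = c(4L, 4L),
    layers = list(convLayerSpec(7L, 2L, padding = "valid")))),
    "kernel larger")
})

test_that("all-zero input produces no spikes, ever", {
  net <- buildNetwork(smallConfig())
  r <- spikeRaster(matrix(0, 16 * 16, 200))
  res <- runRaster(net, r)
  expect_equal(sum(res$counts$long) + sum(res$counts$short), 0)
})

test_that("forward dynamics are deterministic given seed and input", {
  s <- renderSequence(makeSprite("cross"), "constant",
                      motionSpec("static", "rotation"),
                      canvas = c(16L, 16L), seed = 2)
  r <- framesToSpikes(s@frames, tObs = 50, seed = 3)
  net1 <- buildNetwork(smallConfig())
  net2 <- buildNetwork(smallConfig())
  res1 <- runRaster(net1, r)
  res2 <- runRaster(net2, r)
  expect_identical(res1$counts, res2$counts)
  expect_gt(sum(res1$counts$short), 0)   # the drive actually spikes
})

test_that("cross-depth inhibition keeps one winner per location", {
  sp <- matrix(0, 4, 3); vp <- matrix(0, 4, 3)
  sp[2, ] <- 1                     # three candidates at one location
  vp[2, ] <- c(0.5, 0.9, 0.7)
  res <- crossDepthInhibit(sp, vp)
  expect_equal(res$spikes[2, ], c(0, 1, 0))
  expect_equal(res$suppressed[2, ], c(TRUE, FALSE, TRUE))
  ## single candidate passes unchanged
  sp1 <- matrix(0, 4, 3); sp1[1, 2] <- 1
  expect_equal(crossDepthInhibit(sp1, vp)$spikes, sp1)
  ## ties resolved toward the lowest depth index
  vp2 <- matrix(0, 4, 3); sp2 <- matrix(0, 4, 3); sp2[3, ] <- 1
  expect_equal(crossDepthInhibit(sp2, vp2)$spikes[3, ], c(1, 0, 0))
})

test_that("local inhibition suppresses only within its radius", {
  geom <- list(outH = 5L, outW = 5L)
  sp <- matrix(0, 25, 1); vp <- matrix(0, 25, 1)
  ## isolated spike passes
  sp[13, 1] <- 1
  expect_equal(localInhibit(sp, vp, geom, 1L)$spikes, sp)
  ## two spikes beyond the radius both survive
  sp2 <- matrix(0, 25, 1); sp2[c(1, 25), 1] <- 1
  expect_equal(sum(localInhibit(sp2, vp, geom, 1L)$spikes), 2)
  ## a full 3x3 cluster collapses to its strongest member
  sp3 <- matrix(0, 25, 1)
  cluster <- c(7, 8, 9, 12, 13, 14, 17, 18, 19)
  sp3[cluster, 1] <- 1
  vp3 <- matrix(0, 25, 1); vp3[13, 1] <- 1
  out <- localInhibit(sp3, vp3, geom, 1L)$spikes
  expect_equal(sum(out), 1)
  expect_equal(which(out > 0), 13L)
  ## inhibition never creates spikes
  expect_true(all(out <= sp3))
})

test_that("section-lateral inhibition isolates objectives", {
  sections <- c(class = 3L, motion = 2L)
  sp <- c(1, 1, 0, 1, 0)
  pot <- c(0.2, 0.9, 0, 0.5, 0)
  out <- sectionLateralInhibit(sp, pot, sections)
  expect_equal(out, c(0, 1, 0, 1, 0))   # both sections keep their winner
  ## one-hot per section under random drives
  set.seed(21)
  for (i in 1:50) {
    sp <- as.numeric(runif(5) < 0.6)
    pot <- runif(5)
    out <- sectionLateralInhibit(sp, pot, sections)
    expect_lte(sum(out[1:3]), 1)
    expect_lte(sum(out[4:5]), 1)
    expect_true(all(out <= sp))
  }
  expect_error(sectionLateralInhibit(c(1, 0), c(1, 0), sections), "sum")
})

test_that("conductance transfer is exact, idempotent, and memory stays frozen", {
  net <- buildNetwork(smallConfig())
  s <- renderSequence(makeSprite("bar"), "constant",
                      motionSpec("static", "rotation"),
                      canvas = c(16L, 16L), seed = 4)
  r <- framesToSpikes(s@frames, tObs = 50, seed = 5)
  mem0 <- memoryKernels(net, 1)
  runRaster(net, r, learnLayer = 1)      # STDP on the learner module
  expect_false(identical(layerKernels(net, 1), mem0))
  expect_identical(memoryKernels(net, 1), mem0)   # unchanged by learning
  transferConductance(net, 1)
  expect_identical(memoryKernels(net, 1), layerKernels(net, 1))
  transferConductance(net, 1)                      # idempotent
  expect_identical(memoryKernels(net, 1), layerKernels(net, 1))
  ## perception never touches the transferred kernels
  memT <- memoryKernels(net, 1)
  resetNetworkState(net)
  runRaster(net, r)
  expect_identical(memoryKernels(net, 1), memT)
})

test_that("a single driven unit follows the neuron response prediction", {
  ## 1x1 kernel, depth 1, fixed conductance: layer output = one LIF neuron
  cfg <- networkConfig(inputShape = c(1L, 1L),
                       layers = list(convLayerSpec(1L, 1L, stride = 1L)),
                       inhibitionRadius = 0L, seed = 1L)
  net <- buildNetwork(cfg, gInit = c(0.5, 0.5))
  raster <- framesToSpikes(matrix(1, 1, 1), fMaxHz = 100, tObs = 2000,
                           mode = "periodic")
  res <- runRaster(net, raster)
  p <- calibratedNeuron("long")
  gam <- gammaMinSpikes(p, G = 0.5, fIn = 0.1)
  pred <- neuronResponse(0.1, gam, p@rRefrac) * 2000
  expect_lt(abs(sum(res$counts$long) - pred) / pred, 0.10)
})
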
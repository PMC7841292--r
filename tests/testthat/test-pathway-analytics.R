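## All ordered type sequences over {long, short} up to a given length.
allPathways <- function(maxLen, r = 10) {
  out <- list()
  for (L in seq_len(maxLen)) {
    combos <- do.call(expand.grid,
                      rep(list(c("long", "short")), L))
    for (i in seq_len(nrow(combos)))
      out[[length(out) + 1L]] <-
        pathwaySpec(unlist(combos[i, ], use.names = FALSE), r = r)
  }
  out
}

test_that("neuron response has the right limits and values", {
  expect_equal(neuronResponse(0, 2, 10), 0)
  expect_equal(neuronResponse(0.1, 2, 10), 1 / 30)
  expect_equal(neuronResponse(1e9, 3, 10), 1 / 10, tolerance = 1e-6)
  expect_error(neuronResponse(-1, 2, 10))
})

test_that("pathway response is the composition of stage responses", {
  sp <- pathwaySpec(c("long", "short"), gamma = c(2L, 3L), r = 10)
  expect_equal(pathwayResponse(0.1, sp), 0.01)   # 10 Hz
  ## m = 1 degenerates to the single-neuron response
  one <- pathwaySpec("short", gamma = 4L, r = 10)
  f <- seq(0.01, 0.3, by = 0.01)
  expect_equal(pathwayResponse(f, one), neuronResponse(f, 4, 10))
  ## identity on random specs, to machine precision
  set.seed(3)
  for (i in 1:100) {
    m <- sample(1:4, 1)
    g <- sample(1:6, m, replace = TRUE)
    r <- sample(c(5, 10, 20), 1)
    sp <- pathwaySpec(rep("learner", m), gamma = g, r = r)
    fIn <- runif(1, 0.01, 0.5)
    fold <- fIn
    for (k in seq_len(m)) fold <- neuronResponse(fold, g[k], r)
    expect_equal(pathwayResponse(fIn, sp), fold, tolerance = 1e-12)
  }
})

test_that("response functions distinguish differently ordered pathways", {
  s23 <- pathwaySpec(c("long", "short"), gamma = c(2L, 3L), r = 10)
  s32 <- pathwaySpec(c("short", "long"), gamma = c(3L, 2L), r = 10)
  ## direct evaluation of the two order-dependent forms
  f <- 0.1
  expect_equal(pathwayResponse(f, s23), 1 / (6 / f + 40))
  expect_equal(pathwayResponse(f, s32), 1 / (6 / f + 30))
  res <- responsesDistinct(s23, s32)
  expect_true(res$distinct)
  expect_false(is.na(res$witness))
  expect_false(responsesDistinct(s23, s23)$distinct)
  ## every pair of distinct ordered specs up to length 3 is distinguishable
  specs <- allPathways(3)
  keys <- vapply(specs, function(s) paste(s@types, collapse = "-"),
                 character(1))
  for (i in seq_along(specs)) for (j in seq_along(specs)) {
    if (i >= j) next
    if (identical(specs[[i]]@gamma, specs[[j]]@gamma)) next
    expect_true(responsesDistinct(specs[[i]], specs[[j]])$distinct,
                info = paste(keys[i], "vs", keys[j]))
  }
})

test_that("exact cut-off behaves and calibrates against the reference", {
  p <- learnerNeuron()
  X <- calibrateOffset(105.8, p, 0.1)
  expect_equal(X, 0.3127, tolerance = 1e-3)
  expect_equal(cutoffFrequencyExact(cutoffModel(p, 0.1, X = X)), 105.8,
               tolerance = 1e-9)
  ## strictly decreasing in G; diverges as G -> 0
  f0s <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(g)
    cutoffFrequencyExact(cutoffModel(p, g, X = X)), numeric(1))
  expect_true(all(diff(f0s) < 0))
  expect_gt(cutoffFrequencyExact(cutoffModel(p, 1e-6, X = X)), 1e5)
  expect_error(cutoffFrequencyExact(cutoffModel(p, 0.1, X = -1)),
               "domain")
})

test_that("constant-leak law scales as 1/G and inverts its calibration", {
  s <- calibrateLeakSlope(105.8, 0.31, 0.1)
  expect_equal(cutoffFrequencyLinear(s, 0.31, 0.1), 105.8)
  expect_equal(cutoffFrequencyLinear(s, 0.31, 0.2) * 2,
               cutoffFrequencyLinear(s, 0.31, 0.1))
  expect_error(cutoffFrequencyLinear(-1, 0.31, 0.1))
})

test_that("simulated firing boundary matches the exact cut-off form", {
  ## one-spike-margin threshold (span = cG): the regime of the closed form
  G <- 0.1
  p <- calibratedNeuron("learner", span = 0.31 * G)
  f0 <- cutoffFrequencyExact(cutoffModel(p, G))
  sim <- simulateCutoff(p, G, bracketHz = c(0.5 * f0, 2 * f0), tolHz = 0.5)
  expect_lt(abs(sim - f0), 2)
  ## no spikes at 0.9 f0 over 10 s, spikes at 1.1 f0
  probe <- function(f) {
    times <- seq(1000 / f, 10000, by = 1000 / f)
    length(runNeuronExact(p, times, G))
  }
  expect_equal(probe(0.9 * f0), 0)
  expect_gt(probe(1.1 * f0), 0)
  ## a full threshold span pushes the simulated boundary strictly up
  pFull <- calibratedNeuron("learner", span = 1)
  expect_equal(length(runNeuronExact(pFull,
                                     seq(1000 / (1.1 * f0), 10000,
                                         by = 1000 / (1.1 * f0)), G)), 0)
})

test_that("aligned chained simulation reproduces the response calculus", {
  for (sp in allPathways(3)) {
    for (fHz in c(20, 60, 100)) {
      pred <- 1000 * pathwayResponse(fHz / 1000, sp)
      sim <- simulatePathway(fHz, sp, mode = "aligned")
      expect_lt(abs(sim - pred) / pred, 0.05,
                label = paste(paste(sp@types, collapse = "-"), "at", fHz,
                              "Hz"))
    }
  }
})

test_that("free-running drive matches at commensurate rates and never lags", {
  ## single stage, input period dividing the refractory period: exact
  one <- pathwaySpec("learner", r = 20)   # gamma 4
  pred <- 1000 * neuronResponse(0.1, 4, 20)
  expect_lt(abs(simulatePathway(100, one, mode = "free") - pred) / pred,
            0.05)
  ## in general the free-running phase residual can only speed spiking up
  for (sp in allPathways(2)[c(1, 3, 6)]) {
    for (fHz in c(40, 100)) {
      pred <- 1000 * pathwayResponse(fHz / 1000, sp)
      sim <- simulatePathway(fHz, sp, mode = "free")
      expect_gte(sim, pred * 0.999)
      expect_lte(sim, 1000 / sp@r + 1)   # refractory ceiling
    }
  }
})

test_that("retention lengths follow the closed form and its ordering", {
  ## m = 2 hand evaluation
  sp <- pathwaySpec(c("long", "long"), gamma = c(2L, 2L), r = 10)
  expect_equal(retentionLength(sp, fcLast = 0.02), 20)
  expect_equal(retentionLength(sp, fcLast = 0.02),
               retentionLength(sp, fcLast = 0.02))
  ## cannot-retain signal, not an exception
  expect_warning(T0 <- retentionLength(sp, fcLast = 0.2), "cannot retain")
  expect_lte(T0, 0)
  ## all length-3 pathways: pairwise distinct, short < mixed < long
  specs <- allPathways(3)
  specs <- specs[vapply(specs, pathwayLength, integer(1)) == 3L]
  Ts <- vapply(specs, retentionLength, numeric(1))
  names(Ts) <- vapply(specs, function(s) paste(s@types, collapse = "-"),
                      character(1))
  expect_equal(anyDuplicated(round(Ts, 9)), 0L)
  pure_short <- Ts[["short-short-short"]]
  pure_long <- Ts[["long-long-long"]]
  mixed <- Ts[setdiff(names(Ts), c("short-short-short", "long-long-long"))]
  expect_true(all(mixed > pure_short))
  expect_true(all(mixed < pure_long))
  expect_error(retentionLength(pathwaySpec("long"), 0.01), ">= 2")
})

test_that("numeric inversion of the response function round-trips", {
  sp <- pathwaySpec(c("short", "long", "short"), r = 10)
  for (fIn in c(0.05, 0.1, 0.3)) {
    fOut <- pathwayResponse(fIn, sp)
    expect_equal(invertPathwayResponse(sp, fOut), fIn, tolerance = 1e-6)
  }
  expect_error(invertPathwayResponse(sp, 1), "saturation")
})
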
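test_that("preset parameters satisfy the heterogeneity ordering", {
  ln <- learnerNeuron(); st <- shortTermNeuron(); lt <- longTermNeuron()
  expect_equal(c(ln@a, ln@b, ln@c, ln@rRefrac), c(-4.1, -0.01, 0.31, 20))
  expect_equal(c(st@a, st@b, st@c, st@rRefrac), c(-5.1, -0.02, 0.45, 10))
  expect_equal(c(lt@a, lt@b, lt@c, lt@rRefrac), c(-1.6, -0.001, 0.16, 10))
  expect_true(st@a < ln@a && ln@a < lt@a)
  expect_true(st@b < ln@b && ln@b < lt@b)  # short leaks fastest
  expect_true(st@c > lt@c)
  expect_equal(membraneTau(ln), 100)
  expect_equal(membraneResistance(ln), 31)
})

test_that("parameter validity is enforced", {
  expect_error(neuronParams(a = 1, b = 0.01, c = 1, rRefrac = 1),
               "negative")
  expect_error(neuronParams(a = 1, b = -0.01, c = 1, rRefrac = -1))
  expect_error(neuronParams(a = 1, b = -0.01, c = 1, rRefrac = 1,
                            vReset = 2, vThreshold = 1))
})

test_that("a single Euler step does the membrane arithmetic", {
  p <- learnerNeuron()
  st <- neuronState(p)
  res <- stepNeuron(st, p, inputCurrent = 0, dt = 1)
  expect_equal(res$state@v, -4.1)
  expect_false(res$spiked)
  ## equilibrium -a/b is a fixed point
  st@v <- -p@a / p@b
  res <- stepNeuron(st, p, inputCurrent = 0, dt = 1)
  expect_equal(res$state@v, -p@a / p@b)
  expect_false(res$spiked)
  expect_error(stepNeuron(st, p, inputCurrent = NaN, dt = 1), "finite")
  expect_error(stepNeuron(st, p, inputCurrent = 0, dt = 0), "positive")
})

test_that("coarse-grid first spike agrees with a fine-step reference", {
  p <- calibratedNeuron("learner")
  I <- 2                          # constant suprathreshold drive
  coarse <- simulateNeuron(p, impulse = rep(I, 300), dt = 1,
                           keepTrace = FALSE)
  fine <- simulateNeuron(p, impulse = rep(I * 0.01, 30000), dt = 0.01,
                         keepTrace = FALSE)
  expect_gt(length(coarse$spikeBins), 0)
  expect_gt(length(fine$spikeBins), 0)
  expect_lt(abs(coarse$spikeTimes[1] - fine$spikeTimes[1]), 1 + 1e-9)
})

test_that("decay time closed form matches its examples and a fine-step oracle", {
  pX1 <- neuronParams(a = -0.01, b = -0.01, c = 0.5, rRefrac = 0)  # X = 1
  expect_equal(decayTime(pX1, 0), 0)
  expect_equal(decayTime(pX1, 1), 100 * log(1.5), tolerance = 1e-12)
  ## fine-step simulated decay back to vReset agrees within 0.1 ms
  dt <- 0.005
  v <- pX1@vReset + pX1@c * 1
  t <- 0
  while (v > pX1@vReset) {
    v <- v + dt * (pX1@a + pX1@b * v)
    t <- t + dt
  }
  expect_lt(abs(t - decayTime(pX1, 1)), 0.1)
  ## strictly increasing in the input pulse
  grid <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(decayTime(pX1, grid)) > 0))
  ## domain errors are named
  bad <- learnerNeuron(vReset = -500)   # X < 0
  expect_error(decayTime(bad, 1), "domain error")
})

test_that("decay ordering: long-term slower than learner slower than short-term", {
  ## identical effective offsets X = vReset + a/b and identical input pulse
  X0 <- 1; I <- 1
  times <- vapply(c("long", "learner", "short"), function(ty) {
    p <- neuronPreset(ty)
    p@vReset <- X0 - p@a / p@b
    p@vThreshold <- p@vReset + 1
    decayTime(p, I)
  }, numeric(1))
  expect_true(times[["long"]] > times[["learner"]])
  expect_true(times[["learner"]] > times[["short"]])
})

test_that("closed-form membrane matches initial condition, equilibrium and Euler", {
  p <- neuronParams(a = -0.003, b = -0.01, c = 0.31, rRefrac = 20,
                    vReset = 0.2, vThreshold = 50)   # O(1) potentials
  expect_equal(membraneClosedForm(p, numeric(0), 0.5, 0), p@vReset)
  expect_equal(membraneClosedForm(p, numeric(0), 0.5, 1e6), -p@a / p@b,
               tolerance = 1e-9)
  expect_error(membraneClosedForm(p, c(5, 1), 0.5, 10), "sorted")
  ## Euler at dt = 0.01 tracks the closed form within 1e-3 over 100 ms
  G <- 0.5
  dt <- 0.01
  spikes <- c(0, 5, 10)
  impulse <- numeric(100 / dt)
  impulse[spikes / dt + 1] <- G
  sim <- simulateNeuron(p, impulse, dt = dt)
  tt <- seq(20, 100, by = 10)
  cf <- vapply(tt, function(t) membraneClosedForm(p, spikes, G, t),
               numeric(1))
  expect_lt(max(abs(cf - sim$v[tt / dt])), 1e-3)
})

test_that("Euler error shrinks linearly with dt on the learner preset", {
  p <- learnerNeuron()
  G <- 0.5; spikes <- c(0, 5, 10)
  err <- vapply(c(0.01, 0.001), function(dt) {
    impulse <- numeric(100 / dt)
    impulse[spikes / dt + 1] <- G
    sim <- simulateNeuron(p, impulse, dt = dt)
    abs(membraneClosedForm(p, spikes, G, 100) - sim$v[100 / dt])
  }, numeric(1))
  expect_lt(err[2], err[1] / 5)
})

test_that("refractory period separates output spikes and discards input", {
  p <- calibratedNeuron("learner")
  set.seed(42)
  impulse <- (runif(3000) < 0.5) * 3    # strong random drive
  sim <- simulateNeuron(p, impulse, dt = 1, keepTrace = FALSE)
  expect_gt(length(sim$spikeBins), 5)
  expect_true(all(diff(sim$spikeBins) >= p@rRefrac))
  ## bitwise determinism
  sim2 <- simulateNeuron(p, impulse, dt = 1, keepTrace = FALSE)
  expect_identical(sim$spikeBins, sim2$spikeBins)
})

test_that("event-driven exact simulation agrees with the Euler grid", {
  p <- calibratedNeuron("long")
  times <- seq(10, 5000, by = 10)       # 100 Hz
  exact <- runNeuronExact(p, times, G = 0.5)
  impulse <- numeric(5000)
  impulse[times] <- 0.5
  euler <- simulateNeuron(p, impulse, dt = 1, keepTrace = FALSE)
  expect_equal(length(exact), length(euler$spikeBins))
  expect_lt(max(abs(exact - euler$spikeBins)), 1 + 1e-9)
})

test_that("gamma counts spikes to threshold", {
  p <- neuronParams(a = 0, b = -1e-9, c = 0.31, rRefrac = 10)
  expect_equal(gammaMinSpikes(p, G = 1, fIn = 0.1, method = "no-decay"), 4L)
  ## single-spike threshold crossing
  expect_equal(gammaMinSpikes(p, G = 4, fIn = 0.1, method = "no-decay"), 1L)
  p2 <- neuronParams(a = 0, b = -1e-9, c = 4, rRefrac = 10)
  expect_equal(gammaMinSpikes(p2, G = 1, fIn = 0.1), 1L)
  ## leak only loses potential: simulated gamma >= no-decay gamma
  for (ty in c("learner", "short", "long")) {
    p3 <- calibratedNeuron(ty)
    gSim <- gammaMinSpikes(p3, G = 0.5, fIn = 0.1)
    gNd <- gammaMinSpikes(p3, G = 0.5, fIn = 0.1, method = "no-decay")
    expect_gte(gSim, gNd)
  }
  ## below the cut-off: distinct no-spike signal
  pc <- calibratedNeuron("learner", span = 0.31 * 0.1)
  f0 <- cutoffFrequencyExact(cutoffModel(pc, 0.1))
  expect_true(is.na(gammaMinSpikes(pc, G = 0.1, fIn = 0.5 * f0 / 1000)))
  expect_error(gammaMinSpikes(pc, G = 0, fIn = 0.1), "positive")
})
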
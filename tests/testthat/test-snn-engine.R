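test_that("sampled synaptic parameters respect the optimised ranges", {
  p <- sampleCoreParams(10000, seed = 2)
  expect_true(all(p$tauExcMs >= 3 & p$tauExcMs <= 6))
  expect_true(all(p$tauExcMs - p$tauInhMs >= 0.1 - 1e-12))
  expect_true(all(p$tauExcMs - p$tauInhMs <= 1 + 1e-12))
  expect_true(all(p$tauInhMs > 0 & p$tauInhMs < p$tauExcMs))
  expect_true(all(p$wUp %in% c(1, 2)))
  expect_true(all(p$wDn %in% c(-1, -2)))
})

test_that("the mean excitatory time constant converges to 4.5 ms", {
  p <- sampleCoreParams(100000, seed = 5)
  expect_lt(abs(mean(p$tauExcMs) - 4.5), 0.01)
})

test_that("substream sampling decouples a neuron's draw from the layer size", {
  a <- sampleCoreParams(10, seed = 3)
  b <- sampleCoreParams(200, seed = 3)
  expect_equal(a, b[1:10, ], ignore_attr = TRUE)
})

test_that("network wiring matches the architecture definitions", {
  ins4 <- c("UP_ripple", "DN_ripple", "UP_FR", "DN_FR")
  core <- buildNetwork("core", ins4, nNeurons = 256, seed = 1)
  expect_equal(nConnections(core), 4 * 256)
  expect_equal(nrow(core@neurons), 256)
  # in-band rejection adds 2 neurons and 2 + 1 + 256 connections (2 trains)
  ins2 <- c("UP_FR", "DN_FR")
  c2 <- buildNetwork("core", ins2, nNeurons = 256, seed = 1)
  ib <- buildNetwork("core_inband", ins2, nNeurons = 256, seed = 1)
  expect_equal(nrow(ib@neurons) - nrow(c2@neurons), 2)
  expect_equal(nConnections(ib) - nConnections(c2), 2 + 1 + 256)
  # in-band parameters: dis exc tau 5 ms w 3; dis->glob tau 20 ms w -2.5;
  # glob->layer tau 5 ms w -2.5; glob carries a tonic drive
  disState <- ib@states[ib@states$role == "dis_exc", ]
  expect_equal(disState$tau, 5e-3)
  expect_equal(ib@inputMap$UP_FR$weight[ib@inputMap$UP_FR$state ==
                                          which(ib@states$role == "dis_exc")], 3)
  expect_equal(ib@states$tau[ib@states$role == "glob_inh"], 20e-3)
  expect_equal(unique(ib@connections$weight), -2.5)
  expect_gt(ib@neurons$tonic[ib@neurons$population == "glob"], 0)
  # the artifact layer reuses the core sampling ranges
  full <- buildNetwork("core_inband_artifact", c("UP_ripple", "DN_ripple"),
                       nNeurons = 64, seed = 1)
  artTau <- full@states$tau[full@states$role == "exc" &
    full@states$post %in% which(full@neurons$population == "artifact")]
  expect_true(all(artTau >= 3e-3 & artTau <= 6e-3))
  expect_error(buildNetwork("core", c("XX_ripple")), "UP or DN")
})

test_that("a quiet network stays quiet", {
  net <- buildNetwork("core", c("UP_FR", "DN_FR"), nNeurons = 8, seed = 1)
  res <- simulateNetwork(net, list(UP_FR = numeric(0), DN_FR = numeric(0)),
                         span = 0.5)
  expect_equal(nrow(res$spikes), 0L)
})

test_that("time-averaged synaptic current matches the shot-noise mean", {
  # Poisson input at rate nu through one excitatory synapse: mean current
  # w * nu * tau_syn; read out through the subthreshold membrane mean
  # V_mean = I_mean * tau_mem.
  set.seed(31)
  nu <- 500
  span <- 21
  ev <- sort(runif(nu * span, 0, span))
  w <- 2
  tauS <- 4e-3
  net <- probeNeuron(tauExcMs = 4, w = w)
  res <- simulateNetwork(net, list(UP = ev, DN = numeric(0)), span = span,
                         recordV = 1L)
  v <- res$v[, 1]
  keep <- seq(round(0.5 / res$dt), length(v))   # drop the onset transient
  imean <- mean(v[keep]) / 0.015
  expect_lt(abs(imean - w * nu * tauS) / (w * nu * tauS), 0.05)
})

test_that("grid simulation matches the exact event-driven oracle to 1e-6", {
  dt <- 5e-5
  net <- probeNeuron(tauExcMs = 4.5, tauInhMs = 3.9, w = 2)
  up <- c(0.010, 0.0145)
  dn <- 0.0125                      # all multiples of dt
  res <- simulateNetwork(net, list(UP = up, DN = dn), span = 0.05, dt = dt,
                         recordV = 1L)
  events <- data.frame(time = c(up, dn), state = c(1L, 1L, 2L),
                       amount = c(2, 2, -2))
  events <- events[order(events$time), ]
  times <- seq(0, 0.05 - dt, by = dt)
  oracle <- exactLIFTrace(0.015, c(4.5e-3, 3.9e-3), events, times)
  sim <- res$v[seq_along(times), 1]
  scale <- max(abs(oracle))
  expect_lt(max(abs(sim - oracle)) / scale, 1e-6)
})

test_that("halving dt changes the second-layer spike count by < 2%", {
  out <- ecogScene(41, duration = 20)
  trains <- encodeScene(out$recording, "ECoG")
  inputs <- spikeTrainInputs(trains)
  names(inputs) <- c("UP_FR", "DN_FR")
  net <- buildNetwork("core", names(inputs), nNeurons = 64, seed = 2)
  n1 <- nrow(simulateNetwork(net, inputs, span = 20, dt = 5e-5)$spikes)
  n2 <- nrow(simulateNetwork(net, inputs, span = 20, dt = 2.5e-5)$spikes)
  expect_gt(n1, 20)
  expect_lt(abs(n1 - n2) / n1, 0.02)
})

test_that("identical seeds reproduce identical rasters", {
  out <- ecogScene(42, duration = 10)
  inputs <- spikeTrainInputs(encodeScene(out$recording, "ECoG"))
  net1 <- buildNetwork("core_inband", names(inputs), nNeurons = 32, seed = 9)
  net2 <- buildNetwork("core_inband", names(inputs), nNeurons = 32, seed = 9)
  r1 <- simulateNetwork(net1, inputs, span = 10)
  r2 <- simulateNetwork(net2, inputs, span = 10)
  expect_identical(r1$spikes, r2$spikes)
  net3 <- buildNetwork("core_inband", names(inputs), nNeurons = 32, seed = 10)
  r3 <- simulateNetwork(net3, inputs, span = 10)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("a sustained burst dis-inhibits the second layer", {
  net <- buildNetwork("core_inband", c("UP_FR", "DN_FR"), nNeurons = 4,
                      seed = 1)
  # no input: the global-inhibitory neuron fires tonically near 200 Hz
  quiet <- simulateNetwork(net, list(UP_FR = numeric(0), DN_FR = numeric(0)),
                           span = 1)
  globQuiet <- populationSpikes(quiet, "glob")
  expect_gt(nrow(globQuiet), 150)
  expect_lt(nrow(globQuiet), 250)
  # a strong UP+DN burst drives the dis-inhibitory neuron, which silences
  # the global-inhibitory neuron for the burst's duration
  burst <- seq(0.5, 0.56, by = 5e-4)
  drive <- simulateNetwork(net, list(UP_FR = burst, DN_FR = burst + 2.5e-4),
                           span = 1)
  glob <- populationSpikes(drive, "glob")$time
  dis <- populationSpikes(drive, "dis")$time
  expect_gt(length(dis), 0)
  inBurst <- sum(glob > 0.515 & glob < 0.56)
  expect_lt(inBurst, 3)
  expect_gt(sum(glob < 0.5), 80)   # tonic before the burst
})

test_that("zero-weight synapses give a flat zero tuning curve", {
  fr <- frequencyResponse(c(2, 5, 20), w = 0,
                          neuron = neuronParams(threshold = 0.001))
  expect_true(all(fr$count == 0))
})

test_that("a short-tau neuron prefers ripple-period probes over slow trains", {
  np <- neuronParams(threshold = 0.0045)
  fr <- frequencyResponse(c(2, 3, 4, 5, 6, 50), tauExcMs = 3, w = 2,
                          nPeriods = 60, neuron = np)
  expect_gt(fr$count[fr$isiMs == 2], 0)       # responds in the ripple range
  expect_equal(fr$count[fr$isiMs == 50], 0)   # silent for slow trains
})

test_that("selectivity shifts toward shorter probe periods as tau_exc shrinks", {
  np <- neuronParams(threshold = 0.0045)
  isis <- c(1, 1.5, 2, 3, 4, 5, 6, 8)
  shortFrac <- vapply(c(3, 4.5, 6), function(te) {
    fr <- frequencyResponse(isis, tauExcMs = te, w = 2, nPeriods = 40,
                            neuron = np)
    tot <- sum(fr$count)
    if (tot == 0) return(NA_real_)
    sum(fr$count[fr$isiMs <= 2]) / tot
  }, numeric(1))
  expect_false(anyNA(shortFrac))
  expect_true(all(diff(shortFrac) < 0))  # monotone across tau 3 -> 4.5 -> 6
})

test_that("network specs survive the YAML round trip and replay exactly", {
  out <- ecogScene(43, duration = 5)
  inputs <- spikeTrainInputs(encodeScene(out$recording, "ECoG"))
  net <- buildNetwork("core_inband", names(inputs), nNeurons = 16, seed = 4)
  path <- tempfile(fileext = ".yaml")
  networkToYAML(net, path)
  net2 <- networkFromYAML(path)
  expect_equal(net@states$tau, net2@states$tau)
  r1 <- simulateNetwork(net, inputs, span = 5)
  r2 <- simulateNetwork(net2, inputs, span = 5)
  expect_identical(r1$spikes, r2$spikes)
})
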
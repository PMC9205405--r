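#' Frozen calibration constants of the LIF detector
#'
#' Synaptic weights are dimensionless relative magnitudes (1, 2, 2.5, 3); the
#' membrane threshold is the single calibration constant that ties them to
#' the membrane scale.  It was fixed once, by requiring that a weight-2
#' excitatory synapse driven by an alternating UP/DN probe at ripple-band
#' inter-spike intervals (2-6 ms) fires the neuron while a 50 ms probe leaves
#' it silent, and is never tuned per run.  The dis-inhibitory neuron carries
#' a higher threshold so that it responds only to the elevated UP+DN spiking
#' of an oscillatory event or fast transient, not to background; the
#' global-inhibitory neuron's tonic drive makes it fire at 200 Hz in
#' isolation so it constantly suppresses the second layer unless inhibited.
#'
#' @return list with `threshold` (second-layer and artifact-layer neurons),
#'   `disThreshold` (dis-inhibitory neuron), `globThreshold` and `globRate`
#'   (global-inhibitory neuron: its tonic drive is set to fire it at
#'   `globRate` Hz in isolation; a low threshold keeps the drive small enough
#'   that the dis-inhibitory neuron's weight-2.5 synapse can silence it
#'   within a few spikes).
#' @export
snnCalibration <- function() {
  list(threshold = 0.06, disThreshold = 0.20, globThreshold = 0.01,
       globRate = 200)
}

#' Leaky integrate-and-fire neuron parameters
#'
#' @param tauMem membrane time constant in seconds (default 15 ms, the mean
#'   second-layer value).
#' @param threshold spiking threshold in membrane units.
#' @param reset reset value after a spike.
#' @param refractory neuron refractory period in seconds.
#' @param tonic constant drive current (membrane units per second).
#' @return list of class `NeuronParams`.
#' @export
neuronParams <- function(tauMem = 15e-3, threshold = snnCalibration()$threshold,
                         reset = 0, refractory = 1e-3, tonic = 0) {
  if (tauMem <= 0) stop("tauMem must be > 0")
  if (threshold <= reset) stop("threshold must exceed reset")
  structure(list(tauMem = tauMem, threshold = threshold, reset = reset,
                 refractory = refractory, tonic = tonic),
            class = "NeuronParams")
}

#' Tonic drive producing a target firing rate in isolation
#'
#' Solves the deterministic LIF period `T = refractory +
#' tauMem * log(D tauMem / (D tauMem - threshold))` for the drive `D`.
#'
#' @param rate target rate in Hz.
#' @param neuron a [neuronParams()].
#' @return Drive current `D`.
#' @export
tonicForRate <- function(rate, neuron = neuronParams()) {
  tint <- 1 / rate - neuron$refractory
  if (tint <= 0) stop("rate unreachable with this refractory period")
  (neuron$threshold - neuron$reset * exp(-tint / neuron$tauMem)) /
    (neuron$tauMem * (1 - exp(-tint / neuron$tauMem)))
}

.substreamSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + i) %% 2147483647)
}

#' Sample per-neuron synaptic parameters of the core detection layer
#'
#' For each second-layer neuron the excitatory time constant (UP inputs) is
#' drawn uniformly from 3-6 ms and the inhibitory one (DN inputs) is the
#' excitatory value minus a uniform draw from 0.1-1 ms, so the inhibitory
#' time constant is always shorter.  Weight magnitudes are drawn equiprobably
#' from {1, 2}, positive for UP (excitatory) and negative for DN
#' (inhibitory).  Each neuron uses its own counter-derived RNG substream, so
#' neuron `i`'s draw does not depend on how many neurons are sampled.
#'
#' @param n number of neurons.
#' @param seed integer seed.
#' @param tauExcRange,tauInhDelta ranges in ms.
#' @param weightChoices candidate weight magnitudes.
#' @return data.frame: `tauExcMs`, `tauInhMs`, `wUp`, `wDn`.
#' @examples
#' p <- sampleCoreParams(5, seed = 1)
#' all(p$tauInhMs > 0 & p$tauInhMs < p$tauExcMs)
#' @export
sampleCoreParams <- function(n, seed = 1L, tauExcRange = c(3, 6),
                             tauInhDelta = c(0.1, 1),
                             weightChoices = c(1, 2)) {
  stopifnot(n >= 1)
  draw <- function(i) {
    set.seed(.substreamSeed(seed, i))
    te <- runif(1, tauExcRange[1], tauExcRange[2])
    u <- runif(1, tauInhDelta[1], tauInhDelta[2])
    w <- sample(weightChoices, 2L, replace = TRUE)
    c(te, te - u, w[1], -w[2])
  }
  m <- t(vapply(seq_len(n), draw, numeric(4)))
  data.frame(tauExcMs = m[, 1], tauInhMs = m[, 2], wUp = m[, 3], wDn = m[, 4])
}

.sampleConnWeights <- function(seed, i, nTrains, weightChoices = c(1, 2)) {
  set.seed(.substreamSeed(seed, 70001L + i))
  sample(weightChoices, nTrains, replace = TRUE)
}

#' Build a detector network
#'
#' Three architectures are available.  `"core"`: named UP/DN input trains
#' project to `nNeurons` second-layer neurons; each neuron has one excitatory
#' synaptic state (time constant 3-6 ms) receiving all UP trains and one
#' inhibitory state (0.1-1 ms shorter) receiving all DN trains, with
#' per-connection weight magnitudes of 1 or 2.  `"core_inband"` adds the
#' in-band artifact-rejection circuit: every core input also excites a
#' dis-inhibitory neuron (tau 5 ms, weight 3), which inhibits a
#' global-inhibitory neuron (tau 20 ms, weight 2.5), which in turn inhibits
#' every second-layer neuron (tau 5 ms, weight 2.5) and carries a tonic
#' drive making it fire at 200 Hz when not inhibited.
#' `"core_inband_artifact"` further adds a parallel detection layer with the
#' same sampling ranges fed by the above-500 Hz band trains
#' (`artifactInputNames`), whose spikes mark artifact intervals.
#'
#' Input train names must start with `"UP"` or `"DN"`; that prefix decides
#' the synapse polarity.
#'
#' @param architecture `"core"`, `"core_inband"` or `"core_inband_artifact"`.
#' @param inputNames names of the core input trains, e.g.
#'   `c("UP_ripple", "DN_ripple", "UP_FR", "DN_FR")`.
#' @param nNeurons second-layer size (default 256).
#' @param seed integer seed for parameter sampling.
#' @param neuron a [neuronParams()] for the second-layer neurons.
#' @param artifactInputNames input names of the artifact-detection layer.
#' @param calibration calibration constants (see [snnCalibration()]).
#' @return A [NetworkSpec-class].
#' @examples
#' net <- buildNetwork("core", c("UP_FR", "DN_FR"), nNeurons = 16, seed = 7)
#' net
#' @export
buildNetwork <- function(architecture = c("core", "core_inband",
                                          "core_inband_artifact"),
                         inputNames, nNeurons = 256L, seed = 1L,
                         neuron = neuronParams(),
                         artifactInputNames = c("UP_artifact", "DN_artifact"),
                         calibration = snnCalibration()) {
  architecture <- match.arg(architecture)
  nNeurons <- as.integer(nNeurons)
  pol <- function(nm) {
    p <- toupper(substr(nm, 1, 2))
    if (!p %in% c("UP", "DN"))
      stop("input name must start with UP or DN: ", nm)
    p
  }
  calib <- calibration

  buildLayer <- function(n, seedOffset, inNames, population, stateOffset,
                         neuronOffset) {
    pars <- sampleCoreParams(n, seed + seedOffset)
    neurons <- data.frame(
      population = population,
      tauMem = neuron$tauMem, threshold = neuron$threshold,
      reset = neuron$reset, refractory = neuron$refractory, tonic = 0)
    neurons <- neurons[rep(1L, n), , drop = FALSE]
    states <- data.frame(
      post = rep(seq_len(n) + neuronOffset, 2L),
      tau = c(pars$tauExcMs, pars$tauInhMs) / 1000,
      role = rep(c("exc", "inh"), each = n))
    wm <- t(vapply(seq_len(n), function(i)
      .sampleConnWeights(seed + seedOffset, i, length(inNames)), numeric(length(inNames))))
    if (length(inNames) == 1L) wm <- matrix(wm, ncol = 1L)
    inputMap <- lapply(seq_along(inNames), function(k) {
      if (pol(inNames[k]) == "UP")
        data.frame(state = stateOffset + seq_len(n), weight = wm[, k])
      else
        data.frame(state = stateOffset + n + seq_len(n), weight = -wm[, k])
    })
    names(inputMap) <- inNames
    list(neurons = neurons, states = states, inputMap = inputMap)
  }

  core <- buildLayer(nNeurons, 0L, inputNames, "core", 0L, 0L)
  neurons <- core$neurons
  states <- core$states
  inputMap <- core$inputMap
  connections <- data.frame(src = integer(0), state = integer(0),
                            weight = numeric(0))

  if (architecture %in% c("core_inband", "core_inband_artifact")) {
    disId <- nrow(neurons) + 1L
    globId <- nrow(neurons) + 2L
    globNeuron <- neuronParams(tauMem = neuron$tauMem,
                               threshold = calib$globThreshold,
                               refractory = 2e-3)
    neurons <- rbind(
      neurons,
      data.frame(population = "dis", tauMem = neuron$tauMem,
                 threshold = calib$disThreshold, reset = neuron$reset,
                 refractory = 1e-3, tonic = 0),
      data.frame(population = "glob", tauMem = globNeuron$tauMem,
                 threshold = globNeuron$threshold, reset = globNeuron$reset,
                 refractory = globNeuron$refractory,
                 tonic = tonicForRate(calib$globRate, globNeuron)))
    disState <- nrow(states) + 1L       # UP+DN -> dis, exc, tau 5 ms
    globState <- nrow(states) + 2L      # dis -> glob, inh, tau 20 ms
    giStates <- nrow(states) + 2L + seq_len(nNeurons)  # glob -> layer, tau 5 ms
    states <- rbind(states,
      data.frame(post = disId, tau = 5e-3, role = "dis_exc"),
      data.frame(post = globId, tau = 20e-3, role = "glob_inh"),
      data.frame(post = seq_len(nNeurons), tau = 5e-3, role = "gi"))
    for (nm in inputNames)
      inputMap[[nm]] <- rbind(inputMap[[nm]],
                              data.frame(state = disState, weight = 3))
    connections <- rbind(
      connections,
      data.frame(src = disId, state = globState, weight = -2.5),
      data.frame(src = globId, state = giStates, weight = -2.5))
  }

  if (architecture == "core_inband_artifact") {
    art <- buildLayer(nNeurons, 1L, artifactInputNames, "artifact",
                      nrow(states), nrow(neurons))
    neurons <- rbind(neurons, art$neurons)
    states <- rbind(states, art$states)
    inputMap <- c(inputMap, art$inputMap)
  }

  rownames(neurons) <- NULL
  rownames(states) <- NULL
  new("NetworkSpec", architecture = architecture, nNeurons = nNeurons,
      neurons = neurons, states = states, inputMap = inputMap,
      connections = connections, seed = as.integer(seed))
}

#' Simulate a network on input spike trains
#'
#' Integrates the current-based LIF dynamics: each synaptic state jumps by
#' its connection weight on a presynaptic spike and decays exponentially;
#' each neuron integrates its states plus tonic drive with membrane leak.
#' Within each `dt` step the coupled state/membrane equations are propagated
#' with their closed-form solution, so the only discretisation effect is the
#' quantisation of event delivery and threshold crossings to the grid.
#'
#' @param net a [buildNetwork()] result.
#' @param inputs named list of numeric spike-time vectors (seconds); names
#'   must match `net`'s input map (see [spikeTrainInputs()]).
#' @param span simulated duration in seconds.
#' @param dt integration step in seconds (default 0.05 ms).
#' @param recordV integer vector of neuron indices whose membrane trace to
#'   record.
#' @return list of class `SimulationResult`: `spikes` (data.frame neuron,
#'   time, population), `v` (matrix of recorded traces, one column per
#'   requested neuron), `dt`, `span`, `nNeurons`.
#' @export
simulateNetwork <- function(net, inputs, span, dt = 5e-5,
                            recordV = integer(0)) {
  stopifnot(is(net, "NetworkSpec"))
  if (dt > 1e-4 + 1e-12) stop("dt must be <= 0.1 ms")
  used <- names(net@inputMap)
  missing <- setdiff(used, names(inputs))
  if (length(missing))
    stop("missing input trains: ", paste(missing, collapse = ", "))
  evTime <- numeric(0)
  evSrc <- integer(0)
  mapState <- integer(0)
  mapWeight <- numeric(0)
  srcPtr <- integer(length(used) + 1L)
  srcPtr[1] <- 0L
  for (s in seq_along(used)) {
    tms <- inputs[[used[s]]]
    if (is(tms, "SpikeTrain"))
      stop("pass polarity-split numeric times (see spikeTrainInputs())")
    evTime <- c(evTime, as.numeric(tms))
    evSrc <- c(evSrc, rep(s - 1L, length(tms)))
    m <- net@inputMap[[used[s]]]
    mapState <- c(mapState, as.integer(m$state) - 1L)
    mapWeight <- c(mapWeight, m$weight)
    srcPtr[s + 1L] <- srcPtr[s] + nrow(m)
  }
  o <- order(evTime)
  res <- lif_simulate_cpp(
    net@neurons$tauMem, net@neurons$threshold, net@neurons$reset,
    net@neurons$refractory, net@neurons$tonic,
    net@states$tau, as.integer(net@states$post) - 1L,
    evTime[o], evSrc[o], srcPtr, mapState, mapWeight,
    as.integer(net@connections$src) - 1L,
    as.integer(net@connections$state) - 1L, net@connections$weight,
    dt, span, as.integer(recordV) - 1L)
  spikes <- data.frame(neuron = res$neuron, time = res$time)
  spikes$population <- net@neurons$population[spikes$neuron]
  structure(list(spikes = spikes, v = res$v, dt = dt, span = span,
                 nNeurons = net@nNeurons, architecture = net@architecture),
            class = "SimulationResult")
}

#' @export
print.SimulationResult <- function(x, ...) {
  cat(sprintf("SimulationResult: %d spikes over %.3f s (dt %.3g ms, %s)\n",
              nrow(x$spikes), x$span, x$dt * 1000, x$architecture))
  print(table(x$spikes$population))
  invisible(x)
}

#' Spikes of one population from a simulation result
#'
#' @param res a [simulateNetwork()] result.
#' @param population population name (`"core"`, `"dis"`, `"glob"`,
#'   `"artifact"`).
#' @return data.frame with columns neuron, time.
#' @export
populationSpikes <- function(res, population = "core") {
  res$spikes[res$spikes$population == population, c("neuron", "time")]
}

#' Split per-band spike trains into polarity-named inputs
#'
#' Turns a named list of [SpikeTrain-class] objects (one per band) into the
#' named list of numeric time vectors (`UP_<band>`, `DN_<band>`) that
#' [simulateNetwork()] expects.
#'
#' @param trains named list of `SpikeTrain`s, names are band labels.
#' @return named list of numeric vectors.
#' @export
spikeTrainInputs <- function(trains) {
  out <- list()
  for (nm in names(trains)) {
    out[[paste0("UP_", nm)]] <- spikeTimes(trains[[nm]], "UP")
    out[[paste0("DN_", nm)]] <- spikeTimes(trains[[nm]], "DN")
  }
  out
}

#' Frequency tuning of a single detector neuron
#'
#' Probes one second-layer neuron (one excitatory and one inhibitory synapse,
#' weights +/-`w`) with a periodic alternating UP/DN train: UP spikes every
#' `2 * isi` seconds and DN spikes offset by `isi`, so consecutive input
#' spikes are `isi` apart.  Returns the output spike count per probe ISI,
#' the tuning curve used to verify the band selectivity of the sampled time
#' constants.
#'
#' @param isiMs probe inter-spike intervals in ms.
#' @param tauExcMs,tauInhMs synaptic time constants in ms (inhibitory
#'   defaults to `tauExcMs - 0.55`).
#' @param w weight magnitude.
#' @param nPeriods number of UP/DN periods per probe.
#' @param neuron a [neuronParams()].
#' @param dt integration step in seconds.
#' @return data.frame: `isiMs`, `count`.
#' @export
frequencyResponse <- function(isiMs, tauExcMs = 4.5,
                              tauInhMs = tauExcMs - 0.55, w = 2,
                              nPeriods = 60, neuron = neuronParams(),
                              dt = 5e-5) {
  counts <- vapply(isiMs, function(isi) {
    isiS <- isi / 1000
    up <- (seq_len(nPeriods) - 1) * 2 * isiS
    dn <- up + isiS
    net <- new("NetworkSpec", architecture = "core", nNeurons = 1L,
      neurons = data.frame(population = "core", tauMem = neuron$tauMem,
                           threshold = neuron$threshold, reset = neuron$reset,
                           refractory = neuron$refractory, tonic = 0),
      states = data.frame(post = c(1L, 1L), tau = c(tauExcMs, tauInhMs) / 1000,
                          role = c("exc", "inh")),
      inputMap = list(UP = data.frame(state = 1L, weight = w),
                      DN = data.frame(state = 2L, weight = -w)),
      connections = data.frame(src = integer(0), state = integer(0),
                               weight = numeric(0)),
      seed = 0L)
    span <- max(dn) + 0.05
    res <- simulateNetwork(net, list(UP = up, DN = dn), span = span, dt = dt)
    nrow(res$spikes)
  }, numeric(1))
  data.frame(isiMs = isiMs, count = counts)
}

#' Serialize a network (including sampled parameters) to YAML
#'
#' @param net a [NetworkSpec-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
networkToYAML <- function(net, path) {
  obj <- list(architecture = net@architecture, nNeurons = net@nNeurons,
              seed = net@seed,
              neurons = as.list(net@neurons),
              states = as.list(net@states),
              inputMap = lapply(net@inputMap, as.list),
              connections = as.list(net@connections))
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Restore a network serialized with [networkToYAML()]
#'
#' @param path YAML file.
#' @return A [NetworkSpec-class].
#' @export
networkFromYAML <- function(path) {
  obj <- yaml::read_yaml(path)
  df <- function(l) as.data.frame(l, stringsAsFactors = FALSE)
  new("NetworkSpec", architecture = obj$architecture,
      nNeurons = as.integer(obj$nNeurons),
      neurons = df(obj$neurons), states = df(obj$states),
      inputMap = lapply(obj$inputMap, df),
      connections = if (length(obj$connections$src)) df(obj$connections)
                    else data.frame(src = integer(0), state = integer(0),
                                    weight = numeric(0)),
      seed = as.integer(obj$seed))
}
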
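# Synthetic study scenes shared across tests.  Event SNRs follow the
# recording regimes the detector is designed for: iEEG ripple 3.9 / fast
# ripple 2.3, high-density ECoG fast ripple 7.3, scalp ripple 4.0.

ieegScene <- function(seed, duration = 60, withEvents = TRUE) {
  onsets <- seq(3, duration - 5, length.out = 10)
  evs <- if (withEvents) c(
    lapply(onsets[1:7], function(o)
      eventSpec("ripple_hfo", o, centerFreq = 110 + 15 * (floor(o) %% 5),
                nCycles = 8, amplitudeRatio = 3.9)),
    lapply(onsets[8:10], function(o)
      eventSpec("fr_hfo", o, centerFreq = 280 + 30 * (floor(o) %% 3),
                nCycles = 10, amplitudeRatio = 2.3))) else list()
  generateSynthetic(syntheticSpec(duration, 4000, background = "pink",
                                  events = evs, seed = seed))
}

ecogScene <- function(seed, duration = 60, transientRatio = 8) {
  onsets <- seq(3, duration - 5, length.out = 10)
  evs <- c(
    lapply(onsets[1:6], function(o)
      eventSpec("fr_hfo", o, centerFreq = 280 + 30 * (floor(o) %% 3),
                nCycles = 8, amplitudeRatio = 7.3)),
    lapply(onsets[7:10], function(o)
      eventSpec("sharp_transient", o, amplitudeRatio = transientRatio)))
  generateSynthetic(syntheticSpec(duration, 2000, background = "pink",
                                  events = evs, seed = seed))
}

scalpScene <- function(seed, duration = 30) {
  onsets <- seq(2, duration - 3, length.out = 10)
  evs <- c(
    lapply(onsets[1:6], function(o)
      eventSpec("ripple_hfo", o, centerFreq = 110 + 15 * (floor(o) %% 5),
                nCycles = 12, amplitudeRatio = 4.0)),
    unlist(lapply(onsets[7:10], function(o) list(
      eventSpec("ripple_hfo", o, centerFreq = 130, nCycles = 12,
                amplitudeRatio = 4.0),
      eventSpec("hf_artifact", o, centerFreq = 650, nCycles = 33,
                amplitudeRatio = 8))), recursive = FALSE))
  generateSynthetic(syntheticSpec(duration, 10000, background = "pink",
                                  events = evs, seed = seed))
}

# band-filter + encode one channel with a modality's presets
encodeScene <- function(rec, modality) {
  fs <- samplingRate(rec)
  x <- getChannel(rec, 1)
  bands <- bandPresets(modality)
  adm <- admPresets(modality)
  trains <- list()
  for (bn in names(bands)) {
    xf <- filterBand(x, bands[[bn]], fs = fs)
    bl <- estimateBaseline(xf, fs)
    trains[[bn]] <- admEncode(xf, adm[[bn]], bl, fs, band = bn)
  }
  trains
}

# single-neuron network with one excitatory and one inhibitory synapse
probeNeuron <- function(tauExcMs, tauInhMs = tauExcMs - 0.55, w = 2,
                        threshold = 1e9, tauMem = 0.015, refractory = 1e-3) {
  new("NetworkSpec", architecture = "core", nNeurons = 1L,
      neurons = data.frame(population = "core", tauMem = tauMem,
                           threshold = threshold, reset = 0,
                           refractory = refractory, tonic = 0),
      states = data.frame(post = c(1L, 1L),
                          tau = c(tauExcMs, tauInhMs) / 1000,
                          role = c("exc", "inh")),
      inputMap = list(UP = data.frame(state = 1L, weight = w),
                      DN = data.frame(state = 2L, weight = -w)),
      connections = data.frame(src = integer(0), state = integer(0),
                               weight = numeric(0)),
      seed = 0L)
}

# exact event-driven integration of one LIF neuron with exponential synapses
# (closed-form decay between events; independent oracle for the grid engine)
exactLIFTrace <- function(tauMem, stateTaus, events, times) {
  # events: data.frame(time, state, amount), sorted; times: sorted query grid
  S <- numeric(length(stateTaus))
  V <- 0
  tcur <- 0
  out <- numeric(length(times))
  qi <- 1L
  prop <- function(dt) {
    if (dt <= 0) return()
    newV <- V * exp(-dt / tauMem)
    for (j in seq_along(S)) {
      a <- 1 / tauMem - 1 / stateTaus[j]
      contrib <- if (abs(a) < 1e-9) S[j] * dt * exp(-dt / tauMem)
                 else S[j] * (exp(-dt / stateTaus[j]) - exp(-dt / tauMem)) / a
      newV <- newV + contrib
      S[j] <<- S[j] * exp(-dt / stateTaus[j])
    }
    V <<- newV
  }
  evq <- rbind(events, data.frame(time = Inf, state = 1L, amount = 0))
  ei <- 1L
  for (qi in seq_along(times)) {
    tq <- times[qi]
    while (evq$time[ei] <= tq + 1e-15) {
      prop(evq$time[ei] - tcur)
      tcur <- evq$time[ei]
      S[evq$state[ei]] <- S[evq$state[ei]] + evq$amount[ei]
      ei <- ei + 1L
    }
    prop(tq - tcur)
    tcur <- tq
    out[qi] <- V
  }
  out
}
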
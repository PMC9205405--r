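#' @include AllGenerics.R
NULL

#' Multichannel sampled EEG recording
#'
#' Container for a multichannel sampled signal.  Amplitudes are stored in
#' microvolts, one column per channel; the recording duration is
#' `nrow(samples) / samplingRate` seconds.
#'
#' @slot samples numeric matrix, time x channel, amplitudes in microvolts.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelNames one name per column of `samples`.
#'
#' @seealso [EEGRecording()], [readRecording()], [makeBipolar()]
#' @export
setClass("EEGRecording",
  slots = c(
    samples = "matrix",
    samplingRate = "numeric",
    channelNames = "character"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- NULL
  if (!is.numeric(object@samples))
    msg <- c(msg, "'samples' must be a numeric matrix")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "'samplingRate' must be a single positive number")
  if (ncol(object@samples) != length(object@channelNames))
    msg <- c(msg, "one channel name per column of 'samples' is required")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  if (is.null(msg)) TRUE else msg
})

#' Construct an EEGRecording
#'
#' @param samples numeric matrix (time x channel) or vector (one channel) of
#'   amplitudes in microvolts.
#' @param samplingRate sampling rate in Hz.
#' @param channelNames channel names; defaults to the column names of
#'   `samples` or `ch1, ch2, ...`.
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(4000), ncol = 2), 2000)
#' recordingDuration(rec)
#' @export
EEGRecording <- function(samples, samplingRate, channelNames = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (is.null(channelNames)) {
    channelNames <- colnames(samples)
    if (is.null(channelNames))
      channelNames <- paste0("ch", seq_len(ncol(samples)))
  }
  colnames(samples) <- channelNames
  new("EEGRecording", samples = samples, samplingRate = as.numeric(samplingRate),
      channelNames = as.character(channelNames))
}

#' @describeIn EEGRecording-class sampling rate in Hz.
#' @param x an `EEGRecording`.
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@samplingRate)

#' @describeIn EEGRecording-class channel names.
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)

#' @describeIn EEGRecording-class number of channels.
#' @export
setMethod("nChannels", "EEGRecording", function(x) ncol(x@samples))

#' @describeIn EEGRecording-class number of samples per channel.
#' @export
setMethod("nSamples", "EEGRecording", function(x) nrow(x@samples))

#' @describeIn EEGRecording-class duration in seconds.
#' @export
setMethod("recordingDuration", "EEGRecording",
          function(x) nrow(x@samples) / x@samplingRate)

#' @describeIn EEGRecording-class extract one channel as a numeric vector.
#' @param channel channel name or index.
#' @export
setMethod("getChannel", "EEGRecording", function(x, channel) {
  if (is.character(channel)) {
    i <- match(channel, x@channelNames)
    if (is.na(i)) stop("unknown channel: ", channel)
  } else {
    i <- as.integer(channel)
  }
  x@samples[, i]
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channel(s), %.3f s @ %g Hz\n",
              ncol(object@samples), recordingDuration(object),
              object@samplingRate))
  cat("channels:", paste(head(object@channelNames, 8L), collapse = ", "),
      if (ncol(object@samples) > 8L) "..." else "", "\n")
})

#' Timestamped UP/DN spike train
#'
#' Events produced by the asynchronous delta modulator (or any point process
#' with polarity labels).  Times are seconds from recording start, strictly
#' increasing; polarity is `"UP"` or `"DN"`.
#'
#' @slot times spike times in seconds, strictly increasing.
#' @slot polarity `"UP"`/`"DN"` per spike.
#' @slot band name of the frequency band the train encodes.
#' @slot channel source channel name.
#' @slot span duration of the underlying recording in seconds.
#'
#' @seealso [SpikeTrain()], [admEncode()]
#' @export
setClass("SpikeTrain",
  slots = c(
    times = "numeric",
    polarity = "character",
    band = "character",
    channel = "character",
    span = "numeric"
  )
)

setValidity("SpikeTrain", function(object) {
  msg <- NULL
  if (length(object@times) != length(object@polarity))
    msg <- c(msg, "'times' and 'polarity' must have equal length")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be strictly increasing")
  if (!all(object@polarity %in% c("UP", "DN")))
    msg <- c(msg, "'polarity' must be \"UP\" or \"DN\"")
  if (length(object@span) != 1L || object@span < 0)
    msg <- c(msg, "'span' must be a single non-negative number")
  if (length(object@times) &&
      (min(object@times) < 0 || max(object@times) > object@span + 1e-9))
    msg <- c(msg, "spike times must lie within [0, span]")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SpikeTrain
#'
#' @param times spike times in seconds (strictly increasing).
#' @param polarity character vector of `"UP"`/`"DN"`, one per spike.
#' @param band frequency band label (e.g. `"ripple"`).
#' @param channel source channel name.
#' @param span recording duration in seconds (defaults to the last spike time).
#' @return A [SpikeTrain-class] object.
#' @export
SpikeTrain <- function(times, polarity, band = "ripple", channel = "ch1",
                       span = if (length(times)) max(times) else 0) {
  new("SpikeTrain", times = as.numeric(times), polarity = as.character(polarity),
      band = band, channel = channel, span = as.numeric(span))
}

#' @describeIn SpikeTrain-class spike times, optionally restricted to one
#'   polarity (`"UP"` or `"DN"`).
#' @param x a `SpikeTrain`.
#' @param polarity optional polarity filter.
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x, polarity = NULL) {
  if (is.null(polarity)) x@times else x@times[x@polarity == polarity]
})

#' @describeIn SpikeTrain-class polarity labels.
#' @export
setMethod("spikePolarity", "SpikeTrain", function(x) x@polarity)

#' @describeIn SpikeTrain-class number of spikes.
#' @export
setMethod("nSpikes", "SpikeTrain", function(x) length(x@times))

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf(
    "SpikeTrain: %d spikes (%d UP / %d DN), band %s, channel %s, span %.3f s\n",
    length(object@times), sum(object@polarity == "UP"),
    sum(object@polarity == "DN"), object@band, object@channel, object@span))
})

#' Spiking network architecture with sampled synaptic parameters
#'
#' Describes one of the three detector architectures (`"core"`,
#' `"core_inband"`, `"core_inband_artifact"`) fully instantiated: every
#' neuron's membrane parameters, every synaptic state (time constant and
#' target neuron), the mapping from named input spike trains to states and
#' weights, and the internal (neuron-to-state) connections.  The object is
#' self-contained: together with the input spike trains it determines the
#' simulation bit-for-bit.
#'
#' @slot architecture architecture name.
#' @slot nNeurons number of second-layer neurons (per detection layer).
#' @slot neurons data.frame: population, tauMem, threshold, reset, refractory,
#'   tonic (taus and refractory in seconds).
#' @slot states data.frame: post (neuron index), tau (seconds), role.
#' @slot inputMap named list (one element per input train name) of data.frames
#'   with columns state, weight.
#' @slot connections data.frame of internal connections: src (neuron), state,
#'   weight.
#' @slot seed integer seed used for parameter sampling.
#'
#' @seealso [buildNetwork()], [simulateNetwork()]
#' @export
setClass("NetworkSpec",
  slots = c(
    architecture = "character",
    nNeurons = "integer",
    neurons = "data.frame",
    states = "data.frame",
    inputMap = "list",
    connections = "data.frame",
    seed = "integer"
  )
)

setValidity("NetworkSpec", function(object) {
  msg <- NULL
  if (!object@architecture %in% c("core", "core_inband", "core_inband_artifact"))
    msg <- c(msg, "unknown architecture")
  if (nrow(object@states) &&
      (min(object@states$post) < 1 || max(object@states$post) > nrow(object@neurons)))
    msg <- c(msg, "state 'post' indices out of range")
  if (any(object@states$tau <= 0)) msg <- c(msg, "state taus must be > 0")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "NetworkSpec", function(object) {
  nconn <- sum(vapply(object@inputMap, nrow, 1L)) + nrow(object@connections)
  cat(sprintf("NetworkSpec: %s, %d neurons, %d synaptic states, %d connections\n",
              object@architecture, nrow(object@neurons), nrow(object@states),
              nconn))
  cat("inputs:", paste(names(object@inputMap), collapse = ", "), "\n")
})

#' @describeIn NetworkSpec-class total number of connections (input-to-state
#'   plus internal).
#' @param x a `NetworkSpec`.
#' @export
nConnections <- function(x) {
  stopifnot(is(x, "NetworkSpec"))
  sum(vapply(x@inputMap, nrow, 1L)) + nrow(x@connections)
}
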
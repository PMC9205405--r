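#' @include snnHFO-package.R
NULL

#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))

#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' @export
setGeneric("spikeTimes", function(x, polarity = NULL) standardGeneric("spikeTimes"))

#' @export
setGeneric("spikePolarity", function(x) standardGeneric("spikePolarity"))

#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))
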
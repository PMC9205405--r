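#' Frequency band specification
#'
#' Defines a Butterworth band-pass: the ripple band (80-250 Hz), the
#' fast-ripple band (250-500 Hz) or the above-HFO artifact band (500-900 Hz).
#' The default order is 2 (two analog poles), applied causally once in the
#' forward direction, mirroring a real-time second-order analog filter; set
#' `causal = FALSE` for zero-phase forward-backward filtering in offline
#' analyses.
#'
#' @param name band name, one of `"ripple"`, `"FR"`, `"artifact"`, or a
#'   custom label when `low`/`high` are given.
#' @param low,high band edges in Hz; defaults depend on `name`.
#' @param order analog prototype order (poles).
#' @param causal logical; apply the filter once forward (`TRUE`) or
#'   forward-backward (`FALSE`).
#' @return A list of class `BandSpec`.
#' @examples
#' bandSpec("ripple")
#' bandSpec("FR", order = 4, causal = FALSE)
#' @export
bandSpec <- function(name = c("ripple", "FR", "artifact"),
                     low = NULL, high = NULL, order = 2L, causal = TRUE) {
  defaults <- list(ripple = c(80, 250), FR = c(250, 500),
                   artifact = c(500, 900))
  if (is.null(low) || is.null(high)) {
    name <- match.arg(name)
    low <- defaults[[name]][1]
    high <- defaults[[name]][2]
  } else {
    name <- as.character(name)[1]
  }
  if (!(low > 0 && high > low))
    stop("band edges must satisfy 0 < low < high")
  structure(list(name = name, low = low, high = high,
                 order = as.integer(order), causal = isTRUE(causal)),
            class = "BandSpec")
}

#' @export
print.BandSpec <- function(x, ...) {
  cat(sprintf("BandSpec %s: %g-%g Hz, order %d, %s\n", x$name, x$low, x$high,
              x$order, if (x$causal) "causal" else "zero-phase"))
  invisible(x)
}

#' Band presets per recording modality
#'
#' iEEG is analysed in the ripple and fast-ripple bands, intraoperative ECoG
#' in the fast-ripple band only, and scalp EEG in the ripple band plus the
#' above-HFO artifact band (500-900 Hz) used by the artifact-detection
#' network.
#'
#' @param modality `"iEEG"`, `"ECoG"` or `"scalp"`.
#' @param causal passed to [bandSpec()].
#' @return Named list of `BandSpec`s.
#' @export
bandPresets <- function(modality = c("iEEG", "ECoG", "scalp"), causal = TRUE) {
  modality <- match.arg(modality)
  switch(modality,
    iEEG = list(ripple = bandSpec("ripple", causal = causal),
                FR = bandSpec("FR", causal = causal)),
    ECoG = list(FR = bandSpec("FR", causal = causal)),
    scalp = list(ripple = bandSpec("ripple", causal = causal),
                 artifact = bandSpec("artifact", causal = causal)))
}

#' Band-pass filter a recording
#'
#' Applies a digital Butterworth band-pass (bilinear transform of the analog
#' prototype of the given order) to every channel.  With `band$causal = TRUE`
#' the filter runs once forward, reproducing the phase behaviour of a
#' real-time analog filter; otherwise it runs forward-backward (zero phase,
#' squared magnitude response).
#'
#' @param rec an [EEGRecording-class] (or a numeric vector, with `fs` given).
#' @param band a [bandSpec()].
#' @param fs sampling rate in Hz, only needed when `rec` is a bare vector.
#' @return Filtered object of the same kind as `rec`.
#' @examples
#' rec <- EEGRecording(rnorm(8000), 2000)
#' filtered <- filterBand(rec, bandSpec("ripple"))
#' @export
filterBand <- function(rec, band, fs = NULL) {
  stopifnot(inherits(band, "BandSpec"))
  if (is(rec, "EEGRecording")) {
    fs <- samplingRate(rec)
    x <- rec@samples
  } else {
    if (is.null(fs)) stop("'fs' is required for plain numeric input")
    x <- matrix(as.numeric(rec), ncol = 1L)
  }
  nyq <- fs / 2
  if (band$high >= nyq)
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                 band$high, nyq))
  bf <- signal::butter(band$order, c(band$low, band$high) / nyq, type = "pass")
  y <- apply(x, 2L, function(col) {
    if (band$causal) as.numeric(signal::filter(bf, col))
    else as.numeric(signal::filtfilt(bf, col))
  })
  if (is.matrix(y) == FALSE) y <- matrix(y, ncol = ncol(x))
  if (is(rec, "EEGRecording"))
    EEGRecording(y, fs, channelNames(rec))
  else
    as.numeric(y)
}

#' Analytic Butterworth band-pass magnitude
#'
#' Magnitude response of the analog Butterworth band-pass prototype
#' `|H(f)|^2 = 1 / (1 + ((f^2 - f0^2) / (f * B))^(2 n))` with centre
#' `f0 = sqrt(low * high)` and bandwidth `B = high - low`.  Used as the
#' closed-form reference for gain checks; the digital filter matches it up to
#' bilinear-transform frequency warping (negligible well below Nyquist).
#'
#' @param f frequency in Hz (vectorised).
#' @param band a [bandSpec()].
#' @return Magnitude gain at `f`.
#' @export
butterBandGain <- function(f, band) {
  f0 <- sqrt(band$low * band$high)
  B <- band$high - band$low
  1 / sqrt(1 + ((f^2 - f0^2) / (f * B))^(2 * band$order))
}
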
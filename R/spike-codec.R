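#' Asynchronous delta modulator parameters
#'
#' The spiking threshold `delta` is expressed as a fraction of the estimated
#' background baseline amplitude of the band-filtered signal; UP and DN
#' thresholds are symmetric about the running reference.  The refractory
#' period blocks both polarities (single-circuit modulator).  The
#' interpolation factor linearly upsamples the signal before encoding, which
#' lets spike times resolve finer than the sampling grid (used for scalp EEG).
#'
#' Modality presets (threshold fraction / refractory): iEEG ripple 0.5 /
#' 300 us, iEEG FR 0.3 / 300 us, ECoG FR 0.5 / 300 us, scalp ripple 0.3 /
#' 1 ms, scalp artifact band 0.3 / 300 us.
#'
#' @param thresholdFraction positive scalar, delta as a fraction of baseline.
#' @param refractory refractory period in seconds (>= 0).
#' @param interpolationFactor integer >= 1 linear upsampling factor.
#' @return A list of class `ADMParams`.
#' @examples
#' admParams(0.5, 300e-6)
#' @export
admParams <- function(thresholdFraction, refractory = 300e-6,
                      interpolationFactor = 1L) {
  if (!(thresholdFraction > 0)) stop("thresholdFraction must be > 0")
  if (refractory < 0) stop("refractory must be >= 0")
  interpolationFactor <- as.integer(interpolationFactor)
  if (interpolationFactor < 1L) stop("interpolationFactor must be >= 1")
  structure(list(thresholdFraction = thresholdFraction,
                 refractory = refractory,
                 interpolationFactor = interpolationFactor),
            class = "ADMParams")
}

#' @export
print.ADMParams <- function(x, ...) {
  cat(sprintf("ADMParams: threshold %g x baseline, refractory %g us, interpolation x%d\n",
              x$thresholdFraction, x$refractory * 1e6, x$interpolationFactor))
  invisible(x)
}

#' Estimate the background baseline amplitude of a filtered signal
#'
#' Splits the signal into 1 s windows, computes the mean envelope amplitude of
#' each window (rectified mean times pi/2, the expectation-matching envelope
#' estimate for narrow-band Gaussian noise), takes the median over the quieter
#' half of the windows, and doubles it so the estimate tracks the typical peak
#' amplitude of the background (about 2.5 sigma on Gaussian noise, near the
#' Rayleigh 95th percentile of the envelope).  Restricting to the quieter half
#' makes the estimate insensitive to sparse high-amplitude events.
#'
#' @param x numeric vector, a band-filtered single-channel signal.
#' @param fs sampling rate in Hz.
#' @param window window length in seconds.
#' @return Positive scalar baseline amplitude (same units as `x`).
#' @examples
#' estimateBaseline(rnorm(8000), 2000)
#' @export
estimateBaseline <- function(x, fs, window = 1) {
  if (length(x) < 2 * fs)
    stop("need at least 2 s of signal to estimate a baseline")
  if (all(x == 0)) stop("all-zero input: baseline would be zero")
  wlen <- max(1L, as.integer(round(window * fs)))
  nw <- floor(length(x) / wlen)
  idx <- rep(seq_len(nw), each = wlen)
  env <- vapply(split(abs(x[seq_len(nw * wlen)]), idx), mean, 0) * (pi / 2)
  quiet <- sort(env)[seq_len(max(1L, floor(nw / 2)))]
  2 * median(quiet)
}

#' Encode a filtered signal into UP/DN spikes (asynchronous delta modulation)
#'
#' A running reference starts at the first sample; whenever the signal rises
#' more than `delta = thresholdFraction * baseline` above it an UP spike is
#' emitted and the reference steps up by `delta`; a symmetric rule emits DN
#' spikes.  After a spike of either polarity no spike can occur for the
#' refractory period.  With `interpolationFactor > 1` the signal is first
#' linearly upsampled.  Deterministic; at most one spike per (interpolated)
#' sample.
#'
#' @param x numeric vector, band-filtered single-channel signal.
#' @param params an [admParams()].
#' @param baseline positive baseline amplitude (see [estimateBaseline()]).
#' @param fs sampling rate in Hz.
#' @param band,channel labels stored in the returned train.
#' @return A [SpikeTrain-class].
#' @examples
#' x <- sin(2 * pi * 130 * seq(0, 1, by = 1 / 2000))
#' admEncode(x, admParams(0.5), baseline = 1, fs = 2000)
#' @export
admEncode <- function(x, params, baseline, fs, band = "ripple",
                      channel = "ch1") {
  stopifnot(inherits(params, "ADMParams"))
  if (!(baseline > 0)) stop("baseline must be > 0")
  delta <- params$thresholdFraction * baseline
  if (delta <= 0) stop("degenerate threshold delta = 0")
  k <- params$interpolationFactor
  if (k > 1L) {
    n <- length(x)
    t0 <- (seq_len(n) - 1) / fs
    ti <- seq(0, (n - 1) / fs, by = 1 / (fs * k))
    x <- approx(t0, x, xout = ti)$y
    fs <- fs * k
  }
  enc <- adm_encode_cpp(as.numeric(x), fs, delta, params$refractory)
  SpikeTrain(enc$time, ifelse(enc$polarity > 0, "UP", "DN"),
             band = band, channel = channel, span = length(x) / fs)
}

#' Reconstruct a piecewise-constant signal from an ADM spike train
#'
#' Cumulative sum of `+delta` per UP spike and `-delta` per DN spike from the
#' initial reference.  Serves as the reconstruction oracle for the delta
#' modulator: with zero refractory the sup-norm tracking error of
#' encode-then-decode is bounded by `delta`.
#'
#' @param spikes a [SpikeTrain-class] from [admEncode()].
#' @param delta the threshold amplitude used at encoding.
#' @param fs output sampling rate in Hz.
#' @param span duration in seconds (defaults to the train's span).
#' @param init initial reference value.
#' @return Numeric vector of `round(span * fs)` samples.
#' @export
admDecode <- function(spikes, delta, fs, span = spikes@span, init = 0) {
  n <- round(span * fs)
  t <- (seq_len(n) - 1) / fs
  y <- rep(init, n)
  if (nSpikes(spikes)) {
    step <- ifelse(spikePolarity(spikes) == "UP", delta, -delta)
    # right-continuous: the step applies from the spike time onward
    y <- init + cumsum(c(0, step))[findInterval(t, spikeTimes(spikes)) + 1L]
  }
  y
}

#' Inter-spike-interval quartiles per window class
#'
#' Pools inter-spike intervals over windows of each class (e.g. HFO windows
#' versus background windows) and returns the quartiles in milliseconds,
#' using linear interpolation between order statistics.  Only intervals
#' between consecutive spikes falling inside the same window are counted.
#'
#' @param spikes a [SpikeTrain-class] (subset to one polarity beforehand if
#'   per-polarity statistics are wanted).
#' @param windows data.frame with columns `start`, `end` (seconds) and
#'   `class`.
#' @return data.frame with one row per class: `class`, `n` (number of
#'   intervals), `q1Ms`, `medianMs`, `q3Ms`; classes with fewer than 2 spikes
#'   in every window get `n = 0` and `NA` quartiles (flagged absent, not
#'   zero).
#' @export
isiStats <- function(spikes, windows) {
  stopifnot(all(c("start", "end", "class") %in% names(windows)))
  tms <- spikeTimes(spikes)
  cls <- unique(as.character(windows$class))
  res <- lapply(cls, function(cl) {
    w <- windows[windows$class == cl, , drop = FALSE]
    isis <- unlist(lapply(seq_len(nrow(w)), function(i) {
      inwin <- tms[tms >= w$start[i] & tms < w$end[i]]
      if (length(inwin) >= 2) diff(inwin) else numeric(0)
    }))
    if (length(isis) == 0)
      data.frame(class = cl, n = 0L, q1Ms = NA_real_, medianMs = NA_real_,
                 q3Ms = NA_real_)
    else {
      q <- quantile(isis, c(0.25, 0.5, 0.75), type = 7, names = FALSE) * 1000
      data.frame(class = cl, n = length(isis), q1Ms = q[1], medianMs = q[2],
                 q3Ms = q[3])
    }
  })
  do.call(rbind, res)
}

#' Count UP-DN cycles in a spike train
#'
#' A cycle is a maximal run of one or more UP spikes followed by a maximal
#' run of one or more DN spikes; its duration runs from the first UP of the
#' UP-run to the last DN of the DN-run.  UP-DN cycles proxy individual
#' oscillation periods of the underlying signal.
#'
#' @param spikes a [SpikeTrain-class].
#' @param window optional `c(start, end)` in seconds restricting the count.
#' @return list with `nCycles` and `meanCycleMs` (NA when no cycles).
#' @examples
#' st <- SpikeTrain(1:6 / 1000, c("UP", "DN", "UP", "DN", "UP", "DN"))
#' updnCycles(st)$nCycles  # 3
#' @export
updnCycles <- function(spikes, window = NULL) {
  tms <- spikeTimes(spikes)
  pol <- spikePolarity(spikes)
  if (!is.null(window)) {
    keep <- tms >= window[1] & tms < window[2]
    tms <- tms[keep]
    pol <- pol[keep]
  }
  if (length(tms) < 2) return(list(nCycles = 0L, meanCycleMs = NA_real_))
  r <- rle(pol)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  durs <- numeric(0)
  i <- 1L
  while (i < length(r$values)) {
    if (r$values[i] == "UP" && r$values[i + 1L] == "DN") {
      durs <- c(durs, tms[ends[i + 1L]] - tms[starts[i]])
      i <- i + 2L
    } else i <- i + 1L
  }
  list(nCycles = length(durs),
       meanCycleMs = if (length(durs)) mean(durs) * 1000 else NA_real_)
}

#' Modality presets for the signal-to-spike conversion
#'
#' Threshold fractions and refractory periods per band: iEEG ripple 0.5 /
#' 300 us and fast-ripple 0.3 / 300 us; ECoG fast-ripple 0.5 / 300 us;
#' scalp ripple 0.3 / 1 ms and artifact band 0.3 / 300 us.  The ECoG preset
#' linearly upsamples by 4 before encoding: at the native 2 kHz sampling
#' rate a sampled modulator can emit at most one spike per 0.5 ms, far below
#' the 300 us refractory bound of the continuous-time circuit it emulates,
#' which truncates the burst rates that carry the detection signal.
#'
#' @param modality `"iEEG"`, `"ECoG"` or `"scalp"`.
#' @return Named list (one entry per band) of [admParams()].
#' @export
admPresets <- function(modality = c("iEEG", "ECoG", "scalp")) {
  modality <- match.arg(modality)
  switch(modality,
    iEEG = list(ripple = admParams(0.5, 300e-6),
                FR = admParams(0.3, 300e-6)),
    ECoG = list(FR = admParams(0.5, 300e-6, interpolationFactor = 4L)),
    scalp = list(ripple = admParams(0.3, 1e-3),
                 artifact = admParams(0.3, 300e-6)))
}
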
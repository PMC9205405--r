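#' Specify one synthetic EEG event
#'
#' HFO events (`ripple_hfo`, `fr_hfo`) are Tukey-enveloped sinusoids with
#' exactly `nCycles` periods (at least 4, the defining cycle count of an
#' HFO); `hf_artifact` is the same construction above 500 Hz;
#' `sharp_transient` is a non-oscillatory biphasic pulse of total width
#' `width` (default 8 ms, the typical duration of a fast transient).
#'
#' `amplitudeRatio` is the SNR control: the event envelope amplitude divided
#' by the typical peak amplitude of the background in the event's band,
#' operationalised as half the peak-to-peak excursion of the in-band
#' background over event-length flanking windows.  With this convention the
#' SNR measured by [snr()] (event peak-to-peak over flanking peak-to-peak)
#' reproduces `amplitudeRatio`.
#'
#' @param kind `"ripple_hfo"`, `"fr_hfo"`, `"hf_artifact"` or
#'   `"sharp_transient"`.
#' @param onset event onset in seconds.
#' @param centerFreq oscillation frequency in Hz (ripple 80-250, fast ripple
#'   250-500, artifact 500-900).
#' @param nCycles number of oscillation periods (>= 4 for HFO kinds).
#' @param amplitudeRatio dimensionless SNR control.
#' @param channel target channel index.
#' @param width total width in seconds (sharp transients only, <= 10 ms).
#' @return list of class `EventSpec`.
#' @export
eventSpec <- function(kind = c("ripple_hfo", "fr_hfo", "hf_artifact",
                               "sharp_transient"),
                      onset, centerFreq = NULL, nCycles = 8,
                      amplitudeRatio = 4, channel = 1L, width = 0.008) {
  kind <- match.arg(kind)
  bandOf <- list(ripple_hfo = c(80, 250), fr_hfo = c(250, 500),
                 hf_artifact = c(500, 900))
  if (kind == "sharp_transient") {
    if (width > 0.010)
      stop(sprintf("EventSpec (sharp_transient @ %gs): width %g s exceeds 10 ms",
                   onset, width))
    centerFreq <- NA_real_
    nCycles <- NA_real_
  } else {
    if (is.null(centerFreq))
      centerFreq <- mean(bandOf[[kind]])
    b <- bandOf[[kind]]
    lowOk <- if (kind == "hf_artifact") centerFreq > b[1] else centerFreq >= b[1]
    if (!lowOk || centerFreq > b[2])
      stop(sprintf("EventSpec (%s @ %gs): centerFreq %g Hz outside band %g-%g Hz",
                   kind, onset, centerFreq, b[1], b[2]))
    if (kind != "hf_artifact" && nCycles < 4)
      stop(sprintf("EventSpec (%s @ %gs): HFO needs >= 4 cycles, got %g",
                   kind, onset, nCycles))
  }
  structure(list(kind = kind, onset = onset, centerFreq = centerFreq,
                 nCycles = nCycles, amplitudeRatio = amplitudeRatio,
                 channel = as.integer(channel), width = width),
            class = "EventSpec")
}

.eventDuration <- function(ev) {
  if (ev$kind == "sharp_transient") ev$width else ev$nCycles / ev$centerFreq
}

.eventBand <- function(ev) {
  switch(ev$kind,
         ripple_hfo = bandSpec("ripple", causal = FALSE),
         fr_hfo = bandSpec("FR", causal = FALSE),
         hf_artifact = bandSpec("artifact", causal = FALSE),
         sharp_transient = NULL)
}

.tukey <- function(n, alpha = 0.5) {
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / alpha - 1)))
  w
}

#' Noiseless template of a synthetic event
#'
#' Unit-amplitude waveform added (scaled) to the background: a Tukey-windowed
#' sinusoid with exactly `nCycles` periods for oscillatory kinds, a biphasic
#' single-cycle pulse for sharp transients.
#'
#' @param ev an [eventSpec()].
#' @param fs sampling rate in Hz.
#' @return numeric vector of `round(duration * fs)` samples.
#' @export
eventTemplate <- function(ev, fs) {
  d <- .eventDuration(ev)
  n <- round(d * fs)
  t <- (seq_len(n) - 1) / fs
  if (ev$kind == "sharp_transient") {
    # biphasic pulse: one full sine period under a Hann envelope
    sin(2 * pi * t / ev$width) * sin(pi * t / ev$width)^2
  } else {
    sin(2 * pi * ev$centerFreq * t) * .tukey(n, 0.5)
  }
}

#' Specify a synthetic EEG recording
#'
#' The background is band-unlimited white or 1/f ("pink") Gaussian noise at a
#' given RMS amplitude (arbitrary units, treated as microvolts; the detection
#' pipeline is scale-invariant because spiking thresholds are relative to the
#' estimated baseline).  Events from `events` are added on top.  The seed
#' fully determines the output.
#'
#' @param duration recording duration in seconds (> 0).
#' @param samplingRate sampling rate in Hz (>= 2000, to resolve 500 Hz
#'   content with margin).
#' @param nChannels number of channels.
#' @param background `"pink"` (1/f, EEG-like) or `"white"`.
#' @param amplitude background RMS amplitude in microvolts.
#' @param events list of [eventSpec()]s.
#' @param seed integer seed.
#' @return list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(duration, samplingRate = 2000, nChannels = 1L,
                          background = c("pink", "white"), amplitude = 10,
                          events = list(), seed = 1L) {
  background <- match.arg(background)
  if (duration <= 0) stop("duration must be > 0")
  if (samplingRate < 2000) stop("samplingRate must be >= 2000 Hz")
  for (ev in events) {
    if (!inherits(ev, "EventSpec")) stop("events must be eventSpec() objects")
    if (ev$onset < 0 || ev$onset + .eventDuration(ev) > duration)
      stop(sprintf("EventSpec (%s @ %gs) extends outside [0, %g s]",
                   ev$kind, ev$onset, duration))
    if (ev$channel < 1 || ev$channel > nChannels)
      stop(sprintf("EventSpec (%s @ %gs): channel %d does not exist",
                   ev$kind, ev$onset, ev$channel))
    nyq <- samplingRate / 2
    f <- if (ev$kind == "sharp_transient") 1 / ev$width else ev$centerFreq
    if (f >= nyq)
      stop(sprintf("EventSpec (%s @ %gs): content at %g Hz at or above Nyquist",
                   ev$kind, ev$onset, f))
  }
  structure(list(duration = duration, samplingRate = samplingRate,
                 nChannels = as.integer(nChannels), background = background,
                 amplitude = amplitude, events = events,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

.pinkNoise <- function(n, fs) {
  w <- rnorm(n)
  W <- fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)          # two-sided spectrum symmetry
  f <- pmax(f, 1)               # clamp below 1 Hz to avoid runaway drift
  W <- W / sqrt(f)
  W[1] <- 0
  x <- Re(fft(W, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate an annotated synthetic EEG recording
#'
#' Draws the background noise per channel, scales each planned event against
#' the measured in-band background at its flanks (see [eventSpec()]), and
#' adds the noiseless templates.  Identical spec (including seed) gives
#' bit-identical output.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `recording` (an [EEGRecording-class]) and `groundTruth`
#'   (data.frame: channel, kind, start, end, sorted by channel and start).
#' @examples
#' spec <- syntheticSpec(10, 2000, events = list(
#'   eventSpec("ripple_hfo", onset = 4, centerFreq = 150)))
#' out <- generateSynthetic(spec)
#' out$groundTruth
#' @export
generateSynthetic <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  fs <- spec$samplingRate
  n <- round(spec$duration * fs)
  set.seed(spec$seed)
  noise <- matrix(0, n, spec$nChannels)
  for (ch in seq_len(spec$nChannels)) {
    noise[, ch] <- if (spec$background == "pink")
      .pinkNoise(n, fs) * spec$amplitude
    else rnorm(n) * spec$amplitude
  }
  samples <- noise
  gt <- data.frame(channel = character(0), kind = character(0),
                   start = numeric(0), end = numeric(0))
  chNames <- paste0("ch", seq_len(spec$nChannels))
  # cache the band-filtered noise per (channel, band) for amplitude calibration
  bandCache <- new.env(parent = emptyenv())
  bandNoise <- function(ch, ev) {
    band <- .eventBand(ev)
    if (is.null(band)) return(noise[, ch])
    key <- paste(ch, band$name)
    if (is.null(bandCache[[key]]))
      bandCache[[key]] <- filterBand(noise[, ch], band, fs = fs)
    bandCache[[key]]
  }
  for (ev in spec$events) {
    d <- .eventDuration(ev)
    tpl <- eventTemplate(ev, fs)
    i0 <- round(ev$onset * fs) + 1L
    idx <- i0:(i0 + length(tpl) - 1L)
    bn <- bandNoise(ev$channel, ev)
    p2p <- function(a, b) {           # clip flank to the recording
      a <- max(1L, a); b <- min(n, b)
      if (b <= a) return(NA_real_)
      seg <- bn[a:b]
      max(seg) - min(seg)
    }
    len <- length(tpl)
    flanks <- c(p2p(i0 - len, i0 - 1L), p2p(i0 + len, i0 + 2L * len - 1L))
    flank <- mean(flanks, na.rm = TRUE)
    if (!is.finite(flank) || flank <= 0) flank <- 2 * sd(bn)
    # solve for the template amplitude so that the measured in-band
    # peak-to-peak of template-plus-background equals ratio x flank p2p:
    # one fixed-point step on p2p(A tpl + noise) ~ 2A + c
    a1 <- ev$amplitudeRatio * flank / 2
    seg <- bn[idx]
    cbias <- (max(a1 * tpl + seg) - min(a1 * tpl + seg)) - 2 * a1
    amp <- max((ev$amplitudeRatio * flank - cbias) / 2, 0.2 * a1)
    samples[idx, ev$channel] <- samples[idx, ev$channel] + amp * tpl
    gt <- rbind(gt, data.frame(channel = chNames[ev$channel], kind = ev$kind,
                               start = ev$onset, end = ev$onset + d))
  }
  gt <- gt[order(gt$channel, gt$start), , drop = FALSE]
  rownames(gt) <- NULL
  list(recording = EEGRecording(samples, fs, chNames), groundTruth = gt)
}

#' Write / read ground-truth annotations as TSV
#'
#' Columns: channel, kind, start_s, end_s -- the same schema used for
#' detected events, so synthetic truth and detections can be scored directly.
#'
#' @param gt data.frame with columns channel, kind (or status), start, end.
#' @param path file path.
#' @return `path` invisibly (write) or the data.frame (read).
#' @export
writeAnnotations <- function(gt, path) {
  kind <- if ("kind" %in% names(gt)) gt$kind else gt$status
  out <- data.frame(channel = gt$channel, kind = kind,
                    start_s = gt$start, end_s = gt$end)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  data.frame(channel = as.character(d$channel), kind = d$kind,
             start = d$start_s, end = d$end_s)
}

#' Serialize / restore a synthetic spec as YAML
#'
#' @param spec a [syntheticSpec()].
#' @param path YAML file path.
#' @return `path` invisibly (write) or the `SyntheticSpec` (read).
#' @export
syntheticSpecToYAML <- function(spec, path) {
  obj <- unclass(spec)
  obj$events <- lapply(spec$events, unclass)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname syntheticSpecToYAML
#' @export
syntheticSpecFromYAML <- function(path) {
  obj <- yaml::read_yaml(path)
  events <- lapply(obj$events, function(e)
    eventSpec(e$kind, e$onset,
              centerFreq = if (is.null(e$centerFreq) || is.na(e$centerFreq))
                NULL else e$centerFreq,
              nCycles = if (is.na(e$nCycles)) 8 else e$nCycles,
              amplitudeRatio = e$amplitudeRatio, channel = e$channel,
              width = e$width))
  syntheticSpec(obj$duration, obj$samplingRate, obj$nChannels,
                obj$background, obj$amplitude, events, obj$seed)
}
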
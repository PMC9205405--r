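#' Modality preset: bands, conversion parameters, architecture, decision rule
#'
#' iEEG: ripple (threshold fraction 0.5) and fast-ripple (0.3) bands,
#' 300 us refractory, core architecture, HFO-area/resection rule.
#' ECoG: fast-ripple band (0.5, 300 us), core plus in-band artifact
#' rejection, residual max-rate rule (1 HFO/min).
#' Scalp: ripple band (0.3, 1 ms refractory) plus the 500-900 Hz artifact
#' band (0.3, 300 us), core plus in-band rejection plus artifact-detection
#' network, affected-hemisphere median-rate rule (0.25 HFO/min).
#'
#' Each preset also carries the frozen neuron calibration for its
#' deployment (see [snnCalibration()]); like hardware bias settings, these
#' are fixed per modality, never per run.  The scalp deployment runs at a
#' lower layer and dis-inhibitory threshold because its 1 ms conversion
#' refractory caps attainable spike rates (and hence synaptic drive) well
#' below the intracranial configurations.
#'
#' @param modality `"iEEG"`, `"ECoG"` or `"scalp"`.
#' @param nNeurons second-layer size.
#' @param windowMs event-marking window (ms).
#' @return list of class `ModalityPreset`.
#' @export
modalityPreset <- function(modality = c("iEEG", "ECoG", "scalp"),
                           nNeurons = 256L, windowMs = 15) {
  modality <- match.arg(modality)
  arch <- switch(modality, iEEG = "core", ECoG = "core_inband",
                 scalp = "core_inband_artifact")
  rule <- switch(modality,
    iEEG = list(type = "hfo_area", percentile = 95),
    ECoG = list(type = "max_rate", threshold = 1),
    scalp = list(type = "median_rate", threshold = 0.25))
  calibration <- snnCalibration()
  if (modality == "scalp") {
    calibration$threshold <- 0.035
    calibration$disThreshold <- 0.15
  }
  structure(list(modality = modality, bands = bandPresets(modality),
                 adm = admPresets(modality), architecture = arch,
                 nNeurons = as.integer(nNeurons), windowMs = windowMs,
                 rule = rule, calibration = calibration),
            class = "ModalityPreset")
}

#' @export
print.ModalityPreset <- function(x, ...) {
  cat(sprintf("ModalityPreset %s: bands %s, architecture %s, %d neurons\n",
              x$modality, paste(names(x$bands), collapse = "+"),
              x$architecture, x$nNeurons))
  invisible(x)
}

#' Run the full HFO detection pipeline on a recording
#'
#' For each channel: band-pass filter per the preset, estimate the baseline
#' of each filtered trace, convert to UP/DN spikes, simulate the detector
#' network, suppress outlier neurons, mark events in 15 ms windows, and
#' (scalp) screen events against the artifact-detection raster.  Returns
#' per-channel events and HFO rates, and applies the modality decision rule
#' when clinical side-information is supplied.
#'
#' @param rec an [EEGRecording-class] (bipolar channels).
#' @param preset a [modalityPreset()].
#' @param clinical optional data.frame (see [readClinicalTable()]) for this
#'   recording's channels; enables the prediction step.
#' @param seed integer seed for network parameter sampling.
#' @param dt integration step in seconds.
#' @param verbose print per-stage progress.
#' @return list of class `DetectionResult`: `events` (data.frame),
#'   `rates` (named vector, HFO/min), `prediction` (rule output or NULL),
#'   `network` (the sampled [NetworkSpec-class]), `preset`, `seed`.
#' @export
runDetection <- function(rec, preset, clinical = NULL, seed = 1L, dt = 5e-5,
                         verbose = FALSE) {
  stopifnot(is(rec, "EEGRecording"), inherits(preset, "ModalityPreset"))
  fs <- samplingRate(rec)
  for (b in preset$bands)
    if (b$high >= fs / 2)
      stop(sprintf("preset band %s (%g-%g Hz) needs a sampling rate > %g Hz",
                   b$name, b$low, b$high, 2 * b$high))
  span <- recordingDuration(rec)
  coreBands <- setdiff(names(preset$bands), "artifact")
  inputNames <- as.vector(vapply(coreBands,
                                 function(b) paste0(c("UP_", "DN_"), b),
                                 character(2)))
  cal <- preset$calibration
  net <- buildNetwork(preset$architecture, inputNames,
                      nNeurons = preset$nNeurons, seed = seed,
                      neuron = neuronParams(threshold = cal$threshold),
                      calibration = cal)
  events <- NULL
  rates <- numeric(0)
  stage <- function(what, ch, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed on channel %s: %s", what, ch,
                   conditionMessage(e)), call. = FALSE))
  }
  for (ch in channelNames(rec)) {
    x <- getChannel(rec, ch)
    trains <- list()
    for (bn in names(preset$bands)) {
      b <- preset$bands[[bn]]
      xf <- stage("filter", ch, filterBand(x, b, fs = fs))
      bl <- stage("baseline", ch, estimateBaseline(xf, fs))
      trains[[bn]] <- stage("adm", ch,
        admEncode(xf, preset$adm[[bn]], bl, fs, band = bn, channel = ch))
      if (verbose)
        message(sprintf("%s/%s: baseline %.3g, %d spikes", ch, bn, bl,
                        nSpikes(trains[[bn]])))
    }
    inputs <- spikeTrainInputs(trains)
    res <- stage("snn", ch, simulateNetwork(net, inputs, span = span, dt = dt))
    raster <- suppressOutlierNeurons(populationSpikes(res, "core"), span,
                                     preset$windowMs)
    eoi <- markEvents(raster, span, preset$windowMs, channel = ch)
    artifactRaster <- if (preset$architecture == "core_inband_artifact")
      suppressOutlierNeurons(populationSpikes(res, "artifact"), span,
                             preset$windowMs)
    else NULL
    ev <- rejectArtifacts(eoi, artifactRaster, preset$windowMs)
    events <- rbind(events, ev)
    rates[ch] <- hfoRate(ev, span / 60)
    if (verbose)
      message(sprintf("%s: %d events, %.2f HFO/min", ch,
                      sum(ev$status == "HFO"), rates[ch]))
  }
  if (is.null(events))
    events <- data.frame(channel = character(0), start = numeric(0),
                         end = numeric(0), nSpikes = integer(0),
                         status = character(0))
  prediction <- NULL
  if (!is.null(clinical)) {
    rule <- preset$rule
    prediction <- switch(rule$type,
      hfo_area = {
        area <- hfoArea(rates, rule$percentile)
        resected <- clinical$channel[clinical$resected == 1]
        outcome <- unique(clinical$outcome[!is.na(clinical$outcome) &
                                           clinical$outcome != ""])
        c(list(area = area, resected = resected),
          if (length(outcome) == 1)
            predictOutcomeIEEG(area, resected, outcome))
      },
      max_rate = predictOutcomeECoG(rates, rule$threshold),
      median_rate = {
        aff <- clinical$channel[clinical$hemisphere == "affected"]
        predictEpilepsyScalp(rates[names(rates) %in% aff], rule$threshold)
      })
  }
  structure(list(events = events, rates = rates, prediction = prediction,
                 network = net, preset = preset, seed = as.integer(seed)),
            class = "DetectionResult")
}

#' @export
print.DetectionResult <- function(x, ...) {
  cat(sprintf("DetectionResult (%s): %d HFO on %d channel(s)\n",
              x$preset$modality, sum(x$events$status == "HFO"),
              length(x$rates)))
  print(round(x$rates, 2))
  if (!is.null(x$prediction) && !is.null(x$prediction$prediction))
    cat("prediction:", x$prediction$prediction, "\n")
  invisible(x)
}

#' Sweep the signal-to-spike conversion parameters
#'
#' Runs the encode-simulate-mark chain for every grid point and counts, per
#' point, the detections that intersect a reference interval (agreements)
#' and those that do not (disagreements).  Points are ranked by agreements
#' descending, then disagreements ascending -- the optimum reproduces more
#' reference detections with fewer spurious ones.
#'
#' @param x single-channel band-filtered signal.
#' @param fs sampling rate in Hz.
#' @param grid data.frame with columns `thresholdFraction`, `refractory`,
#'   `interpolationFactor`.
#' @param reference data.frame of reference intervals (`start`, `end`).
#' @param band band label for the spike trains.
#' @param nNeurons,seed,dt passed to the network stage.
#' @return `grid` with added `agree`, `disagree`, `rank`, sorted by rank.
#' @export
sweepADM <- function(x, fs, grid, reference, band = "ripple",
                     nNeurons = 64L, seed = 1L, dt = 5e-5) {
  if (nrow(grid) == 0) stop("empty grid")
  span <- length(x) / fs
  bl <- estimateBaseline(x, fs)
  net <- buildNetwork("core", paste0(c("UP_", "DN_"), band),
                      nNeurons = nNeurons, seed = seed)
  agree <- integer(nrow(grid))
  disagree <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- admParams(grid$thresholdFraction[i], grid$refractory[i],
                   grid$interpolationFactor[i])
    st <- admEncode(x, p, bl, fs, band = band)
    trains <- list()
    trains[[band]] <- st
    res <- simulateNetwork(net, spikeTrainInputs(trains), span = span, dt = dt)
    raster <- suppressOutlierNeurons(populationSpikes(res, "core"), span)
    ev <- rejectArtifacts(markEvents(raster, span))
    det <- ev[ev$status == "HFO", , drop = FALSE]
    hits <- vapply(seq_len(nrow(det)), function(k)
      any(reference$start < det$end[k] & reference$end > det$start[k]),
      logical(1))
    agree[i] <- sum(hits)
    disagree[i] <- sum(!hits)
  }
  out <- cbind(grid, agree = agree, disagree = disagree)
  ord <- order(-out$agree, out$disagree)
  out$rank[ord] <- seq_along(ord)
  out[ord, , drop = FALSE]
}

#' Render confusion summaries as a Table-3-style cohort report
#'
#' One column per detector/modality, rows specificity, sensitivity, NPV,
#' PPV, accuracy formatted as `pct (lower upper%)`, undefined metrics as
#' `-`.
#'
#' @param ... named [confusionMetrics()] results.
#' @return character matrix (rows = metrics).
#' @export
cohortReport <- function(...) {
  cols <- list(...)
  metrics <- c("specificity", "sensitivity", "npv", "ppv", "accuracy")
  out <- vapply(cols, function(cs) {
    vapply(metrics, function(m) {
      r <- cs[cs$metric == m, ]
      if (is.na(r$pct)) "-" else
        sprintf("%d (%d %d%%)", r$pct, r$pctLower, r$pctUpper)
    }, "")
  }, character(5))
  rownames(out) <- metrics
  out
}
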
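#' Remove continuously spiking outlier neurons from a raster
#'
#' Neurons whose firing occupies more than `maxOccupancy` of all 15 ms
#' windows of the recording are considered uninformative and are removed for
#' the whole recording (removal is recording-global, never per-segment).
#'
#' @param raster data.frame with columns `neuron`, `time` (seconds).
#' @param span recording duration in seconds.
#' @param windowMs marking window in milliseconds.
#' @param maxOccupancy occupancy fraction above which a neuron is removed.
#' @return The filtered raster; removed neuron ids in attribute `"removed"`.
#' @export
suppressOutlierNeurons <- function(raster, span, windowMs = 15,
                                   maxOccupancy = 0.5) {
  w <- windowMs / 1000
  nWin <- max(1L, ceiling(span / w - 1e-9))
  if (nrow(raster) == 0) {
    attr(raster, "removed") <- integer(0)
    return(raster)
  }
  win <- floor(raster$time / w)
  occ <- vapply(split(win, raster$neuron),
                function(v) length(unique(v)) / nWin, 0)
  removed <- as.integer(names(occ)[occ > maxOccupancy])
  out <- raster[!raster$neuron %in% removed, , drop = FALSE]
  if (nrow(out) == 0 && length(removed))
    warning("all neurons removed as outliers; raster is empty")
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Mark events from a second-layer raster (15 ms windows)
#'
#' The recording is tiled into consecutive `windowMs` windows anchored at
#' t = 0.  Any window containing at least one spike (from any neuron) is
#' marked, and maximal runs of marked windows are concatenated into one
#' event whose boundaries are the run's window boundaries.  Events are
#' labelled `"EoI"` (event of interest): they become `"HFO"` after the
#' artifact screen of [rejectArtifacts()] (which, with no artifact spikes,
#' promotes every EoI).
#'
#' @param raster data.frame with columns `neuron`, `time` (after
#'   [suppressOutlierNeurons()]).
#' @param span recording duration in seconds.
#' @param windowMs window length in milliseconds.
#' @param channel channel label for the returned events.
#' @return data.frame: channel, start, end, nSpikes, status (all `"EoI"`).
#' @export
markEvents <- function(raster, span, windowMs = 15, channel = "ch1") {
  empty <- data.frame(channel = character(0), start = numeric(0),
                      end = numeric(0), nSpikes = integer(0),
                      status = character(0))
  if (nrow(raster) == 0) return(empty)
  w <- windowMs / 1000
  win <- floor(raster$time / w)
  marked <- sort(unique(win))
  runEnds <- c(which(diff(marked) > 1), length(marked))
  runStarts <- c(1L, head(runEnds, -1L) + 1L)
  ev <- data.frame(
    channel = channel,
    start = marked[runStarts] * w,
    end = (marked[runEnds] + 1) * w,
    nSpikes = vapply(seq_along(runStarts), function(i)
      sum(win >= marked[runStarts[i]] & win <= marked[runEnds[i]]), 0L),
    status = "EoI")
  ev$end <- pmin(ev$end, ceiling(span / w - 1e-9) * w)
  ev
}

#' Screen events of interest against the artifact-detection raster
#'
#' Every spike of the artifact-detection network at time `t` defines an
#' artifact interval `[t, t + windowMs)`.  An EoI with any temporal
#' intersection with an artifact interval is rejected
#' (`status = "rejected_artifact"`); all others are promoted to `"HFO"`.
#' Intervals are half-open, so an artifact starting exactly at an EoI's end
#' does not reject it.
#'
#' @param eoi data.frame from [markEvents()].
#' @param artifactRaster data.frame with column `time` (artifact-network
#'   spikes); an empty data.frame promotes every EoI.
#' @param windowMs artifact interval length in milliseconds.
#' @return `eoi` with updated `status`.
#' @export
rejectArtifacts <- function(eoi, artifactRaster = NULL, windowMs = 15) {
  if (nrow(eoi) == 0) return(eoi)
  w <- windowMs / 1000
  at <- if (is.null(artifactRaster) || nrow(artifactRaster) == 0)
    numeric(0) else sort(artifactRaster$time)
  hit <- vapply(seq_len(nrow(eoi)), function(i) {
    any(at < eoi$end[i] & (at + w) > eoi$start[i])
  }, logical(1))
  eoi$status <- ifelse(hit, "rejected_artifact", "HFO")
  eoi
}

#' Score detected events against reference intervals
#'
#' An interval of `truth` counts as hit when any detection with
#' `status == "HFO"` on the same channel intersects it (half-open interval
#' intersection).
#'
#' @param events detections (data.frame: channel, start, end, status).
#' @param truth reference intervals (data.frame: channel, start, end,
#'   optionally kind).
#' @param kinds optional subset of `truth$kind` to score.
#' @return list: `nTruth`, `nHit`, `sensitivity`, and per-interval logical
#'   `hit`.
#' @export
scoreDetections <- function(events, truth, kinds = NULL) {
  if (!is.null(kinds) && "kind" %in% names(truth))
    truth <- truth[truth$kind %in% kinds, , drop = FALSE]
  det <- events[events$status == "HFO", , drop = FALSE]
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    d <- det[det$channel == truth$channel[i], , drop = FALSE]
    any(d$start < truth$end[i] & d$end > truth$start[i])
  }, logical(1))
  list(nTruth = nrow(truth), nHit = sum(hit),
       sensitivity = if (nrow(truth)) sum(hit) / nrow(truth) else NA_real_,
       hit = hit)
}

#' Write detected events as TSV
#'
#' Same schema as [writeAnnotations()] (`kind` column holds the status), so
#' detections can be scored against synthetic ground truth directly.
#'
#' @param events data.frame: channel, start, end, status.
#' @param path file path.
#' @export
writeEvents <- function(events, path) {
  out <- data.frame(channel = events$channel, kind = events$status,
                    start_s = events$start, end_s = events$end)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
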
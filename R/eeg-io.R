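#' Read a multichannel recording
#'
#' CSV files hold one column per channel with a header row of channel names;
#' the sampling rate comes from the `samplingRate` argument or from a YAML
#' sidecar `<path>.yaml` with a `sampling_rate` field.  EDF files are
#' standard 16-bit continuous EDF; the sampling rate is taken from the
#' header.  Amplitudes are microvolts; channel order is preserved.
#'
#' @param path input file.
#' @param format `"csv"` or `"edf"` (default guessed from the extension).
#' @param samplingRate sampling rate in Hz (CSV only).
#' @return An [EEGRecording-class].
#' @export
readRecording <- function(path, format = NULL, samplingRate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  format <- match.arg(tolower(format), c("csv", "edf"))
  if (format == "edf") return(.readEDF(path))
  d <- read.csv(path, check.names = FALSE)
  if (is.null(samplingRate)) {
    sidecar <- paste0(path, ".yaml")
    if (file.exists(sidecar))
      samplingRate <- yaml::read_yaml(sidecar)$sampling_rate
  }
  if (is.null(samplingRate))
    stop("missing sampling rate: pass 'samplingRate' or provide ", path,
         ".yaml with a 'sampling_rate' field")
  if (any(!vapply(d, is.numeric, TRUE))) stop("non-numeric channel data")
  EEGRecording(as.matrix(d), samplingRate, names(d))
}

#' Write a recording to CSV (with YAML sidecar) or EDF
#'
#' CSV: one column per channel, header row, plus `<path>.yaml` carrying the
#' sampling rate.  EDF: standard 16-bit continuous EDF, physical dimension
#' "uV" (amplitudes are quantised to 16 bits of the per-channel range).
#'
#' @param rec an [EEGRecording-class].
#' @param path output file.
#' @param format `"csv"` or `"edf"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, format = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  if (is.null(format))
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  format <- match.arg(tolower(format), c("csv", "edf"))
  if (format == "edf") return(.writeEDF(rec, path))
  d <- as.data.frame(rec@samples)
  names(d) <- channelNames(rec)
  write.csv(d, path, row.names = FALSE)
  yaml::write_yaml(list(sampling_rate = samplingRate(rec)),
                   paste0(path, ".yaml"))
  invisible(path)
}

.splitChannelName <- function(nm) {
  m <- regmatches(nm, regexec("^([A-Za-z]+)([0-9]+)$", nm))[[1]]
  if (length(m) == 3) list(prefix = m[2], num = as.integer(m[3]))
  else list(prefix = nm, num = NA_integer_)
}

#' Construct bipolar channels
#'
#' Each output channel is anode minus cathode.  When the two contacts share
#' an alphabetic prefix the channel is named in the clinical style
#' `"AR2-3"`; otherwise the full names are joined (`"A-B"`).  Without an
#' explicit pair list, adjacent contacts on the same shaft/strip are paired
#' by name-numeric order (`AR1-2`, `AR2-3`, ...), the standard clinical
#' convention.
#'
#' @param rec an [EEGRecording-class] of referential channels.
#' @param pairs optional 2-column matrix/data.frame (anode, cathode) of
#'   channel names.
#' @return An [EEGRecording-class] of bipolar channels.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(6000), ncol = 3), 2000,
#'                     c("AR1", "AR2", "AR3"))
#' channelNames(makeBipolar(rec))  # "AR1-2" "AR2-3"
#' @export
makeBipolar <- function(rec, pairs = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  if (is.null(pairs)) {
    parts <- lapply(channelNames(rec), .splitChannelName)
    prefixes <- vapply(parts, `[[`, "", "prefix")
    nums <- vapply(parts, `[[`, 1L, "num")
    pairs <- do.call(rbind, lapply(unique(prefixes), function(p) {
      i <- which(prefixes == p & !is.na(nums))
      i <- i[order(nums[i])]
      if (length(i) < 2) return(NULL)
      cbind(channelNames(rec)[i[-length(i)]], channelNames(rec)[i[-1]])
    }))
    if (is.null(pairs)) stop("no adjacent contact pairs could be formed")
  }
  pairs <- as.matrix(pairs)
  miss <- setdiff(unique(as.vector(pairs)), channelNames(rec))
  if (length(miss))
    stop("missing electrode name(s): ", paste(miss, collapse = ", "))
  out <- matrix(0, nSamples(rec), nrow(pairs))
  nms <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]
    b <- pairs[k, 2]
    out[, k] <- getChannel(rec, a) - getChannel(rec, b)
    pa <- .splitChannelName(a)
    pb <- .splitChannelName(b)
    nms[k] <- if (!is.na(pa$num) && !is.na(pb$num) && pa$prefix == pb$prefix)
      paste0(a, "-", pb$num) else paste0(a, "-", b)
  }
  EEGRecording(out, samplingRate(rec), nms)
}

#' Read a clinical side-information table
#'
#' Tab-separated with columns `patient_id`, `channel`, `resected` (0/1,
#' iEEG), `hemisphere` (`affected`/`non-affected`, scalp), `phase`
#' (`pre`/`post`, ECoG), `outcome` (`seizure_free`/`recurrence`) and
#' `seizure_freq_per_month`.  Unused columns may be empty or absent.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readClinicalTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "channel") %in% names(d)))
    stop("clinical table needs at least patient_id and channel columns")
  if ("seizure_freq_per_month" %in% names(d) &&
      any(d$seizure_freq_per_month < 0, na.rm = TRUE))
    stop("seizure_freq_per_month must be >= 0")
  d
}
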
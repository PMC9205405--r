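# Minimal reader/writer for standard continuous 16-bit EDF.
# One data-record per second; physical dimension fixed to "uV".

.edfPad <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

.writeEDF <- function(rec, path) {
  fs <- samplingRate(rec)
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  x <- rec@samples
  ns <- ncol(x)
  nrec <- as.integer(ceiling(nrow(x) / fs))
  pad <- nrec * fs - nrow(x)
  if (pad > 0) x <- rbind(x, matrix(0, pad, ns))
  physMax <- apply(abs(x), 2, max)
  physMax[physMax == 0] <- 1
  physMax <- physMax * 1.0001
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(.edfPad(s, width), con, width, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate X X X X", 80)
  wr("01.01.26", 8)
  wr("00.00.00", 8)
  wr(as.character(256L * (ns + 1L)), 8)
  wr("", 44)
  wr(as.character(nrec), 8)
  wr("1", 8)
  wr(as.character(ns), 4)
  for (nm in channelNames(rec)) wr(nm, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.8g", -physMax[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.8g", physMax[i]), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(fs), 8)
  for (i in seq_len(ns)) wr("", 32)
  # same affine map the reader applies: [-physMax, physMax] <-> [-32768, 32767]
  for (r in seq_len(nrec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((x[rows, i] + physMax[i]) * 65535 / (2 * physMax[i])) - 32768
      dig <- as.integer(pmax(-32768, pmin(32767, dig)))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

.readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    raw <- readBin(con, "raw", width)
    trimws(rawToChar(raw))
  }
  rd(8)                      # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)          # transducer
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)          # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("EDF with per-signal sampling rates is not supported")
  fs <- spr[1] / recDur
  x <- matrix(0, nrec * spr[1], ns)
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- physMin[i] + (dig - digMin[i]) *
        (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
      x[((r - 1L) * spr[i] + 1L):(r * spr[i]), i] <- phys
    }
  }
  EEGRecording(x, fs, labels)
}
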
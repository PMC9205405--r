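#' HFO rate of a channel
#'
#' Number of detected HFO (events with `status == "HFO"`) divided by the
#' recording duration in minutes.
#'
#' @param events data.frame of events for one channel (or a count).
#' @param minutes recording duration in minutes (> 0).
#' @return rate in HFO/min.
#' @examples
#' hfoRate(12, 4)  # 3
#' @export
hfoRate <- function(events, minutes) {
  if (minutes <= 0) stop("minutes must be > 0")
  n <- if (is.data.frame(events)) sum(events$status == "HFO") else events
  n / minutes
}

#' HFO area: channels whose rate exceeds the 95th percentile
#'
#' Channels whose (per-patient mean) HFO rate strictly exceeds the given
#' percentile of the channel-rate distribution (linear-interpolation
#' quantile).  With all-equal rates the strict exceedance rule yields an
#' empty area.
#'
#' @param rates named numeric vector of per-channel rates (HFO/min); for
#'   multiple recordings per patient, pass the per-channel means.
#' @param percentile percentile in \[0, 100\].
#' @return character vector of channel names in the area.
#' @examples
#' hfoArea(c(A = 10, B = 0, C = 0, D = 0))
#' @export
hfoArea <- function(rates, percentile = 95) {
  if (length(rates) < 2) stop("need at least 2 channels")
  if (is.null(names(rates))) names(rates) <- paste0("ch", seq_along(rates))
  thr <- quantile(rates, percentile / 100, type = 7, names = FALSE)
  names(rates)[rates > thr]
}

#' Seizure-outcome prediction from HFO area and resection (iEEG)
#'
#' If the HFO area is fully contained in the resected channel set the
#' prediction is seizure freedom, otherwise seizure recurrence.  Crossing
#' the prediction with the actual outcome gives the confusion label:
#' TP = predicted recurrence and seizures recurred, TN = predicted freedom
#' and patient seizure-free, FN = predicted freedom but seizures recurred,
#' FP = predicted recurrence but patient seizure-free.
#'
#' @param area channel names in the HFO area (see [hfoArea()]).
#' @param resected channel names resected at surgery.
#' @param outcome `"seizure_free"` or `"recurrence"`.
#' @return list: `prediction`, `label` (TP/TN/FP/FN).
#' @examples
#' predictOutcomeIEEG(c("A"), c("B", "C"), "recurrence")$label  # TP
#' @export
predictOutcomeIEEG <- function(area, resected, outcome) {
  if (missing(outcome) || length(outcome) != 1L || is.na(outcome))
    stop("missing outcome")
  outcome <- match.arg(outcome, c("seizure_free", "recurrence"))
  prediction <- if (all(area %in% resected)) "seizure_free" else "recurrence"
  label <- if (prediction == "recurrence") {
    if (outcome == "recurrence") "TP" else "FP"
  } else {
    if (outcome == "seizure_free") "TN" else "FN"
  }
  list(prediction = prediction, label = label)
}

#' Seizure-outcome prediction from residual HFO rate (ECoG)
#'
#' The post-resection channel with the highest HFO rate decides: a maximal
#' rate of at least `threshold` (1 HFO/min) flags residual HFO and predicts
#' seizure recurrence; otherwise seizure freedom.
#'
#' @param postRates numeric vector of post-resection per-channel rates
#'   (HFO/min).
#' @param threshold residual-HFO rate threshold in HFO/min.
#' @return list: `maxRate`, `prediction`.
#' @export
predictOutcomeECoG <- function(postRates, threshold = 1) {
  if (length(postRates) == 0) stop("empty rate table")
  maxRate <- max(postRates)
  list(maxRate = maxRate,
       prediction = if (maxRate >= threshold) "recurrence" else "seizure_free")
}

#' Active-epilepsy prediction from scalp HFO rates
#'
#' The median HFO rate over the electrodes of the affected hemisphere is
#' compared with a rate threshold (0.25 HFO/min): above it the recording
#' shows HFO and predicts active epilepsy (seizure frequency >= 1/month),
#' otherwise seizure freedom.
#'
#' @param rates numeric vector of affected-hemisphere channel rates
#'   (HFO/min).
#' @param threshold rate threshold in HFO/min.
#' @return list: `medianRate`, `prediction`.
#' @export
predictEpilepsyScalp <- function(rates, threshold = 0.25) {
  if (length(rates) == 0) stop("empty rate table")
  m <- median(rates)
  list(medianRate = m,
       prediction = if (m > threshold) "active" else "seizure_free")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided interval from Beta quantiles: lower bound
#' `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`), upper bound
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).  For `x = n` the
#' lower bound has the closed form `(alpha/2)^(1/n)`.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return c(lower, upper) as proportions.
#' @examples
#' round(100 * clopperPearson(6, 6))  # lower 54
#' @export
clopperPearson <- function(x, n, conf = 0.95) {
  a <- 1 - conf
  lo <- if (x == 0) 0 else qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
  c(lower = lo, upper = hi)
}

.roundHalfUp <- function(x) floor(x + 0.5)

#' Confusion metrics with exact binomial confidence intervals
#'
#' Computes sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive and
#' negative predictive values and accuracy (TP+TN)/N, each with a two-sided
#' 95% Clopper-Pearson interval on its own numerator/denominator.  Exact
#' fractions are retained; display values are percentages rounded to the
#' nearest integer (ties rounded half up).  A metric with zero denominator
#' is undefined and rendered "-".
#'
#' @param TP,TN,FP,FN non-negative counts.
#' @param conf confidence level.
#' @return data.frame of class `ConfusionSummary`: metric, x, n, value
#'   (proportion), lower, upper, pct, pctLower, pctUpper.
#' @examples
#' confusionMetrics(TP = 1, TN = 6, FP = 0, FN = 2)
#' @export
confusionMetrics <- function(TP, TN, FP, FN, conf = 0.95) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  N <- TP + TN + FP + FN
  if (N < 1) stop("N must be >= 1")
  rows <- list(
    sensitivity = c(TP, TP + FN),
    specificity = c(TN, TN + FP),
    ppv = c(TP, TP + FP),
    npv = c(TN, TN + FN),
    accuracy = c(TP + TN, N))
  out <- do.call(rbind, lapply(names(rows), function(m) {
    x <- rows[[m]][1]
    n <- rows[[m]][2]
    if (n == 0) {
      data.frame(metric = m, x = x, n = n, value = NA_real_,
                 lower = NA_real_, upper = NA_real_, pct = NA_real_,
                 pctLower = NA_real_, pctUpper = NA_real_)
    } else {
      ci <- clopperPearson(x, n, conf)
      data.frame(metric = m, x = x, n = n, value = x / n,
                 lower = ci[1], upper = ci[2],
                 pct = .roundHalfUp(100 * x / n),
                 pctLower = .roundHalfUp(100 * ci[1]),
                 pctUpper = .roundHalfUp(100 * ci[2]))
    }
  }))
  class(out) <- c("ConfusionSummary", "data.frame")
  attr(out, "counts") <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  out
}

#' @export
print.ConfusionSummary <- function(x, ...) {
  counts <- attr(x, "counts")
  cat(sprintf("ConfusionSummary (TP=%d TN=%d FP=%d FN=%d, N=%d)\n",
              counts["TP"], counts["TN"], counts["FP"], counts["FN"],
              sum(counts)))
  for (i in seq_len(nrow(x))) {
    val <- if (is.na(x$pct[i])) "-" else
      sprintf("%d (%d %d%%)", x$pct[i], x$pctLower[i], x$pctUpper[i])
    cat(sprintf("  %-12s %s\n", x$metric[i], val))
  }
  invisible(x)
}

#' Log-log regression of seizure frequency on HFO rate
#'
#' Ordinary least squares on log10-transformed pairs
#' (`log10(seizureFreq) ~ log10(rate)`) plus Spearman rank correlation on
#' the raw pairs (average ranks for ties).  Pairs with a zero (or negative)
#' rate or frequency are excluded from the log-log fit and counted.
#'
#' @param rate HFO rate in HFO/min, one value per patient/recording.
#' @param seizureFreq seizures per month.
#' @return list: slope, intercept, r2, rho, pSpearman, n, nExcluded.
#' @examples
#' r <- c(0.5, 1, 2, 4, 8)
#' rateSeizureRegression(r, 10^0.7 * r^2.27)
#' @export
rateSeizureRegression <- function(rate, seizureFreq) {
  stopifnot(length(rate) == length(seizureFreq))
  ok <- rate > 0 & seizureFreq > 0 & is.finite(rate) & is.finite(seizureFreq)
  if (sum(ok) < 3) stop("fewer than 3 usable (positive) pairs")
  lx <- log10(rate[ok])
  ly <- log10(seizureFreq[ok])
  fit <- lm(ly ~ lx)
  ct <- suppressWarnings(cor.test(rate, seizureFreq, method = "spearman"))
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noiseless fits warn
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = r2,
       rho = unname(ct$estimate), pSpearman = ct$p.value,
       n = sum(ok), nExcluded = sum(!ok))
}

#' Signal-to-noise ratio of events against their flanks
#'
#' For each event interval, the peak-to-peak amplitude inside the event
#' divided by the mean peak-to-peak amplitude of equal-length windows
#' immediately before and after it (the amplitude of the signal before and
#' after the event).  Flanks that would extend beyond the recording are
#' shrunk with a warning.
#'
#' @param x numeric vector, typically the band-filtered signal.
#' @param events data.frame with columns `start`, `end` (seconds).
#' @param fs sampling rate in Hz.
#' @return numeric vector, one SNR per event.
#' @export
snr <- function(x, events, fs) {
  n <- length(x)
  vapply(seq_len(nrow(events)), function(i) {
    i0 <- max(1L, round(events$start[i] * fs) + 1L)
    i1 <- min(n, round(events$end[i] * fs))
    len <- i1 - i0 + 1L
    p2p <- function(a, b) {
      if (a < 1L || b > n) {
        warning("flank extends beyond recording; shrinking")
        a <- max(1L, a)
        b <- min(n, b)
      }
      if (b <= a) return(NA_real_)
      max(x[a:b]) - min(x[a:b])
    }
    evp <- max(x[i0:i1]) - min(x[i0:i1])
    fl <- c(p2p(i0 - len, i0 - 1L), p2p(i1 + 1L, i1 + len))
    evp / mean(fl, na.rm = TRUE)
  }, numeric(1))
}

#' Logistic-regression baseline score on four spike trains
#'
#' The simple pre-SNN baseline: the mean firing rate (spikes/s) of each of
#' the four trains (UP ripple, DN ripple, UP fast-ripple, DN fast-ripple) is
#' computed in 45 ms windows advanced by 35 ms (10 ms overlap), and each
#' window's score is the weighted sum of the four rates using the trained
#' weights 0.0052, 0.0086, 0.00044 and 0.0031.  The binary label applies a
#' logistic threshold to the score; the published model's intercept is
#' unknown, so a zero intercept with decision point 0.5 (score > 0) is the
#' default.
#'
#' @param trains list of four [SpikeTrain-class]s or numeric time vectors, in
#'   the order UP ripple, DN ripple, UP FR, DN FR.
#' @param span recording duration in seconds.
#' @param windowMs window length (ms).
#' @param overlapMs overlap between consecutive windows (ms).
#' @param weights the four regression weights.
#' @param decision decision point on the logistic of the score.
#' @return data.frame: start, end, score, label.
#' @export
lrBaselineScore <- function(trains, span, windowMs = 45, overlapMs = 10,
                            weights = c(0.0052, 0.0086, 0.00044, 0.0031),
                            decision = 0.5) {
  stopifnot(length(trains) == 4, length(weights) == 4)
  w <- windowMs / 1000
  if (w > span) stop("window longer than recording")
  stepS <- (windowMs - overlapMs) / 1000
  starts <- seq(0, span - w, by = stepS)
  tms <- lapply(trains, function(tr)
    if (is(tr, "SpikeTrain")) spikeTimes(tr) else as.numeric(tr))
  score <- vapply(starts, function(s) {
    rates <- vapply(tms, function(tt) sum(tt >= s & tt < s + w) / w, 0)
    sum(weights * rates)
  }, numeric(1))
  data.frame(start = starts, end = starts + w, score = score,
             label = as.integer(stats::plogis(score) > decision))
}
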
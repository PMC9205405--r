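test_that("HFO rates divide counts by minutes", {
  expect_equal(hfoRate(0, 5), 0)
  expect_equal(hfoRate(12, 4), 3)
  ev <- data.frame(status = c("HFO", "rejected_artifact", "HFO"))
  expect_equal(hfoRate(ev, 2), 1)
  expect_error(hfoRate(3, 0), "minutes")
})

test_that("the HFO area takes strict exceedance of the 95th percentile", {
  expect_equal(hfoArea(c(a = 2, b = 2, c = 2)), character(0))
  rates <- c(10, rep(0, 19))
  names(rates) <- paste0("ch", 1:20)
  expect_equal(hfoArea(rates), "ch1")
  # the area shrinks (or holds) as the percentile rises
  set.seed(19)
  r2 <- runif(30)
  names(r2) <- paste0("c", 1:30)
  sizes <- vapply(c(50, 75, 90, 95), function(p) length(hfoArea(r2, p)), 0L)
  expect_true(all(diff(sizes) <= 0))
  expect_error(hfoArea(c(a = 1)), "2 channels")
})

test_that("iEEG outcome labels cross prediction with outcome", {
  # empty area is always fully resected: predict freedom
  expect_equal(predictOutcomeIEEG(character(0), c("A"), "seizure_free")$label,
               "TN")
  expect_equal(predictOutcomeIEEG(c("A"), c("B", "C"), "recurrence")$label,
               "TP")
  # fully resected area but seizures recurred: false freedom prediction
  expect_equal(predictOutcomeIEEG(c("A"), c("A", "B"), "recurrence")$label,
               "FN")
  expect_equal(predictOutcomeIEEG(c("A"), c("B"), "seizure_free")$label, "FP")
  expect_error(predictOutcomeIEEG(c("A"), c("A")), "outcome")
})

test_that("ECoG residual-rate rule thresholds at 1 HFO/min", {
  expect_equal(predictOutcomeECoG(c(0, 0, 0))$prediction, "seizure_free")
  expect_equal(predictOutcomeECoG(c(0.2, 1.3))$prediction, "recurrence")
  expect_equal(predictOutcomeECoG(c(0.9))$prediction, "seizure_free")
  expect_error(predictOutcomeECoG(numeric(0)), "empty")
})

test_that("scalp rule takes the affected-hemisphere median against 0.25/min", {
  expect_equal(predictEpilepsyScalp(c(0, 0))$prediction, "seizure_free")
  p <- predictEpilepsyScalp(c(0.1, 0.3, 0.5))
  expect_equal(p$medianRate, 0.3)
  expect_equal(p$prediction, "active")
})

test_that("Clopper-Pearson intervals match their closed forms", {
  # x = n: lower bound is (alpha/2)^(1/n) exactly
  for (n in c(1, 3, 6, 10)) {
    ci <- clopperPearson(n, n)
    expect_equal(ci[["lower"]], 0.025^(1 / n), tolerance = 1e-12)
    expect_equal(ci[["upper"]], 1)
  }
  expect_equal(clopperPearson(0, 5)[["lower"]], 0)
  # 0 < x < n: Beta-quantile definition to 1e-10
  for (n in 2:8) for (x in 1:(n - 1)) {
    ci <- clopperPearson(x, n)
    expect_equal(ci[["lower"]], qbeta(0.025, x, n - x + 1), tolerance = 1e-10)
    expect_equal(ci[["upper"]], qbeta(0.975, x + 1, n - x), tolerance = 1e-10)
  }
})

test_that("confusion metrics agree with direct formula enumeration (N <= 6)", {
  for (TP in 0:3) for (TN in 0:3) for (FP in 0:2) for (FN in 0:2) {
    if (TP + TN + FP + FN < 1 || TP + TN + FP + FN > 6) next
    cs <- confusionMetrics(TP, TN, FP, FN)
    chk <- function(metric, num, den) {
      r <- cs[cs$metric == metric, ]
      if (den == 0) expect_true(is.na(r$value))
      else expect_equal(r$value, num / den)
    }
    chk("sensitivity", TP, TP + FN)
    chk("specificity", TN, TN + FP)
    chk("ppv", TP, TP + FP)
    chk("npv", TN, TN + FN)
    chk("accuracy", TP + TN, TP + TN + FP + FN)
  }
})

test_that("a perfect classifier scores 100 on every defined metric", {
  cs <- confusionMetrics(TP = 5, TN = 5, FP = 0, FN = 0)
  expect_true(all(cs$pct == 100))
  expect_true(all(cs$upper == 1))
})

test_that("zero-denominator metrics render as '-' in the cohort report", {
  cs <- confusionMetrics(TP = 0, TN = 6, FP = 0, FN = 3)
  expect_true(is.na(cs$value[cs$metric == "ppv"]))
  rep <- cohortReport(detector = cs)
  expect_equal(unname(rep["ppv", 1]), "-")
  expect_match(rep["specificity", 1], "^100 \\(54 100%\\)$")
})

test_that("log-log regression recovers a noiseless power law exactly", {
  r <- c(0.5, 1, 2, 4, 8)
  fit <- rateSeizureRegression(r, 10^0.7 * r^2.27)
  expect_equal(fit$slope, 2.27, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.7, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$rho, 1)
  # zero rates are excluded and counted, not log-transformed
  fit2 <- rateSeizureRegression(c(r, 0), c(10^0.7 * r^2.27, 5))
  expect_equal(fit2$nExcluded, 1L)
  expect_equal(fit2$slope, 2.27, tolerance = 1e-10)
  expect_error(rateSeizureRegression(c(1, 2), c(1, 2)), "3 usable")
})

test_that("log-log slope is recovered within 0.1 under log-normal noise", {
  set.seed(23)
  n <- 100
  r <- 10^runif(n, -0.7, 0.8)
  y <- 10^(0.7 + 2.27 * log10(r) + rnorm(n, 0, 0.2))
  fit <- rateSeizureRegression(r, y)
  expect_lt(abs(fit$slope - 2.27), 0.1)
  expect_gt(fit$rho, 0.9)
})

test_that("SNR compares event peak-to-peak against equal-length flanks", {
  fs <- 2000
  t <- seq(0, 3, by = 1 / fs)
  x <- sin(2 * pi * 140 * t)
  ev <- data.frame(start = 1, end = 1.2)
  # an event identical to its surroundings has SNR ~ 1
  expect_equal(snr(x, ev, fs), 1, tolerance = 0.02)
  # quadrupling the amplitude inside the event interval gives ~ 4
  x2 <- x
  x2[t >= 1 & t < 1.2] <- 4 * x2[t >= 1 & t < 1.2]
  expect_equal(snr(x2, ev, fs), 4, tolerance = 0.02)
  expect_warning(snr(x, data.frame(start = 0.05, end = 0.25), fs), "flank")
})

test_that("LR-baseline windows score the weighted sum of firing rates", {
  # all-silent trains score zero everywhere
  silent <- lrBaselineScore(rep(list(numeric(0)), 4), span = 1)
  expect_true(all(silent$score == 0))
  expect_equal(silent$start[2] - silent$start[1], 0.035)  # 10 ms overlap
  expect_equal(silent$end[1] - silent$start[1], 0.045)
  # hand-computed score: known counts in the first window
  trains <- list(seq(0.001, 0.044, length.out = 9),   # 9 spikes -> 200 Hz
                 seq(0.001, 0.044, length.out = 9),
                 numeric(0),
                 seq(0.001, 0.044, length.out = 18))   # 18 -> 400 Hz
  sc <- lrBaselineScore(trains, span = 0.06)
  expect_equal(sc$score[1], 200 * 0.0052 + 200 * 0.0086 + 400 * 0.0031,
               tolerance = 1e-12)
  expect_error(lrBaselineScore(rep(list(numeric(0)), 4), span = 0.01),
               "window longer")
})
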
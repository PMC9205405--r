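test_that("baseline on pure band noise sits in [2, 4] sigma and is stable", {
  fs <- 2000
  set.seed(11)
  for (i in 1:3) {
    x <- filterBand(rnorm(20 * fs), bandSpec("ripple", causal = FALSE),
                    fs = fs)
    s <- sd(x)
    bl <- estimateBaseline(x, fs)
    expect_gte(bl, 2 * s)
    expect_lte(bl, 4 * s)
    b1 <- estimateBaseline(x[1:(10 * fs)], fs)
    b2 <- estimateBaseline(x[(10 * fs + 1):(20 * fs)], fs)
    expect_lt(abs(b1 - b2) / b1, 0.10)
  }
})

test_that("baseline is robust to sparse high-amplitude events (5% duty)", {
  fs <- 2000
  evs <- lapply(seq(1, 19, by = 2), function(o)
    eventSpec("ripple_hfo", o, centerFreq = 150, nCycles = 15,
              amplitudeRatio = 8))
  noise <- generateSynthetic(syntheticSpec(20, fs, seed = 12))
  withEv <- generateSynthetic(syntheticSpec(20, fs, events = evs, seed = 12))
  b0 <- estimateBaseline(filterBand(getChannel(noise$recording, 1),
                                    bandSpec("ripple"), fs = fs), fs)
  b1 <- estimateBaseline(filterBand(getChannel(withEv$recording, 1),
                                    bandSpec("ripple"), fs = fs), fs)
  expect_lt(abs(b1 - b0) / b0, 0.15)
  expect_error(estimateBaseline(rep(0, 3 * fs), fs), "all-zero")
})

test_that("constant signals produce no spikes; degenerate delta is rejected", {
  st <- admEncode(rep(2.5, 4000), admParams(0.5, 0), baseline = 1, fs = 2000)
  expect_equal(nSpikes(st), 0L)
  expect_error(admEncode(rnorm(4000), admParams(0.5), baseline = 0, fs = 2000),
               "baseline")
})

test_that("a ramp through 10 thresholds gives exactly 10 UP spikes", {
  fs <- 10000
  delta <- 0.1
  x <- seq(0, 10.5 * delta, length.out = fs)  # 1 s ramp through 10 thresholds
  st <- admEncode(x, admParams(1, 0), baseline = delta, fs = fs)
  expect_equal(sum(spikePolarity(st) == "UP"), 10L)
  expect_equal(sum(spikePolarity(st) == "DN"), 0L)
})

test_that("the conversion refractory bounds every inter-spike interval", {
  set.seed(13)
  fs <- 10000
  x <- filterBand(rnorm(2 * fs), bandSpec("FR", causal = FALSE), fs = fs)
  bl <- estimateBaseline(x, fs)
  st <- admEncode(x, admParams(0.3, 300e-6), bl, fs)
  expect_gt(nSpikes(st), 100)
  expect_gte(min(diff(spikeTimes(st))), 300e-6 - 1e-12)
})

test_that("encode-decode tracks a smooth signal within delta at zero refractory", {
  fs <- 10000
  t <- seq(0, 1, by = 1 / fs)
  x <- 3 * sin(2 * pi * 5 * t) + sin(2 * pi * 11 * t)
  delta <- 0.05
  st <- admEncode(x, admParams(1, 0), baseline = delta, fs = fs)
  xhat <- admDecode(st, delta, fs, span = length(x) / fs, init = x[1])
  expect_lte(max(abs(x - xhat)), delta + 1e-9)
  # empty train decodes to a constant
  empty <- SpikeTrain(numeric(0), character(0), span = 1)
  expect_true(all(admDecode(empty, delta, fs, span = 1, init = 2) == 2))
})

test_that("a refractory period lets fast ramps escape the delta bound", {
  fs <- 10000
  delta <- 0.05
  refr <- 5e-3
  t <- seq(0, 0.5, by = 1 / fs)
  x <- t * (3 * delta / refr)     # slope 3 delta per refractory
  st <- admEncode(x, admParams(1, refr), baseline = delta, fs = fs)
  xhat <- admDecode(st, delta, fs, span = length(x) / fs, init = x[1])
  expect_gt(max(abs(x - xhat)), delta)
})

test_that("encoding is scale-invariant when signal and baseline scale together", {
  set.seed(14)
  x <- filterBand(rnorm(8000), bandSpec("ripple", causal = FALSE), fs = 2000)
  a <- admEncode(x, admParams(0.5, 300e-6), baseline = 2, fs = 2000)
  b <- admEncode(100 * x, admParams(0.5, 300e-6), baseline = 200, fs = 2000)
  expect_equal(spikeTimes(a), spikeTimes(b))
  expect_equal(spikePolarity(a), spikePolarity(b))
})

test_that("raising the threshold never increases the spike count", {
  set.seed(15)
  for (i in 1:3) {
    x <- filterBand(rnorm(6000), bandSpec("ripple", causal = FALSE), fs = 2000)
    counts <- vapply(c(0.2, 0.35, 0.5, 0.8, 1.2), function(fr)
      nSpikes(admEncode(x, admParams(fr, 300e-6), baseline = 2.5 * sd(x),
                        fs = 2000)), 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("ISI quartiles follow the linear-interpolation convention", {
  # regular train: Q1 = Q3 = period
  st <- SpikeTrain(seq(0.01, 0.1, by = 0.01), rep("UP", 10), span = 1)
  w <- data.frame(start = 0, end = 1, class = "hfo")
  s <- isiStats(st, w)
  expect_equal(s$q1Ms, 10)
  expect_equal(s$q3Ms, 10)
  # ISIs {1,2,3,4,5} ms -> Q1 = 2 ms, Q3 = 4 ms
  st2 <- SpikeTrain(cumsum(c(0.01, 1:5 / 1000)), rep("UP", 6), span = 1)
  s2 <- isiStats(st2, w)
  expect_equal(s2$q1Ms, 2)
  expect_equal(s2$q3Ms, 4)
  # an empty class is flagged absent, not zero
  s3 <- isiStats(st2, data.frame(start = c(0, 0.5), end = c(0.3, 0.6),
                                 class = c("hfo", "noise")))
  expect_equal(s3$n[s3$class == "noise"], 0L)
  expect_true(is.na(s3$q1Ms[s3$class == "noise"]))
})

test_that("UP-DN cycles follow the run-based grouping", {
  expect_equal(updnCycles(SpikeTrain(1:4 / 1000, rep("UP", 4)))$nCycles, 0L)
  alt <- SpikeTrain(1:6 / 1000, c("UP", "DN", "UP", "DN", "UP", "DN"))
  expect_equal(updnCycles(alt)$nCycles, 3L)
  runs <- SpikeTrain(1:6 / 1000, c("UP", "UP", "DN", "UP", "DN", "DN"))
  expect_equal(updnCycles(runs)$nCycles, 2L)
  # duration measured first-UP to last-DN
  expect_equal(updnCycles(runs)$meanCycleMs, mean(c(3 - 1, 6 - 4)))
})

test_that("spike-train ISI statistics on iEEG-like input land near the ripple IQR regime", {
  out <- ieegScene(21, duration = 30)
  trains <- encodeScene(out$recording, "iEEG")
  gt <- out$groundTruth
  hfoW <- data.frame(start = gt$start, end = gt$end, class = "hfo")
  up <- SpikeTrain(spikeTimes(trains$ripple, "UP"),
                   rep("UP", length(spikeTimes(trains$ripple, "UP"))),
                   span = trains$ripple@span)
  s <- isiStats(up, hfoW)
  # qualitative reproduction of the 0.5-6.3 ms interquartile window
  expect_gte(s$q1Ms, 0.2)
  expect_lte(s$q3Ms, 12)
})
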
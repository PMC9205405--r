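# snnHFO

Detection of high-frequency oscillations (HFO) in EEG with spiking neural
networks.

HFO — oscillatory EEG events of at least four cycles between 80 and 500 Hz
that clearly stand out of the background — are biomarkers of epileptogenic
brain tissue. Channels with high HFO rates delineate candidate resection
areas in intracranial EEG (iEEG), flag residual epileptogenic cortex in
intraoperative ECoG, and track epilepsy severity in scalp EEG. snnHFO is
aimed at researchers in computational neurophysiology and neuromorphic
engineering who want a fully automated, hardware-faithful HFO detector they
can dissect stage by stage and validate on annotated synthetic data.

## The method

Each bipolar channel runs through a pipeline whose stages all have direct
analog-circuit counterparts:

1. **Band-pass filtering** — causal second-order Butterworth filters in the
   ripple band (80–250 Hz), fast-ripple band (250–500 Hz), and, for scalp
   EEG, an above-HFO artifact band (500–900 Hz).
2. **Asynchronous delta modulation (ADM)** — a running reference tracks the
   filtered trace x(t); whenever x rises (falls) more than δ above (below)
   the reference, an UP (DN) spike is emitted and the reference steps by ±δ.
   δ is a fixed fraction (0.3–0.5 per modality band) of an automatically
   estimated background baseline amplitude, so the pipeline is scale
   invariant; a refractory period (300 µs, 1 ms for scalp) bounds the spike
   rate. With zero refractory the reconstruction error of the spike code is
   provably ≤ δ.
3. **Spiking neural network** — the UP/DN trains drive 256 leaky
   integrate-and-fire neurons through excitatory/inhibitory exponential
   synapses (membrane τ = 15 ms). Per neuron, the excitatory synaptic time
   constant is drawn from 3–6 ms and the inhibitory one is 0.1–1 ms shorter,
   with weights of 1 or 2: an ensemble of weak classifiers tuned to
   different HFO frequency content. For ECoG and scalp EEG a dis-inhibitory
   circuit (weights 3 and 2.5, τ 5/20/5 ms) tonically suppresses the layer
   and releases it only during sustained in-band activity, rejecting sharp
   transients; scalp EEG adds a parallel artifact-detection network on the
   >500 Hz band whose spikes veto coincident detections.
4. **Event marking** — any 15 ms window containing a second-layer spike is
   marked; consecutive marked windows concatenate into one HFO.
5. **Clinical rules** — per-channel rates (HFO/min) feed the modality
   decision rules: the 95th-percentile "HFO area" versus the resected area
   (iEEG), residual HFO at ≥ 1 HFO/min after resection (ECoG), and a median
   affected-hemisphere rate > 0.25 HFO/min (scalp), with exact
   Clopper–Pearson 95 % intervals on all confusion metrics, log–log
   rate/seizure-frequency regression, and SNR measurement.

A deterministic synthetic-EEG generator plants Tukey-windowed oscillations,
biphasic sharp transients and >500 Hz artifacts at controlled SNR in 1/f
background, with ground-truth annotations, so every stage is testable
without patient data.

## Worked example

Plant four fast-ripple HFO (SNR 7.3, the high-density ECoG regime) and one
sharp transient in 50 s of 1/f background at 2 kHz, then run the ECoG
detector (core network + in-band artifact rejection):

```r
library(snnHFO)

evs <- c(lapply(c(5, 18, 31, 44), function(o)
  eventSpec("fr_hfo", o, centerFreq = 310, nCycles = 8, amplitudeRatio = 7.3)),
  list(eventSpec("sharp_transient", 25, amplitudeRatio = 8)))
sim <- generateSynthetic(syntheticSpec(50, 2000, background = "pink",
                                       events = evs, seed = 7))
det <- runDetection(sim$recording, modalityPreset("ECoG"), seed = 1)
det$events
#>   channel  start    end nSpikes status
#> 1     ch1  5.010  5.040      47    HFO
#> 2     ch1 18.015 18.030      36    HFO
#> 3     ch1 31.005 31.035      61    HFO
#> 4     ch1 44.010 44.040      34    HFO
```

All four planted oscillations are recovered at their planted onsets (5, 18,
31 and 44 s), each spanning one or two 15 ms marking windows and carrying
the number of second-layer spikes that marked it; the high-amplitude
transient at 25 s is suppressed by the dis-inhibitory circuit and produces
no event. The channel's HFO rate is `4 / (50/60) = 4.8` HFO/min — above the
1 HFO/min residual threshold, so on a post-resection recording this channel
would predict seizure recurrence.

Confusion metrics reproduce reference worked examples exactly, e.g. a
nine-patient iEEG outcome table:

```r
confusionMetrics(TP = 1, TN = 6, FP = 0, FN = 2)
#> ConfusionSummary (TP=1 TN=6 FP=0 FN=2, N=9)
#>   sensitivity  33 (1 91%)
#>   specificity  100 (54 100%)
#>   ppv          100 (3 100%)
#>   npv          75 (35 97%)
#>   accuracy     78 (40 97%)
```

A command-line front end (`inst/scripts/hfo.R`) wraps the same functions as
`simulate`, `detect`, `sweep` and `report` verbs for shell use.

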
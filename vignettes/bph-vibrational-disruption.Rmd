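---
title: "Modelling vibrational courtship disruption in the brown planthopper"
author: "bphdisrupt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vibrational courtship disruption in the brown planthopper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bphdisrupt)
```

## The biological problem

The brown planthopper (BPH, *Nilaparvata lugens*) is a major rice pest that
communicates by substrate-borne vibration: males and females exchange
courtship signals through the rice stem, and males locate females by their
replies. Because these signals are highly species-specific, broadcasting an
artificial signal that masks or confuses them is a candidate physical pest
control: if a male can no longer recognize the female's call, courtship — and
eventually mating — is disrupted without pesticides.

`bphdisrupt` models this screening problem end to end at the desk scale:

1. **Signal synthesis** — parametric generators for the three natural BPH
   signal classes, serving both as a stand-in for recorded waveforms (none
   are publicly deposited) and as ground truth for the estimators.
2. **Disruptive signals** — the seven-candidate screening set: pure tones
   (PT) at 150/225/300 Hz, continuous pulse signals (CPS) at a 22 Hz pulse
   rate with the same three carriers, and 0 dBW white Gaussian noise (WGN).
3. **Feature extraction** — main vibration frequency (MVF), pulse rate (PR)
   and multi-part segmentation, behind a Chebyshev band-pass front end.
4. **Playback experiments** — the active-reply-period protocol, a seeded
   behavioral simulator, reply-rate/reply-delay summaries, and
   Kruskal–Wallis plus Dunn rank statistics.

## Signal model

All natural signals are built from one primitive, the *continuous pulse
train*: a sine carrier at the MVF $f_c$, amplitude-modulated by a periodic
triangular envelope repeating at the pulse rate $f_p$,

$$x(t) = A \, \mathrm{tri}_{f_p, d}(t)\, \sin(2 \pi f_c t),$$

where $\mathrm{tri}_{f_p,d}$ rises linearly 0→1 and falls 1→0 over the
leading fraction $d$ (the duty cycle) of each period $1/f_p$ and is 0
otherwise. The oscillograms of the recorded signals show this shape but no
envelope equation is published; the triangular "filling" is the same
construction used for the artificial CPS, so it is reused for the natural
classes. The default duty of 0.8 reproduces the dense, nearly-continuous
look of the recorded trains while leaving a visible inter-pulse dip.

Per-individual parameters vary across animals. The generators draw them from
normal distributions with the reported class moments:

| class | part | carrier (Hz) | pulse rate (Hz) |
|---|---|---|---|
| female courtship | whole signal | 236 ± 43 | 23 ± 2 |
| male courtship | b (continuous train) | 255 ± 24 | 82 (mean only) |
| male competition | a (continuous train) | 281 ± 46 | 82 (assumed) |

Draws are truncated at ±3 sd (a symmetric truncation, so means are
preserved) and re-drawn until the carrier exceeds twice the pulse rate, so
each pulse contains several carrier cycles. For the competition class this
floor (164 Hz at the default 82 Hz pulse rate) slightly exceeds the −3 sd
point of Normal(281, 46), pulling the realized mean up by roughly 0.7 Hz — a
documented property of the clipping rule, well inside the population spread.
The female MVF is quoted as 234 Hz in one place and 236 ± 43 Hz in the
results; the generator uses 236. The 82 Hz male pulse rate appears only as a
mean, so its sd defaults to 0 and both male values are configurable.

Male courtship signals have three parts — (a) 3–10 irregular pulses, (b) the
continuous train, (c) 0–5 wide pulses — and competition signals two: (a) the
train, (b) 2–4 short pulses. Counts are drawn uniformly over these observed
ranges. "Irregular", "wide" and "short" are only qualitative in the source,
so the generator fixes: irregular pulses have amplitudes uniform in
[0.3, 1.0] of the train amplitude and inter-pulse gaps uniform in
[20, 80] ms; wide pulses are 3× the train pulse width and short pulses
0.5×. Background noise is additive white Gaussian at 20 dB SNR by default
(recording-noise statistics are unreported). Every generator attaches the
drawn parameters and 0-based half-open part boundaries as ground truth
(`signal_truth()`), which is what makes the estimator tests closed-loop.

## Feature extraction

**Band-pass front end.** The recording hardware used a sixth-order Chebyshev
active band-pass filter; `bandpass_filter()` emulates it digitally as a
Chebyshev type-I design (`signal::cheby1`) applied forward–backward
(zero-phase), so segmentation boundaries are not delayed — the analog
original is causal, a deliberate deviation. The corner frequencies are not
published; the default band (100, 500) Hz with 0.5 dB ripple covers all
reported carriers ±3 population sd with margin. The design's magnitude
response is validated against the closed-form Chebyshev formula after
bilinear prewarping and the lowpass→bandpass transform.

**MVF.** The dominant FFT-magnitude bin within the analysis band, with the
transform zero-padded to the next power of two ≥ 8× the signal length and
the peak refined by quadratic interpolation over its three bins; exact ties
break toward the lowest frequency. On 1–2 s signals this localizes tones to
well under 0.01 Hz, far below the between-individual spread.

**Pulse rate.** The amplitude envelope (analytic-signal magnitude via an FFT
Hilbert transform; a rectify-and-smooth alternative is selectable) is
mean-removed and its spectrum searched in (5, 60) Hz with the same peak
interpolation. Signals whose envelope modulation depth (sd/mean) is below
0.05 are treated as unmodulated and return `NA` — a pure tone has no pulse
rate.

**Segmentation.** Pulses are detected where the smoothed envelope exceeds
20% of its 95th percentile, with detections separated by gaps under 10 ms
merged and detections narrower than 1 ms discarded. At duty 0.8 the
continuous train's internal gaps (≈2.4 ms at 82 Hz) fall below the merge
hysteresis, so the train coalesces into the single longest envelope block;
discrete pulses before that block form part a and pulses after it part c
(male courtship) or part b (competition). This positional rule replaces a
width/interval classification and is robust precisely because the duty
cycle guarantees the train merges. The train's own pulse count is reported
as `NA` — its pulses are deliberately not resolved; `estimate_pulse_rate()`
measures the train. The thresholds are heuristics chosen once; they are part
of the method, not fitted to any outcome.

## The playback experiment model

The screening protocol is encoded in `protocol_config()`: a male is in the
active reply period (ARP) if it replied within 10 s twice in a row
(`check_arp()`), and responses are observed for 45 s after playback.
`table1_screening()` carries the published per-condition counts, rates and
delay moments; reply rates are always recomputed from the counts
(`reply_rate()`, 1-decimal percentages). One published row (PT 225 Hz) is
internally inconsistent — 17 replies out of 42 tests is 40.5%, not the
printed 33.3% — and is flagged; analyses here derive from the counts.

`simulate_experiment()` is the synthetic stand-in for live insects: each
trial is an independent Bernoulli reply with the condition's probability
(subjects were discarded after testing, so no repeated-measures correlation
is modelled), and repliers draw delays from a normal distribution truncated
to (0, 45] s with the published mean and sd (a moment-matched lognormal is
available behind a flag). Note the truncation shifts the realized mean
slightly above the nominal one for small means; tests compare against the
truncated-normal's implied mean.

Reply delays are compared across the eight conditions with a Kruskal–Wallis
test implemented directly from the rank-sum formula on midranks with tie
correction, and Dunn's pairwise z on pooled midranks. No multiplicity
adjustment is applied by default because the published pairwise p-values do
not state one; Bonferroni and Holm are available. The published overall
statistic (H = 19.550 on the real delays) is not reproducible because the
raw delays are unpublished; the package's statistics are instead validated
against `stats::kruskal.test`, an exact-permutation oracle at small n, an
independent transcription of Dunn's formula, and the algebraic identity
z² = H for two groups.

## What the synthetic data do and do not show

The generators emulate the *parametric statistical structure* of the
recorded signals — class-level frequency and pulse-rate distributions, part
counts, additive noise — not the recorded waveforms themselves. Passing
recovery tests therefore demonstrates that the estimators are unbiased and
precise *under the stated model* (triangular envelopes, stationary carriers,
white noise). Real recordings add plant filtering and attenuation, amplitude
drift, overlapping callers and non-white noise, none of which are modelled
(plant transmission is explicitly out of scope). Likewise the behavioral
simulator reproduces the published per-condition rates and delay moments by
construction; it cannot validate the biology, only the analysis pipeline
around it.

## Problem sizes and numerical choices

The package's own validation uses: pointwise oracles at float tolerance for
the deterministic synthesizers; n = 10 000 draws for population-moment
recovery (3 standard errors); corpora of n = 2000 signals per class for
estimator-level recovery of the class means; 200 seeded signals for
segmentation-boundary recovery (≥90% of boundaries within 50 ms); and
n = 10 000 trials per condition for simulator fidelity (3 binomial standard
errors). Signals default to 8 kHz sampling — every frequency of interest is
below 500 Hz, so this is a comfortable 8× Nyquist margin with small files —
and 2 s syllables (the published protocol plays "one syllable at a time"
without a printed duration). WAV output is 32-bit float by default so disk
round trips are exact at float precision.

## A worked run

```{r, eval = FALSE}
out <- run_replication(tempfile("bph_run"), seed = 7)
out$corpus_summary$summary     # per-class MVF / PR, mean +/- sd
out$condition_summary          # screening-table analogue
out$report                     # disruption per condition, KW + Dunn
```

`run_replication()` chains the whole pipeline — corpus, feature extraction,
class summary, the seven disruptors, simulated screening, statistics and a
JSON report — and is bit-reproducible under a fixed seed.

## Known limitations

- No plant-transmission or transducer model; amplitudes are dimensionless.
- The "uniform intensity" of signal mixing is interpreted as equal RMS (the
  published description does not define its intensity measure); a peak-equal
  option exists.
- Segmentation assumes the generator's part structure (one dominant
  continuous block); heavily degraded or overlapping signals are out of
  scope.
- Qualitative behavioral modes of searching males are not modelled.
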
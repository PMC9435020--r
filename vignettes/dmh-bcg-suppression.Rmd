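---
title: "Suppressing ballistocardiogram artifacts by dynamic modeling of heartbeats"
author: "dmhbcg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suppressing ballistocardiogram artifacts by dynamic modeling of heartbeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmhbcg)
```

## The problem

EEG recorded inside an MRI scanner is contaminated by the ballistocardiogram
(BCG): with every heartbeat, cardiac-driven motion of the head and electrodes
in the static field, and the Hall voltage of pulsatile blood flow, induce
deflections of roughly 150–200 µV lasting about a second — one to two orders
of magnitude above the neural signals of interest (~1–10 µV). The artifact's
shape, timing, and amplitude drift from beat to beat, which is what defeats
static template subtraction. During image acquisition a second, much larger
contaminant is present: the gradient artifact (GA) induced by gradient-coil
switching, which is TR-periodic and handled upstream.

## The model

Let $s_\mathrm{EKG}(t)$ be the simultaneously recorded EKG and let detected
R peaks split the timeline into cardiac cycles. Every sample between the
first and last R peak gets cardiac coordinates $(m, \varphi)$: cycle index
and latency in samples since that cycle's R peak. The cardiac dynamical
state at $(m, \varphi)$ is represented by a delay embedding of the EKG,

$$k^m(\varphi) = \big(s_\mathrm{EKG}(t_m+\varphi),\,
  s_\mathrm{EKG}(t_m+\varphi+\tau),\,\dots,\,
  s_\mathrm{EKG}(t_m+\varphi+(e-1)\tau)\big),$$

with embedding dimension $e$ and lag $\tau$. Stacking $k^m(\varphi)$ over
cycles gives a manifold per latency. For a query cycle $m$, the $n$ cycles
$m_1,\dots,m_n$ with the smallest Euclidean distances
$d_{m_1}\le\dots\le d_{m_n}$ to $k^m(\varphi)$ are its dynamical neighbors,
weighted by

$$u_i = e^{-d_{m_i}}/e^{-d_{m_1}} = \exp(d_{m_1}-d_{m_i}), \qquad
  w_i = u_i \Big/ \sum_i u_i,$$

and the BCG at $(m,\varphi)$ is modeled as the weighted EEG at the same
latency in those neighbors,

$$\hat s_\mathrm{EEG}^m(\varphi) = \sum_{i=1}^n w_i\,
  s_\mathrm{EEG}^{m_i}(\varphi), \qquad
  s^\mathrm{clean}_\mathrm{EEG}(t) = s_\mathrm{EEG}(t) - \hat s_\mathrm{EEG}(t).$$

Because the estimate is interpolated from *other* cardiac cycles at the same
cardiac latency, it carries the cycle-locked artifact but not the neural
activity specific to time $t$ (provided that activity is asynchronous with
the heartbeat). Only this linear interpolation is used; no nonlinear scheme
is attempted.

### Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `e` | embedding dimension | 8 | samples of EKG describing the state |
| `tau` | lag (samples @ 500 Hz) | 10 | 20 ms |
| `n` | neighbor count | 10 | convex combination size |
| `kernel` | weight law | `exp_diff` | see below |
| `exclusion_radius` | cycles excluded around the query | 1 | see below |

The defaults $e=8$, $\tau=10$, $n=10$ sit mid-grid of the stability sweep
($n \in \{5,10,15\}$, $e \in \{6,8,10\}$, $\tau \in \{7,10,13\}$) that the
acceptance suite exercises; recovered evoked power varies by less than a
factor of two across that grid on synthetic sessions.

### Numerical and design choices

* **Weight kernel.** The kernel formula is typeset ambiguously in the
  literature this follows; `exp_diff` reads it as
  $u_i=e^{-d_{m_i}}/e^{-d_{m_1}}$, which gives $u_1 = 1$ and stays finite
  when $d_{m_1}=0$. The simplex-projection convention
  $u_i=\exp(-d_{m_i}/d_{m_1})$ is available as `kernel = "sugihara"`, with
  uniform weights over all zero-distance neighbors when $d_{m_1}=0$.
* **Self-exclusion.** The query cycle must not be its own neighbor
  (otherwise $d=0$ and the subtraction is identically zero). The default
  `exclusion_radius = 1` also drops the two adjacent cycles so that slow
  neural activity cannot leak into its own artifact model. The estimate at
  cycle $m$ never reads EEG from cycles $m-1, m, m+1$: neighbors whose
  continuous-timeline read sample falls inside that zone are dropped too.
* **Latency convention.** $\varphi$ runs over $[0, RR_m)$ per cycle; the
  neighbor's EEG is read at $t_{m_i}+\varphi$ on the continuous timeline
  even when $\varphi$ exceeds that neighbor's RR interval, avoiding
  arbitrary truncation for short cycles. Samples outside any complete cycle
  (before the first or after the last R peak) get a zero estimate and are
  flagged in a coverage mask.
* **Distances** are plain Euclidean in µV on the 1–50 Hz, 500-Hz
  preprocessed EKG (the same preprocessing as the EEG, so `tau` is defined
  on the processing timeline). Optional z-scoring (`zscore_ekg`) is off by
  default. Ties in distance are broken by ascending cycle index, making the
  whole path deterministic.
* **One search serves all channels.** The manifold is built from the EKG
  alone, so neighbor sets and weights are channel-independent and computed
  once per $(m, \varphi)$.
* **QRS detection** follows the classic adaptive-threshold
  derivative/squaring/integration design: 5–15 Hz detection band,
  150-ms integration window, 200-ms refractory period, T-wave rejection by
  slope within 360 ms, search-back at 1.66× the running mean RR. Detections
  are refined to the extremum of the demeaned EKG within ±50 ms; a larger
  candidate inside the refractory window supersedes the previous detection
  (the band-passed QRS has a leading sidelobe that can fire first).
  Detection is polarity- and offset-invariant.

## Baselines and upstream steps

**OBS** extracts heartbeat-locked epochs (0.1 s before each R peak, length
1.1× the median RR), removes the across-epoch mean, and fits each epoch with
the mean epoch plus the first three principal components; the fit is
subtracted and overlapping windows are blended with a linear cross-fade.
PCA signs are fixed (largest-magnitude loading positive) for
reproducibility. `templateSuppress()` is the degenerate static variant —
global mean epoch, no fitting — and serves as the comparison floor.

**AAS** corrects the TR-periodic gradient artifact: each TR epoch is
corrected by the mean of the surrounding epochs across a seven-TR span
(excluding the epoch itself, so none of its own neural signal is subtracted
coherently; the exclusion costs nothing for a periodic artifact). Epoch and
template are aligned by a four-level subsample search (accuracies 0.2, 0.02,
0.002, 0.0002 samples, ±1 coarse sample at the first level, ± the previous
accuracy thereafter) using Fourier-domain fractional delays, which absorbs
clock-rate mismatch between the MRI and EEG systems.

The fixed processing order is AAS → zero-phase 1–50 Hz band-pass (4th-order
Butterworth applied forward–backward) → downsampling to 500 Hz → QRS
detection → DMH or OBS. Event indices are rescaled on resampling with
half-away-from-zero rounding. All sample indices in the package are 1-based,
R's native convention; the time of sample $i$ is $(i-1)/f_s$.

## Evaluation

SSVEP epochs span −200 to +1000 ms around stimulus onset; each trial and
channel is linearly detrended, and trials whose post-detrend absolute
maximum across EEG channels exceeds 700 µV are rejected. The evoked response
(trial average) is transformed with complex Morlet wavelets of 5 cycles
($\sigma_t = 5/2\pi f$, L2-normalized); the SSVEP readout is mean 15-Hz
power over +0.2 to +1.0 s averaged across O1, O2, Oz. Noise normalization
divides power per channel and frequency by the baseline-interval standard
deviation. Channel-level detection is quantified by an ROC threshold sweep
with trapezoid AUC (the original analysis sweeps cortical source locations;
source modeling is out of scope here, so the unit is a channel with the
generator's occipital mask as truth). The bootstrap comparison (100
resamples of each group mean, then a two-sample t-test between the bootstrap
distributions) is implemented exactly in that form even though bootstrap
draws violate the t-test's independence assumptions — it is kept faithful to
the evaluation tradition rather than statistically idealized.

## The synthetic generator

`composeRecording()` builds a 32-channel, 500-Hz session with stored ground
truth so every stage is testable without human data:

* **EKG / RR model:** beat intervals are the mean RR (1.0 s) plus AR(1)
  jitter (SD 0.05 s, lag-one correlation 0.4) plus sinusoidal respiratory
  modulation (0.02 s at 0.25 Hz) — not a full cardiovascular model, but
  enough to create manifold structure. Beats are sums of Gaussian P/Q/R/S/T
  waves; R and T amplitudes and the T latency vary deterministically with
  the beat's RR deviation and respiratory phase, and a respiratory baseline
  wander is added, so the EKG morphology carries the state that drives the
  artifact.
* **BCG:** per beat, a damped two-oscillation waveform with a faster 13-Hz
  ripple riding on it (so the artifact spectrum overlaps the EEG bands of
  interest, as real BCG does), starting 0.21 s after the R peak, ~1 s long,
  with a fixed polarity-reversing topography.
  Amplitude and time scale are deterministic functions of the same RR/resp
  state (squashed through a tanh so the channel maximum stays inside
  150–200 µV). This realizes, measurably, the core modeling premise: beats
  with similar EKG dynamics have similar artifacts.
* **Neural:** 15-Hz SSVEP bursts of 1 s (100-ms cosine ramps, 5 µV,
  weighted toward occipital channels) at onsets spaced ≥ 2 s, on top of 1/f
  (spectrally shaped) and white noise.
* **GA (optional):** a band-limited TR-periodic template (harmonics of 1/TR
  with 1/h roll-off) with volume-trigger events and optional per-epoch
  fractional-sample timing offsets for alignment tests.

All randomness flows from one seed; the composed EEG equals
neural + BCG + GA exactly.

What the generator does *not* emulate: real BCG topographies and
multi-component waveforms, electrode-specific motion, EKG pathologies,
head movement, non-stationary noise spectra, and any coupling between
neural activity and the cardiac cycle. Passing tests on this generator
therefore demonstrate correctness of the algorithms under the stated
artifact model, not clinical-grade performance on arbitrary human data.

## Problem sizes used in the test and acceptance suites

Unit tests run on 1–2-minute sessions; the acceptance checks use a 5-minute
session for the identical-cycle limit, five 6-minute sessions for dynamic
recovery, ten ~100-beat runs for the QRS benchmark, and one 2-minute session
for the 27-point parameter-grid sweep. These sizes were chosen as the
smallest at which the measured quantities are stable against seed choice.

## Known limitations

* DMH needs a usable EKG; failed QRS detection degrades it directly.
* Latencies near the end of the recording lack full embedding support and
  are left uncorrected (flagged in the coverage mask).
* Neighbor interpolation injects a small amount of other-cycle neural noise
  (variance bounded by $\sum_i w_i^2$ per sample); with $n=10$ this is an
  order of magnitude below the artifact variance it removes.
* The OBS epoch geometry (pre 0.1 s, 1.1× median RR) follows the
  convention of the standard plugin implementation; only the PCA order is
  prescribed by the method definition.
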
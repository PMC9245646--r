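---
title: "Methods: event-related effective connectivity of sleep slow oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-related effective connectivity of sleep slow oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(soflow)
```

## The scientific question

During non-REM sleep the cortex produces slow oscillations (SOs): large
(< 1 Hz) waves with a deep negative trough (the down-state) flanked by
up-states. `soflow` implements an event-related *effective-connectivity*
analysis of such events: around every detected SO trough it asks which EEG
channels *drive* which others, in the Granger sense, and how that directed
flow waxes and wanes with the phase of the oscillation. The downstream
statistics relate the height of the flow peaks to the scalp geometry of the
event (where the SO was, where the sender and receiver sit) and to overnight
memory improvement.

## The estimator

### MVAR model

Twelve channels (frontal F3/Fz/F4, central C3/Cz/C4, parietal P3/Pz/P4,
occipital O1/POz/O2) are modelled in each 0.5-s analysis window as a
multivariate autoregression

$$X(n) = \sum_{k=1}^{p} A_k X(n-k) + w(n), \qquad w \sim N(0, \Sigma),$$

where `A_k[i, j]` measures how strongly channel *j* at lag *k* predicts
channel *i*. `mvar()` is the fitting function and returns a classed object
with the usual `coef`, `summary`, `residuals`, `simulate` and `predict`
methods.

Two estimators are provided. Multivariate least squares over lag-stacked
regressors is used whenever the window holds more equations than unknowns
(`W - p > N p`). The default sliding-window configuration (0.5 s = 128
samples at 256 Hz, order p = 13, N = 12 channels) is *under-determined* in
that sense: 115 usable equations face 156 unknowns per channel, so no
ordinary least-squares fit exists for these windows. For that regime
`mvar()` uses block Yule–Walker estimation on biased sample autocovariances
— the standard short-window MVAR estimator in EEG connectivity toolboxes —
with escalating diagonal loading of the block-Toeplitz system, which is
structurally rank-deficient there, and the residual covariance computed
from the data rather than from the Yule–Walker identity so that it stays
positive semi-definite. The consequence, visible in all short-window
results, is a substantial estimator noise floor: single-window flow values
are dominated by finite-sample variance, and planted or physiological
effects emerge only after averaging over many events, which is exactly how
the analysis uses them. Model order can be re-selected on the data at hand
with `select_order_aic()`, which minimises the median across windows of
`log det Sigma(p) + 2 p N^2 / W`.

### GPDC

From a fitted model, `gpdc()` evaluates the spectral coefficient matrix

$$\bar{A}_{ij}(f) = \delta_{ij} - \sum_{k=1}^{p} a_{ij}(k)\,
  e^{-2\pi i f k}$$

and the generalized partial directed coherence

$$|\bar\pi_{ij}(f)| = \frac{\tfrac{1}{\sigma_i}\,|\bar A_{ij}(f)|}
 {\sqrt{\sum_{k} \tfrac{1}{\sigma_k^2} |\bar A_{kj}(f)|^2}},
 \qquad \sigma_i = \sqrt{\Sigma_{ii}}.$$

Column *j* carries the directed flow out of channel *j*; each column is
normalized so its squared entries sum to one at every frequency, and the
residual-variance weights make the measure insensitive to amplitude
differences between channels. The frequency grid is 128 uniform bins on
normalized frequency (0, 0.5] — 1-Hz spacing (1–128 Hz) at 256 Hz; the
printed statement of the grid in the source material is ambiguous and this
reading (1-Hz actual spacing) was adopted. Frequency averaging is over
$|\bar\pi|$ by default; averaging $|\bar\pi|^2$ is available via
`freq_average = "power"` (stored as the root so the downstream squaring
recovers the mean power).

### Flow quantifiers

With the averaged matrix $\pi(i, j)$, `quantifiers()` computes, for a
source channel CH (one of Fz, Cz, Pz, POz),

$$\mathrm{CH{\to}R} = \sum_{i \in R} \pi(i, \mathrm{CH})^2, \qquad
  \mathrm{CH_{outflow}} = \sum_{R \ne R(\mathrm{CH})} \mathrm{CH{\to}R},$$

i.e. flow into one sink region and total flow into all out-of-region
channels.

### Sliding windows

`so_epoch_quantifiers()` takes the 2-s epoch around a trough, slides a
0.5-s window with a 2-sample stride (7.8125 ms, reported as 7.8 ms), fits
the MVAR model per window (each window demeaned), and assigns each
quantifier value to the window's central sample — 193 windows spanning
−750 ms to +750 ms.

## Preprocessing

Connectivity channels are high-pass filtered with an order-46 Butterworth,
zero phase (forward–backward). The design is realised as a cascade of
second-order sections from an own bilinear-transform designer, because an
order-46 filter is numerically meaningless in expanded polynomial form. The
printed specification gives the stopband edge (0.5 Hz) and order only; the
−3 dB cutoff was placed at 0.6 Hz, between that stopband edge and a 0.75-Hz
passband edge, giving ≥ 70 dB single-pass attenuation at 0.5 Hz while
leaving 10-Hz content untouched to within 1 %. Zero-phase application was
chosen because trough latency and phase must not be shifted; the input is
demeaned before filtering (exact for a high-pass) and padded by odd
reflection scaled to the slowest pole's time constant, which suppresses the
long edge transients such a sharp filter otherwise produces.

Detection and phase estimation use a 0.1–4 Hz band-pass (order-4
high-pass plus order-4 low-pass from the same designer, zero phase),
applied to the *full record*, never to isolated epochs — filtering a 2-s
epoch in isolation visibly shifts the zero crossings that anchor the phase
convention.

## SO detection

Candidates are delimited by zero crossings of the band-passed trace: a
candidate begins at a positive-to-negative crossing, its negative half-wave
ends at the next negative-to-positive crossing, and the candidate ends at
the following positive-to-negative crossing. Four criteria admit an event:
trough ≤ −80 µV; peak-to-peak range ≥ 80 µV; negative half-wave duration
between 300 ms and 1 s; candidate span ≤ 10 s. The trough must lie in a
Stage-2/SWS epoch, and of two overlapping candidates the deeper trough is
kept. Two readings were fixed here as design choices: "below or equal to
80 uV" is read as a signed trough threshold (≤ −80 µV), and the
first-to-second-crossing duration is read as the negative half-wave. Note a
structural property of these printed thresholds: any candidate that
satisfies the trough criterion automatically satisfies the peak-to-peak
criterion (its span touches a zero crossing, so the range is at least
80 µV); the detector still checks both independently.

Non-SO control windows (0.5 s) are drawn uniformly from samples more than
10 s away from every trough on any channel, entirely inside Stage-2/SWS,
one per detected SO, with an explicit seed.

## Phase resampling

The SO phase is the Hilbert-transform phase of the *negated* band-passed
2-s epoch (negation puts the trough at the analytic-signal peak), unwrapped
and shifted so the trough sample is exactly phase 0; a cosine taper on the
outer 10 % of the epoch limits edge artifacts (a config option, default
on). Only the largest interval around the trough on which the phase rises
strictly, intersected with [−π, π], is used. Quantifier values at window
centres are linearly interpolated onto the fixed grid −π…π in steps of
π/64 (129 points); per-subject series are pointwise available-case means
over SOs. Peak extraction takes the maximum over (−π, 0) (prepeak) and
(0, π) (postpeak), ties to the earliest grid point, plus the values at the
five canonical phases −π, −π/2, 0, π/2, π.

## Clustering and coupling

Each detected SO yields a 22-element binary footprint (channels whose own
SO trough lies within ±400 ms). `kmeans_hamming()` is a K-modes procedure:
minimum-Hamming assignment, componentwise-majority centroid updates
(majority ties resolved to 1, assignment ties to the lower cluster index),
200 random restarts keeping the lowest total within-cluster Hamming cost.
With K = 2, the cluster with the larger mean footprint is labelled Global,
the other Local. An SO is spindle-coupled if any spindle interval on any
channel intersects ±1 s of its trough (noncoupled = 1, coupled = 2).
Footprints from all subjects and both stages are pooled by default; the
stage question (pool versus per-stage) is ambiguous in the source and
pooling was chosen.

## Statistics

Positions are coded 1–4 anterior→posterior for both the midline channels
(Fz…POz) and the regions (F…O); distances are absolute differences of these
codes, and the relative distance is `d(sink, SO) - d(source, SO)`. All
tests first drop values outside mean ± 2 SD (computed once). The SO-phase
versus non-SO comparison is a one-way ANOVA over the six conditions
followed by Tukey-adjusted contrasts against the non-SO level (the post hoc
procedure is unstated in the source; Tukey HSD was chosen, and the ANOVA is
one-way with subjects as observations rather than repeated-measures, also
an open reading). Peak heights are modelled with `lmerTest` as
`height ~ fixed terms + (1 | subject)` by REML — random intercept only —
with Satterthwaite p values. Behavioural regressions average post-peak flow
per subject within each distance group, regress the improvement ratio on
the average, and adjust p values by Bonferroni across the group family (or
Benjamini–Hochberg for the source-by-SO-channel grid variant).

## The synthetic-data generator

`simulate_subject()` builds recordings in which every downstream claim has
a known ground truth:

- **Background**: a stable VAR process across all 22 channels (default
  AR(1) diagonal 0.55, innovation SD 15 µV, weak directed coupling
  0.05 from Fz into the other analysis channels). Stability of base and
  boosted coefficient sets is checked at configuration time via the
  companion spectral radius, and the stationary covariance is testable
  against the discrete-Lyapunov closed form.
- **SO waveform**: three half-sine lobes — positive lead (up-state),
  negative half-wave whose trough hits the configured amplitude exactly
  (default −120 µV, 800-ms half-wave), positive tail — zero-mean with the
  default half-amplitude positive lobes. A triphasic shape was chosen over
  a two-lobe cycle so that the Hilbert phase is defined over the whole
  ±π range by the waveform itself rather than by background noise; with
  equal-amplitude lobes (`so_pos_amplitude_uv`) the wave is nearly
  sinusoidal and its phase advances linearly, which the planted-signature
  tests exploit.
- **Coupling modulation**: the off-diagonal VAR coefficients are multiplied
  by a gain that follows Gaussian bumps (default σ 120 ms, peak gain 8)
  centred at ±half-wave/2 — the negative half-wave edges, i.e. SO phases
  ∓π/2 — and back at baseline at the trough. Modulating the coefficients,
  rather than mixing a signal in additively, makes the planted effect
  genuinely autoregressive (Granger-causal). Two bumps rather than one flat
  window are essential: a 0.5-s analysis window smears any single
  trough-centred window flat, whereas separated bumps survive as pre/post
  peaks with a trough minimum.
- **Events**: troughs on a jittered grid (≥ 4.5 s apart) inside the first
  65 % of each alternating 5-min Stage-2/SWS block — the tail of each block
  stays SO-free so that non-SO control windows exist with the 10-s margin.
  Global events cover the whole montage, local events their seed region's
  three channels, with per-step propagation lags (default 15 ms/step).
- **Spindles**: 13-Hz Hann-windowed bursts (0.8 s, 20 µV) starting 250 ms
  after a configurable fraction of troughs.
- **Behaviour**: improvement ratios `1 + slope * standardize(flow) + noise`
  from a per-subject flow summary. In the demo study the summary is the
  subject's coupling-boost gain — the true driver of measured outflow — so
  the planted dependence is recoverable by the measured-flow regressions.

What the generator does *not* emulate: 1/f spectra beyond the VAR
background, artifacts, REM, realistic spindle morphology, or traveling-wave
dynamics beyond fixed lags. Passing tests therefore demonstrate that the
pipeline recovers known causal structure under its own model assumptions,
not that it is robust to everything real sleep EEG contains.

## Problem sizes and numerical choices

The test-suite simulations use 5–10-minute recordings, 2 SOs per minute per
source channel, and 2–6 subjects; the planted-signature analyses use
0.125-s windows with order 2 and a 32-bin frequency grid, where the
per-window fit is fully determined and the estimator floor sits well below
the planted contrast. The reference analysis configuration (0.5-s windows,
order 13, 128 bins) is the default of `run_pipeline()` and of
`so_epoch_quantifiers()`. Peak-location assertions use the mean of
per-subject peak phases: the 0.5-s-window convolution gives the
phase-domain flow bump a flat top on which a single argmax is
noise-limited, while its expected location is stable. Clustering restarts
default to 200; tests use fewer restarts on separable fixtures. Ties and
degenerate inputs are all resolved deterministically and documented on the
relevant functions (majority ties to 1, assignment ties to the lower
cluster, peak ties to the earlier grid point, all-identical footprints an
error, zero-variance epochs an error).

## Known limitations

Per-window flow at the default order is noise-floor-dominated (see above);
only averages over many events are interpretable. The Yule–Walker loading
ladder introduces a small shrinkage bias in exchange for defined fits.
Phase is estimated from a single channel's waveform; multi-channel phase
disagreement is not modelled. The behavioural stage treats subjects as
units and assumes the improvement ratio is well-defined (positive presleep
scores).
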
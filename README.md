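# soflow

Event-related effective connectivity of sleep slow oscillations (SOs) from
multichannel EEG.

During non-REM sleep, the cortex produces slow oscillations — large
(< 1 Hz) waves with a deep negative trough. `soflow` asks which channels
*causally drive* which others around each of these events, and how that
directed information flow varies with the phase of the oscillation. It is
aimed at sleep and memory researchers who have staged EEG recordings and
want an auditable, fully scriptable version of this analysis, together with
a synthetic-data generator that plants every effect the pipeline is
supposed to find.

## What it computes

1. **SO detection** — zero-crossing candidates on the 0.1–4 Hz filtered
   trace, admitted by four criteria (trough ≤ −80 µV, peak-to-peak ≥ 80 µV,
   negative half-wave 300 ms–1 s, candidate span ≤ 10 s) inside
   Stage-2/SWS, plus matched non-SO control windows > 10 s from any trough.
2. **Sliding-window MVAR/GPDC** — in each 0.5-s window (2-sample stride,
   193 windows across ±1 s of the trough), a 12-channel multivariate
   autoregression

   `X(n) = Σ_k A_k X(n−k) + w(n)`

   is fitted and converted to generalized partial directed coherence

   `|π̄_ij(f)| = (1/σ_i)|Ā_ij(f)| / sqrt(Σ_k (1/σ_k²)|Ā_kj(f)|²)`,

   a column-normalized, amplitude-robust frequency-domain measure of the
   directed flow j → i. Frequency-averaged flow is summarised as
   `CH→R = Σ_{i∈R} π(i,CH)²` (source channel to sink region) and
   `CHoutflow` (source to all out-of-region channels).
3. **Phase resampling** — Hilbert phase of the trough-centred epoch
   (trough = phase 0), quantifiers interpolated onto the fixed grid −π…π
   in steps of π/64, averaged per subject, and reduced to pre-trough and
   post-trough peak heights.
4. **Global/Local clustering and spindle coupling** — binary co-occurrence
   footprints (±400 ms over all 22 channels) clustered by K-means with
   Hamming distance (K = 2, 200 restarts); SOs flagged as spindle-coupled
   when a spindle interval intersects ±1 s of the trough.
5. **Statistics** — one-way ANOVA of outflow at the five canonical phases
   against non-SO windows with Tukey post hocs; linear mixed-effects models
   of peak height (random intercept per subject) with anterior–posterior
   distance codings; and distance-stratified regressions of overnight
   word-pair improvement on post-peak flow, Bonferroni/FDR adjusted. All
   stages apply the mean ± 2 SD outlier rule.

## Worked example

Simulate one subject with planted slow oscillations, detect them, and
measure the directed flow around one trough:

```r
library(soflow)

cfg <- so_sim_config(duration_s = 300, so_rate = 1, seed = 42)
sim <- simulate_subject(cfg)
sim$recording
#> Sleep EEG recording: 22 channels x 76800 samples @ 256 Hz ( 5 min )
#> Hypnogram (30-s epochs): W=0 N1=0 N2=10 SWS=0 REM=0

events <- detect_sos_all(sim$recording, channels = c("Fz", "Cz", "Pz", "POz"))
nrow(events)
#> [1] 50
head(as.data.frame(events)[, c("channel", "trough_time", "trough_uv",
                               "p2p_uv", "stage")], 3)
#>   channel trough_time trough_uv   p2p_uv stage
#> 1      Pz    6.691406 -123.2002 182.1158    N2
#> 2      Pz   16.488281 -122.9501 190.1131    N2
#> 3     POz   16.527344 -123.2180 192.1009    N2

hp <- highpass_connectivity(sim$recording)
qs <- so_epoch_quantifiers(hp, events$trough_time[1])
qs
#> SO-locked quantifier series: 193 windows, centers -750 to 750 ms, MVAR order 13
```

Each detected event reports its trough time and amplitude, peak-to-peak
range, zero crossings and sleep stage; `quantifier_trace(qs, "Fz", "ALL")`
returns the 193-point outflow series for source Fz (the value at each
window centre, assigned to its SO phase downstream). `run_pipeline()`
chains all stages — detection, clustering, coupling, sliding-window GPDC,
phase resampling, peak extraction and the inferential models — over a study
directory written by `make_demo()`, and writes tidy CSV tables plus a JSON
run manifest.

The default configuration (order p = 13 on 0.5-s windows) mirrors the
reference analysis; it carries a substantial finite-sample noise floor,
and flow effects are interpretable only after averaging over many
events — see the methods vignette
(`vignettes/soflow-methods.Rmd`) for the estimator details, all tunable
parameters, and what the synthetic generator does and does not emulate.

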
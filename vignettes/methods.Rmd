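---
title: "Methods: SWR features, behavioral scores, and cross-cohort prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SWR features, behavioral scores, and cross-cohort prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ripplescreen)
```

This vignette is the package's account of its methods: what each stage
computes, which parameters matter and why their defaults were chosen, what
the synthetic-data generators do and do not emulate, and where the design
was genuinely open.

## The analysis chain

The scientific object is a per-animal pair of resting-state features —
**SWR abundance** (sharp-wave-ripple events per second of qualified
immobility) and **slow-gamma power during SWRs** (z-scored 30–50 Hz power
in the 0–100 ms after event onset) — and their ability to predict composite
spatial-memory scores measured weeks later. The chain is:

1. *Preprocessing*: wide-band LFP is zero-phase band-pass filtered
   (Butterworth 0.1–300 Hz, order 4, forward–backward) and decimated to
   1 kHz; narrow bands (ripple 150–250 Hz, slow gamma 30–50 Hz) use
   equiripple FIR filters applied with group-delay compensation, the
   conventional choice when sharp transition bands matter more than
   filter order.
2. *Immobility*: tracked position (30 Hz) is Gaussian-smoothed
   (σ = 0.25 s) and converted to speed by central differences. A maximal
   run with speed < 1 cm/s lasting ≥ 30 s contributes analysis time
   starting 30 s after run onset — the animal must already have been
   still for the qualification period. Sessions with < 600 s of such
   time are excluded. The alternative reading (count the whole run) is
   available as `count_full_run = TRUE`.
3. *SWR detection*: the ripple-band envelope is the magnitude of the
   analytic signal, Gaussian-smoothed with σ = 4 ms (shorter than an
   event, longer than a carrier cycle). Baseline mean and SD are computed
   in a single pass over immobility samples, with no iterative event
   exclusion. Supra-threshold runs (mean + 5 SD) within immobility are
   merged across gaps < 15 ms, kept if ≥ 15 ms long, and extended
   outward to the nearest baseline-mean crossing. `onset_s` (the
   threshold crossing) is t = 0 for all peri-event windows; `peak_sd`
   reports the envelope peak in baseline-SD units so detection is
   invariant to overall amplitude scaling.
4. *Spectral feature*: multitaper spectrograms use a 100 ms window,
   10 ms step, time-bandwidth NW = 2 with 3 Slepian tapers (±20 Hz
   analysis bandwidth; the frequency grid at 10 Hz resolution places
   bins at 30, 40, 50 Hz inside the slow-gamma band). Each frequency bin
   is z-scored against all immobility windows of the same session and
   site — a session-level reference rather than a pre-event one, so that
   event-locked increases are measured against the animal's own resting
   spectrum. The per-event value averages bins with centers in 30–50 Hz
   over windows with centers in `(onset, onset + 100 ms]` (right-closed,
   by the window-center convention); events, then sites within a region,
   then sessions are averaged so each mouse contributes one number.
   An optional pre-event reference (`zscore_spectrogram` on a mask of
   windows −500 to −250 ms before onsets) can be built from the same
   primitives; the session reference is the default because it is
   estimable from two orders of magnitude more windows.
5. *Behavior*: Morris water maze (MWM) metrics are computed in the pool
   frame (122 cm pool, 14 × 14 cm platform, 60 s trials); active place
   avoidance (APA) metrics in a 40 cm arena rotating at 1 rpm with a
   60° room-fixed shock zone. Zone entrances use a 0.5 s hysteresis so
   camera jitter on the sector boundary is not double counted; starting
   inside the zone is not an entrance (this is what makes an animal
   riding the arena sweep the zone exactly 10 times in 600 s), but it
   gives a first-entrance latency of 0. The "opposite quadrant" is the
   90° sector antipodal to the zone center. Movement bouts are runs of
   arena-frame speed > 2 cm/s sustained ≥ 0.5 s, separated by ≥ 1 s
   below threshold; the bout metric is the net change in arc distance
   (at the animal's mean radius) from the nearest zone boundary, signed
   positive away from the zone. Net-versus-cumulative is exposed as
   `cumulative = TRUE`. The pseudoshock schedule delivers a shock at
   entrance and every 1.5 s while inside.
6. *Cohort statistics*: metrics are z-scored with the sample SD (n − 1);
   composite scores average sign-oriented z-scores over fixed metric
   sets (see `?score_definitions`); a mouse missing more than half of a
   score's metrics gets a missing score, and mice missing a feature
   (e.g., no CA3 electrode) are excluded pairwise, never imputed.
   Correlations use Pearson when both variables pass Shapiro-Wilk at
   α = 0.05 and Spearman otherwise; replication-cohort p values are
   Holm–Šidák adjusted (step-down, `1 − (1 − p)^k` with the usual
   running maximum); enrichment of significant comparisons uses the
   exact one-sided binomial upper tail at the per-comparison α. The
   screen-cohort model is an OLS fit of score on z-scored feature;
   cross-cohort transfer z-scores the feature within each cohort, which
   normalizes cohort-level differences in feature means. Leave-one-out
   robustness re-runs the full correlation (including method selection)
   on every n − 1 subset and requires p < α throughout.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| ripple band | 150–250 | Hz | canonical ripple band; 125–250 variant supported |
| detection threshold | 5 | baseline SD | high-specificity setting; 3 SD variant supported |
| minimum event duration | 15 | ms | ~3 ripple cycles; rejects envelope noise |
| merge gap | 15 | ms | envelope dips within one event are not event boundaries |
| envelope smoothing σ | 4 | ms | below event timescale, above carrier period |
| immobility threshold / qualification | 1 / 30 | cm/s, s | extended-rest definition for SWR analysis |
| session inclusion | 600 | s immobile | boundary counts as included |
| spectrogram window / step | 100 / 10 | ms | resolves 30–50 Hz with 10 Hz bins; NW = 2, K = 3 |
| SG window | (0, 100] | ms post-onset | event-locked slow-gamma window |
| velocity smoothing σ | 0.25 | s | suppresses 30 Hz tracking jitter |
| MUA threshold | 75 | µV | spike threshold on the referenced 600–6000 Hz band |
| redundancy cutoff | R² < 0.5 | — | keeps metrics that capture distinct behavior |

Filter designs not dictated by the band definitions are package choices:
Butterworth order 4 applied forward–backward; equiripple FIR with 10 Hz
transition bands and ≥ 40 dB stopband, odd tap count so the group delay is
an integer; decimation in stages of at most 10 so the anti-alias poles stay
well inside the unit circle.

## What the generators emulate — and what they do not

`simulate_lfp_session()` produces per-site 1/f (exponent 1) background
noise scaled to 30 µV, a position track realizing a mobility/immobility
schedule, and planted SWR complexes during qualified immobility: a
Gaussian-enveloped ripple burst (σ = 20 ms, carrier uniform in 150–220 Hz,
amplitude 8 × the ripple-band noise SD) on the CA1 pyramidal site, a
negative sharp wave on CA1 stratum radiatum, and a 40 Hz burst (default
40 µV) on CA3/CA1-SR/DG in the post-onset window. Event counts are drawn
Poisson at the planted rate over qualified time and placed by rejection
under a 250 ms hard-core separation — drawing a Poisson process and
thinning it would bias the planted rate low by roughly `rate × 0.25`.
Events keep a 1 s guard from immobility-block edges so peri-event windows
are never truncated.

Two ground-truth conventions deserve note. The planted *onset* is defined
as the time the event's noiseless smoothed envelope crosses the session's
own nominal 5 SD detection level (computed by the generator from its
synthesized trace). Under this convention the detector's onset error
measures timing jitter (~1–2 ms) rather than an arbitrary definitional
offset; the burst center is also stored for conventions that prefer it.
And `simulate_cohort()` plants its effect sizes at the *score* level: each
metric loads on a latent task ability with reliability 0.6 (pairwise
metric R² = 0.36, below the 0.5 redundancy cutoff), and the
ability–feature R² is raised by the known metric-averaging attenuation
factor `rel / (rel + (1 − rel)/m)` so that the population R² between the
feature and the *composite score* equals the requested target — the
score-level relationship is the quantity the analysis reports.

The generators do **not** emulate: electrode drift or artifacts, line
noise, theta/ripple interactions, replay content, state transitions other
than the block schedule, swim-speed or thigmotaxis structure in MWM
paths, or shock-evoked escape kinematics in APA. Passing tests therefore
demonstrate that the estimators recover what was planted under realistic
noise and geometry — not that the pipeline is robust to every artifact of
real recordings.

## Numerical choices and degenerate inputs

* Envelope and FIR filtering use FFT convolution padded to highly
  composite lengths; Gaussian smoothing renormalizes the truncated kernel
  at signal edges.
* DPSS tapers come from the symmetric tridiagonal commuting matrix
  (unit-normalized; sign is irrelevant for power).
* Zero-variance situations fail loudly rather than silently: constant
  envelopes, zero-variance spectrogram bins (reported by bin index),
  constant metrics, degenerate predictors.
* Missing values propagate as `NA` sentinels and are excluded pairwise;
  they never become zeros.
* Half-open `[start, end)` intervals everywhere; sample i sits at
  `(i − 1)/rate`; a sub-threshold run of exactly the qualification length
  contributes no analysis time; the 600 s inclusion boundary is inclusive.
* `detect_swrs` on an envelope with no excursions returns a zero-row
  event table, and abundance of an empty table is 0.

## Test and validation scale

The validation suite checks detection recovery on a session with ~600 s
of qualified immobility and planted 0.2 Hz events (sensitivity, 10 ms
onset accuracy, false positives); abundance over 100 seeded sessions
against the 2σ Poisson band `2·sqrt(rate/T)`; null SG calibration on a
~370-event rest session with no planted modulation plus a 4-point
amplitude grid over 10 seeds (monotone recovery); brute-force oracle
equivalence for the detector (1000 random envelopes), Holm–Šidák (1000
random vectors), and the binomial tail; composite-score contracts;
cross-cohort recovery of planted R² = 0.51 (abundance → learning,
n = 16 → 11) and 0.77 (CA3 SG → precision) over 100 cohort pairs with
type-I calibration over 500 null cohorts; exact behavioral geometry
cases; and leave-one-out robustness on constructed linear and
single-outlier datasets. These problem sizes keep each property's
sampling error comfortably below its tolerance while the full suite runs
in a few minutes on one CPU. One caveat is intrinsic: the abundance band
is exactly ±2σ of the Poisson count, so even a perfect detector passes
~95.5% of seeds per run and a 100-seed sample occasionally dips below
the 95% line; the detector's own contribution is verified separately by
the count-exact comparison against planted events.

## Known limitations and open choices

* The baseline SD includes event samples (single pass). At high event
  rates or amplitudes this inflates the SD and effectively raises the
  threshold; an iterative exclusion scheme would change detected
  durations slightly.
* The session-immobility z-reference makes the SG feature sensitive to
  the composition of rest (e.g., long quiet epochs with spindle-band
  activity would shift the reference); the pre-event reference option
  trades that for a much noisier baseline.
* The APA path-length orientation in the composite score (higher =
  better) encodes the view that active avoidance on a rotating arena
  requires continuous counter-rotation movement; passively riding the
  arena yields near-zero arena-frame path length and repeated shocks.
* The per-bout distance metric is one formalization of "distance traveled
  relative to the shock zone per movement bout"; the bout thresholds
  (2 cm/s, 0.5 s on, 1 s off) and the net-versus-cumulative choice are
  exposed as arguments.
* `read_crcns_hc26()` is a documented converter stub: public-deposit
  ingestion requires that archive's MATLAB-side containers, and the
  bundle format (`signals.f32` + `meta.json` + `position.csv`) is the
  documented target for any converter.
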